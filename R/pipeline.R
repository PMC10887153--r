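#' Pipeline configuration
#'
#' Collects the stage parameters for the end-to-end analysis. Unknown keys
#' are rejected so a config file round-trips losslessly.
#'
#' @param ... overrides of the default fields: `n_subjects`, `grid_shape`,
#'   `voxel_size`, `tr`, `fwhm`, `band`, `alpha`, `display_threshold_trial`,
#'   `display_threshold_mean`, `mask_fraction`, `pattern_consistency`,
#'   `amplitude_mean`, `amplitude_sd`, `subject_deviation_sd`, `task_overlap`,
#'   `noise_sd`,
#'   `ar1_coef`, `drift_amplitude`, `seed`, `write_maps`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    n_subjects = 9L,
    grid_shape = c(24L, 24L, 18L),
    voxel_size = 3.5,
    tr = 2.5,
    fwhm = 4.0,
    band = c(0.009, 0.08),
    alpha = 0.05,
    display_threshold_trial = NA_real_,  # NA: use critical_r(n, alpha)
    display_threshold_mean = 0.3,
    mask_fraction = 0.3,
    pattern_consistency = c(WR = 0.4, PV = 0.6, FT = 0.9),
    amplitude_mean = 1, amplitude_sd = 0.25,
    subject_deviation_sd = 0.5,
    task_overlap = 0.3,
    noise_sd = 2.5, ar1_coef = 0.3, drift_amplitude = 0.5,
    seed = 1L,
    write_maps = TRUE,
    version = as.character(utils::packageVersion("trialfc"))
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline config from a YAML file
#'
#' @param path a YAML file of key-value pairs; unknown keys are rejected.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$version <- NULL
  pc <- vals$pattern_consistency
  if (!is.null(pc)) vals$pattern_consistency <- unlist(pc)
  do.call(pipeline_config, vals)
}

#' Write a pipeline config to YAML
#'
#' @param config a [pipeline_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  vals <- unclass(config)
  # keep the task names: YAML sequences drop names of atomic vectors
  vals$pattern_consistency <- as.list(vals$pattern_consistency)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Hash of a pipeline config
#'
#' MD5 of the canonical serialized config; runs with different configs never
#' share a hash, and every output table records it.
#'
#' @param config a [pipeline_config()].
#' @return hex digest string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate, preprocess, FC mapping, similarity, identification and
#' group stages in order, writing delimited tables (and optionally NIfTI
#' maps) under `out_dir`. All numeric tables are written with fixed
#' formatting, so a rerun with the same config produces byte-identical
#' tables.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the report bundle: per-subject FC results, SC matrices,
#'   block summaries, identification results, group tables and the config
#'   hash.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  logf <- file.path(out_dir, "pipeline_log.txt")
  logc <- file(logf, open = "wt")
  on.exit(close(logc))
  logit <- function(...) writeLines(sprintf(...), logc)
  logit("# trialfc pipeline")
  logit("config_hash: %s", hash)
  for (nm in names(config))
    logit("param %s: %s", nm, paste(format(unclass(config)[[nm]]), collapse = " "))

  paradigm <- .stage("config", make_paradigm(
    onsets = default_paradigm(config$tr)$onsets,
    labels = default_paradigm(config$tr)$labels,
    tr = config$tr, run_length = 720, task_levels = TASK_LEVELS))
  # validate the band before any heavy work
  .stage("preprocess", .validate_band(config$band, config$tr))
  spec <- .stage("simulate", synthetic_spec(
    grid_shape = config$grid_shape, voxel_size = config$voxel_size,
    tr = config$tr, paradigm = paradigm,
    pattern_consistency = config$pattern_consistency,
    amplitude_mean = config$amplitude_mean, amplitude_sd = config$amplitude_sd,
    subject_deviation_sd = config$subject_deviation_sd,
    task_overlap = config$task_overlap,
    noise_sd = config$noise_sd, ar1_coef = config$ar1_coef,
    drift_amplitude = config$drift_amplitude, seed = config$seed))
  cohort <- .stage("simulate", make_cohort(spec, config$n_subjects))
  write_paradigm(paradigm, file.path(out_dir, "paradigm.txt"))

  subjects <- names(cohort)
  fc_bund <- list()
  sc_list <- list()
  block_rows <- list()
  ident <- list()
  mean_maps <- list()
  masks <- list()
  for (s in subjects) {
    b <- cohort[[s]]
    pp <- .stage("preprocess", preprocess_run(
      b$run, fwhm = config$fwhm, band = config$band,
      mask_fraction = config$mask_fraction))
    fb <- .stage("fcmap", fc_maps_for_run(pp$run, pp$mask, paradigm))
    fc_bund[[s]] <- fb
    masks[[s]] <- fb$mask
    blk <- .stage("similarity", pairwise_blocks(fb$maps, fb$mask, subject_id = s,
                                                task_levels = TASK_LEVELS))
    sc_list[[s]] <- blk$sc
    write_sc_matrix(blk$sc, file.path(out_dir, sprintf("sc_matrix_%s.tsv", s)))
    bs <- blk$summary
    bs$subject <- s
    block_rows[[s]] <- bs
    ident[[s]] <- .stage("identify", run_identification(blk$sc,
                                                        task_levels = TASK_LEVELS))
    mm <- list()
    for (lv in TASK_LEVELS) {
      sel <- fb$windows$task_label == lv
      mm[[lv]] <- .stage("group", task_mean_map(fb$maps[sel]))
      mm[[lv]]$subject_id <- s
      if (isTRUE(config$write_maps))
        write_fc_map(mm[[lv]],
                     file.path(out_dir, sprintf("%s_%s_taskmean.nii.gz", s, lv)),
                     voxel_size = config$voxel_size)
    }
    mean_maps[[s]] <- mm
    logit("subject %s: mask %d voxels, FC maps %d", s, fb$mask$n_voxels,
          length(fb$maps))
  }

  blocks <- do.call(rbind, block_rows)
  blocks$config_hash <- hash
  write_table_tsv(blocks, file.path(out_dir, "similarity_blocks.tsv"))

  rates <- do.call(rbind, lapply(subjects, function(s)
    data.frame(subject = s, task = TASK_LEVELS,
               correct_rate = as.numeric(ident[[s]]$correct_rate[TASK_LEVELS]),
               stringsAsFactors = FALSE)))
  # mean within-category R per subject/task for the association
  rates$mean_within_R <- vapply(seq_len(nrow(rates)), function(i) {
    bs <- block_rows[[rates$subject[i]]]
    bs$mean[bs$block_kind == sprintf("within %s", rates$task[i])]
  }, numeric(1))
  rates$config_hash <- hash
  write_table_tsv(rates, file.path(out_dir, "identification_rates.tsv"))

  assoc <- .stage("identify", associate_similarity_rate(rates$mean_within_R,
                                                        rates$correct_rate))
  assoc_df <- data.frame(r = assoc$r, p_value = assoc$p_value, n = assoc$n,
                         config_hash = hash)
  write_table_tsv(assoc_df, file.path(out_dir, "similarity_rate_association.tsv"))

  group_mask <- .stage("group", intersect_masks(masks))
  if (isTRUE(config$write_maps))
    write_mask_nifti(group_mask, file.path(out_dir, "group_mask.nii.gz"),
                     voxel_size = config$voxel_size)
  gblocks <- .stage("group", cross_subject_blocks(mean_maps, group_mask))
  gblocks$config_hash <- hash
  write_table_tsv(gblocks, file.path(out_dir, "group_similarity_blocks.tsv"))
  gid <- .stage("group", cross_subject_identification(mean_maps, group_mask))
  gid_df <- data.frame(task = names(gid$correct_rate),
                       correct_rate = as.numeric(gid$correct_rate),
                       config_hash = hash, stringsAsFactors = FALSE)
  write_table_tsv(gid_df, file.path(out_dir, "group_identification_rates.tsv"))

  logit("group mask: %d voxels", group_mask$n_voxels)
  logit("association r=%.4f p=%.3g n=%d", assoc$r, assoc$p_value, assoc$n)
  invisible(list(config = config, config_hash = hash, paradigm = paradigm,
                 fc = fc_bund, sc = sc_list, blocks = blocks,
                 identification = ident, rates = rates, association = assoc,
                 task_mean_maps = mean_maps, group_mask = group_mask,
                 group_blocks = gblocks, group_identification = gid))
}
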