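#' Write a BOLD run to NIfTI
#'
#' Geometry (voxel size) and the TR (stored in the 4th pixdim slot) are
#' preserved on round-trip.
#'
#' @param run a [bold_run()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(run$voxel_size, run$tr)
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D BOLD run from NIfTI
#'
#' @param path a NIfTI-1 file containing a 4D image.
#' @param tr optional TR (seconds) overriding the header's 4th pixdim.
#' @return a [bold_run()].
#' @export
read_bold_nifti <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("expected a 4D image, got %dD: %s", length(d), path), call. = FALSE)
  pd <- RNifti::pixdim(img)
  tr <- tr %||% (if (length(pd) >= 4L && pd[4] > 0) pd[4] else
    stop("TR not recorded in the NIfTI header; pass 'tr'", call. = FALSE))
  bold_run(array(as.numeric(img), dim = d), voxel_size = pd[1:3], tr = tr,
           provenance = sprintf("read %s", basename(path)))
}

#' Write a brain mask to NIfTI (0/1 values)
#'
#' @param mask a [brain_mask()].
#' @param path output path.
#' @param voxel_size voxel size in mm recorded in the header.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(mask, "brain_mask"))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  img <- RNifti::asNifti(array(as.integer(mask$inside), dim = dim(mask$inside)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::pixunits(img) <- "mm"
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a brain mask from NIfTI
#'
#' Non-0/1 values are coerced to logical with a warning.
#'
#' @param path a 3D NIfTI file.
#' @return a [brain_mask()].
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D mask, got %dD: %s", length(d), path), call. = FALSE)
  brain_mask(array(as.numeric(img), dim = d))
}

#' Write an FC map (or task-mean map) to NIfTI
#'
#' Out-of-mask voxels are written as NaN.
#'
#' @param map an `fc_map` or `task_mean_map`.
#' @param path output path.
#' @param voxel_size voxel size in mm for the header.
#' @return `path`, invisibly.
#' @export
write_fc_map <- function(map, path, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(map, "fc_map") || inherits(map, "task_mean_map"))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  img <- RNifti::asNifti(map$r)
  RNifti::pixdim(img) <- voxel_size
  RNifti::pixunits(img) <- "mm"
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Export an ideal-response regressor as one-column text
#'
#' @param ideal an [ideal_response()].
#' @param path output path; one row per volume.
#' @return `path`, invisibly.
#' @export
write_regressor <- function(ideal, path) {
  stopifnot(inherits(ideal, "ideal_response"))
  writeLines(sprintf("%.10g", ideal$samples), path)
  invisible(path)
}

# deterministic table writer: tab-separated, fixed significant digits
write_table_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2))
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]]))
      df2[[j]] <- sprintf("%.10g", df2[[j]])
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an SC matrix as labeled delimited text
#'
#' @param sc an [sc_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sc_matrix <- function(sc, path) {
  stopifnot(inherits(sc, "sc_matrix"))
  df <- data.frame(trial = rownames(sc$R),
                   matrix(sprintf("%.10g", sc$R), nrow = nrow(sc$R),
                          dimnames = list(NULL, colnames(sc$R))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
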