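#' Construct a brain mask
#'
#' @param inside 3D logical (or 0/1 numeric) array; TRUE marks brain voxels.
#' @return an object of class `brain_mask` with fields `inside`, `n_voxels`.
#' @export
brain_mask <- function(inside) {
  if (!is.array(inside) || length(dim(inside)) != 3L)
    stop("'inside' must be a 3D array", call. = FALSE)
  if (!is.logical(inside)) {
    vals <- unique(as.vector(inside))
    if (!all(vals %in% c(0, 1)))
      warning("mask values are not all 0/1; coercing non-zero to TRUE")
    inside <- array(inside != 0, dim = dim(inside))
  }
  n <- sum(inside)
  if (n == 0L) stop("mask is empty", call. = FALSE)
  structure(list(inside = inside, n_voxels = as.integer(n)), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  d <- dim(x$inside)
  cat(sprintf("brain_mask: %d of %d voxels (%d x %d x %d grid)\n",
              x$n_voxels, prod(d), d[1], d[2], d[3]))
  invisible(x)
}

# 6-connected components of a 3D logical array; returns labels (0 = background)
.connected_components3d <- function(inside) {
  d <- dim(inside)
  idx <- which(inside)
  if (length(idx) == 0L) return(array(0L, dim = d))
  pos <- arrayInd(idx, d)
  lin <- function(p) p[, 1] + d[1] * (p[, 2] - 1) + d[1] * d[2] * (p[, 3] - 1)
  edges <- list()
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(pos, 2, offs[o, ], "+")
    ok <- nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
    from <- idx[ok]
    to <- lin(nb[ok, , drop = FALSE])
    keep <- inside[to]
    edges[[o]] <- cbind(from[keep], to[keep])
  }
  edges <- do.call(rbind, edges)
  # map linear voxel indices to vertex ids 1..n
  vid <- integer(prod(d))
  vid[idx] <- seq_along(idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, t(cbind(vid[edges[, 1]], vid[edges[, 2]])))
  comp <- igraph::components(g)
  lab <- array(0L, dim = d)
  lab[idx] <- comp$membership
  lab
}

#' Build a brain mask from a mean volume
#'
#' Includes every voxel whose mean intensity is at least `fraction` times the
#' robust maximum (99th percentile) of the mean volume, then keeps only the
#' largest 6-connected component. A stand-in for anatomically informed mask
#' construction: suitable for EPI mean images and synthetic phantoms.
#'
#' @param mean_volume 3D array of per-voxel mean intensity.
#' @param fraction threshold as a fraction of the robust maximum, in (0, 1).
#' @return a [brain_mask()].
#' @export
make_brain_mask <- function(mean_volume, fraction = 0.3) {
  if (!is.array(mean_volume) || length(dim(mean_volume)) != 3L)
    stop("'mean_volume' must be a 3D array", call. = FALSE)
  stop_if_not_scalar_num(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must be in (0, 1)", call. = FALSE)
  robust_max <- stats::quantile(mean_volume, 0.99, names = FALSE)
  inside <- mean_volume >= fraction * robust_max
  if (!any(inside)) stop("mask is empty at this threshold", call. = FALSE)
  lab <- .connected_components3d(inside)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  brain_mask(array(lab == keep, dim = dim(mean_volume)))
}

#' Intersect brain masks
#'
#' @param ... `brain_mask` objects on one grid, or a list of them.
#' @return the voxelwise intersection as a [brain_mask()].
#' @export
intersect_masks <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1L]]) && !inherits(ms[[1L]], "brain_mask"))
    ms <- ms[[1L]]
  stopifnot(length(ms) >= 1L, all(vapply(ms, inherits, logical(1), "brain_mask")))
  inside <- Reduce(`&`, lapply(ms, `[[`, "inside"))
  brain_mask(inside)
}
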