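#' 3D label volume
#'
#' The common currency of the pipeline: a 3D integer lattice of cell IDs
#' (0 = extracellular medium, positive integers = cells) together with the
#' physical voxel spacing. The in-memory axis order is (x, y, z) with z the
#' slice axis, matching how stack sizes are reported ("xyz") and how
#' multi-page TIFFs are laid out (one page per z slice).
#'
#' @param lattice 3D array of non-negative integers; 0 is reserved for
#'   medium. Coerced to integer storage.
#' @param spacing numeric length-3 vector (dx, dy, dz), voxel edge lengths
#'   in micrometers; all components must be strictly positive.
#' @return An object of class `label_volume`: a list with elements
#'   `lattice` (integer array) and `spacing` (numeric(3)).
#' @examples
#' v <- label_volume(array(0L, c(4, 4, 2)))
#' dim(v)
#' @export
label_volume <- function(lattice, spacing = c(1, 1, 1)) {
  if (!is.array(lattice) || length(dim(lattice)) != 3L) {
    stop("`lattice` must be a 3D array")
  }
  if (is.double(lattice)) {
    if (any(lattice != floor(lattice), na.rm = TRUE)) {
      stop("`lattice` must contain integer label values")
    }
    storage.mode(lattice) <- "integer"
  }
  if (!is.integer(lattice)) stop("`lattice` must be integer-valued")
  if (anyNA(lattice)) stop("`lattice` must not contain NA")
  if (min(lattice) < 0L) stop("label IDs must be non-negative (0 = medium)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive voxel edge lengths")
  }
  structure(list(lattice = lattice, spacing = spacing),
            class = "label_volume")
}

#' @export
dim.label_volume <- function(x) dim(x$lattice)

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$lattice)
  ids <- label_ids(x)
  cat(sprintf("<label_volume> %d x %d x %d voxels (x,y,z), spacing %s um\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x ")))
  cat(sprintf("  %d cell label(s), %d foreground voxel(s)\n",
              length(ids), sum(x$lattice > 0L)))
  invisible(x)
}

#' Label IDs present in a volume
#'
#' @param vol a `label_volume`
#' @return sorted integer vector of the distinct nonzero labels
#' @export
label_ids <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  ids <- which(tabulate(vol$lattice, nbins = max(vol$lattice, 0L)) > 0L)
  as.integer(ids)
}

#' Per-label voxel counts
#'
#' @param vol a `label_volume`
#' @return named integer vector of voxel counts, one entry per nonzero label
#' @export
label_sizes <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  counts <- tabulate(vol$lattice, nbins = max(vol$lattice, 0L))
  ids <- which(counts > 0L)
  stats::setNames(as.integer(counts[ids]), ids)
}

# Shift a 3D array by one voxel along `axis` in direction `dir` (+1/-1),
# filling the vacated plane with `fill`. Used for face-neighbor queries.
shift3 <- function(a, axis, dir, fill = 0L) {
  d <- dim(a)
  out <- array(fill, d)
  idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (dir > 0) {
    idx_dst[[axis]] <- 2:d[axis]
    idx_src[[axis]] <- 1:(d[axis] - 1L)
  } else {
    idx_dst[[axis]] <- 1:(d[axis] - 1L)
    idx_src[[axis]] <- 2:d[axis]
  }
  if (d[axis] > 1L) {
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  out
}

# Apply f(lattice, face-shifted lattice) for all 6 face directions and
# accumulate with `+`. f must return a numeric/integer array.
face_neighbor_reduce <- function(a, f) {
  acc <- NULL
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      v <- f(a, shift3(a, axis, dir))
      acc <- if (is.null(acc)) v else acc + v
    }
  }
  acc
}

# Offsets (integer matrix, one row per offset) of the neighborhood of the
# given order: 1 = 6 faces, 2 = +12 edges (18), 3 = +8 corners (26).
neighborhood_offsets <- function(order) {
  stopifnot(order %in% 1:3)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  r2 <- rowSums(g^2)
  g[r2 > 0 & r2 <= order, , drop = FALSE]
}

# True for voxels (logical array) lying on any lattice face.
boundary_mask <- function(d) {
  m <- array(FALSE, d)
  m[c(1L, d[1]), , ] <- TRUE
  m[, c(1L, d[2]), ] <- TRUE
  m[, , c(1L, d[3])] <- TRUE
  m
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
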