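#' Names of the per-cell morphological features
#'
#' The seven features used both for target assignment and for similarity
#' scoring: volume, surface (border-voxel count), major and minor principal
#' axis length, eccentricity, volume-to-surface ratio, and sphericity.
#'
#' @export
morphology_features <- c("volume", "surface", "major_axis", "minor_axis",
                         "eccentricity", "v_over_a", "sphericity")

#' Per-cell morphological features of a label volume
#'
#' For every nonzero label:
#' \describe{
#'   \item{volume}{voxel count.}
#'   \item{surface}{border-voxel count: cell voxels with at least one of
#'     their 6 face neighbors outside the cell (the lattice edge counts as
#'     outside). This is the metric surface proxy; it is deliberately
#'     distinct from the face-contact area the simulation engine tracks
#'     for its surface constraint.}
#'   \item{major_axis, minor_axis}{principal axis lengths (in voxels) of
#'     the ellipsoid with the same second central moments as the voxel
#'     set. Each voxel is treated as a unit cube (a 1/12 variance term per
#'     axis), so a single voxel has axes of length sqrt(20/12) rather than
#'     0 and eccentricity is always < 1. For a solid ellipsoid of semi-axis
#'     a the principal second moment is a^2/5, hence axis length =
#'     sqrt(20 * eigenvalue).}
#'   \item{eccentricity}{sqrt(1 - (minor/major)^2), the 3D extension (via
#'     the extreme principal axes) of the usual 2D definition; in [0, 1).}
#'   \item{v_over_a}{volume / surface, exactly.}
#'   \item{sphericity}{pi^(1/3) * (6 * volume)^(2/3) / surface, i.e. the
#'     surface of the equal-volume sphere over the measured surface. A
#'     border-voxel count underestimates the continuum area, so digital
#'     balls score around 1.3 rather than 1; treat sphericity as a
#'     relative compactness score, not an absolute one.}
#' }
#'
#' Features are computed in voxel units and are invariant under lattice
#' translations and 90-degree lattice rotations.
#'
#' @param vol a [label_volume()]
#' @return a data frame (class `morphology_table`) with one row per label,
#'   columns `cell_id` plus [morphology_features]; empty volume gives an
#'   empty table.
#' @export
compute_features <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  lat <- vol$lattice
  d <- dim(lat)
  nmax <- max(lat, 0L)
  empty <- data.frame(cell_id = integer(0), volume = numeric(0),
                      surface = numeric(0), major_axis = numeric(0),
                      minor_axis = numeric(0), eccentricity = numeric(0),
                      v_over_a = numeric(0), sphericity = numeric(0))
  class(empty) <- c("morphology_table", "data.frame")
  if (nmax == 0L) return(empty)

  counts <- tabulate(lat, nbins = nmax)
  ids <- which(counts > 0L)

  # border voxels: any face neighbor (or the lattice edge) differs
  border <- array(FALSE, d)
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      border <- border | (shift3(lat, axis, dir, fill = -1L) != lat)
    }
  }
  surf <- tabulate(lat[border & lat > 0L], nbins = nmax)

  idx <- which(lat > 0L)
  co <- arrayInd(idx, d)
  grp <- lat[idx]
  ord <- order(grp)
  co <- co[ord, , drop = FALSE]
  grp <- grp[ord]
  splits <- split(seq_len(nrow(co)), grp)

  n <- length(ids)
  major <- minor <- numeric(n)
  for (k in seq_len(n)) {
    rows <- splits[[as.character(ids[k])]]
    pts <- co[rows, , drop = FALSE]
    ctr <- colMeans(pts)
    cen <- sweep(pts, 2, ctr)
    covm <- crossprod(cen) / nrow(pts) + diag(1 / 12, 3)
    ev <- sort(pmax(eigen(covm, symmetric = TRUE,
                          only.values = TRUE)$values, 0),
               decreasing = TRUE)
    major[k] <- sqrt(20 * ev[1])
    minor[k] <- sqrt(20 * ev[3])
  }
  ecc <- ifelse(major > 0, sqrt(pmax(1 - (minor / major)^2, 0)), 0)
  v <- as.numeric(counts[ids])
  s <- as.numeric(surf[ids])
  out <- data.frame(
    cell_id = as.integer(ids),
    volume = v,
    surface = s,
    major_axis = major,
    minor_axis = minor,
    eccentricity = ecc,
    v_over_a = v / s,
    sphericity = pi^(1 / 3) * (6 * v)^(2 / 3) / s
  )
  class(out) <- c("morphology_table", "data.frame")
  out
}
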