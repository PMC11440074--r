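#' Specification of a synthetic spheroid label mask
#'
#' The generator emulates the segmented interior of a packed tumor
#' spheroid: a roughly spherical aggregate of convex-ish, space-filling
#' cells. Cells are the Voronoi regions of jittered grid seed points
#' restricted to a digital ball, which gives controllable cell count and a
#' realistic size spread without modeling imaging at all.
#'
#' @param n_cells number of cells (>= 1)
#' @param radius ball radius in x-voxels (>= 2)
#' @param spacing voxel edge lengths (dx, dy, dz) in micrometers; the ball
#'   and the Voronoi metric live in physical units, so anisotropic spacing
#'   yields the flattened-in-z geometry of a raw confocal stack
#' @param jitter dimensionless seed-point perturbation as a fraction of the
#'   seed grid pitch (0 = perfectly regular packing)
#' @param seed integer RNG seed; identical specs give bit-identical volumes
#' @return object of class `spheroid_spec`
#' @export
spheroid_spec <- function(n_cells = 80L, radius = 20L, spacing = c(1, 1, 1),
                          jitter = 0.35, seed = 1L) {
  n_cells <- as.integer(n_cells)
  radius <- as.numeric(radius)
  stopifnot(n_cells >= 1L, radius >= 2, length(spacing) == 3L,
            all(spacing > 0), jitter >= 0)
  structure(list(n_cells = n_cells, radius = radius,
                 spacing = as.numeric(spacing), jitter = jitter,
                 seed = as.integer(seed)),
            class = "spheroid_spec")
}

#' Generate a spheroid-like 3D label mask
#'
#' Every nonzero voxel lies inside the ball of `spec$radius` (measured in
#' physical units, with the radius given in x-voxels); labels 1..n_cells
#' are the Voronoi cells of the jittered seed points. A medium margin and
#' the voxel parity are controlled by `dims`: by default the lattice is
#' `2*radius + 7` voxels in x/y (scaled by dx/dz in z) leaving a >= 3 voxel
#' medium margin so that a wall shell can be added without touching cells.
#'
#' @param spec a [spheroid_spec()]
#' @param dims optional explicit lattice dimensions (x, y, z)
#' @return a [label_volume()] carrying attribute `"seeds"` (the seed-point
#'   matrix, in physical units relative to the lattice center)
#' @export
generate_spheroid <- function(spec, dims = NULL) {
  stopifnot(inherits(spec, "spheroid_spec"))
  sp <- spec$spacing
  r_phys <- spec$radius * sp[1]
  if (is.null(dims)) {
    ext <- ceiling(r_phys / sp) # radius in voxels per axis
    dims <- as.integer(2L * ext + 7L)
  }
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  center <- (dims + 1) / 2 # lattice center, voxel coordinates

  # physical coordinates of voxel centers relative to the lattice center
  ax <- lapply(1:3, function(k) (seq_len(dims[k]) - center[k]) * sp[k])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  inside <- which(r2 <= r_phys^2)
  if (length(inside) < spec$n_cells) {
    stop(sprintf(
      "impossible packing: ball of radius %g holds %d voxel(s) < n_cells = %d",
      spec$radius, length(inside), spec$n_cells))
  }

  seeds <- with_seed(spec$seed, spheroid_seed_points(spec, r_phys))
  co <- arrayInd(inside, dims)
  pts <- cbind((co[, 1] - center[1]) * sp[1],
               (co[, 2] - center[2]) * sp[2],
               (co[, 3] - center[3]) * sp[3])
  # nearest seed per in-ball voxel; ties to the lowest seed index
  d2 <- outer(rowSums(pts^2), rep(1, nrow(seeds))) -
    2 * pts %*% t(seeds) +
    outer(rep(1, nrow(pts)), rowSums(seeds^2))
  lab <- max.col(-d2, ties.method = "first")

  lat <- array(0L, dims)
  lat[inside] <- lab
  out <- label_volume(lat, spacing = sp)
  attr(out, "seeds") <- seeds
  out
}

# Jittered grid seed points inside the ball (physical coordinates relative
# to the ball center). Pitch is chosen from the equal-share cell volume and
# relaxed until the grid offers at least n_cells candidates.
spheroid_seed_points <- function(spec, r_phys) {
  n <- spec$n_cells
  pitch <- (4 / 3 * pi * r_phys^3 / n)^(1 / 3)
  repeat {
    g <- seq(-r_phys, r_phys, by = pitch)
    cand <- as.matrix(expand.grid(x = g, y = g, z = g))
    keep <- rowSums(cand^2) <= (r_phys - pitch / 2)^2
    if (sum(keep) >= n || pitch < r_phys / 64) break
    pitch <- pitch * 0.9
  }
  cand <- cand[rowSums(cand^2) <= max((r_phys - pitch / 2)^2,
                                      (r_phys / 2)^2), , drop = FALSE]
  if (nrow(cand) < n) {
    # tiny balls: fall back to uniform rejection sampling
    cand <- matrix(stats::runif(3 * 8 * n, -r_phys, r_phys), ncol = 3)
    cand <- cand[rowSums(cand^2) <= (0.9 * r_phys)^2, , drop = FALSE]
    if (nrow(cand) < n) stop("impossible packing: cannot place seed points")
  }
  # prefer central candidates for stable packing, then jitter
  ord <- order(rowSums(cand^2))
  seeds <- cand[ord[seq_len(n)], , drop = FALSE]
  seeds + matrix(stats::runif(3 * n, -spec$jitter * pitch,
                              spec$jitter * pitch), ncol = 3)
}

#' Specification of injected segmentation artifacts
#'
#' Describes the error classes a real segmentation leaves behind and that
#' the preprocessing stage is designed to remove: sub-threshold debris
#' labels, "sliver" labels confined to one or two z-planes, and cells whose
#' size falls outside the plausible band (below 15% of the mean volume or
#' above the mean plus two standard deviations).
#'
#' @param n_debris number of 1-4 voxel debris labels to inject
#' @param n_slivers number of labels spanning at most 2 z-planes to inject
#' @param n_outliers number of existing cells to rescale out of the valid
#'   size band
#' @return object of class `artifact_spec`
#' @export
artifact_spec <- function(n_debris = 0L, n_slivers = 0L, n_outliers = 0L) {
  spec <- list(n_debris = as.integer(n_debris),
               n_slivers = as.integer(n_slivers),
               n_outliers = as.integer(n_outliers))
  stopifnot(all(unlist(spec) >= 0L))
  structure(spec, class = "artifact_spec")
}

#' Inject segmentation artifacts into a clean label mask
#'
#' Debris and slivers are carved out of medium voxels adjacent to the
#' aggregate surface (mimicking shed-voxel errors without damaging real
#' cells) and receive fresh IDs above the existing maximum. Outliers are
#' existing cells rescaled by repeated 6-neighborhood erosion (shrink below
#' 15% of the pre-injection mean volume) or dilation into medium (grow
#' above mean + 2 SD); connectivity is preserved by construction.
#'
#' @param vol a nonempty [label_volume()]
#' @param art an [artifact_spec()]
#' @param seed integer RNG seed
#' @return a [label_volume()] with attribute `"manifest"`: a list with
#'   `debris`, `slivers` (injected IDs) and `outliers` (data frame of
#'   rescaled IDs and direction)
#' @export
inject_artifacts <- function(vol, art, seed = 1L) {
  stopifnot(inherits(vol, "label_volume"), inherits(art, "artifact_spec"))
  if (sum(vol$lattice > 0L) == 0L) stop("cannot inject into an empty volume")
  lat <- vol$lattice
  d <- dim(lat)
  next_id <- max(lat) + 1L
  manifest <- list(debris = integer(0), slivers = integer(0),
                   outliers = data.frame(cell_id = integer(0),
                                         direction = character(0)))
  with_seed(seed, {
    # medium voxels with at least one foreground face neighbor
    surface_medium <- function() {
      fg <- lat > 0L
      adj <- face_neighbor_reduce(lat, function(a, nb) (nb > 0L) * 1L) > 0
      which(!fg & adj)
    }

    grow_clump <- function(anchor, target_size) {
      clump <- anchor
      while (length(clump) < target_size) {
        cand <- setdiff(medium_neighbors(clump, lat, d), clump)
        if (length(cand) == 0L) break
        clump <- c(clump, cand[sample.int(length(cand), 1L)])
      }
      clump
    }

    if (art$n_debris > 0L) {
      pool <- surface_medium()
      if (length(pool) < art$n_debris) stop("no room to inject debris")
      for (i in seq_len(art$n_debris)) {
        pool <- pool[lat[pool] == 0L]
        anchor <- pool[sample.int(length(pool), 1L)]
        clump <- grow_clump(anchor, sample(1:4, 1L))
        lat[clump] <- next_id
        manifest$debris <- c(manifest$debris, next_id)
        next_id <- next_id + 1L
      }
    }

    if (art$n_slivers > 0L) {
      for (i in seq_len(art$n_slivers)) {
        pool <- surface_medium()
        placed <- FALSE
        for (try in seq_len(200L)) {
          anchor <- pool[sample.int(length(pool), 1L)]
          co <- arrayInd(anchor, d)
          xs <- max(1L, co[1] - 1L):min(d[1], co[1] + 1L)
          ys <- max(1L, co[2] - 1L):min(d[2], co[2] + 1L)
          zs <- co[3]:min(d[3], co[3] + 1L)
          patch <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
          pidx <- patch[, 1] + (patch[, 2] - 1L) * d[1] +
            (patch[, 3] - 1L) * d[1] * d[2]
          pidx <- pidx[lat[pidx] == 0L]
          if (length(pidx) >= 5L) {
            lat[pidx] <- next_id
            manifest$slivers <- c(manifest$slivers, next_id)
            next_id <- next_id + 1L
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("no room to inject sliver labels")
      }
    }

    if (art$n_outliers > 0L) {
      sizes <- label_sizes(label_volume(lat, vol$spacing))
      sizes <- sizes[!names(sizes) %in%
                       as.character(c(manifest$debris, manifest$slivers))]
      mu <- mean(sizes)
      sdv <- if (length(sizes) > 1L) stats::sd(sizes) else 0
      lo <- 0.15 * mu
      hi <- mu + 2 * sdv
      if (length(sizes) < art$n_outliers) stop("not enough cells to rescale")
      chosen <- as.integer(names(sizes))[
        sample.int(length(sizes), art$n_outliers)]
      for (k in seq_along(chosen)) {
        id <- chosen[k]
        dirn <- if (k %% 2L == 1L) "shrink" else "grow"
        if (dirn == "shrink") {
          lat <- erode_label_below(lat, d, id, lo)
        } else {
          res <- dilate_label_above(lat, d, id, hi)
          if (!res$ok) { # not enough reachable medium: shrink instead
            dirn <- "shrink"
            lat <- erode_label_below(lat, d, id, lo)
          } else {
            lat <- res$lat
          }
        }
        manifest$outliers <- rbind(manifest$outliers,
                                   data.frame(cell_id = id, direction = dirn))
      }
    }
  })
  out <- label_volume(lat, spacing = vol$spacing)
  attr(out, "manifest") <- manifest
  out
}

# linear indices of medium face neighbors of a voxel index set
medium_neighbors <- function(idx, lat, d) {
  co <- arrayInd(idx, d)
  offs <- neighborhood_offsets(1L)
  out <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
    out <- c(out, lin[lat[lin] == 0L])
  }
  unique(out)
}

# shrink label `id` by 6-neighborhood erosion until its volume is < lo
erode_label_below <- function(lat, d, id, lo) {
  mask <- array(lat == id, d)
  while (sum(mask) >= lo) {
    er <- mask
    for (axis in 1:3) {
      for (dir in c(-1L, 1L)) {
        er <- er & shift3(mask, axis, dir, fill = FALSE)
      }
    }
    if (!any(er)) { # keep a single voxel rather than vanishing
      keep <- which(mask)[1]
      er[] <- FALSE
      er[keep] <- TRUE
      lat[mask & !er] <- 0L
      mask <- er
      break
    }
    lat[mask & !er] <- 0L
    mask <- er
  }
  lat
}

# grow label `id` by dilation into medium until its volume is > hi
dilate_label_above <- function(lat, d, id, hi) {
  mask <- array(lat == id, d)
  for (iter in seq_len(64L)) {
    if (sum(mask) > hi) return(list(ok = TRUE, lat = lat))
    grown <- mask
    for (axis in 1:3) {
      for (dir in c(-1L, 1L)) {
        grown <- grown | shift3(mask, axis, dir, fill = FALSE)
      }
    }
    new <- grown & !mask & (lat == 0L)
    if (!any(new)) return(list(ok = FALSE, lat = lat))
    lat[new] <- id
    mask <- mask | new
  }
  list(ok = sum(mask) > hi, lat = lat)
}
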