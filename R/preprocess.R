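#' Preprocessing configuration
#'
#' Parameters of the label-mask cleanup. Defaults follow the rules the
#' pipeline is built around: objects smaller than 5 voxels are removed
#' (strictly-smaller rule: a 5-voxel label survives), labels spanning at
#' most 2 z-planes count as "thin", and per-label closing/opening uses a
#' Euclidean ball of radius 1 (the 7-voxel octahedron).
#'
#' @param min_volume voxel-count threshold for small-object removal (>= 1)
#' @param max_thin_planes z-plane span at or below which a label is thin
#' @param closing_radius,opening_radius structuring-element radii in voxels
#'   (0 disables the corresponding operation); the element is a Chebyshev
#'   ball, i.e. a (2r+1)^3 box
#' @return object of class `preprocess_config`
#' @export
preprocess_config <- function(min_volume = 5L, max_thin_planes = 2L,
                              closing_radius = 1L, opening_radius = 1L) {
  cfg <- list(min_volume = as.integer(min_volume),
              max_thin_planes = as.integer(max_thin_planes),
              closing_radius = as.integer(closing_radius),
              opening_radius = as.integer(opening_radius))
  stopifnot(cfg$min_volume >= 1L, cfg$max_thin_planes >= 1L,
            cfg$closing_radius >= 0L, cfg$opening_radius >= 0L)
  structure(cfg, class = "preprocess_config")
}

#' Remove labels smaller than a voxel-count threshold
#'
#' Labels with volume strictly smaller than `min_volume` become medium;
#' all other labels are untouched. Idempotent.
#'
#' @param vol a [label_volume()]
#' @param min_volume threshold in voxels
#' @return a [label_volume()] with attribute `"removed"` (IDs removed)
#' @export
remove_small_labels <- function(vol, min_volume = 5L) {
  stopifnot(inherits(vol, "label_volume"))
  nmax <- max(vol$lattice, 0L)
  lat <- vol$lattice
  removed <- integer(0)
  if (nmax > 0L) {
    counts <- tabulate(lat, nbins = nmax)
    removed <- which(counts > 0L & counts < min_volume)
    if (length(removed) > 0L) lat[lat %in% removed] <- 0L
  }
  out <- label_volume(lat, spacing = vol$spacing)
  attr(out, "removed") <- as.integer(removed)
  out
}

# Chebyshev-ball (box) structuring element as an offset matrix. An L-inf
# ball is used rather than a Euclidean one: it leaves convex solids (the
# shape cells are expected to have) exactly invariant under opening,
# whereas the octahedral Euclidean ball of radius 1 rounds off cube edges.
ball_offsets <- function(radius) {
  as.matrix(expand.grid(dx = -radius:radius, dy = -radius:radius,
                        dz = -radius:radius))
}

# binary dilation/erosion of a logical 3D array by an offset SE;
# outside the array counts as background
morph_op <- function(mask, offsets, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(mask)
  acc <- NULL
  for (r in seq_len(nrow(offsets))) {
    sh <- mask
    for (axis in 1:3) {
      k <- offsets[r, axis]
      while (k != 0L) {
        sh <- shift3(sh, axis, sign(k), fill = FALSE)
        k <- k - sign(k)
      }
    }
    acc <- if (is.null(acc)) sh else if (op == "dilate") acc | sh else acc & sh
  }
  acc
}

#' Per-label morphological closing then opening
#'
#' Each label's binary mask is independently closed (fill small holes and
#' gulfs) and then opened (shave small protrusions) with a Euclidean ball.
#' Working per label avoids the label mixing that grayscale morphology on
#' the raw ID image would cause. Voxels still claimed by their original
#' owner keep it; voxels freed by one label and claimed by another go to
#' the lowest claiming ID; unclaimed voxels become medium. Note that with
#' an opening radius of 1 any object at most 2 z-planes thick is erased
#' outright — thin slivers rarely survive to the merge stage unless
#' `opening_radius = 0`.
#'
#' @param vol a [label_volume()]
#' @param cfg a [preprocess_config()] (only the radii are used)
#' @return a [label_volume()] with attributes `"removed"` (labels erased
#'   entirely) and `"changed"` (labels whose voxel set changed)
#' @export
close_open_labels <- function(vol, cfg = preprocess_config()) {
  stopifnot(inherits(vol, "label_volume"))
  lat <- vol$lattice
  d <- dim(lat)
  ids <- label_ids(vol)
  r_c <- cfg$closing_radius
  r_o <- cfg$opening_radius
  if ((r_c == 0L && r_o == 0L) || length(ids) == 0L) {
    out <- label_volume(lat, vol$spacing)
    attr(out, "removed") <- integer(0)
    attr(out, "changed") <- integer(0)
    return(out)
  }
  se_c <- if (r_c > 0L) ball_offsets(r_c) else NULL
  se_o <- if (r_o > 0L) ball_offsets(r_o) else NULL
  pad <- r_c + 1L

  claims <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    idx <- which(lat == id)
    co <- arrayInd(idx, d)
    lo <- pmax(apply(co, 2, min) - pad, 1L)
    hi <- pmin(apply(co, 2, max) + pad, d)
    sub <- array(FALSE, hi - lo + 1L)
    sub[cbind(co[, 1] - lo[1] + 1L, co[, 2] - lo[2] + 1L,
              co[, 3] - lo[3] + 1L)] <- TRUE
    if (!is.null(se_c)) {
      sub <- morph_op(morph_op(sub, se_c, "dilate"), se_c, "erode")
    }
    if (!is.null(se_o)) {
      sub <- morph_op(morph_op(sub, se_o, "erode"), se_o, "dilate")
    }
    w <- which(sub)
    if (length(w) == 0L) {
      claims[[k]] <- integer(0)
    } else {
      sc <- arrayInd(w, dim(sub))
      claims[[k]] <- (sc[, 1] + lo[1] - 1L) +
        ((sc[, 2] + lo[2] - 1L) - 1L) * d[1] +
        ((sc[, 3] + lo[3] - 1L) - 1L) * d[1] * d[2]
    }
  }

  out_lat <- array(0L, d)
  # pass 1: original owners keep the voxels their result retains
  for (k in seq_along(ids)) {
    own <- claims[[k]][lat[claims[[k]]] == ids[k]]
    out_lat[own] <- ids[k]
  }
  # pass 2: remaining claims in ascending ID order
  for (k in seq_along(ids)) {
    extra <- claims[[k]][out_lat[claims[[k]]] == 0L & lat[claims[[k]]] == 0L]
    out_lat[extra] <- ids[k]
  }
  out <- label_volume(out_lat, vol$spacing)
  new_counts <- tabulate(out_lat, nbins = max(ids))
  attr(out, "removed") <- ids[new_counts[ids] == 0L]
  changed <- vapply(seq_along(ids), function(k) {
    !identical(which(out_lat == ids[k]), which(lat == ids[k]))
  }, logical(1))
  attr(out, "changed") <- ids[changed]
  out
}

#' Merge or remove labels confined to few z-planes
#'
#' A label whose z-extent is at most `max_thin_planes` planes is "thin".
#' Face-adjacent (6-connectivity) thin labels are merged — chains of
#' mutually adjacent thin labels collapse transitively under the lowest
#' participating ID. A thin label with no thin neighbor (its neighbors are
#' all non-thin, or it has none) is deleted. The rule is applied to a fixed
#' point, so a merge whose result is still thin and isolated is
#' subsequently deleted; this makes the operation idempotent. Non-thin
#' labels never change.
#'
#' @param vol a [label_volume()]
#' @param max_thin_planes z-span defining "thin"
#' @return a [label_volume()] with attributes `"merged"` (named list:
#'   surviving ID -> absorbed IDs) and `"removed"` (deleted thin IDs)
#' @export
resolve_thin_labels <- function(vol, max_thin_planes = 2L) {
  stopifnot(inherits(vol, "label_volume"))
  lat <- vol$lattice
  d <- dim(lat)
  merged <- list()
  removed <- integer(0)
  repeat {
    nmax <- max(lat, 0L)
    if (nmax == 0L) break
    idx <- which(lat > 0L)
    z <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
    id <- lat[idx]
    zmin <- tapply(z, id, min)
    zmax <- tapply(z, id, max)
    span <- zmax - zmin + 1L
    thin <- as.integer(names(span))[span <= max_thin_planes]
    if (length(thin) == 0L) break

    # adjacency between thin labels (6-connectivity)
    thin_set <- logical(nmax)
    thin_set[thin] <- TRUE
    pairs <- NULL
    for (axis in 1:3) {
      nb <- shift3(lat, axis, 1L)
      sel <- lat > 0L & nb > 0L & lat != nb
      if (any(sel)) {
        a <- lat[sel]; b <- nb[sel]
        keep <- thin_set[a] & thin_set[b]
        if (any(keep)) {
          pairs <- rbind(pairs, unique(cbind(pmin(a[keep], b[keep]),
                                             pmax(a[keep], b[keep]))))
        }
      }
    }

    changed <- FALSE
    if (!is.null(pairs) && nrow(pairs) > 0L) {
      # union-find over thin labels
      parent <- seq_len(nmax)
      find <- function(x) {
        while (parent[x] != x) x <- parent[x]
        x
      }
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(thin, find, integer(1))
      for (g in unique(roots)) {
        members <- thin[roots == g]
        if (length(members) > 1L) {
          target <- min(members)
          absorb <- setdiff(members, target)
          lat[lat %in% absorb] <- target
          key <- as.character(target)
          merged[[key]] <- unique(c(merged[[key]], absorb))
          changed <- TRUE
        }
      }
    }
    if (!changed) {
      # thin labels with no thin neighbor: delete
      lat[lat %in% thin] <- 0L
      removed <- c(removed, thin)
      changed <- TRUE
    }
    if (!changed) break
  }
  out <- label_volume(lat, vol$spacing)
  attr(out, "merged") <- merged
  attr(out, "removed") <- as.integer(removed)
  out
}

#' Upsample a z-anisotropic stack to isotropic voxels
#'
#' Nearest-neighbor resampling along z only, bringing the slice spacing
#' down to the in-plane resolution: the new slice count is the old count
#' times dz/dx, rounded half away from zero, and every output slice is an
#' exact copy of some input slice. x and y are untouched; the returned
#' spacing is isotropic (dx, dx, dx). Because dz >= dx, every input slice
#' appears at least once, so no label can vanish.
#'
#' @param vol a [label_volume()]; requires dx == dy and dz >= dx
#' @return an isotropic [label_volume()]
#' @export
upsample_isotropic <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  sp <- vol$spacing
  if (abs(sp[1] - sp[2]) > 1e-9 * max(sp[1], sp[2])) {
    stop("anisotropic x-y spacing: dx must equal dy")
  }
  if (sp[3] < sp[1]) stop("dz must be >= dx for z-upsampling")
  d <- dim(vol$lattice)
  nz <- d[3]
  n_out <- as.integer(floor(nz * sp[3] / sp[1] + 0.5))
  if (n_out == nz) {
    return(label_volume(vol$lattice, spacing = c(sp[1], sp[1], sp[1])))
  }
  k <- seq_len(n_out)
  src <- pmin(pmax(floor((k - 0.5) * nz / n_out) + 1L, 1L), nz)
  label_volume(vol$lattice[, , src, drop = FALSE],
               spacing = c(sp[1], sp[1], sp[1]))
}

#' Full label-mask cleanup pipeline
#'
#' Applies, in order: small-object removal, per-label closing/opening,
#' thin-label merge/removal, and (optionally) isotropic z-upsampling.
#' Thin-label extent is measured after closing/opening, per the stage
#' order.
#'
#' @param vol a [label_volume()]
#' @param cfg a [preprocess_config()]
#' @param upsample logical; run the isotropic upsampling stage
#' @return list with `volume` (the final [label_volume()]) and `log` (per
#'   stage: removed, changed and merged IDs)
#' @export
preprocess_pipeline <- function(vol, cfg = preprocess_config(),
                                upsample = TRUE) {
  s1 <- remove_small_labels(vol, cfg$min_volume)
  s2 <- close_open_labels(s1, cfg)
  s3 <- resolve_thin_labels(s2, cfg$max_thin_planes)
  out <- if (isTRUE(upsample)) upsample_isotropic(s3) else s3
  log <- list(
    small_removed = attr(s1, "removed"),
    morph_removed = attr(s2, "removed"),
    morph_changed = attr(s2, "changed"),
    thin_merged = attr(s3, "merged"),
    thin_removed = attr(s3, "removed")
  )
  log$removed <- sort(unique(c(log$small_removed, log$morph_removed,
                               log$thin_removed)))
  list(volume = label_volume(out$lattice, out$spacing), log = log)
}
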