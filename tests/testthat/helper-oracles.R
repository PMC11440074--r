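# Fixture builders and independent brute-force oracles. Everything here is
# deliberately naive (triple loops, BFS) so it cannot share bugs with the
# vectorized / compiled implementation paths it checks.

make_vol <- function(d, spacing = c(1, 1, 1)) {
  label_volume(array(0L, d), spacing = spacing)
}

# place an axis-aligned box of label `id` into a volume
put_box <- function(vol, id, x, y, z) {
  vol$lattice[x, y, z] <- as.integer(id)
  vol
}

# per-label volume and border-voxel surface by explicit voxel loops
oracle_volume_surface <- function(lat) {
  d <- dim(lat)
  ids <- sort(unique(lat[lat > 0L]))
  vol <- surf <- stats::setNames(integer(length(ids)), ids)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    id <- lat[x, y, z]
    if (id == 0L) next
    key <- as.character(id)
    vol[key] <- vol[key] + 1L
    border <- FALSE
    for (r in 1:6) {
      p <- c(x, y, z) + offs[r, ]
      q <- if (any(p < 1L) || any(p > d)) 0L else lat[p[1], p[2], p[3]]
      if (q != id) border <- TRUE
    }
    if (border) surf[key] <- surf[key] + 1L
  }
  list(volume = vol, surface = surf)
}

# per-label face-contact area (count of faces to any different ID),
# counting only in-lattice faces — the engine's A_i
oracle_face_area <- function(lat) {
  d <- dim(lat)
  ids <- sort(unique(lat[lat > 0L]))
  area <- stats::setNames(integer(length(ids)), ids)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    id <- lat[x, y, z]
    for (k in 1:3) {
      p <- c(x, y, z)
      p[k] <- p[k] + 1L
      if (p[k] > d[k]) next
      q <- lat[p[1], p[2], p[3]]
      if (q != id) {
        if (id > 0L) area[as.character(id)] <- area[as.character(id)] + 1L
        if (q > 0L) area[as.character(q)] <- area[as.character(q)] + 1L
      }
    }
  }
  area
}

# number of 6-connected components of a logical mask (BFS flood fill)
oracle_n_components6 <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  idx_of <- function(p) p[1] + (p[2] - 1L) * d[1] + (p[3] - 1L) * d[1] * d[2]
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  n <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (seen[start]) next
    n <- n + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0L) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      p0 <- arrayInd(cur, d)
      for (r in 1:6) {
        p <- p0 + offs[r, ]
        if (any(p < 1L) || any(p > d)) next
        i <- idx_of(p)
        if (mask[i] && !seen[i]) {
          seen[i] <- TRUE
          queue <- c(queue, i)
        }
      }
    }
  }
  n
}

# a small random multi-cell lattice with a clean 1-voxel medium margin,
# suitable for init_state(); blobs are grown around random centers so most
# labels have several voxels
random_cell_volume <- function(d = c(12, 12, 12), n_cells = 4, seed = 1) {
  set.seed(seed)
  lat <- array(0L, d)
  centers <- cbind(sample(3:(d[1] - 2), n_cells, replace = TRUE),
                   sample(3:(d[2] - 2), n_cells, replace = TRUE),
                   sample(3:(d[3] - 2), n_cells, replace = TRUE))
  for (x in 2:(d[1] - 1)) for (y in 2:(d[2] - 1)) for (z in 2:(d[3] - 1)) {
    d2 <- colSums((t(centers) - c(x, y, z))^2)
    k <- which.min(d2)
    if (d2[k] <= 9) lat[x, y, z] <- k
  }
  label_volume(lat)
}

# measured-as-target assignment for engine tests that need exact targets
identity_targets <- function(vol) {
  ft <- compute_features(vol)
  rec <- oracle_face_area(vol$lattice)
  data.frame(cell_id = ft$cell_id,
             target_volume = ft$volume,
             target_surface = as.numeric(rec[as.character(ft$cell_id)]))
}
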