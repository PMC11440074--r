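#' Model parameters of the Potts engine
#'
#' The energy function combines quadratic penalties on deviations of each
#' cell's volume and face-contact surface from per-cell targets with
#' contact energies per unit shared interface:
#'
#' H = sum_i lambda_V (V_i - V_i^target)^2
#'   + sum_i lambda_A (A_i - A_i^target)^2
#'   + sum_{i<j} J_cc A_ij^(c-c) + sum_i J_cm A_i^(c-m)
#'   + sum_i J_cw A_i^(c-w)
#'
#' with energies in arbitrary lattice units (J/pix^2 for contact energies,
#' J/pix^6 and J/pix^4 for the volume and surface weights). Medium is
#' unconstrained; wall voxels are frozen.
#'
#' The defaults are the contact energies and constraint weights that a
#' grid scan over this model family selects for HT-29-like spheroids
#' (strong volume constraint, negligible surface constraint, weak cell-cell
#' adhesion cost relative to cell-medium), plus engine conventions:
#' Metropolis temperature 10 (same units as H), face (order-1) contact
#' neighborhood, 26-neighborhood copy attempts, and a high wall contact
#' energy so nothing gains by touching the frozen shell.
#'
#' @param lambda_V volume-constraint weight (>= 0)
#' @param lambda_A surface-constraint weight (>= 0)
#' @param J_cc,J_cm,J_cw cell-cell, cell-medium and cell-wall contact
#'   energies
#' @param temperature Metropolis fluctuation amplitude (> 0)
#' @param contact_neighbor_order neighborhood order for contact-energy
#'   sums: 1 (6 faces), 2 (18) or 3 (26)
#' @param copy_neighborhood neighborhood for copy attempts: 6 or 26
#' @param n_mcs default Monte Carlo step budget
#' @param seed integer RNG seed
#' @return object of class `model_params`
#' @export
model_params <- function(lambda_V = 10, lambda_A = 0.001, J_cc = 2,
                         J_cm = 55, J_cw = 100, temperature = 10,
                         contact_neighbor_order = 1L,
                         copy_neighborhood = 26L, n_mcs = 100L, seed = 1L) {
  stopifnot(lambda_V >= 0, lambda_A >= 0, temperature > 0,
            contact_neighbor_order %in% 1:3, copy_neighborhood %in% c(6L, 26L),
            n_mcs >= 0)
  structure(list(lambda_V = lambda_V, lambda_A = lambda_A, J_cc = J_cc,
                 J_cm = J_cm, J_cw = J_cw, temperature = temperature,
                 contact_neighbor_order = as.integer(contact_neighbor_order),
                 copy_neighborhood = as.integer(copy_neighborhood),
                 n_mcs = as.integer(n_mcs), seed = as.integer(seed)),
            class = "model_params")
}

#' Assign per-cell target volume and surface
#'
#' Cells whose measured volume lies within the plausible band
#' [0.15 * mean(V), mean(V) + 2 * sd(V)] are taken to be correctly
#' segmented and start the simulation already at their targets: their own
#' measured (volume, surface) pair. Cells outside the band (likely
#' under- or over-segmentation) instead receive the (volume, surface)
#' pair of an in-band donor cell drawn uniformly at random — the pair is
#' sampled jointly, never mixed across donors, so target volume and
#' surface stay physically consistent.
#'
#' @param table a `morphology_table` from [compute_features()]
#' @param seed RNG seed for donor sampling
#' @return data frame with `cell_id`, `target_volume`, `target_surface`,
#'   and `resampled` (logical)
#' @export
assign_targets <- function(table, seed = 1L) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  v <- table$volume
  mu <- mean(v)
  sdv <- if (nrow(table) > 1L) stats::sd(v) else 0
  lo <- 0.15 * mu
  hi <- mu + 2 * sdv
  in_band <- v >= lo & v <= hi
  if (!any(in_band)) {
    stop("no cell lies within the target band [0.15*mean, mean + 2*sd]")
  }
  tv <- v
  ta <- table$surface
  out_idx <- which(!in_band)
  if (length(out_idx) > 0L) {
    donors <- which(in_band)
    pick <- with_seed(seed,
                      donors[sample.int(length(donors), length(out_idx),
                                        replace = TRUE)])
    tv[out_idx] <- v[pick]
    ta[out_idx] <- table$surface[pick]
  }
  data.frame(cell_id = table$cell_id, target_volume = tv,
             target_surface = ta, resampled = !in_band)
}

#' Per-cell face-contact areas
#'
#' The engine's surface measure: for each label, the number of lattice
#' faces between one of its voxels and a voxel with any other ID (medium
#' included; faces on the lattice edge are not counted). This is distinct
#' from — and roughly three times larger than — the border-voxel surface
#' in [compute_features()], and it is the quantity the surface constraint
#' acts on, so target surfaces handed to the engine must be in these
#' units.
#'
#' @param vol a [label_volume()]
#' @return named numeric vector of face counts per label
#' @export
face_contact_areas <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  nmax <- max(vol$lattice, 0L)
  if (nmax == 0L) return(stats::setNames(numeric(0), character(0)))
  rec <- cpm_recount_cpp(vol$lattice, dim(vol$lattice), nmax + 1L)
  ids <- label_ids(vol)
  stats::setNames(rec$surface[ids + 1L], ids)
}

# feature table with the surface column in engine units, for target
# assignment consistent with "cells start at their targets"
engine_feature_table <- function(vol) {
  ft <- compute_features(vol)
  ft$surface <- unname(face_contact_areas(vol)[as.character(ft$cell_id)])
  ft
}

#' Initialize a Potts state from a label volume
#'
#' Copies the lattice, claims the one-voxel boundary shell for a frozen
#' Wall cell (a barrier that keeps cells from sticking to the simulation
#' box), and computes per-cell bookkeeping: current volume (voxel count)
#' and current surface (face-contact area, in faces). Errors if any cell
#' voxel lies on the lattice boundary.
#'
#' @param vol a [label_volume()]
#' @param targets data frame from [assign_targets()] covering every label
#' @param params a [model_params()]
#' @return object of class `potts_state`: list with `lattice` (integer
#'   array including the wall shell), `cells` (bookkeeping table),
#'   `wall_id`, `mcs`, `spacing`
#' @export
init_state <- function(vol, targets = NULL, params = model_params()) {
  stopifnot(inherits(vol, "label_volume"))
  lat <- vol$lattice
  d <- dim(lat)
  if (any(d < 3L)) stop("lattice too small to carry a wall shell")
  bnd <- boundary_mask(d)
  if (any(lat[bnd] > 0L)) {
    stop("cell voxels overlap the wall shell: drop or crop boundary labels first")
  }
  ids <- label_ids(vol)
  if (is.null(targets)) {
    if (length(ids) > 0L) {
      targets <- assign_targets(engine_feature_table(vol), seed = params$seed)
    } else {
      targets <- data.frame(cell_id = integer(0), target_volume = numeric(0),
                            target_surface = numeric(0))
    }
  }
  missing <- setdiff(ids, targets$cell_id)
  if (length(missing) > 0L) {
    stop("no targets for label ID(s): ", paste(missing, collapse = ", "))
  }
  wall_id <- max(ids, 0L) + 1L
  lat[bnd] <- wall_id

  rec <- cpm_recount_cpp(lat, d, wall_id + 1L)
  cells <- data.frame(
    cell_id = c(ids, wall_id),
    celltype = c(rep("Cell", length(ids)), "Wall"),
    volume = rec$volume[c(ids, wall_id) + 1L],
    surface = rec$surface[c(ids, wall_id) + 1L],
    target_volume = c(targets$target_volume[match(ids, targets$cell_id)], NA),
    target_surface = c(targets$target_surface[match(ids, targets$cell_id)], NA)
  )
  structure(list(lattice = lat, cells = cells, wall_id = wall_id,
                 mcs = 0L, spacing = vol$spacing),
            class = "potts_state")
}

#' @export
print.potts_state <- function(x, ...) {
  d <- dim(x$lattice)
  cat(sprintf("<potts_state> %d x %d x %d lattice, %d cell(s) + wall, MCS %d\n",
              d[1], d[2], d[3], sum(x$cells$celltype == "Cell"), x$mcs))
  invisible(x)
}

# ID-indexed vectors (position id+1) for the C++ core
state_vectors <- function(state) {
  n <- state$wall_id + 1L
  type <- integer(n)
  tv <- ta <- numeric(n)
  vv <- aa <- numeric(n)
  idx <- state$cells$cell_id + 1L
  type[idx] <- ifelse(state$cells$celltype == "Wall", 2L, 1L)
  tv[idx] <- ifelse(is.na(state$cells$target_volume), 0,
                    state$cells$target_volume)
  ta[idx] <- ifelse(is.na(state$cells$target_surface), 0,
                    state$cells$target_surface)
  vv[idx] <- state$cells$volume
  aa[idx] <- state$cells$surface
  list(type = type, tv = tv, ta = ta, v = vv, a = aa)
}

#' Total energy of a Potts state
#'
#' Full recomputation from the lattice (volumes, face-contact surfaces and
#' all contact interfaces are recounted; the bookkept values are not
#' used), which makes this the natural independent check of the engine's
#' incremental energy updates. Each unordered voxel pair in the contact
#' neighborhood contributes once.
#'
#' @param state a `potts_state`
#' @param params a [model_params()]
#' @return energy scalar
#' @export
hamiltonian <- function(state, params = model_params()) {
  stopifnot(inherits(state, "potts_state"))
  lat <- state$lattice
  d <- dim(lat)
  sv <- state_vectors(state)
  nmax <- state$wall_id

  counts <- tabulate(lat, nbins = nmax)
  # face-contact surface per cell
  surf <- numeric(nmax)
  for (axis in 1:3) {
    nb <- shift3(lat, axis, 1L, fill = -1L)
    sel <- nb >= 0L & nb != lat
    if (any(sel)) {
      a <- lat[sel]; b <- nb[sel]
      surf <- surf + tabulate(a[a > 0L], nbins = nmax) +
        tabulate(b[b > 0L], nbins = nmax)
    }
  }
  cell_ids <- state$cells$cell_id[state$cells$celltype == "Cell"]
  h <- 0
  if (length(cell_ids) > 0L) {
    tvv <- sv$tv[cell_ids + 1L]
    tva <- sv$ta[cell_ids + 1L]
    h <- h + params$lambda_V * sum((counts[cell_ids] - tvv)^2) +
      params$lambda_A * sum((surf[cell_ids] - tva)^2)
  }

  # contact term over the configured neighborhood, each pair once
  offs <- neighborhood_offsets(params$contact_neighbor_order)
  offs <- offs[offs[, 3] > 0 |
                 (offs[, 3] == 0 & (offs[, 2] > 0 |
                                      (offs[, 2] == 0 & offs[, 1] > 0))), ,
               drop = FALSE]
  typ <- sv$type
  for (r in seq_len(nrow(offs))) {
    nb <- lat
    for (axis in 1:3) {
      k <- offs[r, axis]
      while (k != 0L) {
        nb <- shift3(nb, axis, sign(k), fill = -1L)
        k <- k - sign(k)
      }
    }
    sel <- nb >= 0L & nb != lat
    if (!any(sel)) next
    ta <- typ[lat[sel] + 1L]
    tb <- typ[nb[sel] + 1L]
    h <- h + params$J_cc * sum(ta == 1L & tb == 1L) +
      params$J_cm * sum((ta == 1L & tb == 0L) | (ta == 0L & tb == 1L)) +
      params$J_cw * sum((ta == 1L & tb == 2L) | (ta == 2L & tb == 1L))
  }
  h
}

#' Energy change of a single voxel copy
#'
#' Computes H(after) - H(before) for writing `candidate_id` into the voxel
#' at `site`, in O(neighborhood) work from the state's bookkeeping. The
#' site must be interior, the candidate must differ from the current
#' owner, and neither may be the wall.
#'
#' @param state a `potts_state`
#' @param params a [model_params()]
#' @param site integer (x, y, z) lattice coordinates, 1-based
#' @param candidate_id the ID to copy in (0 for medium)
#' @return energy difference scalar
#' @export
delta_H <- function(state, params, site, candidate_id) {
  stopifnot(inherits(state, "potts_state"))
  sv <- state_vectors(state)
  cpm_delta_h_cpp(state$lattice, dim(state$lattice), sv$type, sv$v, sv$a,
                  sv$tv, sv$ta, as.integer(site), as.integer(candidate_id),
                  params$lambda_V, params$lambda_A, params$J_cc, params$J_cm,
                  params$J_cw, params$temperature,
                  params$contact_neighbor_order)
}

# advance `n` Monte Carlo steps through the compiled core, returning the
# updated state (bookkeeping refreshed from the engine's incremental
# updates) plus the per-MCS energy trace
advance_state <- function(state, params, n) {
  sv <- state_vectors(state)
  res <- cpm_run_cpp(state$lattice, dim(state$lattice), sv$type, sv$tv,
                     sv$ta, params$lambda_V, params$lambda_A, params$J_cc,
                     params$J_cm, params$J_cw, params$temperature,
                     params$contact_neighbor_order, params$copy_neighborhood,
                     as.integer(n))
  lat <- array(res$lattice, dim(state$lattice))
  state$lattice <- lat
  idx <- state$cells$cell_id + 1L
  state$cells$volume <- res$volume[idx]
  state$cells$surface <- res$surface[idx]
  state$mcs <- state$mcs + as.integer(n)
  attr(state, "h_trace") <- res$h_trace
  attr(state, "accepted") <- res$accepted
  attr(state, "attempted") <- res$attempted
  state
}

#' Perform Monte Carlo steps
#'
#' One Monte Carlo step (MCS) is one copy attempt per interior lattice
#' site: pick a random interior voxel and a random neighbor from the copy
#' neighborhood; if their IDs differ and neither is wall, accept the copy
#' with the Metropolis probability min(1, exp(-dH / T)). Attempts whose
#' neighbor carries the same ID count as attempts but are skipped.
#' Bookkeeping (volumes, surfaces, energy) is updated incrementally.
#'
#' Randomness comes from R's RNG: call `set.seed()` (or use
#' [run_simulation()], which seeds from `params$seed`) for reproducible
#' trajectories.
#'
#' @param state a `potts_state`
#' @param params a [model_params()]
#' @param n number of MCS to perform
#' @return the evolved `potts_state`; attribute `"h_trace"` holds the
#'   total energy after each MCS (element 1 = before the first step)
#' @export
mcs_step <- function(state, params = model_params(), n = 1L) {
  stopifnot(inherits(state, "potts_state"), n >= 0)
  if (n == 0) return(state)
  advance_state(state, params, n)
}

#' Metropolis acceptance decisions
#'
#' Applies the engine's exact acceptance rule min(1, exp(-dH/T)) to a
#' vector of energy differences, consuming R's RNG. Exposed so the
#' acceptance probability can be verified empirically against forced
#' energy differences.
#'
#' @param dh numeric vector of energy differences
#' @param temperature Metropolis temperature
#' @return logical vector of accept decisions
#' @export
metropolis_accept <- function(dh, temperature) {
  metropolis_accept_cpp(as.numeric(dh), temperature)
}

#' Strip the wall shell from a state
#'
#' @param state a `potts_state`
#' @return a [label_volume()] with wall voxels set to medium
#' @export
state_to_volume <- function(state) {
  lat <- state$lattice
  lat[lat == state$wall_id] <- 0L
  label_volume(lat, spacing = state$spacing)
}

#' Run a simulation with periodic snapshots and reports
#'
#' Seeds the RNG from `params$seed`, runs `params$n_mcs` steps, writes the
#' lattice (wall stripped) as TIFF at every `snapshot_interval` MCS when
#' `out_dir` is given, and at every `report_interval` MCS records mean
#' cell volume and surface, the per-cell feature table and the similarity
#' report against the initial configuration.
#'
#' @param state an initialized `potts_state`
#' @param params a [model_params()]
#' @param snapshot_interval MCS between TIFF snapshots (>= 1)
#' @param report_interval MCS between metric reports (>= 1)
#' @param out_dir directory for snapshots; NULL disables them
#' @return list of class `cpm_trajectory`: `reports` (data frame of
#'   summary metrics vs MCS), `features` (feature tables by MCS),
#'   `wip_reports` (similarity reports by MCS), `snapshots` (paths),
#'   `h_trace` (energy after every MCS), `state` (final state)
#' @export
run_simulation <- function(state, params = model_params(),
                           snapshot_interval = 50L, report_interval = 10L,
                           out_dir = NULL) {
  stopifnot(inherits(state, "potts_state"),
            snapshot_interval >= 1L, report_interval >= 1L)
  set.seed(params$seed)
  n_mcs <- params$n_mcs
  start_vol <- state_to_volume(state)

  snaps <- character(0)
  take_snapshot <- function(st, mcs) {
    if (is.null(out_dir)) return(invisible(NULL))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    p <- file.path(out_dir, sprintf("mcs_%06d.tif", mcs))
    write_label_tiff(state_to_volume(st), p)
    snaps[[length(snaps) + 1L]] <<- p
    invisible(p)
  }
  reports <- list()
  features <- list()
  wips <- list()
  take_report <- function(st, mcs) {
    v <- state_to_volume(st)
    ft <- compute_features(v)
    wr <- wip(start_vol, v, mcs = mcs)
    key <- as.character(mcs)
    features[[key]] <<- ft
    wips[[key]] <<- wr
    reports[[key]] <<- data.frame(
      mcs = mcs,
      n_cells = nrow(ft),
      total_volume = sum(ft$volume),
      mean_volume = mean(ft$volume),
      mean_surface = mean(ft$surface),
      mean_w = wr$mean_w, mean_iou = wr$mean_iou, wip = wr$wip)
    invisible(NULL)
  }

  take_snapshot(state, 0L)
  take_report(state, 0L)
  h_trace <- numeric(0)
  if (n_mcs > 0L) {
    every <- function(step) {
      if (step > n_mcs) integer(0) else seq(step, n_mcs, by = step)
    }
    marks <- sort(unique(c(every(snapshot_interval), every(report_interval),
                           n_mcs)))
    prev <- 0L
    for (m in marks) {
      state <- advance_state(state, params, m - prev)
      tr <- attr(state, "h_trace")
      h_trace <- c(h_trace, if (prev == 0L) tr else tr[-1])
      if (m %% snapshot_interval == 0L) take_snapshot(state, m)
      if (m %% report_interval == 0L || m == n_mcs) take_report(state, m)
      prev <- m
    }
  } else {
    h_trace <- hamiltonian(state, params)
  }

  structure(list(reports = do.call(rbind, reports),
                 features = features, wip_reports = wips,
                 snapshots = snaps, h_trace = h_trace, state = state),
            class = "cpm_trajectory")
}
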