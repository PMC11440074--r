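#' Build a parameter scan grid
#'
#' Enumerates the Cartesian product of candidate contact energies and
#' constraint weights in a deterministic order (lambda_A varies fastest,
#' then lambda_V, J_cc, J_cm; replicate seeds vary slowest). The default
#' value lists are the published optimization grid for this model family:
#' J_cm in \{10, 55, 100\}, J_cc in \{2, 4, 6, 8, 10\}, and lambda_V,
#' lambda_A in \{0.001, 2, 4, 6, 8, 10\} — 540 combinations.
#'
#' @param J_cm,J_cc,lambda_V,lambda_A nonempty numeric value lists
#' @param seeds integer replicate seeds (one run per combination per seed)
#' @param fixed a [model_params()] supplying every non-scanned parameter
#' @return object of class `scan_grid`: list with `grid` (data frame, one
#'   row per run) and `fixed`
#' @export
build_grid <- function(J_cm = c(10, 55, 100), J_cc = c(2, 4, 6, 8, 10),
                       lambda_V = c(0.001, 2, 4, 6, 8, 10),
                       lambda_A = c(0.001, 2, 4, 6, 8, 10),
                       seeds = 1L, fixed = model_params()) {
  for (v in list(J_cm, J_cc, lambda_V, lambda_A, seeds)) {
    if (length(v) == 0L) stop("every scanned parameter needs at least one value")
  }
  combos <- expand.grid(lambda_A = lambda_A, lambda_V = lambda_V,
                        J_cc = J_cc, J_cm = J_cm,
                        KEEP.OUT.ATTRS = FALSE)
  grid <- merge(data.frame(seed = as.integer(seeds)), combos, by = NULL)
  grid <- grid[order(grid$seed), c("J_cm", "J_cc", "lambda_V", "lambda_A",
                                   "seed")]
  rownames(grid) <- NULL
  structure(list(grid = grid, fixed = fixed), class = "scan_grid")
}

#' Remove labels touching the lattice boundary
#'
#' Cells clipped by image cropping are incomplete and would bias targets
#' and similarity scores; every label owning at least one voxel on any
#' lattice face is set to medium.
#'
#' @param vol a [label_volume()]
#' @return a [label_volume()] with attribute `"removed"`
#' @export
drop_boundary_labels <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  lat <- vol$lattice
  hit <- unique(lat[boundary_mask(dim(lat))])
  hit <- hit[hit > 0L]
  if (length(hit) > 0L) lat[lat %in% hit] <- 0L
  out <- label_volume(lat, spacing = vol$spacing)
  attr(out, "removed") <- sort(as.integer(hit))
  out
}

#' Grid-scan model parameters against an initial configuration
#'
#' For every grid row, runs the Potts engine for `n_mcs` steps from the
#' given initial volume and scores the final frame against the initial one
#' with [wip()]. Targets are assigned once (seeded by `fixed$seed`) and
#' shared across runs, so runs differ only in the scanned parameters and
#' their replicate seed; per-run seeding makes results independent of
#' execution order. Individual run failures are recorded and the scan
#' continues.
#'
#' @param grid a `scan_grid` from [build_grid()]
#' @param initial a cleaned, isotropic [label_volume()] whose
#'   boundary-touching labels have been dropped (see
#'   [drop_boundary_labels()])
#' @param n_mcs Monte Carlo steps per run
#' @return object of class `scan_result`: `results` (one row per run with
#'   parameters, mean W, mean IoU, WIP, error message if any), `reports`
#'   (the full `wip_report` per run), `best` (row index of the minimal
#'   WIP), `n_failed`
#' @export
run_scan <- function(grid, initial, n_mcs = 100L) {
  stopifnot(inherits(grid, "scan_grid"), inherits(initial, "label_volume"))
  g <- grid$grid
  fixed <- grid$fixed
  feats <- engine_feature_table(initial)
  if (nrow(feats) == 0L) stop("initial volume contains no cells")
  targets <- assign_targets(feats, seed = fixed$seed)

  n <- nrow(g)
  res <- cbind(g, data.frame(mean_w = NA_real_, mean_iou = NA_real_,
                             wip = NA_real_, error = NA_character_))
  reports <- vector("list", n)
  for (i in seq_len(n)) {
    out <- tryCatch({
      params <- model_params(
        lambda_V = g$lambda_V[i], lambda_A = g$lambda_A[i],
        J_cc = g$J_cc[i], J_cm = g$J_cm[i], J_cw = fixed$J_cw,
        temperature = fixed$temperature,
        contact_neighbor_order = fixed$contact_neighbor_order,
        copy_neighborhood = fixed$copy_neighborhood,
        n_mcs = as.integer(n_mcs), seed = g$seed[i])
      state <- init_state(initial, targets, params)
      set.seed(params$seed)
      state <- advance_state(state, params, n_mcs)
      wip(initial, state_to_volume(state), mcs = n_mcs)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      res$error[i] <- conditionMessage(out)
    } else {
      reports[[i]] <- out
      res$mean_w[i] <- out$mean_w
      res$mean_iou[i] <- out$mean_iou
      res$wip[i] <- out$wip
    }
  }
  ok <- which(!is.na(res$wip))
  best <- if (length(ok) > 0L) ok[which.min(res$wip[ok])] else NA_integer_
  structure(list(results = res, reports = reports, best = best,
                 n_failed = sum(!is.na(res$error))),
            class = "scan_result")
}

#' Rank scan results by WIP
#'
#' Orders runs by ascending WIP (smaller = better: stable ensemble
#' statistics with individually mobile cells), breaking ties by the
#' lexicographic order of the parameter tuple (J_cm, J_cc, lambda_V,
#' lambda_A, seed). Failed runs sort last. The per-feature Wasserstein
#' distances of the best and worst successful runs are attached, and the
#' whole report can be written as JSON.
#'
#' @param scan a `scan_result`
#' @param path optional JSON output path
#' @return the ranked results data frame (column `rank` added), with
#'   attributes `"best_w"` and `"worst_w"` (named per-feature distances)
#' @export
report_scan <- function(scan, path = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  res <- scan$results
  if (nrow(res) == 0L) stop("empty scan result")
  o <- order(is.na(res$wip), res$wip, res$J_cm, res$J_cc, res$lambda_V,
             res$lambda_A, res$seed)
  ranked <- res[o, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL
  ok <- which(!is.na(res$wip))
  best_w <- worst_w <- NULL
  if (length(ok) > 0L) {
    best_w <- scan$reports[[ok[which.min(res$wip[ok])]]]$w
    worst_w <- scan$reports[[ok[which.max(res$wip[ok])]]]$w
  }
  attr(ranked, "best_w") <- best_w
  attr(ranked, "worst_w") <- worst_w
  if (!is.null(path)) {
    jsonlite::write_json(
      list(ranked = ranked, best_w = as.list(best_w),
           worst_w = as.list(worst_w)),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  ranked
}
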