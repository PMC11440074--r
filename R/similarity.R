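#' Distance between two empirical feature distributions
#'
#' The default form is the root-mean-square of ordered sample differences,
#'
#'   W = sqrt( (1/n) * sum_i (X_(i) - Y_(i))^2 ),
#'
#' where X_(i), Y_(i) are the ascending order statistics — an L2 variant
#' of the classical order-statistics (first Wasserstein) distance. The
#' classical L1 form, mean(|X_(i) - Y_(i)|), is available via
#' `form = "l1"`. Samples of unequal size are first evaluated at n = max
#' size common quantile ranks (linear interpolation), which reduces to the
#' plain order statistics when sizes match.
#'
#' @param x,y nonempty numeric samples
#' @param form `"rms"` (default) or `"l1"`
#' @return non-negative scalar; 0 iff the interpolated ordered samples
#'   coincide
#' @export
wasserstein <- function(x, y, form = c("rms", "l1")) {
  form <- match.arg(form)
  if (length(x) == 0L || length(y) == 0L) {
    stop("wasserstein() requires nonempty samples")
  }
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n <- max(length(x), length(y))
  if (length(x) == length(y)) {
    xs <- sort(x)
    ys <- sort(y)
  } else {
    p <- seq(0, 1, length.out = n)
    xs <- stats::quantile(x, p, names = FALSE, type = 7)
    ys <- stats::quantile(y, p, names = FALSE, type = 7)
  }
  d <- xs - ys
  if (form == "rms") sqrt(mean(d^2)) else mean(abs(d))
}

#' Intersection over union of one cell's voxel sets
#'
#' |A intersect B| / |A union B| between a cell's voxels in the start
#' frame and in the current frame (same lattice shape). A cell that has
#' vanished from the current frame scores 0; a cell absent from the start
#' frame is an error.
#'
#' @param start,current [label_volume()]s on the same lattice
#' @param cell_id label to score
#' @return scalar in [0, 1]
#' @export
iou <- function(start, current, cell_id) {
  stopifnot(inherits(start, "label_volume"), inherits(current, "label_volume"))
  if (!identical(dim(start$lattice), dim(current$lattice))) {
    stop("start and current volumes must share the same lattice shape")
  }
  a <- start$lattice == cell_id
  if (!any(a)) stop("cell ", cell_id, " is absent from the start volume")
  b <- current$lattice == cell_id
  sum(a & b) / sum(a | b)
}

# vectorized per-start-cell IoU
iou_all <- function(start, current) {
  nmax <- max(start$lattice, 0L)
  vs <- tabulate(start$lattice, nbins = nmax)
  vc <- tabulate(current$lattice, nbins = nmax)
  same <- start$lattice == current$lattice & start$lattice > 0L
  inter <- tabulate(start$lattice[same], nbins = nmax)
  ids <- which(vs > 0L)
  stats::setNames(inter[ids] / (vs[ids] + vc[ids] - inter[ids]), ids)
}

#' Wasserstein-IoU similarity report
#'
#' Scores a simulation frame against the initial configuration: one
#' Wasserstein distance per morphological feature (between the per-cell
#' feature samples of the two frames), one IoU per start cell, and the
#' calibration objective
#'
#'   WIP = mean_k(W_k) * mean_i(IoU_i).
#'
#' Minimizing WIP favors runs whose ensemble feature distributions stay
#' stable (small W) while individual cells still rearrange (small IoU);
#' a frozen simulation has IoU near 1 and is penalized through the second
#' factor even though its W vanishes.
#'
#' Cells that vanished from the current frame contribute IoU 0 and are
#' absent from the current feature samples (no feature row can be computed
#' for them). By default the raw per-feature distances are averaged as-is
#' (mixing units); `normalize = TRUE` divides each W_k by the start
#' sample's standard deviation first.
#'
#' @param start,current [label_volume()]s on the same lattice; start
#'   nonempty
#' @param features subset of [morphology_features] to score
#' @param form Wasserstein form, see [wasserstein()]
#' @param normalize divide each W_k by sd of the start sample
#' @param mcs MCS label stored in the report
#' @return object of class `wip_report`: `w` (named per-feature), `iou`
#'   (named per-cell), `mean_w`, `mean_iou`, `wip`, `mcs`, `n_features`,
#'   `n_cells`
#' @export
wip <- function(start, current, features = morphology_features,
                form = c("rms", "l1"), normalize = FALSE, mcs = NA) {
  form <- match.arg(form)
  stopifnot(inherits(start, "label_volume"), inherits(current, "label_volume"))
  if (!identical(dim(start$lattice), dim(current$lattice))) {
    stop("start and current volumes must share the same lattice shape")
  }
  stopifnot(all(features %in% morphology_features), length(features) >= 1L)
  fs <- compute_features(start)
  if (nrow(fs) == 0L) stop("start volume contains no cells")
  fc <- compute_features(current)
  fc <- fc[fc$cell_id %in% fs$cell_id, , drop = FALSE]
  if (nrow(fc) == 0L) stop("every start cell has vanished from the current frame")

  w <- vapply(features, function(k) {
    wk <- wasserstein(fs[[k]], fc[[k]], form = form)
    if (normalize) {
      s <- stats::sd(fs[[k]])
      if (is.na(s) || s == 0) s <- 1
      wk <- wk / s
    }
    wk
  }, numeric(1))
  ious <- iou_all(start, current)

  structure(list(w = w, iou = ious,
                 mean_w = mean(w), mean_iou = mean(ious),
                 wip = mean(w) * mean(ious), mcs = mcs,
                 n_features = length(w), n_cells = length(ious)),
            class = "wip_report")
}

#' @export
print.wip_report <- function(x, ...) {
  cat(sprintf("<wip_report> MCS %s: WIP = %.6g (mean W %.6g x mean IoU %.4f, %d features, %d cells)\n",
              format(x$mcs), x$wip, x$mean_w, x$mean_iou,
              x$n_features, x$n_cells))
  invisible(x)
}
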