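#' Write and read per-cell feature tables
#'
#' Feature tables are written as plain CSV with a fixed column order and
#' numeric values serialized at full double precision ("%.17g"), so that a
#' read-back reproduces the written values exactly.
#'
#' @param table a data frame (typically from [compute_features()])
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("cannot write feature table to ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  for (j in seq_along(df)) {
    if (is.character(df[[j]]) && !names(df)[j] %in% c("celltype")) {
      num <- suppressWarnings(as.numeric(df[[j]]))
      if (!anyNA(num) || all(is.na(num) == is.na(df[[j]]))) df[[j]] <- num
    }
  }
  df
}

#' Serialize a similarity report to JSON
#'
#' Writes a [wip()] report as JSON with one Wasserstein entry per feature
#' and one IoU entry per cell, plus the two means and their product.
#'
#' @param report a `wip_report`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "wip_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$w <- unlist(obj$w)
  obj$iou <- unlist(obj$iou)
  structure(obj, class = "wip_report")
}
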