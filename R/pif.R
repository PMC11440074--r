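#' CompuCell3D Potts Initial File (PIF) export
#'
#' The PIF format declares the initial lattice occupancy of a Potts
#' simulation as one whitespace-separated record per line:
#'
#' ```
#' cell_ID celltype x1 x2 y1 y2 z1 z2
#' ```
#'
#' where the coordinate pairs are inclusive 0-based ranges. The writer
#' emits exactly one voxel per line (x1 == x2, etc.), one line per nonzero
#' voxel, in canonical z-major, then y, then x order; medium voxels emit
#' nothing. The reader is liberal and also accepts genuine multi-voxel
#' boxes, with later records overwriting earlier ones on collision.
#'
#' @param vol a [label_volume()]
#' @param celltype_map named character vector mapping label IDs to celltype
#'   tokens; defaults to "Cell" for every label. Every nonzero ID must be
#'   covered.
#' @param path optional file path; when given the lines are written there.
#' @return character vector of PIF lines (invisibly when `path` is given).
#' @export
write_pif <- function(vol, celltype_map = NULL, path = NULL) {
  stopifnot(inherits(vol, "label_volume"))
  idx <- which(vol$lattice > 0L)
  ids_present <- label_ids(vol)
  if (is.null(celltype_map)) {
    celltype_map <- stats::setNames(rep("Cell", length(ids_present)),
                                    ids_present)
  }
  missing <- setdiff(as.character(ids_present), names(celltype_map))
  if (length(missing) > 0) {
    stop("no celltype token for label ID(s): ", paste(missing, collapse = ", "))
  }
  if (length(idx) == 0L) {
    lines <- character(0)
  } else {
    co <- arrayInd(idx, dim(vol$lattice)) - 1L   # 0-based (x, y, z)
    id <- vol$lattice[idx]
    o <- order(co[, 3], co[, 2], co[, 1])
    co <- co[o, , drop = FALSE]
    id <- id[o]
    lines <- sprintf("%d %s %d %d %d %d %d %d",
                     id, unname(celltype_map[as.character(id)]),
                     co[, 1], co[, 1], co[, 2], co[, 2], co[, 3], co[, 3])
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a PIF file or its lines back into a label volume
#'
#' @param x a file path or a character vector of PIF lines
#' @param dims optional target lattice dimensions (x, y, z); defaults to
#'   the minimal lattice enclosing all records.
#' @param spacing voxel spacing for the returned volume
#' @return list with `volume` (a [label_volume()]) and `celltype_map`
#'   (named character vector, ID -> token).
#' @export
read_pif <- function(x, dims = NULL, spacing = c(1, 1, 1)) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  keep <- nzchar(trimws(lines))
  fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  lineno <- which(keep)
  n <- length(fields)
  if (n > 0) {
    bad <- which(lengths(fields) != 8L)
    if (length(bad) > 0) {
      stop(sprintf("malformed PIF record on line %d: expected 8 fields, got %d",
                   lineno[bad[1]], lengths(fields)[bad[1]]))
    }
  }
  m <- matrix(NA_integer_, nrow = n, ncol = 7)
  types <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    v <- suppressWarnings(as.integer(f[-2]))
    if (anyNA(v)) {
      stop(sprintf("malformed PIF record on line %d: non-integer field",
                   lineno[i]))
    }
    if (any(v[-1] < 0)) {
      stop(sprintf("negative coordinate in PIF record on line %d", lineno[i]))
    }
    if (v[1] <= 0) {
      stop(sprintf("non-positive cell_ID in PIF record on line %d", lineno[i]))
    }
    if (v[2] > v[3] || v[4] > v[5] || v[6] > v[7]) {
      stop(sprintf("inverted coordinate range in PIF record on line %d",
                   lineno[i]))
    }
    m[i, ] <- v
    types[i] <- f[2]
  }
  if (is.null(dims)) {
    dims <- if (n == 0) c(1L, 1L, 1L) else
      c(max(m[, 3]) + 1L, max(m[, 5]) + 1L, max(m[, 7]) + 1L)
  }
  dims <- as.integer(dims)
  lat <- array(0L, dims)
  cmap <- character(0)
  for (i in seq_len(n)) {
    if (m[i, 3] >= dims[1] || m[i, 5] >= dims[2] || m[i, 7] >= dims[3]) {
      stop(sprintf("PIF record on line %d falls outside the target lattice",
                   lineno[i]))
    }
    lat[(m[i, 2] + 1L):(m[i, 3] + 1L),
        (m[i, 4] + 1L):(m[i, 5] + 1L),
        (m[i, 6] + 1L):(m[i, 7] + 1L)] <- m[i, 1]
    cmap[as.character(m[i, 1])] <- types[i]
  }
  list(volume = label_volume(lat, spacing = spacing), celltype_map = cmap)
}
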