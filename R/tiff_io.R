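#' Read and write 3D label masks as multi-page TIFF
#'
#' Label stacks travel as plain multi-page TIFF: one page per z slice,
#' single-channel, uncompressed, 32-bit signed integer pixels (the writer's
#' only dialect; the reader additionally accepts 8/16-bit and unsigned
#' integer data). Voxel spacing is not guessed from TIFF metadata: it is
#' taken from a JSON sidecar written next to the stack, or must be passed
#' explicitly — otherwise reading errors out.
#'
#' No external TIFF library is linked: the baseline format (header, IFD
#' chain, strip offsets) is small enough to handle directly, and the
#' round-trip is cross-checked against an independent TIFF implementation
#' in the test suite.
#'
#' @param vol a [label_volume()]
#' @param path file path of the `.tif` stack
#' @param sidecar logical; also write `<path minus extension>.json` holding
#'   the spacing (and any extra metadata in `meta`)
#' @param meta optional named list merged into the sidecar JSON
#' @return `write_label_tiff` returns `path` invisibly.
#' @export
write_label_tiff <- function(vol, path, sidecar = TRUE, meta = NULL) {
  stopifnot(inherits(vol, "label_volume"))
  d <- dim(vol$lattice)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  page_bytes <- nx * ny * 4
  n_tags <- 10L
  ifd_bytes <- 2L + n_tags * 12L + 4L
  data_off <- function(z) 8 + (z - 1) * page_bytes
  ifd_off <- function(z) 8 + nz * page_bytes + (z - 1) * ifd_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  writeBin(charToRaw("II"), con)
  w16(42L)
  w32(ifd_off(1L))
  for (z in seq_len(nz)) {
    writeBin(as.integer(vol$lattice[, , z]), con, size = 4, endian = "little")
  }
  # tag ids must appear in ascending order within an IFD
  for (z in seq_len(nz)) {
    w16(n_tags)
    tag <- function(id, type, count, value) {
      w16(id); w16(type); w32(count)
      if (type == 3L) { w16(value); w16(0L) } else w32(value)
    }
    tag(256L, 4L, 1L, nx)              # ImageWidth
    tag(257L, 4L, 1L, ny)              # ImageLength
    tag(258L, 3L, 1L, 32L)             # BitsPerSample
    tag(259L, 3L, 1L, 1L)              # Compression: none
    tag(262L, 3L, 1L, 1L)              # Photometric: BlackIsZero
    tag(273L, 4L, 1L, data_off(z))     # StripOffsets
    tag(277L, 3L, 1L, 1L)              # SamplesPerPixel
    tag(278L, 4L, 1L, ny)              # RowsPerStrip: one strip per page
    tag(279L, 4L, 1L, page_bytes)      # StripByteCounts
    tag(339L, 3L, 1L, 2L)              # SampleFormat: signed integer
    w32(if (z < nz) ifd_off(z + 1L) else 0L)
  }
  if (isTRUE(sidecar)) {
    side <- list(spacing = vol$spacing, shape = as.integer(d), axes = "xyz")
    if (!is.null(meta)) side <- utils::modifyList(side, meta)
    jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' @rdname write_label_tiff
#' @param spacing voxel spacing to use when no sidecar JSON is found;
#'   reading fails if neither is available.
#' @return `read_label_tiff` returns a [label_volume()].
#' @export
read_label_tiff <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  bom <- rawToChar(raw[1:2])
  endian <- if (bom == "II") "little" else if (bom == "MM") "big" else
    stop("not a TIFF file (bad byte-order mark): ", path)
  rd <- function(off, size, n = 1L, signed = TRUE) {
    # readBin only honors signed=FALSE for sizes 1 and 2
    if (size == 4L) signed <- TRUE
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = signed, endian = endian)
  }
  if (rd(2, 2) != 42L) stop("not a TIFF file (bad magic): ", path)

  pages <- list()
  ifd <- rd(4, 4)
  while (ifd != 0L) {
    n_tags <- rd(ifd, 2)
    tags <- list()
    for (i in seq_len(n_tags)) {
      base <- ifd + 2 + (i - 1) * 12
      id <- rd(base, 2, signed = FALSE)
      type <- rd(base + 2, 2)
      count <- rd(base + 4, 4)
      # value(s): SHORT (3) or LONG (4), inline if they fit in 4 bytes
      vsize <- if (type == 3L) 2L else 4L
      voff <- if (count * vsize <= 4) base + 8 else rd(base + 8, 4)
      tags[[as.character(id)]] <-
        rd(voff, vsize, n = count, signed = FALSE)
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    if (any(g(259L, 1L) != 1L)) stop("compressed TIFF not supported: ", path)
    fmt <- g(339L, 1L)[1]
    if (fmt == 3L) {
      stop("label masks must have an integer pixel type, got dtype float")
    }
    if (!fmt %in% c(1L, 2L)) stop("unsupported TIFF sample format: ", fmt)
    bits <- g(258L, 8L)[1]
    if (!bits %in% c(8L, 16L, 32L)) {
      stop("unsupported TIFF bit depth: ", bits)
    }
    if (g(277L, 1L) != 1L) stop("multi-sample TIFF not supported: ", path)
    w <- g(256L); h <- g(257L)
    offs <- g(273L); cnts <- g(279L)
    if (is.null(w) || is.null(h) || is.null(offs) || is.null(cnts)) {
      stop("TIFF page missing required tags: ", path)
    }
    bytes <- bits / 8L
    vals <- integer(w * h)
    pos <- 0L
    for (s in seq_along(offs)) {
      n_px <- cnts[s] / bytes
      # 8-bit reads must be unsigned; wider label values are signed reads
      # (unsigned 16-bit is safe in a signed 32-bit read via size=2
      # signed=FALSE)
      vals[(pos + 1):(pos + n_px)] <- rd(offs[s], bytes, n = n_px,
                                         signed = (bytes == 4L) || fmt == 2L)
      pos <- pos + n_px
    }
    pages[[length(pages) + 1L]] <- list(w = w, h = h, vals = vals)
    ifd <- rd(ifd + 2 + n_tags * 12, 4)
  }
  if (length(pages) == 0L) stop("TIFF contains no pages: ", path)
  w <- pages[[1]]$w; h <- pages[[1]]$h
  same <- vapply(pages, function(p) p$w == w && p$h == h, logical(1))
  if (!all(same)) stop("TIFF pages differ in size: ", path)
  lat <- array(0L, c(w, h, length(pages)))
  for (z in seq_along(pages)) lat[, , z] <- pages[[z]]$vals

  side <- sidecar_path(path)
  if (is.null(spacing)) {
    if (file.exists(side)) {
      spacing <- as.numeric(jsonlite::fromJSON(side)$spacing)
    } else {
      stop("voxel spacing unavailable: no sidecar ", basename(side),
           " and no `spacing` argument given")
    }
  }
  label_volume(lat, spacing = spacing)
}
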