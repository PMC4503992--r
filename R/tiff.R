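# Minimal baseline TIFF support for multi-channel voxel stacks.
#
# No TIFF package is available in the supported environment, so the small
# dialect this package needs is implemented directly: little-endian,
# uncompressed, grayscale, 32-bit IEEE float samples, one strip per page,
# pages ordered z-major / channel-minor.  Stack metadata (channel names,
# shape, voxel size) rides in the first page's ImageDescription as JSON.
# The reader supports exactly this dialect (plus 8/16-bit unsigned
# integer samples) and rejects anything else.

TIFF_TYPE_SIZES <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)

tiff_ifd_entry <- function(tag, type, count, value_bytes) {
  # value_bytes must be a raw vector of length <= 4 (inline) already padded
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    value_bytes)
}

raw_long <- function(v) writeBin(as.integer(v), raw(), size = 4, endian = "little")
raw_short4 <- function(v) c(writeBin(as.integer(v), raw(), size = 2,
                                     endian = "little"), raw(2))

#' Write a voxel stack as a multi-page TIFF
#'
#' Uncompressed little-endian baseline TIFF, 32-bit float samples, one
#' page per (z-slice, channel) in z-major order; channel names, shape and
#' voxel sizes are stored as JSON in the first page's ImageDescription.
#'
#' @param stack A [voxel_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "voxel_stack"))
  d <- dim(stack$channels[[1]])
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  nch <- length(stack$channels)
  desc <- jsonlite::toJSON(list(channels = names(stack$channels),
                                shape = d,
                                voxel_size_um = stack$voxel_size,
                                page_order = "z-major,channel-minor"),
                           auto_unbox = FALSE)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))
  n_pages <- nz * nch
  page_bytes <- nx * ny * 4
  desc_off <- 8L
  data_off <- desc_off + length(desc_raw)
  ifd_off <- data_off + n_pages * page_bytes
  ifd_size <- function(n_entries) 2 + 12 * n_entries + 4
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off), con, size = 4, endian = "little")
  writeBin(desc_raw, con)
  for (z in seq_len(nz)) for (ch in seq_len(nch)) {
    slice <- stack$channels[[ch]][z, , ]
    writeBin(as.numeric(t(slice)), con, size = 4, endian = "little")
  }
  cur_ifd <- ifd_off
  for (p in seq_len(n_pages)) {
    first <- p == 1
    n_entries <- if (first) 10L else 9L
    entries <- c(
      tiff_ifd_entry(256, 4, 1, raw_long(nx)),                 # ImageWidth
      tiff_ifd_entry(257, 4, 1, raw_long(ny)),                 # ImageLength
      tiff_ifd_entry(258, 3, 1, raw_short4(32)),               # BitsPerSample
      tiff_ifd_entry(259, 3, 1, raw_short4(1)),                # Compression
      tiff_ifd_entry(262, 3, 1, raw_short4(1)),                # Photometric
      if (first) tiff_ifd_entry(270, 2, length(desc_raw),
                                raw_long(desc_off)) else raw(0),
      tiff_ifd_entry(273, 4, 1,
                     raw_long(data_off + (p - 1) * page_bytes)), # StripOffsets
      tiff_ifd_entry(278, 4, 1, raw_long(ny)),                 # RowsPerStrip
      tiff_ifd_entry(279, 4, 1, raw_long(page_bytes)),         # StripByteCounts
      tiff_ifd_entry(339, 3, 1, raw_short4(3))                 # SampleFormat
    )
    next_ifd <- if (p < n_pages) cur_ifd + ifd_size(n_entries) else 0L
    writeBin(as.integer(n_entries), con, size = 2, endian = "little")
    writeBin(entries, con)
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    cur_ifd <- cur_ifd + ifd_size(n_entries)
  }
  invisible(path)
}

read_tiff_pages <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, raw(), n = sz)
  rd_int <- function(off, size, signed = FALSE) {
    v <- bytes[(off + 1):(off + size)]
    sum(as.integer(v) * 256^(seq_len(size) - 1))
  }
  if (rawToChar(bytes[1:2]) != "II" || rd_int(2, 2) != 42)
    stop("not a little-endian TIFF file")
  ifd_off <- rd_int(4, 4)
  pages <- list()
  description <- NULL
  while (ifd_off != 0) {
    n_entries <- rd_int(ifd_off, 2)
    tags <- list()
    for (e in seq_len(n_entries)) {
      eo <- ifd_off + 2 + (e - 1) * 12
      tag <- rd_int(eo, 2); type <- rd_int(eo + 2, 2)
      count <- rd_int(eo + 4, 4)
      tsize <- TIFF_TYPE_SIZES[type]
      total <- tsize * count
      voff <- if (total <= 4) eo + 8 else rd_int(eo + 8, 4)
      if (type == 2) {
        val <- rawToChar(bytes[(voff + 1):(voff + count - 1)])
      } else if (type %in% c(3, 4)) {
        val <- vapply(seq_len(count) - 1, function(i)
          rd_int(voff + i * tsize, tsize), numeric(1))
      } else {
        val <- NA
      }
      tags[[as.character(tag)]] <- val
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) stop("TIFF page missing required tags")
    w <- tags[["256"]]; h <- tags[["257"]]
    comp <- tags[["259"]] %||% 1
    if (comp != 1) stop("only uncompressed TIFF is supported")
    bps <- tags[["258"]] %||% 8
    fmt <- tags[["339"]] %||% 1
    offs <- tags[["273"]]; counts <- tags[["279"]]
    if (!is.null(description) || !is.null(tags[["270"]]))
      description <- description %||% tags[["270"]]
    buf <- unlist(lapply(seq_along(offs), function(i)
      bytes[(offs[i] + 1):(offs[i] + counts[i])]), use.names = FALSE)
    vals <- if (fmt == 3 && bps == 32) {
      readBin(buf, numeric(), n = w * h, size = 4, endian = "little")
    } else if (fmt == 1 && bps %in% c(8, 16)) {
      readBin(buf, integer(), n = w * h, size = bps / 8, signed = FALSE,
              endian = "little")
    } else stop("unsupported TIFF sample format (", fmt, "/", bps, " bit)")
    pages[[length(pages) + 1]] <- matrix(vals, h, w, byrow = TRUE)
    ifd_off <- rd_int(ifd_off + 2 + n_entries * 12, 4)
  }
  list(pages = pages, description = description)
}

#' Read a multi-channel voxel stack from TIFF
#'
#' Reads the dialect written by [write_stack_tiff()]: stack shape, channel
#' names and voxel sizes come from the embedded JSON description; an
#' explicit `voxel_size` argument overrides the metadata.  Single-page
#' (2-D) files are rejected as non-stacks.
#'
#' @param path TIFF file path.
#' @param channels Channel names to keep (default: all).
#' @param voxel_size Optional override, um per voxel `(z, y, x)`; required
#'   when the file carries no metadata.
#' @return A [voxel_stack()].
#' @export
read_stack_tiff <- function(path, channels = NULL, voxel_size = NULL) {
  got <- read_tiff_pages(path)
  n_pages <- length(got$pages)
  meta <- NULL
  if (!is.null(got$description))
    meta <- tryCatch(jsonlite::fromJSON(got$description),
                     error = function(e) NULL)
  if (!is.null(meta)) {
    ch_names <- meta$channels
    shp <- as.integer(meta$shape)
    vs <- voxel_size %||% as.numeric(meta$voxel_size_um)
  } else {
    ch_names <- "channel1"
    shp <- c(n_pages, dim(got$pages[[1]]))
    vs <- voxel_size
    if (is.null(vs))
      stop("TIFF carries no voxel-size metadata; supply voxel_size")
  }
  if (n_pages < 2 || shp[1] < 2)
    stop("single-plane TIFF rejected: a z-stack is required")
  nch <- length(ch_names)
  if (n_pages != shp[1] * nch)
    stop("page count does not match shape/channels metadata")
  chans <- lapply(seq_len(nch), function(ci) {
    arr <- array(0, shp)
    for (z in seq_len(shp[1]))
      arr[z, , ] <- got$pages[[(z - 1) * nch + ci]]
    arr
  })
  names(chans) <- ch_names
  if (!is.null(channels)) {
    missing_ch <- setdiff(channels, ch_names)
    if (length(missing_ch) > 0)
      stop("missing channel(s): ", paste(missing_ch, collapse = ", "))
    chans <- chans[channels]
  }
  voxel_stack(chans, vs)
}
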