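# Minimal DICOM series writer/reader (explicit VR little endian, single-frame
# CT). Covers the subset of the standard the pipeline needs — pixel geometry,
# slice position, rescale slope/intercept, series identity — so synthetic
# cohorts can round-trip through the on-disk layout clinical exports use.

dcm_short_vrs <- c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO",
                   "LT","PN","SH","SL","SS","ST","TM","UI","UL","US")

dcm_element <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2 == 1)
    value_raw <- c(value_raw, if (vr == "UI") as.raw(0) else charToRaw(" "))
  hdr <- c(writeBin(as.integer(c(group, element)), raw(), size = 2,
                    endian = "little"),
           charToRaw(vr))
  len <- length(value_raw)
  if (vr %in% dcm_short_vrs) {
    c(hdr, writeBin(as.integer(len), raw(), size = 2, endian = "little"),
      value_raw)
  } else {
    c(hdr, raw(2), writeBin(as.integer(len), raw(), size = 4,
                            endian = "little"),
      value_raw)
  }
}

dcm_str <- function(group, element, vr, s)
  dcm_element(group, element, vr, charToRaw(s))

dcm_us <- function(group, element, v)
  dcm_element(group, element, "US",
              writeBin(as.integer(v), raw(), size = 2, endian = "little"))

fmt_ds <- function(x) paste(formatC(x, format = "fg", digits = 10),
                            collapse = "\\")

#' Write a CT volume as a DICOM series
#'
#' One explicit-VR little-endian single-frame file per axial slice. Stored
#' values are `(HU - intercept) / slope` as signed 16-bit integers.
#'
#' @param volume a [ct_volume()]
#' @param dir output directory (created if needed)
#' @param slope,intercept rescale mapping from stored values to HU
#' @param series_uid series instance UID shared by all slices
#' @return the directory, invisibly
#' @export
write_dicom_series <- function(volume, dir, slope = 1, intercept = -1024,
                               series_uid = "1.2.826.0.1.3680043.9999.1") {
  stopifnot(inherits(volume, "ct_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$intensities)
  sp <- volume$spacing_mm
  for (z in seq_len(d[3])) {
    sl <- volume$intensities[, , z]
    stored <- as.integer(round((sl - intercept) / slope))
    pos <- volume$origin_mm + c(0, 0, (z - 1) * sp[3])
    px <- writeBin(stored, raw(), size = 2, endian = "little")
    body <- c(
      dcm_str(0x0008, 0x0018, "UI", paste0(series_uid, ".", z)),
      dcm_str(0x0008, 0x0060, "CS", "CT"),
      dcm_str(0x0018, 0x0050, "DS", fmt_ds(sp[3])),
      dcm_str(0x0020, 0x000E, "UI", series_uid),
      dcm_str(0x0020, 0x0013, "IS", as.character(z)),
      dcm_str(0x0020, 0x0032, "DS", fmt_ds(pos)),
      dcm_str(0x0020, 0x0037, "DS", fmt_ds(c(1, 0, 0, 0, 1, 0))),
      dcm_us(0x0028, 0x0002, 1L),
      dcm_us(0x0028, 0x0010, d[2]),   # Rows (y)
      dcm_us(0x0028, 0x0011, d[1]),   # Columns (x)
      dcm_str(0x0028, 0x0030, "DS", fmt_ds(c(sp[2], sp[1]))),  # row, col
      dcm_us(0x0028, 0x0100, 16L), dcm_us(0x0028, 0x0101, 16L),
      dcm_us(0x0028, 0x0102, 15L), dcm_us(0x0028, 0x0103, 1L),
      dcm_str(0x0028, 0x1052, "DS", fmt_ds(intercept)),
      dcm_str(0x0028, 0x1053, "DS", fmt_ds(slope)),
      dcm_element(0x7FE0, 0x0010, "OW", px)
    )
    meta <- dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
    meta <- c(dcm_element(0x0002, 0x0000, "UL",
                          writeBin(as.integer(length(meta)), raw(), size = 4,
                                   endian = "little")),
              meta)
    con <- file(file.path(dir, sprintf("CT%04d.dcm", z)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(dir)
}

dcm_parse_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stopf("format error: %s is not a DICOM file", path)
  pos <- 133L
  els <- list()
  n <- length(raw)
  while (pos + 7 <= n) {
    group <- readBin(raw[pos:(pos + 1)], "integer", size = 2,
                     endian = "little", signed = FALSE)
    element <- readBin(raw[(pos + 2):(pos + 3)], "integer", size = 2,
                       endian = "little", signed = FALSE)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% dcm_short_vrs) {
      len <- readBin(raw[(pos + 6):(pos + 7)], "integer", size = 2,
                     endian = "little", signed = FALSE)
      data_at <- pos + 8L
    } else {
      len <- readBin(raw[(pos + 8):(pos + 11)], "integer", size = 4,
                     endian = "little")
      data_at <- pos + 12L
    }
    if (len < 0 || data_at + len - 1 > n)
      stopf("format error: truncated element in %s", path)
    key <- sprintf("%04x,%04x", group, element)
    els[[key]] <- if (len > 0) raw[data_at:(data_at + len - 1)] else raw(0)
    pos <- data_at + len
  }
  els
}

dcm_string <- function(els, key) {
  v <- els[[key]]
  if (is.null(v)) return(NULL)
  trimws(gsub("\\x00", "", rawToChar(v), useBytes = TRUE))
}

dcm_numbers <- function(els, key) {
  s <- dcm_string(els, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us_value <- function(els, key) {
  v <- els[[key]]
  if (is.null(v)) return(NULL)
  readBin(v, "integer", size = 2, endian = "little", signed = FALSE)
}

#' Read a DICOM series directory into a CT volume
#'
#' Slices are sorted by their position along the slice normal regardless of
#' file naming; rescale slope/intercept is applied so intensities are HU.
#'
#' @param path directory containing `.dcm` files of a single series
#' @param slice_gap_tol tolerance on slice-gap uniformity in mm
#' @return a [ct_volume()]
#' @export
read_dicom_series <- function(path, slice_gap_tol = 1e-3) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) stopf("no DICOM files found in %s", path)
  parsed <- lapply(files, dcm_parse_file)
  uids <- vapply(parsed, function(e) dcm_string(e, "0020,000e") %||% "",
                 character(1))
  if (length(unique(uids)) != 1)
    stopf("format error: %s contains mixed series (%s)", path,
          paste(unique(uids), collapse = ", "))
  zpos <- vapply(parsed, function(e) {
    p <- dcm_numbers(e, "0020,0032")
    if (is.null(p)) stopf("format error: missing image position in %s", path)
    p[3]
  }, numeric(1))
  ord <- order(zpos)
  parsed <- parsed[ord]; zpos <- zpos[ord]; files <- files[ord]
  first <- parsed[[1]]
  ps <- dcm_numbers(first, "0028,0030")
  if (is.null(ps)) stopf("format error: missing pixel spacing in %s", files[1])
  rows <- dcm_us_value(first, "0028,0010")
  cols <- dcm_us_value(first, "0028,0011")
  if (length(zpos) > 1) {
    gaps <- diff(zpos)
    if (any(gaps <= 0) || max(gaps) - min(gaps) > slice_gap_tol)
      stopf("format error: non-uniform slice gap in %s (range %.5f-%.5f mm)",
            path, min(gaps), max(gaps))
    dz <- gaps[1]
  } else {
    dz <- dcm_numbers(first, "0018,0050") %||% 1
  }
  slices <- lapply(seq_along(parsed), function(i) {
    e <- parsed[[i]]
    if ((dcm_us_value(e, "0028,0010") %||% -1) != rows ||
        (dcm_us_value(e, "0028,0011") %||% -1) != cols)
      stopf("format error: slice shape mismatch in %s", files[i])
    slope <- (dcm_numbers(e, "0028,1053") %||% 1)[1]
    inter <- (dcm_numbers(e, "0028,1052") %||% 0)[1]
    stored <- readBin(e[["7fe0,0010"]], "integer",
                      n = as.numeric(rows) * cols, size = 2,
                      endian = "little")
    matrix(stored * slope + inter, nrow = cols, ncol = rows)
  })
  vol <- array(0, c(cols, rows, length(slices)))
  for (i in seq_along(slices)) vol[, , i] <- slices[[i]]
  pos0 <- dcm_numbers(first, "0020,0032")
  ct_volume(vol, spacing_mm = c(ps[2], ps[1], dz),
            origin_mm = c(pos0[1], pos0[2], pos0[3]))
}
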