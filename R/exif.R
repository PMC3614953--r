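# Minimal JPEG EXIF support: just enough of the TIFF/EXIF structure to read
# and write the capture timestamp (DateTimeOriginal, tag 0x9003, with
# DateTime, tag 0x0132, as fallback). Timestamps use the EXIF string format
# "YYYY:MM:DD HH:MM:SS" with no timezone; they are parsed as-is (UTC label)
# so calendar-day grouping never shifts.

EXIF_TIME_FORMAT <- "%Y:%m:%d %H:%M:%S"

#' Capture time of a photograph
#'
#' Reads the EXIF `DateTimeOriginal` (falling back to `DateTime`) from a JPEG
#' file. When the file is not a JPEG, carries no readable EXIF block, or the
#' block is corrupt, the file modification time is used instead and a warning
#' is emitted; the `source` field records which path was taken so downstream
#' records keep the provenance.
#'
#' @param path Path to an image file.
#' @return A list with `time` (POSIXct, UTC label, no timezone shifting) and
#'   `source` (`"exif"` or `"mtime"`).
#' @export
read_capture_time <- function(path) {
  if (!file.exists(path)) {
    pc_abort(paste0("Cannot read file: ", path), "pathcurve_unreadable_file")
  }
  ts <- tryCatch(exif_datetime(path), error = function(e) NULL)
  if (!is.null(ts) && !is.na(ts)) {
    return(list(time = ts, source = "exif"))
  }
  warn(paste0("No usable EXIF timestamp in ", basename(path),
              "; falling back to file modification time."))
  mt <- file.mtime(path)
  list(time = as.POSIXct(format(mt, "%Y-%m-%d %H:%M:%S"), tz = "UTC"),
       source = "mtime")
}

# Parse the first EXIF APP1 segment of a JPEG; returns POSIXct or NA.
exif_datetime <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  tiff <- find_exif_tiff(raw)
  if (is.null(tiff)) return(NA)
  le <- identical(as.integer(tiff[1:2]), c(0x49L, 0x49L))     # "II" vs "MM"
  if (!le && !identical(as.integer(tiff[1:2]), c(0x4dL, 0x4dL))) return(NA)
  u16 <- function(off) rd_uint(tiff, off, 2, le)
  u32 <- function(off) rd_uint(tiff, off, 4, le)
  if (u16(3) != 42) return(NA)
  ifd0 <- u32(5) + 1                                           # 1-based offset
  tags0 <- read_ifd(tiff, ifd0, le)
  get_str <- function(tags, tag) {
    row <- tags[tags$tag == tag & tags$type == 2, ]
    if (nrow(row) == 0) return(NULL)
    cnt <- row$count[1]
    off <- if (cnt <= 4) row$entry_off[1] + 8 else row$value[1] + 1
    if (off + cnt - 2 > length(tiff)) return(NULL)
    rawToChar(tiff[off:(off + cnt - 2)])                       # strip NUL
  }
  s <- NULL
  exif_ptr <- tags0[tags0$tag == 0x8769, ]
  if (nrow(exif_ptr) > 0) {
    tags_exif <- read_ifd(tiff, exif_ptr$value[1] + 1, le)
    s <- get_str(tags_exif, 0x9003)
  }
  if (is.null(s)) s <- get_str(tags0, 0x0132)
  if (is.null(s)) return(NA)
  as.POSIXct(trimws(s), format = EXIF_TIME_FORMAT, tz = "UTC")
}

# Locate the TIFF payload of the APP1 "Exif" segment; NULL when absent.
find_exif_tiff <- function(raw) {
  n <- length(raw)
  if (n < 4 || raw[1] != as.raw(0xff) || raw[2] != as.raw(0xd8)) return(NULL)
  i <- 3
  while (i + 3 <= n && raw[i] == as.raw(0xff)) {
    marker <- as.integer(raw[i + 1])
    if (marker == 0xda || marker == 0xd9) break                # SOS / EOI
    len <- 256L * as.integer(raw[i + 2]) + as.integer(raw[i + 3])
    if (marker == 0xe1 && len >= 14 &&
        identical(as.integer(raw[(i + 4):(i + 9)]),
                  c(0x45L, 0x78L, 0x69L, 0x66L, 0L, 0L))) {
      return(raw[(i + 10):(i + 1 + len)])
    }
    i <- i + 2 + len
  }
  NULL
}

rd_uint <- function(raw, off, nbytes, le) {
  b <- as.integer(raw[off:(off + nbytes - 1)])
  if (le) b <- rev(b)
  Reduce(function(a, x) a * 256 + x, b, accumulate = FALSE)
}

# Read one IFD: tibble of tag, type, count, value (interpreted as uint when
# it fits in the 4 value bytes) and entry_off (1-based offset of the entry).
read_ifd <- function(tiff, off, le) {
  if (off + 1 > length(tiff)) stop("truncated IFD")
  n <- rd_uint(tiff, off, 2, le)
  if (n > 256) stop("implausible IFD entry count")
  entries <- lapply(seq_len(n), function(k) {
    eo <- off + 2 + (k - 1) * 12
    if (eo + 11 > length(tiff)) stop("truncated IFD entry")
    data.frame(tag = rd_uint(tiff, eo, 2, le),
               type = rd_uint(tiff, eo + 2, 2, le),
               count = rd_uint(tiff, eo + 4, 4, le),
               value = rd_uint(tiff, eo + 8, 4, le),
               entry_off = eo)
  })
  do.call(rbind, c(entries, list(make.row.names = FALSE)))
}

#' Write a JPEG with an EXIF capture timestamp
#'
#' Encodes the grayscale image (0-255 matrix) as a JPEG and splices in a
#' minimal EXIF APP1 segment carrying `DateTimeOriginal` and `DateTime`.
#'
#' @param img Numeric matrix, intensities 0-255.
#' @param path Output path.
#' @param datetime POSIXct capture time.
#' @param quality JPEG quality in (0, 1].
#' @return `path`, invisibly.
#' @export
write_jpeg_with_time <- function(img, path, datetime, quality = 0.92) {
  tmp <- tempfile(fileext = ".jpg")
  on.exit(unlink(tmp), add = TRUE)
  jpeg::writeJPEG(pmin(pmax(img, 0), 255) / 255, tmp, quality = quality)
  raw <- readBin(tmp, "raw", n = file.size(tmp))
  app1 <- build_exif_app1(datetime)
  out <- c(raw[1:2], app1, raw[3:length(raw)])                 # after SOI
  writeBin(out, path)
  invisible(path)
}

# APP1 segment: IFD0 {DateTime, ExifIFD pointer}, Exif IFD {DateTimeOriginal}.
build_exif_app1 <- function(datetime) {
  s <- format(datetime, EXIF_TIME_FORMAT, tz = "UTC")
  str20 <- c(charToRaw(s), as.raw(0))                          # 20 bytes
  stopifnot(length(str20) == 20)
  le16 <- function(x) as.raw(c(x %% 256, x %/% 256))
  le32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                               (x %/% 65536) %% 256, x %/% 16777216))
  entry <- function(tag, type, count, value)
    c(le16(tag), le16(type), le32(count), le32(value))
  tiff <- c(
    charToRaw("II"), le16(42), le32(8),                        # header
    le16(2),                                                   # IFD0: 2 entries
    entry(0x0132, 2, 20, 56),                                  # DateTime
    entry(0x8769, 4, 1, 38),                                   # Exif IFD at 38
    le32(0),
    le16(1),                                                   # Exif IFD
    entry(0x9003, 2, 20, 76),                                  # DateTimeOriginal
    le32(0),
    str20, str20)                                              # at 56 and 76
  payload <- c(charToRaw("Exif"), as.raw(c(0, 0)), tiff)
  len <- length(payload) + 2
  c(as.raw(c(0xff, 0xe1)), as.raw(c(len %/% 256, len %% 256)), payload)
}
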