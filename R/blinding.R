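# Blinded measurement workflow: the operator must not know which photograph
# (and hence which capture time) is being measured, so a directory of images
# is presented in a persisted random order under sequential codes only.

ORDER_FILE <- "pathcurve_order.txt"
ORDER_HEADER <- "pathcurve-order v1"
RESULTS_FILE <- "measurements.csv"

IMAGE_EXTENSIONS <- c("jpg", "jpeg", "png")

#' Code a directory of images for blinded measurement
#'
#' Lists the supported images of `directory`, shuffles them with a seeded RNG
#' and assigns sequential codes 1..N. The ordering is persisted in a small
#' text order file inside the directory: re-opening the directory reproduces
#' the identical mapping, so repeat measurements can be taken in the same
#' blinded order without the risk of missing a picture. Deleting the order
#' file (see [recode_images()]) is the only way to obtain a new order. A
#' corrupt or inconsistent order file raises an error rather than silently
#' reshuffling.
#'
#' @param directory Directory containing `.jpg`, `.jpeg` or `.png` images.
#' @param seed Integer RNG seed for a fresh shuffle; ignored when an order
#'   file already exists. `NULL` draws a seed from the session RNG.
#' @return An object of class `coded_image_set`. Its print method and
#'   [tidy()] show codes and measurement counts only; real filenames are
#'   revealed only by the explicit [unblind()] step.
#' @export
code_images <- function(directory, seed = NULL) {
  files <- list_images(directory)
  if (length(files) == 0) {
    pc_abort(paste0("No supported images in ", directory),
             "pathcurve_empty_directory")
  }
  order_path <- file.path(directory, ORDER_FILE)
  if (file.exists(order_path)) {
    ord <- read_order_file(order_path, files)
  } else {
    if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
    seed <- as.integer(seed)
    perm <- withr::with_seed(seed, sample.int(length(files)))
    ord <- list(seed = seed,
                entries = tibble(code = seq_along(files),
                                 filename = files[perm]))
    write_order_file(order_path, ord)
  }
  structure(list(directory = directory, entries = ord$entries,
                 seed = ord$seed, order_path = order_path),
            class = "coded_image_set")
}

list_images <- function(directory) {
  if (!dir.exists(directory)) {
    pc_abort(paste0("Not a directory: ", directory),
             "pathcurve_empty_directory")
  }
  files <- list.files(directory)
  sort(files[tolower(tools::file_ext(files)) %in% IMAGE_EXTENSIONS])
}

write_order_file <- function(path, ord) {
  writeLines(c(ORDER_HEADER,
               paste0("seed,", ord$seed),
               paste0(ord$entries$code, ",", ord$entries$filename)),
             path)
}

read_order_file <- function(path, files) {
  lines <- readLines(path, warn = FALSE)
  bad <- function(why) {
    pc_abort(paste0("Corrupt order file ", path, ": ", why,
                    ". Delete it to regenerate a fresh random order."),
             "pathcurve_corrupt_order_file")
  }
  if (length(lines) < 3 || lines[1] != ORDER_HEADER) bad("bad header")
  if (!grepl("^seed,-?[0-9]+$", lines[2])) bad("bad seed line")
  seed <- as.integer(sub("^seed,", "", lines[2]))
  body <- lines[-(1:2)]
  parts <- regmatches(body, regexec("^([0-9]+),(.+)$", body))
  if (any(lengths(parts) != 3)) bad("malformed entry line")
  codes <- as.integer(vapply(parts, `[`, "", 2))
  fnames <- vapply(parts, `[`, "", 3)
  if (!setequal(codes, seq_along(codes)) || anyDuplicated(codes)) {
    bad("codes are not a permutation of 1..N")
  }
  if (!setequal(fnames, files)) {
    bad("listed files do not match the directory contents")
  }
  o <- order(codes)
  list(seed = seed, entries = tibble(code = codes[o], filename = fnames[o]))
}

#' Force a new random order
#'
#' Deletes the order file so the next [code_images()] call reshuffles.
#' @param directory The coded directory.
#' @return `TRUE` invisibly.
#' @export
recode_images <- function(directory) {
  unlink(file.path(directory, ORDER_FILE))
  invisible(TRUE)
}

#' @export
print.coded_image_set <- function(x, ...) {
  counts <- measurement_counts(x)
  cat(sprintf("<coded_image_set> %d blinded images in %s (order seed %d)\n",
              nrow(x$entries), x$directory, x$seed))
  print(as.data.frame(counts), row.names = FALSE)
  invisible(x)
}

#' Blinded listing of a coded image set
#'
#' @param x A [code_images()] result.
#' @param ... Unused.
#' @return A tibble with `code` and `n_measured` only -- no filenames.
#' @export
tidy.coded_image_set <- function(x, ...) measurement_counts(x)

#' Measurement counts per blinded code
#'
#' Scans the results CSV of the coded directory and reports how many
#' measurements each code has received (zero when the CSV is absent). The
#' counts are what the blinded operator sees; they are invariant under the
#' CSV row order.
#'
#' @param set A [code_images()] result.
#' @param csv_path Results file; defaults to `measurements.csv` inside the
#'   coded directory.
#' @return A tibble with columns `code` and `n_measured`.
#' @export
measurement_counts <- function(set, csv_path = file.path(set$directory, RESULTS_FILE)) {
  counts <- tibble(code = set$entries$code, n_measured = 0L)
  if (file.exists(csv_path)) {
    rec <- readr::read_csv(csv_path, show_col_types = FALSE)
    tab <- table(factor(rec$code, levels = counts$code))
    counts$n_measured <- as.integer(tab)
  }
  counts
}

#' Reveal the code-to-filename mapping
#'
#' Unblinding is a deliberate, explicit export step; nothing else in the
#' blinded workflow exposes filenames keyed by code.
#'
#' @param set A [code_images()] result.
#' @return A tibble with `code` and `filename`.
#' @export
unblind <- function(set) {
  stopifnot(inherits(set, "coded_image_set"))
  set$entries
}

# Resolve a code to its image path (internal: used by the measurement loop,
# which never prints the filename).
code_path <- function(set, code) {
  row <- set$entries[set$entries$code == code, ]
  if (nrow(row) != 1) {
    pc_abort(paste0("Unknown code ", code), "pathcurve_unknown_code")
  }
  file.path(set$directory, row$filename)
}

MEASUREMENT_COLUMNS <- c(
  "code", "filename", "capture_time", "capture_time_source", "measured_at",
  "operator", "lambda", "h", "w", "w_eff", "alpha", "x0", "y0",
  "energy", "n_pixels", "threshold", "cut_top", "cut_bottom")

#' Assemble a measurement record
#'
#' One completed fit becomes one append-only CSV row holding the code, the
#' real filename, the capture time (with its provenance), the wall time of
#' the measurement, the operator id, all six curve parameters plus the drawn
#' width `w_eff`, the energy, and the configuration actually used.
#'
#' @param code Blinded code of the image.
#' @param filename Real image filename.
#' @param capture Capture time list from [read_capture_time()].
#' @param fit A `pathcurve_fit` (from [fit_outline()] or [staged_fit()]).
#' @param operator Operator identifier.
#' @param threshold Binarization threshold used.
#' @param measured_at Wall time of the measurement.
#' @return A one-row tibble in the canonical column order.
#' @export
measurement_record <- function(code, filename, capture, fit, operator,
                               threshold = fit$threshold,
                               measured_at = Sys.time()) {
  p <- fit$params
  tibble(code = as.integer(code), filename = filename,
         capture_time = format(capture$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
         capture_time_source = capture$source,
         measured_at = format(measured_at, "%Y-%m-%dT%H:%M:%S"),
         operator = operator,
         lambda = p$lambda, h = p$h, w = p$w, w_eff = w_eff(p),
         alpha = p$alpha, x0 = p$x0, y0 = p$y0,
         energy = fit$energy, n_pixels = fit$n_pixels,
         threshold = threshold,
         cut_top = fit$ecfg$cut_top, cut_bottom = fit$ecfg$cut_bottom)
}

#' Append a measurement record to the results CSV
#'
#' The header is written once, when the file is created; every later call
#' appends exactly one RFC-4180 row (quoting only where needed, ISO-8601
#' timestamps, full float precision). Appends are atomic at row granularity:
#' each row is written in a single call, so interleaved writers cannot split
#' a row.
#'
#' @param record A one-row tibble from [measurement_record()].
#' @param csv_path Path of the results CSV.
#' @return `csv_path`, invisibly.
#' @export
append_record <- function(record, csv_path) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(record))
  if (length(missing_cols) > 0) {
    pc_abort(paste0("Record is missing columns: ",
                    paste(missing_cols, collapse = ", ")),
             "pathcurve_bad_record")
  }
  record <- record[, MEASUREMENT_COLUMNS]
  new <- !file.exists(csv_path)
  readr::write_csv(record, csv_path, append = !new, col_names = new)
  invisible(csv_path)
}

#' Read a results CSV
#'
#' @param csv_path Path of a results file written by [append_record()].
#' @return A tibble with `capture_time` and `measured_at` parsed as POSIXct
#'   (UTC label, no timezone shifting).
#' @export
read_records <- function(csv_path) {
  rec <- readr::read_csv(csv_path, show_col_types = FALSE)
  rec$code <- as.integer(rec$code)
  rec$n_pixels <- as.integer(rec$n_pixels)
  rec$capture_time <- as.POSIXct(rec$capture_time,
                                 format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  rec$measured_at <- as.POSIXct(rec$measured_at,
                                format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  rec
}
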