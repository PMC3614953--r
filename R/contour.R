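#' Read a photograph as a grayscale matrix
#'
#' Reads a JPEG or PNG file and returns an 8-bit grayscale intensity matrix
#' (rows x cols, values 0-255, origin top-left, row-major). Color images are
#' converted with [to_gray()].
#'
#' @param path Path to a `.jpg`, `.jpeg` or `.png` file.
#' @return A numeric matrix of intensities 0-255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    pc_abort(paste0("Cannot read image: ", path), "pathcurve_unreadable_file")
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    jpg = , jpeg = jpeg::readJPEG(path),
    png = png::readPNG(path),
    pc_abort(paste0("Unsupported image format: .", ext),
             "pathcurve_unreadable_file"))
  to_gray(img * 255)
}

#' Convert an image to 8-bit grayscale
#'
#' One-channel input is returned unchanged (rounded to integers); three- or
#' four-channel input is reduced with the standard luma weights
#' `0.299 R + 0.587 G + 0.114 B` (an alpha channel is ignored).
#'
#' @param img A matrix (rows x cols) or array (rows x cols x channels) of
#'   intensities in 0-255.
#' @return A numeric matrix of intensities 0-255.
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(round(img))
  if (is.array(img) && length(dim(img)) == 3 && dim(img)[3] >= 3) {
    luma <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    return(matrix(round(luma), dim(img)[1], dim(img)[2]))
  }
  pc_abort("Expected a rows x cols matrix or rows x cols x 3 array.",
           "pathcurve_bad_image")
}

#' Threshold an image to a binary silhouette
#'
#' The threshold must be chosen by the operator based on the picture's
#' lighting. With `polarity = "dark"` (the default; the organ silhouettes dark
#' against a bright background) foreground pixels are those strictly below the
#' threshold; with `"bright"`, strictly above. Thresholding is monotone:
#' foreground sets are nested as the threshold grows.
#'
#' @param img Grayscale matrix from [read_image()] or [to_gray()].
#' @param threshold Intensity cut in `[0, 255]`.
#' @param polarity `"dark"` or `"bright"`.
#' @return A logical matrix, `TRUE` on the foreground.
#' @export
binarize <- function(img, threshold, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(img), is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 256)
  if (polarity == "dark") img < threshold else img > threshold
}

#' Trace the outline of the photographed object
#'
#' Labels the connected foreground components, keeps the one of largest area
#' (at least `min_area` pixels), and traces its outer boundary as an ordered,
#' 8-connected pixel chain, oriented counter-clockwise when the image is
#' viewed with y up. Holes are ignored.
#'
#' @param bw Logical (or 0/1) foreground matrix from [binarize()].
#' @param min_area Minimum component area in pixels; smaller specks are not
#'   accepted as the object.
#' @return An object of class `outline_contour`: a tibble with integer columns
#'   `row`, `col`, attribute `shape`, and `closed = TRUE`.
#' @section Errors: Raises a `pathcurve_no_object` error when no component
#'   reaches `min_area` -- typically the sign of an inadequate threshold.
#' @export
extract_contour <- function(bw, min_area = 16) {
  stopifnot(is.matrix(bw))
  m <- matrix(as.numeric(bw), nrow(bw), ncol(bw))
  lab <- EBImage::bwlabel(EBImage::Image(m))
  labs <- EBImage::imageData(lab)
  areas <- tabulate(labs[labs > 0])
  if (length(areas) == 0 || max(areas) < min_area) {
    pc_abort(paste0(
      "No object found: no foreground component of area >= ", min_area,
      " px. Check the binarization threshold."), "pathcurve_no_object")
  }
  best <- which.max(areas)
  oc <- EBImage::ocontour(lab)[[best]] + 1L  # 0-based -> 1-based (row, col)
  # drop consecutive duplicates, close implicitly
  keep <- c(TRUE, diff(oc[, 1]) != 0 | diff(oc[, 2]) != 0)
  oc <- oc[keep, , drop = FALSE]
  # fixed orientation: counter-clockwise with y up, i.e. shoelace area on
  # (x = col, y = -row) positive
  xs <- oc[, 2]; ys <- -oc[, 1]
  area2 <- sum(xs * (ys[c(2:length(ys), 1)] - ys[c(length(ys), 1:(length(ys) - 1))]))
  if (area2 < 0) oc <- oc[rev(seq_len(nrow(oc))), , drop = FALSE]
  out <- tibble(row = as.integer(oc[, 1]), col = as.integer(oc[, 2]))
  structure(out, shape = dim(bw), closed = TRUE,
            class = c("outline_contour", class(out)))
}

#' Exact Euclidean distance map of a contour
#'
#' Builds the rows x cols grid holding, for every pixel, the exact (not
#' chamfer-approximate) Euclidean distance to the nearest contour pixel. This
#' map turns the curve-to-contour congruence measure into a set of per-pixel
#' lookups, and its exactness underpins the least-squares interpretation of
#' the fitting energy.
#'
#' @param contour An [extract_contour()] result, or any two-column matrix /
#'   data frame of (row, col) pixels.
#' @param shape Image shape `c(rows, cols)`; defaults to the contour's own
#'   recorded shape.
#' @return A numeric rows x cols matrix of distances in pixels, zero exactly
#'   on contour pixels.
#' @export
distance_map <- function(contour, shape = attr(contour, "shape")) {
  pts <- as.matrix(as.data.frame(contour)[, c("row", "col")])
  stopifnot(nrow(pts) >= 1, length(shape) == 2)
  if (any(pts[, 1] < 1 | pts[, 1] > shape[1] |
          pts[, 2] < 1 | pts[, 2] > shape[2])) {
    pc_abort("Contour pixels fall outside the given shape.",
             "pathcurve_bad_contour")
  }
  m <- matrix(1, shape[1], shape[2])
  m[pts] <- 0
  EBImage::imageData(EBImage::distmap(EBImage::Image(m), metric = "euclidean"))
}
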