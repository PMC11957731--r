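#' Read an image as an 8-bit grayscale matrix
#'
#' Loads a PNG/TIFF/JPEG image and returns a numeric matrix of integer
#' intensities in \[0, 255\], indexed \[row, col\] with row 1 at the top.
#' Color images are converted to grayscale by luminance; for fluorescence
#' plates the green channel alone can be used instead.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @param channel `"luminance"` (default) or `"green"` for fluorescence images.
#' @return Numeric matrix of intensities in \[0, 255\].
#' @export
read_gray <- function(path, channel = c("luminance", "green")) {
  channel <- match.arg(channel)
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) == EBImage::Color) {
    img <- EBImage::channel(img, ifelse(channel == "green", "green", "luminance"))
  }
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2L) m <- m[, , 1L]
  # EBImage stores [x, y]; transpose to [row, col]
  round(t(m) * 255)
}

#' Write a grayscale matrix or binary mask as a PNG
#'
#' @param img Numeric matrix in \[0, 255\] or a logical mask.
#' @param path Output path (extension selects the format).
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  if (is.logical(img)) img <- img * 255
  EBImage::writeImage(EBImage::Image(t(img / 255)), path)
  invisible(path)
}

#' Otsu threshold over integer intensity levels
#'
#' Exhaustively scans all integer thresholds 0..254 and returns the one that
#' maximizes the between-class variance of the split into background
#' (intensity <= t) and foreground (intensity > t). Colonies are assumed
#' bright on a dark background, so foreground is the brighter class.
#'
#' @param img Numeric matrix of intensities in \[0, 255\].
#' @return Integer threshold `t`; pixels with intensity > `t` are foreground.
#'   For a constant image no split exists: the maximum intensity is returned
#'   (empty foreground) with attribute `degenerate = TRUE` and a warning.
#' @export
otsu_threshold <- function(img) {
  v <- as.vector(img)
  stopifnot(length(v) >= 1)
  if (length(unique(v)) == 1L) {
    warning("constant image: no foreground/background split exists")
    return(structure(max(v), degenerate = TRUE))
  }
  h <- tabulate(as.integer(v) + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h) / n                      # P(class bg) at threshold t = lev
  mu0 <- cumsum(h * lev) / n               # unnormalized bg mean
  mu_t <- mu0[256]
  # between-class variance for t = 0..254
  w <- w0[1:255]
  m <- mu0[1:255]
  valid <- w > 0 & w < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w[valid] - m[valid])^2 / (w[valid] * (1 - w[valid]))
  as.integer(which.max(sigma_b) - 1L)
}

#' Binarize a grayscale image with the Otsu threshold
#'
#' @param img Numeric matrix in \[0, 255\].
#' @param invert If `TRUE`, foreground is the darker class (dark colonies on
#'   light agar).
#' @param min_contrast Minimum separation between the class means for the
#'   split to be accepted (default 30 intensity levels). Otsu always finds
#'   *some* threshold, so on a blank plate it would split the noise in two;
#'   colonies are far brighter than agar, so a split whose classes differ
#'   by less than `min_contrast` is treated as background only.
#' @return Logical matrix; `TRUE` = foreground.
#' @export
binarize <- function(img, invert = FALSE, min_contrast = 30) {
  if (invert) img <- 255 - img
  t <- otsu_threshold(img)
  if (isTRUE(attr(t, "degenerate"))) {
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  fg <- img > t
  if (abs(mean(img[fg]) - mean(img[!fg])) < min_contrast) {
    warning("class means closer than min_contrast: treating image as background only")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  fg
}

#' Remove small noise from a binary mask by morphological opening
#'
#' Applies erosion followed by dilation (opening), repeated `times` times,
#' with a square structuring element. Opening is anti-extensive: the result
#' is always a subset of the input.
#'
#' @param mask Logical matrix.
#' @param brush_size Side of the square structuring element (default 3).
#' @param times Number of opening rounds (default 2).
#' @return Logical matrix of the same shape.
#' @export
clean_mask <- function(mask, brush_size = 3L, times = 2L) {
  stopifnot(is.logical(mask))
  if (!any(mask)) return(mask)
  kern <- EBImage::makeBrush(brush_size, shape = "box")
  m <- mask * 1
  for (i in seq_len(times)) {
    m <- EBImage::dilate(EBImage::erode(m, kern), kern)
  }
  m > 0
}

#' Split a mask into connected foreground segments
#'
#' Labels connected components (8-connectivity, so diagonally touching
#' colonies stay one segment) and returns each as a [Segment] carrying a
#' tight-bounding-box mask plus its offset in the parent image. Components
#' smaller than `min_area` pixels are discarded as noise survivors.
#'
#' @param mask Logical matrix (ideally after [clean_mask()]).
#' @param min_area Minimum component area in pixels (default 9).
#' @return List of segments; each is a list with elements `id`, `mask`
#'   (logical matrix), `offset` (row, col of the mask's top-left corner in
#'   the parent, 1-based). Attribute `n_discarded` counts dropped components.
#' @export
label_segments <- function(mask, min_area = 9L) {
  stopifnot(is.logical(mask))
  if (!any(mask)) return(structure(list(), n_discarded = 0L))
  lab <- .label8(mask)
  n <- max(lab)
  segs <- list()
  discarded <- 0L
  next_id <- 1L
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) {
      discarded <- discarded + 1L
      next
    }
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    sm <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sm[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- TRUE
    segs[[next_id]] <- new_segment(next_id, sm, c(r0, c0))
    next_id <- next_id + 1L
  }
  structure(segs, n_discarded = discarded)
}

# 8-connected component labels: start from the (4-connected) labels of
# EBImage::bwlabel, then union labels that touch diagonally
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1L), if (shift[2] == 1L) seq_len(nc - 1L) else 2:nc]
    b <- lab[2:nr, if (shift[2] == 1L) 2:nc else seq_len(nc - 1L)]
    touch <- which(a > 0 & b > 0 & a != b)
    for (t in touch) union_(a[t], b[t])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

new_segment <- function(id, mask, offset) {
  structure(list(id = id, mask = mask, offset = as.integer(offset)),
            class = "colony_segment")
}

#' @export
print.colony_segment <- function(x, ...) {
  cat(sprintf("<colony_segment #%d: %d px, bbox %dx%d at (%d,%d)>\n",
              x$id, sum(x$mask), nrow(x$mask), ncol(x$mask),
              x$offset[1], x$offset[2]))
  invisible(x)
}

#' Summarize segments as a tibble
#'
#' @param segments List of segments from [label_segments()].
#' @return Tibble with one row per segment: id, area, bounding box, offset.
#' @export
segment_table <- function(segments) {
  tibble::tibble(
    segment = vapply(segments, function(s) s$id, integer(1)),
    area = vapply(segments, function(s) sum(s$mask), integer(1)),
    height = vapply(segments, function(s) nrow(s$mask), integer(1)),
    width = vapply(segments, function(s) ncol(s$mask), integer(1)),
    offset_row = vapply(segments, function(s) s$offset[1], integer(1)),
    offset_col = vapply(segments, function(s) s$offset[2], integer(1))
  )
}
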