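#' Crop a plate image into a grid of sub-images
#'
#' Splits a single-well rectangular plate photograph into `rows x cols`
#' equal tiles (after optional margin removal), in row-major order. When
#' the dimensions do not divide evenly, tile boundaries are rounded and a
#' message is logged.
#'
#' @param plate Grayscale matrix.
#' @param rows,cols Grid dimensions (default 8 x 12).
#' @param margin Pixels trimmed from every plate edge before tiling
#'   (default 0).
#' @return List of tiles; each has `image`, `well_row`, `well_col`, `well`.
#' @export
crop_grid <- function(plate, rows = 8L, cols = 12L, margin = 0L) {
  stopifnot(rows >= 1, cols >= 1)
  if (margin > 0) {
    plate <- plate[(margin + 1):(nrow(plate) - margin),
                   (margin + 1):(ncol(plate) - margin), drop = FALSE]
  }
  if (nrow(plate) %% rows != 0 || ncol(plate) %% cols != 0) {
    message(sprintf("plate %dx%d not divisible by %dx%d grid; tile edges rounded",
                    nrow(plate), ncol(plate), rows, cols))
  }
  rb <- round(seq(0, nrow(plate), length.out = rows + 1))
  cb <- round(seq(0, ncol(plate), length.out = cols + 1))
  tiles <- vector("list", rows * cols)
  id <- 0L
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    id <- id + 1L
    tiles[[id]] <- list(
      image = plate[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1], drop = FALSE],
      well_row = i, well_col = j, well = id)
  }
  tiles
}

#' Batch-count a directory of plate sub-images
#'
#' Counts colonies on every image matched by `pattern` in `input`, writing
#' a per-circle CSV (`results.csv`: image_id, segment_id, count,
#' center_row, center_col, radius), a per-image summary
#' (`summary.csv`: image_id, total, n_segments) and, optionally, overlay
#' PNGs with the selected circles.
#'
#' @param input Directory containing images, or a character vector of
#'   image paths.
#' @param output Output directory (created if missing).
#' @param d,lambda Hyperparameters (defaults 0.5 and 26).
#' @param pattern Filename regexp when `input` is a directory (default
#'   PNG/TIFF/JPEG extensions).
#' @param invert,min_area Passed to [count_image()].
#' @param overlay If `TRUE`, writes `<image>_overlay.png` files.
#' @param keep_going If `TRUE`, unreadable or failing images are logged and
#'   skipped instead of aborting.
#' @return Invisibly, the per-image summary tibble.
#' @export
run_batch <- function(input, output, d = 0.5, lambda = 26,
                      pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                      invert = FALSE, min_area = 9L,
                      overlay = FALSE, keep_going = FALSE) {
  paths <- if (length(input) == 1 && dir.exists(input)) {
    list.files(input, pattern = pattern, full.names = TRUE, ignore.case = TRUE)
  } else input
  paths <- sort(paths)
  if (!dir.exists(output)) dir.create(output, recursive = TRUE)
  if (!length(paths)) warning("no input images found")
  results <- tibble::tibble(image_id = character(), segment_id = integer(),
                            count = integer(), center_row = numeric(),
                            center_col = numeric(), radius = numeric())
  summary <- tibble::tibble(image_id = character(), total = integer(),
                            n_segments = integer())
  for (p in paths) {
    id <- sub("\\.[^.]+$", "", basename(p))
    res <- tryCatch(
      count_image(read_gray(p), d = d, lambda = lambda, invert = invert,
                  min_area = min_area, image_id = id),
      error = function(e) {
        if (!keep_going) stop(e)
        message(sprintf("skipping %s: %s", p, conditionMessage(e)))
        NULL
      })
    if (is.null(res)) next
    seg <- tidy(res)
    if (nrow(res$circles)) {
      cnt_of <- stats::setNames(seg$count, seg$segment)
      results <- dplyr::bind_rows(results, tibble::tibble(
        image_id = id,
        segment_id = res$circles$segment,
        count = as.integer(cnt_of[as.character(res$circles$segment)]),
        center_row = res$circles$row,
        center_col = res$circles$col,
        radius = res$circles$radius))
    }
    summary <- dplyr::bind_rows(summary, tibble::tibble(
      image_id = id, total = res$total, n_segments = nrow(seg)))
    if (overlay) {
      gp <- autoplot(res)
      ggplot2::ggsave(file.path(output, paste0(id, "_overlay.png")), gp,
                      width = 5, height = 5, dpi = 120)
    }
  }
  utils::write.csv(results, file.path(output, "results.csv"), row.names = FALSE)
  utils::write.csv(summary, file.path(output, "summary.csv"), row.names = FALSE)
  invisible(summary)
}
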