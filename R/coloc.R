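# Two-channel Pearson colocalization.

#' Construct an image pair
#'
#' @param channel_a,channel_b numeric matrices of identical shape (e.g. an
#'   ABCA1 channel and a membrane-marker channel); intensities >= 0.
#' @param mask optional logical matrix of the same shape selecting pixels;
#'   at least 2 pixels must remain.
#' @param target_r optional generative ground-truth correlation (recorded by
#'   the simulator).
#' @return an `image_pair`.
#' @export
image_pair <- function(channel_a, channel_b, mask = NULL, target_r = NULL) {
  channel_a <- as.matrix(channel_a); channel_b <- as.matrix(channel_b)
  if (!identical(dim(channel_a), dim(channel_b))) {
    stop("channels must have identical shapes", call. = FALSE)
  }
  if (length(channel_a) < 2L) {
    stop("degenerate shape: need at least 2 pixels", call. = FALSE)
  }
  if (any(channel_a < 0) || any(channel_b < 0)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(channel_a)) || !is.logical(mask)) {
      stop("mask must be a logical matrix of the same shape", call. = FALSE)
    }
    if (sum(mask) < 2L) {
      stop("mask must retain at least 2 pixels", call. = FALSE)
    }
  }
  structure(list(channel_a = channel_a, channel_b = channel_b, mask = mask,
                 target_r = target_r, pixel_count = length(channel_a)),
            class = "image_pair")
}

#' Pearson colocalization coefficient of an image pair
#'
#' Sample Pearson correlation of the two channels over the unmasked pixels —
#' the whole image by default, without thresholding. An optional intensity
#' threshold (applied to the sum of both channels) can restrict to brighter
#' pixels, but is off by default.
#'
#' @param pair an [image_pair()], or a numeric matrix (then supply `b`).
#' @param b second channel when `pair` is a bare matrix.
#' @param mask optional logical matrix overriding the pair's mask.
#' @param threshold optional intensity threshold: keep pixels with
#'   `channel_a + channel_b > threshold`.
#' @return a `coloc_result` list: `r`, `n_pixels`.
#' @examples
#' p <- simulate_image_pair(0.8, shape = c(32, 32), seed = 1)
#' pearson_coloc(p)
#' @export
pearson_coloc <- function(pair, b = NULL, mask = NULL, threshold = NULL) {
  if (!inherits(pair, "image_pair")) {
    pair <- image_pair(pair, b, mask = mask)
  } else if (!is.null(mask)) {
    pair <- image_pair(pair$channel_a, pair$channel_b, mask = mask,
                       target_r = pair$target_r)
  }
  keep <- if (is.null(pair$mask)) rep(TRUE, length(pair$channel_a))
          else as.vector(pair$mask)
  if (!is.null(threshold)) {
    keep <- keep & (as.vector(pair$channel_a) + as.vector(pair$channel_b) >
                      threshold)
  }
  a <- as.vector(pair$channel_a)[keep]
  bb <- as.vector(pair$channel_b)[keep]
  if (length(a) < 2L) {
    stop("fewer than 2 pixels left after masking/thresholding",
         call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(bb) == 0) {
    stop("undefined correlation: a channel is constant within the mask",
         call. = FALSE)
  }
  structure(list(r = stats::cor(a, bb), n_pixels = length(a)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> R = %.4f over %d pixels\n", x$r, x$n_pixels))
  invisible(x)
}

#' Summarize colocalization coefficients across replicates
#'
#' Nested design: replicates are averaged *within* each experiment first,
#' then mean and sample SD are taken across experiment means (matching a
#' "three independent experiments, >= three replicates each" design). With
#' `experiment = NULL` all values are treated as one level.
#'
#' @param r numeric vector of per-image coefficients, or a list of
#'   `coloc_result`s.
#' @param experiment optional grouping vector (experiment ids), same length
#'   as `r`.
#' @return list with `mean`, `sd`, `n` (number of experiments).
#' @examples
#' summarize_coloc(c(0.25, 0.27, 0.26))
#' @export
summarize_coloc <- function(r, experiment = NULL) {
  if (is.list(r)) r <- vapply(r, function(x) x$r, numeric(1))
  r <- as.numeric(r)
  if (!is.null(experiment)) {
    stopifnot(length(experiment) == length(r))
    r <- as.numeric(tapply(r, experiment, mean))
  }
  aggregate_replicates(r)
}

#' Read a single-channel image stored as a whitespace-delimited matrix
#'
#' @param path text file of numeric rows (one image row per line).
#' @return numeric matrix.
#' @export
read_image_matrix <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE,
                              colClasses = "numeric"))
}

#' Write a single-channel image as a whitespace-delimited matrix
#'
#' @param image numeric matrix.
#' @param path output path.
#' @export
write_image_matrix <- function(image, path) {
  utils::write.table(format(as.matrix(image), digits = 10, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
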