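#' Gray-level quantization of an intensity image
#'
#' Maps intensities in `[0, input_max]` onto the integer levels
#' `0, ..., levels - 1` by uniform binning, the standard preprocessing step
#' before co-occurrence counting. Out-of-range values are clipped. With the
#' default `levels = 256` and `input_max = 255` the mapping is the identity
#' on 8-bit data.
#'
#' @param image integer or numeric matrix of gray intensities.
#' @param levels number of quantization levels (integer, >= 2).
#' @param input_max top of the input intensity range (255 for 8-bit data).
#' @return integer matrix of the same dimensions with values in
#'   `0:(levels - 1)`.
#' @examples
#' quantize_gray(matrix(c(0, 100, 200), 1), levels = 8)
#' @export
quantize_gray <- function(image, levels = 256L, input_max = 255L) {
  check_gray_image(image)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L)
    stop("'levels' must be an integer >= 2", call. = FALSE)
  if (input_max < 1)
    stop("'input_max' must be positive", call. = FALSE)
  v <- pmin(pmax(as.numeric(image), 0), input_max)
  q <- floor(v * levels / (input_max + 1))
  q <- pmin(q, levels - 1L)  # guard v == input_max when levels does not divide
  out <- matrix(as.integer(q), nrow(image), ncol(image))
  attr(out, "levels") <- levels
  out
}

#' Pixel displacement for a co-occurrence offset
#'
#' Converts a (distance, angle) pair into the `(drow, dcol)` displacement
#' used when counting co-occurring gray levels. Angles follow the usual
#' image convention with the row axis pointing down:
#' 0 deg -> `(0, d)`, 45 deg -> `(-d, d)`, 90 deg -> `(-d, 0)`,
#' 135 deg -> `(-d, -d)`.
#'
#' @param distance pixel distance (positive integer).
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @return integer vector `c(drow, dcol)`.
#' @examples
#' offset_from_angle(1, 0)    # c(0, 1)
#' offset_from_angle(2, 135)  # c(-2, -2)
#' @export
offset_from_angle <- function(distance = 1L, angle = 0) {
  d <- as.integer(distance)
  if (is.na(d) || d < 1L) stop("'distance' must be a positive integer", call. = FALSE)
  switch(as.character(angle),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("'angle' must be one of 0, 45, 90, 135", call. = FALSE)
  )
}

#' Gray level co-occurrence matrix
#'
#' Counts ordered pairs of gray levels `(i, j)` where a pixel of level `i`
#' at position `(r, c)` has a pixel of level `j` at `(r + drow, c + dcol)`,
#' both inside the image (no padding), and normalizes the counts to a joint
#' probability table `p(i, j)`. With `symmetric = TRUE` every pair is also
#' counted with `(i, j)` swapped, which makes the matrix symmetric.
#'
#' @param image quantized integer matrix with values in `0:(levels - 1)`
#'   (see [quantize_gray()]).
#' @param offset integer vector `c(drow, dcol)`, not `c(0, 0)`; see
#'   [offset_from_angle()].
#' @param levels number of gray levels. Defaults to the `levels` attribute
#'   set by [quantize_gray()], or `max(image) + 1` if absent.
#' @param symmetric count each pair in both orders (default `FALSE`).
#' @return an object of class `"glcm"`: a `levels x levels` probability
#'   matrix (rows = level `i` of the reference pixel, 0-based in
#'   dimnames) with attributes `counts_total`, `offset` and `symmetric`.
#' @examples
#' g <- glcm(matrix(c(0L, 1L, 1L, 0L), 2, byrow = TRUE), offset = c(0, 1),
#'           levels = 2)
#' g
#' @export
glcm <- function(image, offset = c(0L, 1L), levels = NULL, symmetric = FALSE) {
  check_gray_image(image)
  offset <- as.integer(offset)
  if (length(offset) != 2L || anyNA(offset))
    stop("'offset' must be an integer vector c(drow, dcol)", call. = FALSE)
  if (all(offset == 0L))
    stop("'offset' must not be c(0, 0)", call. = FALSE)
  if (is.null(levels)) {
    levels <- attr(image, "levels")
    if (is.null(levels)) levels <- max(image) + 1L
  }
  levels <- as.integer(levels)
  if (levels < 2L) stop("'levels' must be >= 2", call. = FALSE)
  if (min(image) < 0L || max(image) >= levels)
    stop("image values must lie in 0:(levels - 1); quantize first", call. = FALSE)

  h <- nrow(image); w <- ncol(image)
  drow <- offset[1L]; dcol <- offset[2L]
  r_lo <- max(1L, 1L - drow); r_hi <- min(h, h - drow)
  c_lo <- max(1L, 1L - dcol); c_hi <- min(w, w - dcol)
  if (r_lo > r_hi || c_lo > c_hi)
    stop("patch too small for offset (", drow, ", ", dcol, ")", call. = FALSE)
  rows <- seq.int(r_lo, r_hi)
  cols <- seq.int(c_lo, c_hi)

  i <- as.vector(image[rows, cols, drop = FALSE])
  j <- as.vector(image[rows + drow, cols + dcol, drop = FALSE])
  counts <- tabulate(i * levels + j + 1L, nbins = levels * levels)
  if (symmetric)
    counts <- counts + tabulate(j * levels + i + 1L, nbins = levels * levels)
  total <- length(i)
  p <- matrix(counts / sum(counts), levels, levels, byrow = TRUE,
              dimnames = list(0:(levels - 1L), 0:(levels - 1L)))
  structure(p, counts_total = total, offset = offset, symmetric = symmetric,
            class = c("glcm", "matrix", "array"))
}

#' @export
print.glcm <- function(x, ...) {
  nz <- sum(x > 0)
  cat("Gray level co-occurrence matrix\n")
  cat(sprintf("  levels: %d x %d, offset: (%d, %d), %s\n",
              nrow(x), ncol(x), attr(x, "offset")[1L], attr(x, "offset")[2L],
              if (isTRUE(attr(x, "symmetric"))) "symmetric" else "asymmetric"))
  cat(sprintf("  pixel pairs: %d, nonzero cells: %d\n",
              attr(x, "counts_total"), nz))
  invisible(x)
}

# index helper matrices for a levels x levels GLCM (0-based indices)
glcm_index <- function(p) {
  L <- nrow(p)
  idx <- seq_len(L) - 1
  list(i = matrix(idx, L, L), j = matrix(idx, L, L, byrow = TRUE))
}

#' Marginal index statistics of a co-occurrence matrix
#'
#' Means and standard deviations of the row and column indices under the
#' joint distribution `p(i, j)`; these are the moments entering the
#' correlation descriptor.
#'
#' @param p a `"glcm"` object or normalized probability matrix.
#' @return named list with `mu_i`, `mu_j`, `sigma_i`, `sigma_j`.
#' @export
glcm_marginal_stats <- function(p) {
  check_glcm(p)
  ix <- glcm_index(p)
  mu_i <- sum(ix$i * p); mu_j <- sum(ix$j * p)
  list(mu_i = mu_i, mu_j = mu_j,
       sigma_i = sqrt(sum((ix$i - mu_i)^2 * p)),
       sigma_j = sqrt(sum((ix$j - mu_j)^2 * p)))
}

#' GLCM contrast
#'
#' `sum (i - j)^2 p(i, j)`: mean squared gray-level difference between a
#' pixel and its offset neighbour. Zero iff all probability mass lies on
#' the diagonal; large for strongly fluctuating texture such as speckle.
#'
#' @param p a `"glcm"` object or normalized probability matrix.
#' @return nonnegative scalar.
#' @export
glcm_contrast <- function(p) {
  check_glcm(p)
  ix <- glcm_index(p)
  sum((ix$i - ix$j)^2 * p)
}

#' GLCM correlation
#'
#' `sum (i - mu_i)(j - mu_j) p(i, j) / (sigma_i sigma_j)`: linear
#' dependence between the gray level of a pixel and its offset neighbour,
#' in `[-1, 1]`. On a constant patch both marginal standard deviations are
#' zero and the descriptor is undefined; `NA_real_` is returned in that
#' case rather than an arbitrary number.
#'
#' @param p a `"glcm"` object or normalized probability matrix.
#' @return scalar in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
glcm_correlation <- function(p) {
  check_glcm(p)
  m <- glcm_marginal_stats(p)
  denom <- m$sigma_i * m$sigma_j
  if (denom == 0) return(NA_real_)
  ix <- glcm_index(p)
  sum((ix$i - m$mu_i) * (ix$j - m$mu_j) * p) / denom
}

#' GLCM energy (angular second moment)
#'
#' `sum p(i, j)^2`, in `(0, 1]`; equals 1 iff a single level pair carries
#' all the mass. Higher values indicate a more uniform, orderly texture.
#'
#' @param p a `"glcm"` object or normalized probability matrix.
#' @return scalar in `(0, 1]`.
#' @export
glcm_energy <- function(p) {
  check_glcm(p)
  sum(p^2)
}

#' GLCM homogeneity (inverse difference moment)
#'
#' `sum p(i, j) / (1 + |i - j|)`, in `(0, 1]`; equals 1 iff all mass lies
#' on the diagonal. High values indicate smooth texture with similar
#' neighbouring intensities.
#'
#' @param p a `"glcm"` object or normalized probability matrix.
#' @return scalar in `(0, 1]`.
#' @export
glcm_homogeneity <- function(p) {
  check_glcm(p)
  ix <- glcm_index(p)
  sum(p / (1 + abs(ix$i - ix$j)))
}

#' Texture descriptors of an image patch
#'
#' Full per-patch computation: quantize the patch, build one co-occurrence
#' matrix per offset, compute contrast, correlation, energy and homogeneity
#' for each, and average the descriptors arithmetically across offsets.
#' Correlation is averaged only over offsets where it is defined and is
#' `NA` when it is defined for none (e.g. a constant patch).
#'
#' @param patch numeric/integer matrix of raw gray intensities.
#' @param levels number of quantization levels (default 256, i.e. native
#'   8-bit resolution).
#' @param input_max top of the input intensity range (default 255).
#' @param offsets a single `c(drow, dcol)` vector or a list of them
#'   (default: single offset `c(0, 1)`, distance 1 at 0 degrees).
#' @param symmetric symmetric pair counting (default `FALSE`).
#' @return object of class `"glcm_features"`: named list with `contrast`,
#'   `correlation`, `energy`, `homogeneity` plus the settings used.
#' @examples
#' glcm_features(matrix(c(0, 1, 1, 0), 2, byrow = TRUE),
#'               levels = 2, input_max = 1)
#' @export
glcm_features <- function(patch, levels = 256L, input_max = 255L,
                          offsets = list(c(0L, 1L)), symmetric = FALSE) {
  if (!is.list(offsets)) offsets <- list(offsets)
  if (length(offsets) < 1L) stop("need at least one offset", call. = FALSE)
  q <- quantize_gray(patch, levels = levels, input_max = input_max)
  per <- lapply(offsets, function(off) {
    p <- glcm(q, offset = off, levels = levels, symmetric = symmetric)
    c(contrast = glcm_contrast(p), correlation = glcm_correlation(p),
      energy = glcm_energy(p), homogeneity = glcm_homogeneity(p))
  })
  m <- do.call(rbind, per)
  corr <- m[, "correlation"]
  corr <- if (all(is.na(corr))) NA_real_ else mean(corr, na.rm = TRUE)
  structure(
    list(contrast = mean(m[, "contrast"]), correlation = corr,
         energy = mean(m[, "energy"]), homogeneity = mean(m[, "homogeneity"]),
         levels = as.integer(levels), offsets = offsets,
         symmetric = symmetric, patch_dim = dim(patch)),
    class = "glcm_features")
}

#' @export
print.glcm_features <- function(x, digits = 6, ...) {
  cat(sprintf("GLCM texture descriptors (%d x %d patch, %d levels, %d offset%s, %s)\n",
              x$patch_dim[1L], x$patch_dim[2L], x$levels, length(x$offsets),
              if (length(x$offsets) > 1L) "s" else "",
              if (isTRUE(x$symmetric)) "symmetric" else "asymmetric"))
  vals <- c(contrast = x$contrast, correlation = x$correlation,
            energy = x$energy, homogeneity = x$homogeneity)
  print(signif(vals, digits))
  invisible(x)
}

#' @export
as.data.frame.glcm_features <- function(x, ...) {
  data.frame(contrast = x$contrast, correlation = x$correlation,
             energy = x$energy, homogeneity = x$homogeneity)
}

check_gray_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(image) < 1L || ncol(image) < 1L || length(image) == 0L)
    stop("image is empty", call. = FALSE)
  if (anyNA(image)) stop("image contains missing values", call. = FALSE)
  invisible(image)
}

check_glcm <- function(p) {
  if (!is.matrix(p) || nrow(p) != ncol(p))
    stop("'p' must be a square co-occurrence matrix", call. = FALSE)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("'p' must be a normalized probability matrix", call. = FALSE)
  invisible(p)
}
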