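#' Parameters of a synthetic B-mode phantom
#'
#' Describes a speckle-textured B-mode-like image containing a hyperechoic
#' (bright) stone focus and a posterior acoustic shadow band below it.
#' The background is fully developed speckle: a Rayleigh-distributed
#' envelope followed by logarithmic compression, the standard first-order
#' B-mode model. Inside the shadow band the pixel distribution is
#' transformed so that its mean is multiplied by `shadow_attenuation` and
#' its fluctuation about the mean by `shadow_smoothing`; a strong shadow is
#' therefore both darker and smoother, which is what drives the texture
#' descriptors apart across diagnostic-probability classes.
#'
#' @param height,width image size in pixels.
#' @param speckle_scale Rayleigh scale of the background envelope
#'   (arbitrary amplitude units).
#' @param stone_center `c(row, col)` of the stone ellipse, 1-based pixels.
#' @param stone_axes `c(semi_row, semi_col)` of the ellipse in pixels.
#' @param stone_gain multiplicative brightness of the stone (> 1 makes it
#'   hyperechoic).
#' @param shadow_attenuation mean-intensity factor of the shadow band, in
#'   (0, 1]; 1 = no attenuation.
#' @param shadow_smoothing fluctuation factor of the shadow band, in
#'   (0, 1]; 1 = background speckle variance.
#' @return list of class `"phantom_params"`.
#' @export
phantom_params <- function(height = 300L, width = 400L, speckle_scale = 1,
                           stone_center = c(80L, 200L), stone_axes = c(12L, 30L),
                           stone_gain = 1.8, shadow_attenuation = 0.5,
                           shadow_smoothing = 0.6) {
  p <- list(height = as.integer(height), width = as.integer(width),
            speckle_scale = speckle_scale,
            stone_center = as.integer(stone_center),
            stone_axes = as.integer(stone_axes), stone_gain = stone_gain,
            shadow_attenuation = shadow_attenuation,
            shadow_smoothing = shadow_smoothing)
  if (p$height < 8L || p$width < 8L)
    stop("phantom must be at least 8 x 8 pixels", call. = FALSE)
  if (p$speckle_scale <= 0) stop("'speckle_scale' must be positive", call. = FALSE)
  for (nm in c("shadow_attenuation", "shadow_smoothing")) {
    if (p[[nm]] <= 0 || p[[nm]] > 1)
      stop("'", nm, "' must lie in (0, 1]", call. = FALSE)
  }
  if (p$stone_gain <= 0) stop("'stone_gain' must be positive", call. = FALSE)
  r <- p$stone_center[1L]; c0 <- p$stone_center[2L]
  a <- p$stone_axes[1L]; b <- p$stone_axes[2L]
  if (a < 1L || b < 1L) stop("stone axes must be >= 1 px", call. = FALSE)
  if (r - a < 1L || r + a > p$height || c0 - b < 1L || c0 + b > p$width)
    stop("stone ellipse exceeds image bounds", call. = FALSE)
  if (r + a + 4L > p$height - 4L)
    stop("no room for a shadow band below the stone", call. = FALSE)
  structure(p, class = "phantom_params")
}

#' Generate one synthetic B-mode phantom image
#'
#' Draws the speckle background, brightens the stone ellipse, applies the
#' shadow transform to the column band below the stone, and quantizes to
#' 8-bit. The same seed always yields the same image. The returned ROI is
#' inset inside the shadow band (2 px below the stone, 2 px from the band
#' sides and image bottom) so it samples pure shadow texture.
#'
#' @param params a [phantom_params()].
#' @param seed integer seed; all randomness flows from it.
#' @return list with `image` (integer matrix, 0..255) and `roi` (a
#'   [roi_spec()] inside the shadow band).
#' @export
generate_phantom <- function(params, seed) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(seed, {
    h <- params$height; w <- params$width
    # Rayleigh envelope: sigma * sqrt(-2 log U)
    env <- params$speckle_scale * sqrt(-2 * log(stats::runif(h * w)))
    field <- matrix(log1p(env), h, w)
    # fixed display mapping; ~99th percentile of log1p(envelope) maps near 255
    gain <- 255 / log1p(4 * params$speckle_scale)
    field <- field * gain

    bg_mean <- mean(field)  # pre-modification speckle mean, used as pivot

    r <- params$stone_center[1L]; c0 <- params$stone_center[2L]
    a <- params$stone_axes[1L]; b <- params$stone_axes[2L]
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    stone <- ((rr - r) / a)^2 + ((cc - c0) / b)^2 <= 1

    shadow_rows <- seq.int(r + a + 1L, h)
    shadow_cols <- seq.int(max(1L, c0 - b), min(w, c0 + b))
    band <- field[shadow_rows, shadow_cols]
    field[shadow_rows, shadow_cols] <-
      params$shadow_attenuation * bg_mean +
      params$shadow_smoothing * (band - bg_mean)

    field[stone] <- field[stone] * params$stone_gain

    img <- matrix(as.integer(pmin(pmax(round(field), 0), 255)), h, w)

    roi <- roi_spec(row0 = r + a + 2L,
                    col0 = shadow_cols[1L] + 1L,
                    height = h - (r + a + 2L) - 2L,
                    width = length(shadow_cols) - 2L)
    list(image = img, roi = roi)
  })
}

#' Per-class phantom parameter templates
#'
#' One [phantom_params()] template per diagnostic-probability class, with
#' shadow strength strictly increasing across classes: the weakest shadow
#' for the 50-60% group and the strongest for >=80%. Defaults
#' (`shadow_attenuation` 0.8 / 0.5 / 0.25, `shadow_smoothing` 0.9 / 0.6 /
#' 0.3) emulate the reported clinical direction -- contrast falls while
#' energy and homogeneity rise as the shadow strengthens -- and are chosen
#' to give confidence-band separation at about 30 images per class, not to
#' model acoustic physics.
#'
#' @param attenuation,smoothing numeric length-3 vectors ordered as
#'   [class_labels()]; must be strictly decreasing (stronger shadow =
#'   smaller factor).
#' @param ... further arguments passed to every [phantom_params()] call
#'   (image size, stone geometry, ...).
#' @return named list of three `phantom_params`, class `"class_params"`.
#' @export
class_params <- function(attenuation = c(0.8, 0.5, 0.25),
                         smoothing = c(0.9, 0.6, 0.3), ...) {
  stopifnot(length(attenuation) == 3L, length(smoothing) == 3L)
  if (any(diff(attenuation) >= 0) || any(diff(smoothing) >= 0))
    stop("shadow strength must be strictly ordered across classes ",
         "(attenuation and smoothing strictly decreasing)", call. = FALSE)
  out <- mapply(function(att, smo) {
    phantom_params(shadow_attenuation = att, shadow_smoothing = smo, ...)
  }, attenuation, smoothing, SIMPLIFY = FALSE)
  names(out) <- class_labels()
  structure(out, class = "class_params")
}

#' Generate a synthetic dataset of phantom images with ROI table
#'
#' Writes `n` phantom images per class as 8-bit grayscale PNGs with the
#' stone position and size jittered per image (all jitter seeded), plus an
#' ROI/label table in the [read_roi_table()] CSV dialect pointing at the
#' shadow ROI of each image. Default per-class counts mirror the clinical
#' kidney cohort (14 / 23 / 15).
#'
#' @param dir output directory (created if needed).
#' @param cls a [class_params()] set of templates.
#' @param n_per_class integer length-3 vector of image counts ordered as
#'   [class_labels()].
#' @param disease `"kidney"` or `"gallbladder"` (recorded in the table).
#' @param seed integer master seed.
#' @return path of the ROI table CSV written into `dir` (invisibly the
#'   full table as a data frame via attribute `"table"`).
#' @export
generate_dataset <- function(dir, cls = class_params(),
                             n_per_class = c(14L, 23L, 15L),
                             disease = "kidney", seed = 1L) {
  stopifnot(inherits(cls, "class_params"))
  disease <- match.arg(disease, c("kidney", "gallbladder"))
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != 3L || any(n_per_class < 1L))
    stop("'n_per_class' must be three counts >= 1", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  rows <- list()
  img_idx <- 0L
  for (k in seq_along(class_labels())) {
    lab <- class_labels()[k]
    tmpl <- cls[[k]]
    for (i in seq_len(n_per_class[k])) {
      img_idx <- img_idx + 1L
      sub_seed <- (seed * 1009L + img_idx * 101L) %% .Machine$integer.max
      jit <- with_seed(sub_seed + 7L, list(
        dr = sample(-10:10, 1L), dc = sample(-25:25, 1L),
        da = sample(-2:2, 1L), db = sample(-5:5, 1L)))
      par_i <- phantom_params(
        height = tmpl$height, width = tmpl$width,
        speckle_scale = tmpl$speckle_scale,
        stone_center = tmpl$stone_center + c(jit$dr, jit$dc),
        stone_axes = pmax(tmpl$stone_axes + c(jit$da, jit$db), c(4L, 8L)),
        stone_gain = tmpl$stone_gain,
        shadow_attenuation = tmpl$shadow_attenuation,
        shadow_smoothing = tmpl$shadow_smoothing)
      ph <- generate_phantom(par_i, seed = sub_seed)
      fname <- sprintf("%s_%03d.png", disease, img_idx)
      png::writePNG(ph$image / 255, file.path(dir, fname))
      rows[[img_idx]] <- data.frame(
        image = fname, disease = disease, label = lab,
        row0 = ph$roi$row0, col0 = ph$roi$col0,
        height = ph$roi$height, width = ph$roi$width,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  table_path <- file.path(dir, sprintf("%s_rois.csv", disease))
  utils::write.csv(tab, table_path, row.names = FALSE, quote = FALSE)
  structure(table_path, table = tab)
}

# run code with a local RNG state; never leaks into or depends on the
# caller's .Random.seed
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  code
}
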