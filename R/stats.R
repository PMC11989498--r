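#' Mean and 95% confidence interval of a feature sample
#'
#' Two-sided Student-t interval, `mean +/- t(0.975, n - 1) * sd / sqrt(n)`.
#' The t multiplier (rather than normal z) is used because per-class group
#' sizes in this setting are small (10-35 images). Missing values must be
#' removed by the caller; an undefined correlation, for instance, is
#' excluded from its group before summarising.
#'
#' @param x numeric vector, `length(x) >= 2`, no `NA`.
#' @param conf confidence level (default 0.95).
#' @return named list `n`, `mean`, `ci_low`, `ci_high`.
#' @examples
#' summarize_group(c(1, 2, 3))  # CI roughly [-0.48, 4.48]
#' @export
summarize_group <- function(x, conf = 0.95) {
  if (anyNA(x)) stop("remove undefined values before summarising", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("insufficient samples for CI (need n >= 2, got ", n, ")",
                   call. = FALSE)
  m <- mean(x)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
  list(n = n, mean = m, ci_low = m - half, ci_high = m + half)
}

#' Do two closed intervals overlap?
#'
#' A shared endpoint counts as overlap, which is the conservative choice
#' when overlap is evidence *against* class separation.
#'
#' @param a,b numeric vectors `c(low, high)` with `low <= high`.
#' @return logical flag.
#' @export
ci_overlap <- function(a, b) {
  for (iv in list(a, b)) {
    if (length(iv) != 2L || anyNA(iv) || iv[1L] > iv[2L])
      stop("interval must be c(low, high) with low <= high", call. = FALSE)
  }
  a[1L] <= b[2L] && b[1L] <= a[2L]
}

#' Confidence-band separation report
#'
#' For each disease and feature, takes the three per-class summaries and
#' reports which pairs of 95% confidence bands overlap, whether all three
#' are pairwise disjoint (`fully_separated`), and the direction of the
#' class means across increasing diagnostic probability (`decreasing`,
#' `increasing` or `non-monotone`). A feature is considered to distinguish
#' the classes when its three bands are pairwise disjoint.
#'
#' @param summaries data frame with columns `disease`, `feature`, `label`,
#'   `mean`, `ci_low`, `ci_high` (and optionally `n`), one row per class;
#'   exactly the three labels of [class_labels()] per disease x feature.
#' @return object of class `"separation_report"`: a data frame with one
#'   row per disease x feature and columns `overlap_50_60_vs_60_80`,
#'   `overlap_60_80_vs_80plus`, `overlap_50_60_vs_80plus`,
#'   `fully_separated`, `ordering`.
#' @export
separation_report <- function(summaries) {
  need <- c("disease", "feature", "label", "mean", "ci_low", "ci_high")
  missing_cols <- setdiff(need, names(summaries))
  if (length(missing_cols) > 0L)
    stop("summaries are missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(summaries$ci_low > summaries$ci_high))
    stop("malformed interval: ci_low > ci_high", call. = FALSE)
  out_mean <- summaries$mean < summaries$ci_low | summaries$mean > summaries$ci_high
  if (any(out_mean))
    warning(sum(out_mean), " summary row(s) have a mean outside the stated CI; ",
            "bands are used as given", call. = FALSE)

  labs <- class_labels()
  groups <- split(summaries, list(summaries$disease, summaries$feature),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    missing_lab <- setdiff(labs, as.character(g$label))
    if (length(missing_lab) > 0L)
      stop("missing class '", missing_lab[1L], "' for ", g$disease[1L], " ",
           g$feature[1L], call. = FALSE)
    g <- g[match(labs, as.character(g$label)), ]
    iv <- function(k) c(g$ci_low[k], g$ci_high[k])
    o12 <- ci_overlap(iv(1L), iv(2L))
    o23 <- ci_overlap(iv(2L), iv(3L))
    o13 <- ci_overlap(iv(1L), iv(3L))
    d <- diff(g$mean)
    ordering <- if (all(d < 0)) "decreasing" else if (all(d > 0)) "increasing"
                else "non-monotone"
    data.frame(disease = g$disease[1L], feature = g$feature[1L],
               overlap_50_60_vs_60_80 = o12, overlap_60_80_vs_80plus = o23,
               overlap_50_60_vs_80plus = o13,
               fully_separated = !(o12 || o23 || o13), ordering = ordering,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("separation_report", "data.frame")
  out
}

#' @export
print.separation_report <- function(x, ...) {
  cat("Confidence-band separation report (95% CI, shared endpoint = overlap)\n\n")
  df <- as.data.frame(x)
  df$separated <- ifelse(df$fully_separated, "yes", "no")
  print(df[c("disease", "feature", "separated", "ordering",
             "overlap_50_60_vs_60_80", "overlap_60_80_vs_80plus",
             "overlap_50_60_vs_80plus")], row.names = FALSE)
  invisible(x)
}

#' Per-patch feature table
#'
#' Flattens a list of per-patch descriptor records into the tabular export
#' used by the pipeline: one row per patch with provenance, ROI geometry
#' and the four descriptors. An undefined correlation is emitted as `NA`.
#'
#' @param samples list of records, each with `image_id`, `disease`,
#'   `label`, `roi` (a [roi_spec()]) and `features` (a
#'   [glcm_features()] object).
#' @return data frame with columns `image`, `disease`, `label`, `row0`,
#'   `col0`, `height`, `width`, `contrast`, `correlation`, `energy`,
#'   `homogeneity`.
#' @export
feature_table <- function(samples) {
  cols <- c("image", "disease", "label", "row0", "col0", "height", "width",
            "contrast", "correlation", "energy", "homogeneity")
  if (length(samples) == 0L) {
    warning("no feature samples; returning header-only table", call. = FALSE)
    out <- data.frame(image = character(0), disease = character(0),
                      label = character(0), row0 = integer(0), col0 = integer(0),
                      height = integer(0), width = integer(0),
                      contrast = numeric(0), correlation = numeric(0),
                      energy = numeric(0), homogeneity = numeric(0))
    return(out[cols])
  }
  rows <- lapply(samples, function(s) {
    data.frame(image = s$image_id, disease = s$disease,
               label = as.character(s$label),
               row0 = s$roi$row0, col0 = s$roi$col0,
               height = s$roi$height, width = s$roi$width,
               contrast = s$features$contrast,
               correlation = s$features$correlation,
               energy = s$features$energy,
               homogeneity = s$features$homogeneity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[cols]
}

#' Per-class summaries of a feature table
#'
#' Applies [summarize_group()] to every disease x feature x class cell of a
#' feature table. Undefined correlations are dropped per group before
#' summarising, and the retained `n` is reported; groups left with fewer
#' than 2 values are skipped with a warning.
#'
#' @param features data frame as produced by [feature_table()].
#' @return data frame with columns `disease`, `feature`, `label`, `n`,
#'   `mean`, `ci_low`, `ci_high`.
#' @export
summarize_features <- function(features) {
  feats <- c("contrast", "correlation", "energy", "homogeneity")
  rows <- list()
  for (dis in unique(features$disease)) {
    sub <- features[features$disease == dis, ]
    for (f in feats) {
      for (lab in intersect(class_labels(), unique(as.character(sub$label)))) {
        x <- sub[[f]][as.character(sub$label) == lab]
        n_dropped <- sum(is.na(x))
        x <- x[!is.na(x)]
        if (n_dropped > 0L)
          warning(sprintf("%s %s %s: dropped %d undefined value(s)",
                          dis, f, lab, n_dropped), call. = FALSE)
        if (length(x) < 2L) {
          warning(sprintf("%s %s %s: fewer than 2 defined values, no CI",
                          dis, f, lab), call. = FALSE)
          next
        }
        s <- summarize_group(x)
        rows[[length(rows) + 1L]] <- data.frame(
          disease = dis, feature = f, label = lab, n = s$n, mean = s$mean,
          ci_low = s$ci_low, ci_high = s$ci_high, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published clinical reference summaries
#'
#' Loads the per-class means and 95% confidence intervals of the four
#' texture descriptors reported for a clinical cohort of 118 ultrasound
#' images (52 kidney, 66 gallbladder stone images), stored with the
#' package exactly as printed in the source report. Three rows carry
#' printed inconsistencies (a mean outside its own band; a negative energy
#' lower bound): they are retained verbatim rather than corrected, and
#' [separation_report()] warns about them.
#'
#' @return data frame with columns `disease`, `feature`, `label`, `n`,
#'   `mean`, `ci_low`, `ci_high`.
#' @export
clinical_reference <- function() {
  path <- system.file("extdata", "clinical_reference_summaries.csv",
                      package = "shadowtex", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$label <- parse_class_label(tab$label)
  tab
}

#' Plot per-class confidence bands for each feature
#'
#' Draws, per feature, the per-patch values by class with horizontal 95%
#' confidence bands in black (50-60%), red (60-80%) and blue (>=80%) -- the
#' display used to judge class separation -- and writes one PNG per feature.
#'
#' @param features data frame from [feature_table()].
#' @param summaries data frame from [summarize_features()].
#' @param dir output directory (created if needed).
#' @param disease which disease to plot (default: each present, prefixed).
#' @param width,height device size in pixels.
#' @return invisible character vector of the files written.
#' @export
plot_feature_bands <- function(features, summaries, dir,
                               disease = unique(features$disease),
                               width = 900, height = 600) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  band_col <- stats::setNames(c("#000000", "#CC0000", "#0000CC"), class_labels())
  files <- character(0)
  for (dis in disease) {
    fsub <- features[features$disease == dis, ]
    for (f in intersect(c("contrast", "correlation", "energy", "homogeneity"),
                        unique(summaries$feature))) {
      ssub <- summaries[summaries$disease == dis & summaries$feature == f, ]
      if (nrow(ssub) == 0L) next
      file <- file.path(dir, sprintf("%s_%s.png", dis, f))
      grDevices::png(file, width = width, height = height)
      tryCatch({
        y <- fsub[[f]]
        ok <- !is.na(y)
        x <- as.integer(factor(as.character(fsub$label), levels = class_labels()))
        graphics::plot(NA, xlim = c(0.5, 3.5),
                       ylim = range(c(y[ok], ssub$ci_low, ssub$ci_high)),
                       xaxt = "n", xlab = "diagnostic-probability class",
                       ylab = f, main = sprintf("%s: %s", dis, f))
        graphics::axis(1, at = 1:3, labels = class_labels())
        for (k in seq_len(nrow(ssub))) {
          lab <- as.character(ssub$label[k])
          col <- grDevices::adjustcolor(band_col[[lab]], alpha.f = 0.25)
          graphics::rect(0.5, ssub$ci_low[k], 3.5, ssub$ci_high[k],
                         col = col, border = NA)
          graphics::segments(0.5, ssub$mean[k], 3.5, ssub$mean[k],
                             col = band_col[[lab]], lty = 2)
        }
        graphics::points(jitter_positions(x[ok]), y[ok], pch = 16,
                         col = band_col[as.character(fsub$label[ok])])
      }, finally = grDevices::dev.off())
      files <- c(files, file)
    }
  }
  invisible(files)
}

# deterministic within-class x spread (no RNG: plots must be reproducible)
jitter_positions <- function(x) {
  out <- as.numeric(x)
  for (v in unique(x)) {
    idx <- which(x == v)
    k <- length(idx)
    out[idx] <- v + seq(-0.2, 0.2, length.out = max(k, 2L))[seq_len(k)]
  }
  out
}
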