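#' Load a grayscale ultrasound image
#'
#' Reads an 8-bit PNG or TIFF image into an integer gray matrix with values
#' in 0..255. Multi-channel input is collapsed with the standard Rec. 601
#' luminance weights (0.299 R + 0.587 G + 0.114 B); an alpha channel, if
#' present, is ignored. Higher bit depths (e.g. 16-bit TIFF) are rescaled
#' linearly onto 0..255 and rounded.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return integer matrix (rows x columns) of gray intensities in 0..255.
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' for ", path,
         " (supported: PNG, TIFF)", call. = FALSE)
  )
  # readPNG/readTIFF return values in [0, 1] regardless of source bit depth,
  # so one rescale handles 8-bit passthrough and 16-bit reduction alike
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    arr <- if (nc >= 3L) {
      0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr[, , 1L]
    }
  }
  if (length(dim(arr)) != 2L)
    stop("could not interpret ", path, " as a 2-D grayscale image", call. = FALSE)
  matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
}

#' ROI rectangle on a source image
#'
#' Constructs the region-of-interest specification used throughout the
#' pipeline: a 0-based, half-open rectangle
#' `[row0, row0 + height) x [col0, col0 + width)` placed by the operator
#' on the posterior acoustic shadow.
#'
#' @param row0,col0 top-left corner, 0-based.
#' @param height,width extents in pixels (>= 2).
#' @return list of class `"roi_spec"`.
#' @export
roi_spec <- function(row0, col0, height, width) {
  g <- c(row0 = row0, col0 = col0, height = height, width = width)
  if (anyNA(g) || any(g != floor(g)))
    stop("ROI geometry must be integer-valued", call. = FALSE)
  structure(as.list(stats::setNames(as.integer(g), names(g))),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("ROI [%d, %d) x [%d, %d) (%d x %d px)\n",
              x$row0, x$row0 + x$height, x$col0, x$col0 + x$width,
              x$height, x$width))
  invisible(x)
}

# side below which a size warning (not an error) is emitted: very small
# shadow ROIs carry too few pixel pairs to characterise texture reliably
.roi_warn_side <- 16L

#' Validate an ROI against an image
#'
#' Checks that the rectangle has positive extents of at least 2 pixels per
#' side and lies fully inside the image. Violations are returned as data,
#' not raised as errors, so callers can report all problems in a batch.
#'
#' @param roi a [roi_spec()].
#' @param image gray matrix the ROI refers to.
#' @return character vector of violations; `character(0)` when valid.
#' @export
validate_roi <- function(roi, image) {
  stopifnot(inherits(roi, "roi_spec"))
  v <- character(0)
  if (roi$height < 2L) v <- c(v, sprintf("height %d below minimum 2", roi$height))
  if (roi$width < 2L) v <- c(v, sprintf("width %d below minimum 2", roi$width))
  if (roi$row0 < 0L || roi$col0 < 0L)
    v <- c(v, "negative corner coordinates")
  if (roi$row0 + roi$height > nrow(image) || roi$col0 + roi$width > ncol(image))
    v <- c(v, sprintf("out of bounds: rectangle reaches (%d, %d) on a %d x %d image",
                      roi$row0 + roi$height, roi$col0 + roi$width,
                      nrow(image), ncol(image)))
  v
}

#' Crop a texture patch from an image
#'
#' Extracts the exact pixels of a validated ROI together with its
#' provenance (image id, class label, disease), producing the unit on
#' which texture descriptors are computed.
#'
#' @param image gray matrix.
#' @param roi a [roi_spec()]; must pass [validate_roi()].
#' @param label diagnostic-probability class, one of `"50-60"`, `"60-80"`,
#'   `">=80"`.
#' @param disease `"kidney"` or `"gallbladder"`.
#' @param image_id identifier recorded in the provenance (defaults to "").
#' @return list of class `"shadow_patch"` with elements `pixels`, `roi`,
#'   `label`, `disease`, `image_id`.
#' @export
extract_patch <- function(image, roi, label = NA_character_,
                          disease = NA_character_, image_id = "") {
  viol <- validate_roi(roi, image)
  if (length(viol) > 0L)
    stop("invalid ROI: ", paste(viol, collapse = "; "), call. = FALSE)
  if (roi$height < .roi_warn_side || roi$width < .roi_warn_side)
    warning(sprintf("ROI %d x %d is smaller than %d px per side; it may not carry enough texture information",
                    roi$height, roi$width, .roi_warn_side), call. = FALSE)
  if (!is.na(label)) label <- match.arg(label, class_labels())
  if (!is.na(disease)) disease <- match.arg(disease, c("kidney", "gallbladder"))
  px <- image[roi$row0 + seq_len(roi$height), roi$col0 + seq_len(roi$width),
              drop = FALSE]
  structure(list(pixels = px, roi = roi, label = label, disease = disease,
                 image_id = image_id),
            class = "shadow_patch")
}

#' Diagnostic-probability class labels
#'
#' The three operator-assigned stone diagnostic-probability groups, in
#' increasing order of posterior-shadow strength.
#'
#' @return character vector `c("50-60", "60-80", ">=80")`.
#' @export
class_labels <- function() c("50-60", "60-80", ">=80")

parse_class_label <- function(x) {
  x <- trimws(as.character(x))
  ok <- x %in% class_labels()
  if (!all(ok))
    stop("unknown class label '", x[!ok][1L],
         "', expected 50-60 | 60-80 | >=80", call. = FALSE)
  factor(x, levels = class_labels(), ordered = TRUE)
}

#' Read an ROI/label table
#'
#' Reads the CSV that stands in for manual ROI placement: one row per
#' image with columns `image, disease, label, row0, col0, height, width`.
#' Labels must be one of `50-60`, `60-80`, `>=80`; diseases `kidney` or
#' `gallbladder`; geometry columns integer.
#'
#' @param path path to the CSV file.
#' @param base_dir directory that relative image paths are resolved
#'   against; defaults to the directory containing the table.
#' @return data frame with columns `image` (resolved path), `disease`,
#'   `label` (ordered factor) and the four geometry columns.
#' @export
read_roi_table <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop("ROI table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "disease", "label", "row0", "col0", "height", "width")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    stop("ROI table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0L) {
    warning("ROI table ", path, " has a header but no rows", call. = FALSE)
    tab$label <- factor(character(0), levels = class_labels(), ordered = TRUE)
    return(tab[need])
  }
  for (col in c("row0", "col0", "height", "width")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad) > 0L)
      stop("ROI table row ", bad[1L], ": column '", col,
           "' is not an integer (value '", tab[[col]][bad[1L]], "')",
           call. = FALSE)
    tab[[col]] <- as.integer(v)
  }
  bad_dis <- which(!tab$disease %in% c("kidney", "gallbladder"))
  if (length(bad_dis) > 0L)
    stop("ROI table row ", bad_dis[1L], ": unknown disease '",
         tab$disease[bad_dis[1L]], "', expected kidney | gallbladder",
         call. = FALSE)
  tab$label <- parse_class_label(tab$label)
  rel <- !grepl("^(/|[A-Za-z]:)", tab$image)
  tab$image[rel] <- file.path(base_dir, tab$image[rel])
  tab[need]
}
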