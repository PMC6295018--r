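#' Configuration of the cell-shape quantification stage
#'
#' @param median_radius_px radius (pixels) of the disk-footprint median
#'   filter applied before thresholding. The screen protocol uses 8.
#' @param threshold_method automatic global threshold; currently `"otsu"`.
#' @param min_area_px components smaller than this pixel count are treated
#'   as debris and dropped (the historic macro states no size filter; this
#'   one is logged and configurable).
#' @param connectivity 8 (default) or 4; 8 keeps thin ramified processes
#'   attached to their somata.
#' @param cap_circularity cap measured circularity at 1.0 (digitization can
#'   push small round objects slightly above 1).
#' @param polarity `"bright"` for fluorescent cells on dark background,
#'   `"dark"` for the inverse.
#' @param smooth_window odd window (vertices) of the circular moving average
#'   applied to marching-squares contours before perimeter measurement.
#' @return A list of class `morph_config`.
#' @export
morph_config <- function(median_radius_px = 8, threshold_method = "otsu",
                         min_area_px = 50, connectivity = 8,
                         cap_circularity = TRUE, polarity = "bright",
                         smooth_window = 5) {
  stopifnot(median_radius_px >= 0, min_area_px >= 0,
            connectivity %in% c(4, 8), smooth_window %% 2 == 1)
  threshold_method <- match.arg(threshold_method, c("otsu"))
  polarity <- match.arg(polarity, c("bright", "dark"))
  structure(list(median_radius_px = median_radius_px,
                 threshold_method = threshold_method,
                 min_area_px = min_area_px, connectivity = connectivity,
                 cap_circularity = cap_circularity, polarity = polarity,
                 smooth_window = as.integer(smooth_window)),
            class = "morph_config")
}

#' Median filter with a disk footprint
#'
#' Each output pixel is the median of input intensities within a disk of the
#' given radius centered on it; image edges are handled by reflection.
#' Radius 0 is the identity.
#'
#' @param image numeric matrix of intensities.
#' @param radius_px footprint radius in pixels (>= 0).
#' @return Filtered matrix of the same dimensions.
#' @export
median_filter <- function(image, radius_px = 8) {
  stopifnot(is.matrix(image), is.numeric(image), radius_px >= 0)
  .median_filter_cpp(image, as.integer(radius_px))
}

# Otsu's threshold on a 256-bin histogram spanning the data range.
otsu_threshold <- function(x) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = 257L)
  h <- as.numeric(tabulate(findInterval(x, breaks, all.inside = TRUE),
                           nbins = 256L))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(256L))
  n <- w[256L]; mt <- mu[256L]
  w1 <- w[-256L]; w2 <- n - w1
  between <- (mt * w1 - mu[-256L] * n)^2 / (w1 * w2 * n^2)
  between[w1 == 0 | w2 == 0] <- -Inf
  k <- which.max(between)
  breaks[k + 1L]  # upper edge of the chosen bin
}

#' Threshold an image into a cell mask
#'
#' Computes a global automatic threshold (Otsu's method on a 256-bin
#' histogram of the image range) and returns the foreground mask. The
#' threshold value used is attached as attribute `"threshold"` so every run
#' can be audited.
#'
#' @param image numeric matrix (typically the median-filtered field).
#' @param method `"otsu"`.
#' @param polarity `"bright"` (foreground above threshold) or `"dark"`.
#' @return Logical matrix with attribute `threshold`.
#' @export
binarize <- function(image, method = "otsu", polarity = "bright") {
  stopifnot(is.matrix(image), is.numeric(image))
  method <- match.arg(method, c("otsu"))
  polarity <- match.arg(polarity, c("bright", "dark"))
  if (diff(range(image)) == 0)
    stop("cannot threshold a constant image with an automatic method",
         call. = FALSE)
  thr <- otsu_threshold(image)
  mask <- if (polarity == "bright") image > thr else image <= thr
  attr(mask, "threshold") <- thr
  mask
}

#' Label cells and measure their shape
#'
#' Connected components of the mask (holes filled first, so only the outer
#' outline is measured) with area at least `min_area_px` become cell
#' objects. The perimeter is the length of a smoothed sub-pixel
#' marching-squares contour; circularity is `4*pi*A / P^2`, optionally
#' capped at 1.
#'
#' @param mask logical matrix (from [binarize()]).
#' @param config a [morph_config()].
#' @return A data.frame with one row per cell: `label`, `area_px`,
#'   `perimeter_px`, `circularity`, `centroid_row`, `centroid_col`,
#'   `touches_border`. The label matrix is attached as attribute `labels`.
#' @export
label_objects <- function(mask, config = morph_config()) {
  stopifnot(is.matrix(mask), is.logical(c(mask)))
  storage.mode(mask) <- "logical"
  filled <- .fill_holes_cpp(mask)
  lab <- .label_components_cpp(filled, as.integer(config$connectivity))
  nlab <- max(lab)
  empty <- data.frame(label = integer(0), area_px = numeric(0),
                      perimeter_px = numeric(0), circularity = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      touches_border = logical(0))
  if (nlab == 0L) {
    attr(empty, "labels") <- lab
    return(empty)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- vector("list", nlab)
  idx <- which(lab > 0L)
  ij <- arrayInd(idx, dim(lab))
  lb <- lab[idx]
  ord <- order(lb)
  ij <- ij[ord, , drop = FALSE]; lb <- lb[ord]
  starts <- c(1L, which(diff(lb) > 0L) + 1L, length(lb) + 1L)
  out <- vector("list", nlab)
  for (k in seq_len(nlab)) {
    sel <- starts[k]:(starts[k + 1L] - 1L)
    pr <- ij[sel, 1L]; pc <- ij[sel, 2L]
    area <- length(sel)
    if (area < config$min_area_px) next
    touches <- any(pr == 1L | pr == nr | pc == 1L | pc == nc)
    r0 <- min(pr); r1 <- max(pr); c0 <- min(pc); c1 <- max(pc)
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(pr - r0 + 1L, pc - c0 + 1L)] <- TRUE
    per <- mask_perimeter(sub, config$smooth_window)
    circ <- 4 * pi * area / per^2
    if (isTRUE(config$cap_circularity)) circ <- min(circ, 1)
    out[[k]] <- data.frame(label = k, area_px = as.numeric(area),
                           perimeter_px = per, circularity = circ,
                           centroid_row = mean(pr), centroid_col = mean(pc),
                           touches_border = touches)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  attr(res, "labels") <- lab
  res
}

#' Exclude cells touching the image border
#'
#' Cells whose component contains any pixel in the first/last row or column
#' are removed from quantification (their outline is truncated by the field
#' of view); they are retained in an audit table.
#'
#' @param cells cell table from [label_objects()].
#' @param image_shape unused except for validation; kept for interface
#'   symmetry with the imaging stage.
#' @return A list with elements `kept` and `audited` (both data.frames);
#'   every labeled object appears in exactly one of the two.
#' @export
exclude_border <- function(cells, image_shape = NULL) {
  stopifnot(is.data.frame(cells), "touches_border" %in% names(cells))
  list(kept = cells[!cells$touches_border, , drop = FALSE],
       audited = cells[cells$touches_border, , drop = FALSE])
}

#' Quantify every cell in a field
#'
#' The full per-field morphometry chain: median filter, automatic
#' threshold, component labeling with sub-pixel perimeter measurement, and
#' border-cell exclusion.
#'
#' @param image numeric matrix of intensities.
#' @param config a [morph_config()].
#' @param metadata named list of condition annotations (e.g. `gene`,
#'   `sirna`, `experiment`, `field`) prepended as columns.
#' @return Data.frame of retained cells (one row per cell) with metadata
#'   columns; attributes `audited` (border cells) and `threshold` (the
#'   global threshold used).
#' @export
analyze_field <- function(image, config = morph_config(), metadata = list()) {
  filt <- tryCatch(median_filter(image, config$median_radius_px),
                   error = function(e) stop_stage("median_filter", conditionMessage(e)))
  mask <- tryCatch(binarize(filt, config$threshold_method, config$polarity),
                   error = function(e) stop_stage("binarize", conditionMessage(e)))
  cells <- tryCatch(label_objects(mask, config),
                    error = function(e) stop_stage("label_objects", conditionMessage(e)))
  split <- exclude_border(cells, dim(image))
  res <- split$kept
  if (length(metadata)) {
    meta <- as.data.frame(metadata, stringsAsFactors = FALSE)
    res <- if (nrow(res)) cbind(meta[rep(1L, nrow(res)), , drop = FALSE], res)
           else cbind(meta[0, , drop = FALSE], res)
    rownames(res) <- NULL
  }
  attr(res, "audited") <- split$audited
  attr(res, "threshold") <- attr(mask, "threshold")
  res
}
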