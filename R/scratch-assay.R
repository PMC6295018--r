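# Wound-healing scratch assay quantification.

# Local variance map via integral images; window must be odd. Values at the
# borders use a shrunken window (edge-clipped box).
local_variance <- function(img, window = 15L) {
  stopifnot(window %% 2 == 1, window >= 3)
  h <- window %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  boxsum <- function(m) {
    cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
    cs <- t(cs)
    cs <- rbind(0, cbind(0, cs))
    r0 <- pmax(seq_len(nr) - h, 1L); r1 <- pmin(seq_len(nr) + h, nr)
    c0 <- pmax(seq_len(nc) - h, 1L); c1 <- pmin(seq_len(nc) + h, nc)
    cs[r1 + 1L, c1 + 1L, drop = FALSE] - cs[r0, c1 + 1L, drop = FALSE] -
      cs[r1 + 1L, c0, drop = FALSE] + cs[r0, c0, drop = FALSE]
  }
  ones <- matrix(1, nr, nc)
  n <- boxsum(ones)
  s1 <- boxsum(img)
  s2 <- boxsum(img^2)
  pmax(s2 / n - (s1 / n)^2, 0)
}

#' Measure the wound width in a scratch-assay image
#'
#' Computes a local-variance texture map, thresholds it automatically
#' (Otsu) to separate the textured cell lawn from the smooth cell-free
#' band, and keeps the largest low-variance component spanning at least
#' `min_height_frac` of the image height. The width is the component area
#' divided by its vertical extent (mean width, robust to ragged edges),
#' plus a compensation of `window - 1` pixels for the texture-window
#' erosion of the band edges.
#'
#' @param image numeric matrix (bright-field scratch image); the scratch is
#'   assumed roughly vertical (use `rotate = TRUE` for horizontal wounds).
#' @param window odd size of the local-variance window (pixels).
#' @param min_height_frac minimum fraction of the image height a candidate
#'   wound component must span.
#' @param max_area_frac a low-variance region covering more than this
#'   fraction of the image is not a wound (blank/degenerate image).
#' @param min_solidity minimum fill fraction of the candidate component in
#'   its bounding box; a real cell-free band is solid, whereas percolating
#'   low-variance speckle in a fully closed lawn is not.
#' @param rotate set `TRUE` if the wound runs horizontally.
#' @return List: `width_px` (0 when closed or degenerate), `status`
#'   (`"ok"`, `"closed"` or `"degenerate"`), `mask` (the wound component),
#'   `threshold` (variance threshold used).
#' @export
detect_wound <- function(image, window = 15, min_height_frac = 0.8,
                         max_area_frac = 0.9, min_solidity = 0.6,
                         rotate = FALSE) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (rotate) image <- t(image)
  v <- local_variance(image, as.integer(window))
  if (diff(range(v)) == 0) {
    # uniform texture everywhere: nothing to separate
    return(list(width_px = 0, status = "degenerate", mask = NULL,
                threshold = NA_real_))
  }
  thr <- otsu_threshold(v)
  low <- v <= thr
  if (mean(low) > max_area_frac)
    return(list(width_px = 0, status = "degenerate", mask = NULL,
                threshold = thr))
  lab <- .label_components_cpp(low, 8L)
  nlab <- max(lab)
  if (nlab == 0L)
    return(list(width_px = 0, status = "closed", mask = NULL, threshold = thr))
  best <- 0L; best_area <- 0
  for (k in seq_len(nlab)) {
    px <- which(lab == k, arr.ind = TRUE)
    hgt <- diff(range(px[, 1])) + 1L
    wid <- diff(range(px[, 2])) + 1L
    if (hgt < min_height_frac * nrow(image)) next
    if (nrow(px) / (hgt * wid) < min_solidity) next
    if (nrow(px) > best_area) { best_area <- nrow(px); best <- k }
  }
  if (best == 0L)
    return(list(width_px = 0, status = "closed", mask = NULL, threshold = thr))
  px <- which(lab == best, arr.ind = TRUE)
  hgt <- diff(range(px[, 1])) + 1L
  width <- nrow(px) / hgt + (window - 1)  # edge-erosion compensation
  mask <- lab == best
  list(width_px = width, status = "ok", mask = mask, threshold = thr)
}

#' Closure percentages and control-normalized scratch widths
#'
#' The 24-h wound width is expressed as a percentage of the 1-h width
#' (`closure_percent = 100 * w24 / w1`), then divided by the same
#' experiment's scrambled-control percentage, so the control is exactly
#' 1.0 in every experiment and values below 1 mean faster closure than
#' control.
#'
#' @param records data.frame with columns `condition`, `experiment`,
#'   `width_t1_px`, `width_t24_px`.
#' @param control_label control condition name.
#' @return The records with `closure_percent` and `normalized_width`
#'   columns; a per-condition summary (mean and SEM of the normalized
#'   width across experiments) is attached as attribute `summary`.
#' @export
closure_and_normalize <- function(records, control_label = "Scrambled") {
  stopifnot(all(c("condition", "experiment", "width_t1_px", "width_t24_px")
                %in% names(records)))
  if (any(records$width_t1_px <= 0))
    stop("invalid scratch: width at 1 h must be positive", call. = FALSE)
  if (any(records$width_t24_px < 0))
    stop("widths must be non-negative", call. = FALSE)
  records$closure_percent <- 100 * records$width_t24_px / records$width_t1_px
  records$normalized_width <- NA_real_
  for (e in unique(records$experiment)) {
    sel <- records$experiment == e
    ctrl <- records$closure_percent[sel & records$condition == control_label]
    if (length(ctrl) == 0)
      stop(sprintf("control '%s' missing in experiment %s", control_label, e),
           call. = FALSE)
    if (mean(ctrl) == 0)
      stop("control scratch fully closed; cannot normalize", call. = FALSE)
    records$normalized_width[sel] <- records$closure_percent[sel] / mean(ctrl)
  }
  smry <- do.call(rbind, lapply(split(records, records$condition), function(g)
    data.frame(condition = g$condition[1],
               mean_normalized = mean(g$normalized_width),
               sem_normalized = if (nrow(g) > 1)
                 stats::sd(g$normalized_width) / sqrt(nrow(g)) else NA_real_,
               n_experiments = nrow(g))))
  rownames(smry) <- NULL
  attr(records, "summary") <- smry
  records
}
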