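#' Generate a synthetic scratch-assay image pair
#'
#' Each image is a textured cell lawn (high local intensity variance) with a
#' centered low-texture vertical band of the requested width, emulating the
#' cell-free wound photographed 1 h and 24 h after scratching a confluent
#' layer. `width_t24 = 0` produces a fully closed lawn.
#'
#' @param width_t1,width_t24 wound widths in pixels at the two timepoints
#'   (`0 <= width_t24 <= width_t1 <= image width`).
#' @param image_size `c(rows, cols)`.
#' @param texture_sd intensity SD of the lawn texture.
#' @param band_sd residual intensity SD inside the wound (much smaller).
#' @param seed integer seed; identical seeds give identical pixel data.
#' @return List of class `scratch_pair`: `t1`, `t24` (image matrices) and
#'   `truth` (`width_t1_px`, `width_t24_px`, `closure_percent`).
#' @export
generate_scratch_pair <- function(width_t1, width_t24,
                                  image_size = c(256, 512), texture_sd = 40,
                                  band_sd = 1.5, seed = NULL) {
  if (width_t1 < 0 || width_t24 < 0)
    stop("scratch widths must be non-negative", call. = FALSE)
  if (width_t24 > width_t1)
    stop("the wound cannot widen: width_t24 must be <= width_t1", call. = FALSE)
  if (width_t1 > image_size[2])
    stop("width_t1 exceeds the image width", call. = FALSE)
  with_seed(seed, {
    render <- function(w) {
      nr <- image_size[1]; nc <- image_size[2]
      img <- matrix(pmin(pmax(rnorm(nr * nc, 128, texture_sd), 0), 255), nr, nc)
      if (w > 0) {
        c0 <- floor((nc - w) / 2) + 1L
        cols <- c0:(c0 + ceiling(w) - 1L)
        img[, cols] <- pmin(pmax(rnorm(nr * length(cols), 40, band_sd), 0), 255)
      }
      round(img)
    }
    structure(list(t1 = render(width_t1), t24 = render(width_t24),
                   truth = data.frame(width_t1_px = width_t1,
                                      width_t24_px = width_t24,
                                      closure_percent =
                                        if (width_t1 > 0) 100 * width_t24 / width_t1
                                        else NA_real_)),
              class = "scratch_pair")
  })
}
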