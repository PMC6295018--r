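#' Generate a synthetic cell field with analytic ground truth
#'
#' Places the requested shapes in a dark image without mask overlap
#' (rejection sampling with a one-pixel separation so 8-connected labeling
#' keeps cells distinct). Exactly `n_border` of the shapes are placed so
#' that their mask intersects an image edge; the rest are strictly
#' interior. Pixels covered by a cell take the constant foreground
#' intensity; Gaussian noise is added everywhere and intensities are
#' clipped to the bit depth and rounded.
#'
#' @param specs list of [shape_spec()] objects (one per cell). The first
#'   `length(specs) - n_border` are placed interior, the rest on the border.
#' @param image_size `c(rows, cols)` in pixels.
#' @param n_border number of cells that must intersect an image edge.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param foreground,background constant intensities of cells / empty field.
#' @param bit_depth 8 or 16.
#' @param max_tries placement attempts per cell before giving up.
#' @param seed integer seed; identical seeds give bit-identical fields.
#' @return Object of class `micro_field`: list with `image` (numeric
#'   matrix), `labels` (integer matrix, 0 = background), `truth`
#'   (data.frame: `cell_id`, `kind`, `size_px`, `aspect_ratio`,
#'   `n_branches`, `area`, `perimeter`, `circularity`, `border`),
#'   `n_interior`, `n_border`, `seed`.
#' @export
generate_field <- function(specs, image_size = c(256, 256), n_border = 0,
                           noise_sd = 5, foreground = 200, background = 30,
                           bit_depth = 8, max_tries = 300, seed = NULL) {
  stopifnot(n_border >= 0, n_border <= length(specs),
            bit_depth %in% c(8, 16), noise_sd >= 0)
  if (!all(vapply(specs, inherits, logical(1), "shape_spec")))
    stop("specs must be a list of shape_spec objects", call. = FALSE)
  nr <- image_size[1]; nc <- image_size[2]
  n <- length(specs)
  with_seed(seed, {
    labels <- matrix(0L, nr, nc)
    # occupancy incl. the 1-px separation halo
    occupied <- matrix(FALSE, nr, nc)
    border_flag <- c(rep(FALSE, n - n_border), rep(TRUE, n_border))
    truth <- vector("list", n)
    for (k in seq_len(n)) {
      sp <- specs[[k]]
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        angle <- runif(1, 0, pi)
        bang <- if (sp$kind == "ramified") draw_branch_angles(sp) else NULL
        ext <- switch(sp$kind, disk = sp$size_px, ellipse = sp$semi_major,
                      ramified = sp$size_px + sp$branch_length)
        if (border_flag[k]) {
          edge <- sample(4L, 1L)
          off <- runif(1, 0, sp$size_px * 0.8)  # center just inside the edge
          ctr <- switch(edge,
            c(1 + off, runif(1, ext, nc - ext)),       # top
            c(nr - off, runif(1, ext, nc - ext)),      # bottom
            c(runif(1, ext, nr - ext), 1 + off),       # left
            c(runif(1, ext, nr - ext), nc - off))      # right
        } else {
          lo <- ext + 2; hi_r <- nr - ext - 1; hi_c <- nc - ext - 1
          if (hi_r <= lo || hi_c <= lo)
            stop("shape too large for interior placement in this image",
                 call. = FALSE)
          ctr <- c(runif(1, lo, hi_r), runif(1, lo, hi_c))
        }
        px <- rasterize_shape(sp, ctr, angle, bang)
        inb <- px[, 1] >= 1 & px[, 1] <= nr & px[, 2] >= 1 & px[, 2] <= nc
        if (border_flag[k]) {
          pxc <- px[inb, , drop = FALSE]
          if (nrow(pxc) < 0.2 * nrow(px)) next  # keep most of the cell visible
          touches <- any(pxc[, 1] == 1 | pxc[, 1] == nr |
                         pxc[, 2] == 1 | pxc[, 2] == nc)
          if (!touches) next
          px <- pxc
        } else {
          if (any(!inb)) next
          if (any(px[, 1] <= 1 | px[, 1] >= nr | px[, 2] <= 1 | px[, 2] >= nc))
            next  # interior cells must not touch the border
        }
        if (any(occupied[px])) next
        labels[px] <- k
        # mark the pixels plus a 2-px chebyshev halo as occupied, so cells
        # stay separable even after mild smoothing
        for (dr in -2:2) for (dc in -2:2) {
          rr <- px[, 1] + dr; cc <- px[, 2] + dc
          ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
          occupied[cbind(rr[ok], cc[ok])] <- TRUE
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("could not place cell %d after %d tries; reduce density",
                     k, max_tries), call. = FALSE)
      truth[[k]] <- data.frame(cell_id = k, kind = sp$kind,
                               size_px = sp$size_px,
                               aspect_ratio = sp$aspect_ratio,
                               n_branches = sp$n_branches,
                               area = sp$area, perimeter = sp$perimeter,
                               circularity = sp$target_circularity,
                               border = border_flag[k])
    }
    img <- matrix(background, nr, nc)
    img[labels > 0L] <- foreground
    if (noise_sd > 0) img <- img + rnorm(nr * nc, 0, noise_sd)
    img <- round(pmin(pmax(img, 0), 2^bit_depth - 1))
    structure(list(image = img, labels = labels,
                   truth = do.call(rbind, truth),
                   n_interior = n - n_border, n_border = n_border,
                   bit_depth = bit_depth, seed = seed),
              class = "micro_field")
  })
}

#' @export
print.micro_field <- function(x, ...) {
  cat(sprintf("<micro_field> %dx%d px, %d cells (%d interior, %d border)\n",
              nrow(x$image), ncol(x$image),
              x$n_interior + x$n_border, x$n_interior, x$n_border))
  invisible(x)
}
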