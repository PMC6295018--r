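#' Describe a synthetic cell shape with analytic ground truth
#'
#' Defines one of three idealized cell outlines used by the field generator:
#' a disk (amoeboid cell), an ellipse of given aspect ratio (elongated cell),
#' or a "ramified" cell built from a circular soma with rectangular processes
#' radiating outwards. Area and perimeter of the continuous shape are computed
#' in closed form, and the ground-truth circularity is `4*pi*A / P^2`.
#'
#' For the ramified kind, each branch is a rectangle of width `branch_width`
#' and radial extent `branch_length` beyond the soma, attached so that its
#' inner edge coincides with the chord of the soma circle at half the branch
#' width; the union's area and perimeter then have exact closed forms
#' (circular-segment geometry). Branch directions are spaced so that branches
#' never intersect each other.
#'
#' @param kind `"disk"`, `"ellipse"` or `"ramified"`.
#' @param size_px characteristic radius in pixels. For ellipses this is the
#'   radius of the equal-area disk (semi-axes `size_px*sqrt(ar)` and
#'   `size_px/sqrt(ar)`); for ramified cells it is the soma radius.
#' @param aspect_ratio major/minor axis ratio (>= 1); must be 1 for disks.
#' @param n_branches number of processes (ramified only, >= 0).
#' @param branch_length radial extent of each process beyond the soma
#'   (default `3 * size_px`).
#' @param branch_width width of each process (default `max(2, size_px / 3)`).
#' @return An object of class `shape_spec`: a list with the input fields plus
#'   `area`, `perimeter` and `target_circularity` of the continuous shape.
#' @examples
#' shape_spec("disk", 20)$target_circularity            # exactly 1
#' shape_spec("ellipse", 20, aspect_ratio = 2)          # ~0.84
#' shape_spec("ramified", 10, n_branches = 3)           # well below 0.5
#' @export
shape_spec <- function(kind = c("disk", "ellipse", "ramified"), size_px,
                       aspect_ratio = 1, n_branches = 0,
                       branch_length = NULL, branch_width = NULL) {
  kind <- match.arg(kind)
  stopifnot(size_px > 0, aspect_ratio >= 1, n_branches >= 0,
            n_branches == round(n_branches))
  if (kind == "disk" && aspect_ratio != 1)
    stop("a disk has aspect_ratio 1", call. = FALSE)
  if (kind != "ramified" && n_branches > 0)
    stop("n_branches applies to kind = 'ramified' only", call. = FALSE)

  r <- size_px
  if (kind == "disk") {
    geom <- list(area = pi * r^2, perimeter = 2 * pi * r)
  } else if (kind == "ellipse") {
    a <- r * sqrt(aspect_ratio)
    b <- r / sqrt(aspect_ratio)
    geom <- list(area = pi * a * b, perimeter = ramanujan_perimeter(a, b),
                 semi_major = a, semi_minor = b)
  } else {
    L <- branch_length %||% (3 * r)
    w <- branch_width %||% max(2, r / 3)
    stopifnot(L > 0, w > 0, w < 2 * r)
    n <- as.integer(n_branches)
    # inner edge of each branch sits at the chord x* = sqrt(r^2 - (w/2)^2)
    xs <- sqrt(r^2 - (w / 2)^2)
    # minimum angular separation so branches cannot intersect
    half_ang <- atan((w / 2) / xs)
    if (n > 0 && 2 * half_ang * 1.25 * n > 2 * pi)
      stop("too many branches for this soma/branch geometry", call. = FALSE)
    # area of the branch rectangle lying outside the soma:
    #   w*(r + L - x*) - 2 * int_{x*}^{r} sqrt(r^2 - x^2) dx
    iseg <- function(x) x / 2 * sqrt(pmax(r^2 - x^2, 0)) + r^2 / 2 * asin(x / r)
    a_out <- w * (r + L - xs) - 2 * (iseg(r) - iseg(xs))
    # perimeter: full circle minus the arc behind each branch, plus the three
    # exposed rectangle sides (two long sides from the circle crossing to the
    # tip, plus the tip)
    arc <- 2 * r * asin(w / (2 * r))
    geom <- list(area = pi * r^2 + n * a_out,
                 perimeter = 2 * pi * r - n * arc + n * (2 * (r + L - xs) + w),
                 branch_length = L, branch_width = w, chord_x = xs,
                 min_branch_sep = 2 * half_ang * 1.25)
  }
  out <- c(list(kind = kind, size_px = size_px, aspect_ratio = aspect_ratio,
                n_branches = as.integer(n_branches)), geom)
  out$target_circularity <- 4 * pi * out$area / out$perimeter^2
  structure(out, class = "shape_spec")
}

#' Ramanujan's approximation to the ellipse perimeter
#'
#' `pi * (3*(a+b) - sqrt((3a+b)*(a+3b)))`; the analytic perimeter oracle used
#' for elongated-cell ground truth.
#'
#' @param a,b semi-axes.
#' @return Approximate perimeter (relative error < 1e-4 for aspect <= 10).
#' @export
ramanujan_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("<shape_spec> %s r=%g ar=%g branches=%d  A=%.2f P=%.2f C=%.4f\n",
              x$kind, x$size_px, x$aspect_ratio, x$n_branches,
              x$area, x$perimeter, x$target_circularity))
  invisible(x)
}

# Rasterize a shape at a given center (row, col) and orientation.
# Returns integer pixel coordinates (matrix with columns row, col), unclipped.
# `branch_angles` must be supplied for ramified shapes.
rasterize_shape <- function(spec, center, angle = 0, branch_angles = NULL) {
  r <- spec$size_px
  ext <- switch(spec$kind,
    disk = r,
    ellipse = spec$semi_major,
    ramified = r + (spec$branch_length %||% (3 * r)))
  ext <- ceiling(ext) + 1L
  rows <- seq.int(floor(center[1] - ext), ceiling(center[1] + ext))
  cols <- seq.int(floor(center[2] - ext), ceiling(center[2] + ext))
  dy <- rows - center[1]
  dx <- cols - center[2]
  Y <- matrix(dy, nrow = length(dy), ncol = length(dx))
  X <- matrix(dx, nrow = length(dy), ncol = length(dx), byrow = TRUE)
  inside <- switch(spec$kind,
    disk = (X^2 + Y^2) <= r^2,
    ellipse = {
      xr <- cos(angle) * X + sin(angle) * Y
      yr <- -sin(angle) * X + cos(angle) * Y
      (xr / spec$semi_major)^2 + (yr / spec$semi_minor)^2 <= 1
    },
    ramified = {
      inside <- (X^2 + Y^2) <= r^2
      xs <- spec$chord_x
      w2 <- spec$branch_width / 2
      tip <- r + spec$branch_length
      for (th in branch_angles %||% numeric(0)) {
        u <- cos(th) * X + sin(th) * Y
        v <- -sin(th) * X + cos(th) * Y
        inside <- inside | (u >= xs & u <= tip & abs(v) <= w2)
      }
      inside
    })
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rows[idx[, 1]], col = cols[idx[, 2]])
}

# Draw well-separated branch angles for a ramified shape.
draw_branch_angles <- function(spec) {
  n <- spec$n_branches
  if (n == 0) return(numeric(0))
  sep <- spec$min_branch_sep
  for (try in 1:200) {
    th <- sort(runif(n, 0, 2 * pi))
    gaps <- diff(c(th, th[1] + 2 * pi))
    if (all(gaps >= sep)) return(th)
  }
  # deterministic fallback: evenly spaced with random rotation
  (runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]) %% (2 * pi)
}
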