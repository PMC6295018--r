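# Independent oracles and small fixture builders. Everything here is
# deliberately naive (loops, brute force) and separate from the package's
# own code paths.

# --- rasterized reference shapes -------------------------------------------

raster_disk <- function(r, sz = 2 * ceiling(r) + 20, cy = sz / 2 + 0.3,
                        cx = sz / 2 + 0.1) {
  yy <- row(matrix(0, sz, sz)); xx <- col(matrix(0, sz, sz))
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

raster_square <- function(side, sz = side + 40) {
  m <- matrix(FALSE, sz, sz)
  s0 <- floor((sz - side) / 2)
  m[s0:(s0 + side - 1), s0:(s0 + side - 1)] <- TRUE
  m
}

raster_ellipse <- function(a, b, sz = 2 * ceiling(a) + 20, theta = 0) {
  yy <- row(matrix(0, sz, sz)) - sz / 2
  xx <- col(matrix(0, sz, sz)) - sz / 2
  xr <- cos(theta) * xx + sin(theta) * yy
  yr <- -sin(theta) * xx + cos(theta) * yy
  (xr / a)^2 + (yr / b)^2 <= 1
}

# measured circularity of a mask through the package's labeling stage
measure_circ <- function(mask, min_area = 10) {
  tab <- label_objects(mask, morph_config(min_area_px = min_area))
  stopifnot(nrow(tab) == 1L)
  tab$circularity
}

# --- naive median filter (O(n r^2) sliding window, reflected edges) --------

reflect1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n - i + 1
  }
  i
}

naive_median_filter <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  out <- img
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- numeric(nrow(off))
      for (k in seq_len(nrow(off))) {
        vals[k] <- img[reflect1(i + off$dr[k], nr), reflect1(j + off$dc[k], nc)]
      }
      out[i, j] <- median(vals)
    }
  }
  out
}

# --- naive two-pass Benjamini-Hochberg -------------------------------------

naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(q[i:m], 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- literal transcription of the moderated one-sample t -------------------
# Given a per-condition matrix of normalized log2 values (rows =
# conditions, columns = experiments), recompute everything with explicit
# loops and an independent trigamma inversion (uniroot).

naive_moderated_t <- function(mat) {
  n_cond <- nrow(mat)
  n <- ncol(mat)
  means <- numeric(n_cond); s2 <- numeric(n_cond)
  for (g in seq_len(n_cond)) {
    x <- mat[g, ]
    means[g] <- sum(x) / n
    s2[g] <- sum((x - means[g])^2) / (n - 1)
  }
  dg <- n - 1
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  ebar <- sum(e) / n_cond
  evar <- sum((e - ebar)^2) / (n_cond - 1)
  rhs <- evar - trigamma(dg / 2)
  if (rhs <= 0) {
    d0 <- 4
    s0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    inv <- uniroot(function(y) trigamma(y) - rhs,
                   lower = 1e-8, upper = 1e8, tol = 1e-15)$root
    d0 <- 2 * inv
    s0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  st2 <- (d0 * s0 + dg * s2) / (d0 + dg)
  tt <- means / sqrt(st2 / n)
  p <- 2 * pt(-abs(tt), df = d0 + dg)
  list(d0 = d0, s0_2 = s0, diff = means, t = tt, p = p)
}

# --- misc ------------------------------------------------------------------

# small all-null aggregated screen table without using the generator
flat_screen_table <- function(n_genes = 4, n_exp = 3, value = 0.5) {
  grid <- expand.grid(sirna = c("#1", "#2"),
                      gene = sprintf("g%02d", seq_len(n_genes)),
                      experiment = seq_len(n_exp),
                      stringsAsFactors = FALSE)[, c("gene", "sirna",
                                                    "experiment")]
  ctrl <- data.frame(gene = "Scrambled", sirna = "ctrl",
                     experiment = seq_len(n_exp))
  tbl <- rbind(grid, ctrl)
  tbl$mean_circularity <- value
  tbl
}
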