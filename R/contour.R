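# Sub-pixel contour extraction and perimeter estimation.
#
# The binary mask is sampled at pixel centers; the 0.5-level iso-contour is
# built by marching squares, giving a closed polygon through pixel-edge
# midpoints. Raw midpoint polygons overestimate the length of smooth
# boundaries (staircase effect), so vertices are smoothed with a short
# circular moving average before the length is measured; this keeps the
# circularity of a large rasterized disk near 1, as the form-factor
# definition intends.

# segment lookup: for each marching-squares case, endpoints among the four
# edge midpoints T(op), R(ight), B(ottom), L(eft). Saddle cases (5, 10 in
# tl*8+tr*4+br*2+bl*1 coding) are resolved treating the foreground as
# 8-connected.
.ms_cases <- list(
  `1`  = list(c("L", "B")),
  `2`  = list(c("B", "R")),
  `3`  = list(c("L", "R")),
  `4`  = list(c("T", "R")),
  `5`  = list(c("T", "L"), c("B", "R")),   # tr+bl foreground
  `6`  = list(c("T", "B")),
  `7`  = list(c("T", "L")),
  `8`  = list(c("T", "L")),
  `9`  = list(c("T", "B")),
  `10` = list(c("T", "R"), c("B", "L")),   # tl+br foreground
  `11` = list(c("T", "R")),
  `12` = list(c("L", "R")),
  `13` = list(c("B", "R")),
  `14` = list(c("L", "B")),
  `15` = list()
)

# Outer 0.5-level contour of a logical mask (holes assumed filled).
# Returns a closed polygon as a matrix (row, col) in pixel-center
# coordinates; when the mask has several boundary loops the longest is
# returned.
outer_contour <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  nr <- nrow(m); nc <- ncol(m)
  tl <- m[-nr, -nc]; tr <- m[-nr, -1]; br <- m[-1, -1]; bl <- m[-1, -nc]
  code <- tl * 8L + tr * 4L + br * 2L + bl * 1L
  cells <- which(code > 0L & code < 15L, arr.ind = TRUE)
  if (nrow(cells) == 0L) return(NULL)

  # endpoint coordinates doubled so they are exact integers (hash keys);
  # cell (i, j) spans pixel centers (i, j)..(i+1, j+1) in padded coords
  seg_from <- character(0); seg_to <- character(0)
  pts <- new.env(parent = emptyenv())
  mid <- function(i, j, side) {
    switch(side,
      T = c(2L * i, 2L * j + 1L),
      R = c(2L * i + 1L, 2L * j + 2L),
      B = c(2L * i + 2L, 2L * j + 1L),
      L = c(2L * i + 1L, 2L * j))
  }
  n_est <- nrow(cells) * 2L
  from <- character(n_est); to <- character(n_est); k <- 0L
  for (s in seq_len(nrow(cells))) {
    i <- cells[s, 1L]; j <- cells[s, 2L]
    for (seg in .ms_cases[[as.character(code[i, j])]]) {
      p1 <- mid(i, j, seg[1]); p2 <- mid(i, j, seg[2])
      k1 <- paste(p1, collapse = ","); k2 <- paste(p2, collapse = ",")
      assign(k1, p1, envir = pts); assign(k2, p2, envir = pts)
      k <- k + 1L; from[k] <- k1; to[k] <- k2
    }
  }
  from <- from[seq_len(k)]; to <- to[seq_len(k)]

  # adjacency: every vertex on a closed loop touches exactly two segments
  adj <- new.env(parent = emptyenv())
  addadj <- function(a, b) {
    cur <- if (exists(a, envir = adj, inherits = FALSE))
      get(a, envir = adj) else character(0)
    assign(a, c(cur, b), envir = adj)
  }
  for (s in seq_len(k)) { addadj(from[s], to[s]); addadj(to[s], from[s]) }

  visited <- new.env(parent = emptyenv())
  best <- NULL; best_len <- -1
  for (s in seq_len(k)) {
    start <- from[s]
    if (exists(start, envir = visited, inherits = FALSE)) next
    loop <- character(0)
    prev <- ""
    cur <- start
    repeat {
      loop <- c(loop, cur)
      assign(cur, TRUE, envir = visited)
      nbrs <- get(cur, envir = adj)
      nxt <- nbrs[nbrs != prev]
      nxt <- nxt[!vapply(nxt, exists, logical(1),
                         envir = visited, inherits = FALSE) | nxt == start]
      if (length(nxt) == 0L) break
      prev <- cur
      cur <- nxt[1L]
      if (cur == start) break
    }
    if (length(loop) > best_len) { best_len <- length(loop); best <- loop }
  }
  xy <- t(vapply(best, function(kk) get(kk, envir = pts), numeric(2)))
  # back to pixel-center coordinates of the unpadded mask
  cbind(row = xy[, 1] / 2 - 1, col = xy[, 2] / 2 - 1)
}

# circular moving average of polygon vertices (window must be odd)
smooth_polygon <- function(poly, window = 5L) {
  n <- nrow(poly)
  if (window <= 1L || n <= window) return(poly)
  half <- window %/% 2L
  idx <- outer(seq_len(n), -half:half, `+`)
  idx <- ((idx - 1L) %% n) + 1L
  out <- poly
  out[, 1] <- rowMeans(matrix(poly[idx, 1], nrow = n))
  out[, 2] <- rowMeans(matrix(poly[idx, 2], nrow = n))
  out
}

polygon_length <- function(poly) {
  n <- nrow(poly)
  if (is.null(poly) || n < 2L) return(0)
  d <- poly - poly[c(2:n, 1L), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# Perimeter of a (hole-filled) binary component mask: smoothed
# marching-squares contour length.
mask_perimeter <- function(mask, smooth_window = 5L) {
  poly <- outer_contour(mask)
  if (is.null(poly)) return(0)
  polygon_length(smooth_polygon(poly, smooth_window))
}
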