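# Independent oracles and fixture builders used across the suite.

# Brute-force grayscale opening: literal double-loop sliding-window erosion
# then dilation over a disc, ignoring out-of-bounds positions. O(n^2 r^2);
# only for small grids.
naive_open <- function(x, r_px) {
  off <- expand.grid(di = -r_px:r_px, dj = -r_px:r_px)
  off <- off[off$di^2 + off$dj^2 <= r_px^2, ]
  nr <- nrow(x); nc <- ncol(x)
  sweep_one <- function(m, fun, init) {
    out <- matrix(init, nr, nc)
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
      acc <- init
      for (k in seq_len(nrow(off))) {
        ii <- a + off$di[k]; jj <- b + off$dj[k]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
          acc <- fun(acc, m[ii, jj])
      }
      out[a, b] <- acc
    }
    out
  }
  sweep_one(sweep_one(x, min, Inf), max, -Inf)
}

# Fast independent opening oracle: EBImage's C dilation plus the grayscale
# duality erode(x) = C - dilate(C - x) with C = max(x). EBImage pads the
# border with 0, so the reflected image must stay non-negative: with this
# offset the pad value C maps to 0 and can never win the min/max, which
# reproduces ignore-outside border handling up to ~1 ulp of C.
ebimage_open <- function(x, r_px) {
  kern <- matrix(0, 2 * r_px + 1, 2 * r_px + 1)
  for (i in -r_px:r_px) for (j in -r_px:r_px)
    if (i * i + j * j <= r_px^2) kern[i + r_px + 1, j + r_px + 1] <- 1
  C <- max(x)
  er <- C - EBImage::dilate(C - x, kern)
  EBImage::dilate(er, kern)
}

# Connected components through igraph (8-connectivity), an implementation
# unrelated to the package's BFS labeller.
igraph_components <- function(mask) {
  idx <- which(mask != 0)
  if (length(idx) == 0) return(list(k = 0L, membership = integer(0), idx = idx))
  nr <- nrow(mask)
  rr <- (idx - 1L) %% nr; cc <- (idx - 1L) %/% nr
  edges <- integer(0)
  for (a in seq_along(idx)) {
    near <- which(abs(rr - rr[a]) <= 1 & abs(cc - cc[a]) <= 1)
    near <- near[near > a]
    if (length(near) > 0) edges <- c(edges, rbind(a, near))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  list(k = comp$no, membership = comp$membership, idx = idx)
}

# Closed-form least-squares slope.
ols_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x * x) - sum(x)^2)
}

# Two overlapping Gaussian blobs whose threshold regions merge into one
# component: amplitude 10, sigma 3 px, centres 8 px apart at a random
# position/orientation, plus mild seeded noise. Returns the image and the
# 0-based generating centres.
make_two_blob <- function(seed, size = 48L, amp = 10, sigma = 3, dist = 8,
                          noise_sd = 0.1) {
  set.seed(seed)
  margin <- 14
  mid_r <- runif(1, margin, size - 1 - margin)
  mid_c <- runif(1, margin, size - 1 - margin)
  ang <- runif(1, 0, pi)
  dr <- dist / 2 * sin(ang); dc <- dist / 2 * cos(ang)
  centers <- rbind(c(mid_r - dr, mid_c - dc), c(mid_r + dr, mid_c + dc))
  rows <- matrix(seq_len(size) - 1, size, size)
  cols <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)
  img <- amp * exp(-((rows - centers[1, 1])^2 + (cols - centers[1, 2])^2) / (2 * sigma^2)) +
    amp * exp(-((rows - centers[2, 1])^2 + (cols - centers[2, 2])^2) / (2 * sigma^2))
  img <- pmax(img + rnorm(size * size, 0, noise_sd), 0)
  list(img = img, centers = centers)
}

# Run the fluorescence pipeline on a raw pixel matrix.
segment_pixels <- function(pixels, params = analysis_params(),
                           pixel_size_um = 2) {
  corrected <- tophat_correct(pixels, params$tophat_radius_um, pixel_size_um)
  labels <- label_connected(
    threshold_mask(corrected, params$threshold_corrected_units))
  labels <- edge_split(labels, corrected, params, pixel_size_um)
  objects <- measure_objects(labels, corrected, pixel_size_um)
  if (params$apply_area_filter_to_fluorescence)
    objects <- area_filter(objects, params$min_object_area_um2)
  list(labels = labels, objects = objects, corrected = corrected)
}

# Frames qualifying for exact-count recovery: every visible spot pairwise
# separated by > 4 sigma and > 4 sigma from the field border.
frame_is_well_separated <- function(truth, t, cfg) {
  vis <- truth[truth$onset_time_min <= t, , drop = FALSE]
  if (nrow(vis) == 0) return(FALSE)
  s4 <- 4 * cfg$spot_sigma_px
  border_ok <- all(vis$row_px > s4 & vis$row_px < cfg$field_px[1] - 1 - s4 &
                     vis$col_px > s4 & vis$col_px < cfg$field_px[2] - 1 - s4)
  if (!border_ok) return(FALSE)
  if (nrow(vis) == 1) return(TRUE)
  d <- as.matrix(dist(cbind(vis$row_px, vis$col_px)))
  diag(d) <- Inf
  all(d > s4)
}

# Layout CSV writer for fixtures.
write_layout_csv <- function(path, rows) {
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
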