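test_that("thresholding is inclusive at the boundary", {
  x <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_equal(threshold_mask(x, 2), matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  expect_equal(sum(threshold_mask(matrix(0, 5, 5), 2)), 0)
  set.seed(41)
  y <- matrix(runif(100, 0, 4), 10, 10)
  expect_equal(sum(threshold_mask(y, 2)), sum(y >= 2))
})

test_that("labeling is 8-connected with contiguous deterministic labels", {
  m <- matrix(0, 5, 5); m[2, 2] <- 1; m[3, 3] <- 1
  lab <- label_connected(m)
  expect_equal(max(lab), 1)           # diagonal touch joins components

  expect_equal(max(label_connected(matrix(FALSE, 6, 6))), 0)

  # five disjoint 2x2 squares
  m5 <- matrix(0, 12, 12)
  anchors <- list(c(1, 1), c(1, 7), c(5, 4), c(9, 1), c(9, 9))
  for (a in anchors) m5[a[1]:(a[1] + 1), a[2]:(a[2] + 1)] <- 1
  lab5 <- label_connected(m5)
  expect_equal(max(lab5), 5)
  expect_equal(sort(unique(as.vector(lab5))), 0:5)
  expect_true(all(tabulate(lab5[lab5 > 0]) == 4))
})

test_that("labeling agrees with an igraph components oracle", {
  set.seed(42)
  for (i in 1:10) {
    m <- matrix(runif(20 * 20) < 0.25, 20, 20)
    lab <- label_connected(m)
    oracle <- igraph_components(m)
    expect_equal(max(lab), oracle$k)
    if (oracle$k > 0) {
      # identical partition of the foreground pixels
      expect_equal(length(unique(paste(lab[oracle$idx], oracle$membership))),
                   oracle$k)
    }
  }
})

test_that("object measurement computes the documented arithmetic", {
  lab <- matrix(0L, 4, 4); lab[2:3, 2:3] <- 1L
  corr <- matrix(3.0, 4, 4)
  obj <- measure_objects(lab, corr, pixel_size_um = 1)
  expect_equal(nrow(obj), 1)
  expect_equal(obj$area_um2, 4)
  expect_equal(obj$integrated_intensity, 12)
  expect_equal(obj$mean_intensity, 3)
  expect_equal(obj$pixel_count, 4L)
  expect_equal(c(obj$centroid_row, obj$centroid_col), c(1.5, 1.5))  # 0-based
  expect_equal(c(obj$bbox_r0, obj$bbox_c0, obj$bbox_r1, obj$bbox_c1),
               c(1, 1, 3, 3))

  expect_equal(nrow(measure_objects(matrix(0L, 3, 3), matrix(1, 3, 3))), 0)
  expect_error(measure_objects(matrix(0L, 3, 3), matrix(1, 4, 4)), "shape")
})

test_that("object invariants hold on a simulated frame", {
  cfg <- sim_config(field_px = c(96, 96), n_cells = 10, seed = 7)
  sim <- simulate_well(cfg, "D05")
  fr <- sim$fluor[[7]]
  corrected <- tophat_correct(fr$pixels, 20, fr$pixel_size_um)
  labels <- label_connected(threshold_mask(corrected, 2))
  obj <- measure_objects(labels, corrected, fr$pixel_size_um)
  expect_gt(nrow(obj), 0)
  expect_equal(obj$area_um2, obj$pixel_count * fr$pixel_size_um^2)
  expect_equal(obj$integrated_intensity, obj$mean_intensity * obj$pixel_count)
  # brute-force per-label masked sums
  for (k in obj$label_id) {
    expect_equal(obj$integrated_intensity[obj$label_id == k],
                 sum(corrected[labels == k]))
  }
})

test_that("area filter keeps the boundary and is idempotent", {
  obj <- tibble::tibble(label_id = 1:3, area_um2 = c(49.9, 50, 120))
  out <- area_filter(obj, 50)
  expect_equal(out$area_um2, c(50, 120))
  expect_equal(area_filter(out, 50), out)                    # idempotent
  shuffled <- obj[c(3, 1, 2), ]
  expect_equal(sort(area_filter(shuffled, 50)$area_um2),
               sort(out$area_um2))                           # order-free
  empty <- obj[0, ]
  expect_equal(nrow(area_filter(empty, 50)), 0)
})

test_that("minimum retained pixel count follows the micron conversion", {
  # at 2 um/px each pixel is 4 um^2: 12 px = 48 um^2 < 50 <= 13 px = 52 um^2
  lab <- matrix(0L, 12, 24)
  lab[2:5, 2:4] <- 1L   # 12 px
  lab[2:5, 10:12] <- 2L; lab[6, 10] <- 2L  # 13 px
  obj <- area_filter(measure_objects(lab, matrix(5, 12, 24), 2), 50)
  expect_equal(obj$label_id, 2L)
  expect_equal(obj$pixel_count, 13L)
})

test_that("edge split separates two merged blobs along the valley", {
  tb <- make_two_blob(101)
  res <- segment_pixels(tb$img)
  expect_equal(nrow(res$objects), 2)
  # each child contains its generating centre
  for (i in 1:2) {
    ridx <- round(tb$centers[i, 1]) + 1
    cidx <- round(tb$centers[i, 2]) + 1
    expect_true(res$labels[ridx, cidx] > 0)
  }
  expect_equal(length(unique(res$labels[
    cbind(round(tb$centers[, 1]) + 1, round(tb$centers[, 2]) + 1)])), 2)
})

test_that("edge split is the identity when disabled or with one seed", {
  tb <- make_two_blob(102)
  p_off <- analysis_params(edge_split = FALSE)
  res_off <- segment_pixels(tb$img, p_off)
  expect_equal(nrow(res_off$objects), 1)

  corrected <- tophat_correct(tb$img, 20, 2)
  labels <- label_connected(threshold_mask(corrected, 2))
  expect_identical(edge_split(labels, corrected, p_off, 2), labels)

  # a single blob stays single with the splitter on
  single <- make_two_blob(103, dist = 0)
  res1 <- segment_pixels(single$img)
  expect_equal(nrow(res1$objects), 1)
})

test_that("edge split preserves foreground pixels and never merges", {
  set.seed(44)
  for (s in 1:5) {
    tb <- make_two_blob(200 + s)
    corrected <- tophat_correct(tb$img, 20, 2)
    labels <- label_connected(threshold_mask(corrected, 2))
    split <- edge_split(labels, corrected, analysis_params(), 2)
    expect_equal(split > 0, labels > 0)                 # same foreground
    expect_gte(max(split), max(labels))                 # count only grows
    # children never span two parents
    for (k in seq_len(max(split))) {
      parents <- unique(labels[split == k])
      expect_equal(length(parents), 1)
    }
  }
})

test_that("the full chain is deterministic", {
  tb <- make_two_blob(105)
  r1 <- segment_pixels(tb$img)
  r2 <- segment_pixels(tb$img)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$objects, r2$objects)
})

test_that("well-separated simulated spots are counted exactly", {
  found <- 0
  for (seed in 1:12) {
    cfg <- sim_config(field_px = c(96, 96), n_cells = 4, seed = seed,
                      base_rate_per_cell_per_min = 0.02,
                      max_events_per_cell = 2)
    sim <- simulate_well(cfg, "E03")
    t_end <- cfg$duration_min
    if (!frame_is_well_separated(sim$truth, t_end, cfg)) next
    found <- found + 1
    res <- segment_pixels(sim$fluor[[length(sim$fluor)]]$pixels)
    expect_equal(nrow(res$objects), visible_events(sim$truth, t_end))
  }
  expect_gt(found, 3)  # the scenario actually exercises the assertion
})
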