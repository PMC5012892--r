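#' Threshold a corrected image into a foreground mask
#'
#' A pixel is foreground iff its corrected intensity is greater than or equal
#' to the threshold (inclusive boundary).
#'
#' @param corrected Background-corrected intensity matrix
#'   (see [tophat_correct()]).
#' @param threshold Threshold in corrected intensity units (default 2).
#' @return Logical matrix of the same shape.
#' @export
threshold_mask <- function(corrected, threshold = 2) {
  stopifnot(is.matrix(corrected), threshold > 0)
  corrected >= threshold
}

#' Label connected foreground components
#'
#' 8-connected component labeling: diagonally touching pixels belong to the
#' same object. Labels form the contiguous set `{0..K}` (0 = background) and
#' are assigned in order of each component's first pixel in R's column-major
#' scan, so the labeling is fully deterministic.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @return Integer matrix of labels, same shape as `mask`.
#' @export
label_connected <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask != 0)
  if (length(fg) == 0) return(lab)
  queue <- integer(length(fg))
  cur <- 0L
  for (p in fg) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    lab[p] <- cur
    queue[1L] <- p; qh <- 1L; qt <- 1L
    while (qh <= qt) {
      q <- queue[qh]; qh <- qh + 1L
      r0 <- ((q - 1L) %% nr) + 1L
      c0 <- ((q - 1L) %/% nr) + 1L
      for (di in -1L:1L) {
        rr <- r0 + di
        if (rr < 1L || rr > nr) next
        for (dj in -1L:1L) {
          cc <- c0 + dj
          if (cc < 1L || cc > nc) next
          q2 <- (cc - 1L) * nr + rr
          if (mask[q2] != 0 && lab[q2] == 0L) {
            lab[q2] <- cur
            qt <- qt + 1L
            queue[qt] <- q2
          }
        }
      }
    }
  }
  lab
}

# Local maxima of sm restricted to one labeled region, thinned so accepted
# seeds are at least min_sep pixels apart (greedy, brightest first; ties
# break on column-major index).
region_seeds <- function(sm, labels, k, idx, min_sep) {
  nr <- nrow(labels); nc <- ncol(labels)
  ismax <- logical(length(idx))
  for (t in seq_along(idx)) {
    p <- idx[t]
    r0 <- ((p - 1L) %% nr) + 1L
    c0 <- ((p - 1L) %/% nr) + 1L
    ok <- TRUE
    for (di in -1L:1L) {
      rr <- r0 + di
      if (rr < 1L || rr > nr) next
      for (dj in -1L:1L) {
        cc <- c0 + dj
        if (cc < 1L || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (labels[q] == k && sm[q] > sm[p]) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    ismax[t] <- ok
  }
  cand <- idx[ismax]
  cand <- cand[order(-sm[cand], cand)]
  sel_r <- numeric(0); sel_c <- numeric(0); sel <- integer(0)
  for (p in cand) {
    r0 <- ((p - 1L) %% nr) + 1L
    c0 <- ((p - 1L) %/% nr) + 1L
    if (length(sel) == 0L ||
        all((r0 - sel_r)^2 + (c0 - sel_c)^2 >= min_sep^2)) {
      sel <- c(sel, p); sel_r <- c(sel_r, r0); sel_c <- c(sel_c, c0)
    }
  }
  sel
}

# Marker-controlled watershed inside one region: pixels are claimed in order
# of decreasing smoothed intensity, each taking the label of its brightest
# already-claimed 8-neighbour within the region (ties: smallest label).
# Repeated sweeps guarantee every pixel of the connected region is claimed.
watershed_region <- function(sm, labels, k, idx, seeds) {
  nr <- nrow(labels)
  child <- integer(length(idx))
  names(child) <- NULL
  pos <- match(seeds, idx)
  child[pos] <- seq_along(seeds)
  ord <- order(-sm[idx], idx)
  lookup <- new.env(hash = TRUE, size = length(idx))
  for (t in seq_along(idx)) assign(as.character(idx[t]), t, envir = lookup)
  repeat {
    changed <- FALSE
    for (t in ord) {
      if (child[t] != 0L) next
      p <- idx[t]
      r0 <- ((p - 1L) %% nr) + 1L
      c0 <- ((p - 1L) %/% nr) + 1L
      best_lab <- 0L; best_val <- -Inf
      for (di in -1L:1L) {
        rr <- r0 + di
        if (rr < 1L || rr > nr) next
        for (dj in -1L:1L) {
          cc <- c0 + dj
          if (cc < 1L || cc > ncol(labels)) next
          q <- (cc - 1L) * nr + rr
          if (labels[q] != k) next
          tq <- get(as.character(q), envir = lookup)
          lq <- child[tq]
          if (lq != 0L && (sm[q] > best_val ||
                           (sm[q] == best_val && lq < best_lab))) {
            best_val <- sm[q]; best_lab <- lq
          }
        }
      }
      if (best_lab != 0L) { child[t] <- best_lab; changed <- TRUE }
    }
    if (all(child != 0L) || !changed) break
  }
  # a region is connected, so this only triggers on pathological ties
  child[child == 0L] <- 1L
  child
}

#' Split merged regions into closely spaced objects
#'
#' Declumping of thresholded regions that contain several fluorescent
#' objects. Within each labeled region, seeds are the local maxima of the
#' Gaussian-smoothed corrected image (sigma `params$smoothing_sigma_px`)
#' thinned to a minimum mutual distance equal to the equivalent diameter of
#' `params$min_object_area_um2`; regions holding two or more seeds are
#' re-partitioned by marker-controlled watershed on the smoothed intensity
#' (flooding downhill from each seed), so the union of the child labels is
#' exactly the parent region. Regions with at most one seed, and all regions
#' when `params$edge_split` is `FALSE`, pass through unchanged.
#'
#' @param labels Integer label matrix from [label_connected()].
#' @param corrected Corrected intensity matrix of the same frame.
#' @param params An [analysis_params()] object.
#' @param pixel_size_um Micrometres per pixel edge.
#' @return A relabeled integer matrix; labels remain contiguous `{0..K'}`
#'   with `K' >= K`.
#' @export
edge_split <- function(labels, corrected, params = analysis_params(),
                       pixel_size_um = 2) {
  stopifnot(is.matrix(labels), all(dim(labels) == dim(corrected)))
  if (!params$edge_split) return(labels)
  K <- max(labels)
  if (K == 0L) return(labels)
  sm <- gaussian_smooth(corrected, params$smoothing_sigma_px)
  min_sep <- 2 * sqrt(params$min_object_area_um2 / pi) / pixel_size_um
  out <- matrix(0L, nrow(labels), ncol(labels))
  next_lab <- 0L
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    seeds <- region_seeds(sm, labels, k, idx, min_sep)
    if (length(seeds) <= 1L) {
      next_lab <- next_lab + 1L
      out[idx] <- next_lab
    } else {
      child <- watershed_region(sm, labels, k, idx, seeds)
      out[idx] <- next_lab + child
      next_lab <- next_lab + max(child)
    }
  }
  out
}

#' Measure labeled objects
#'
#' One record per nonzero label. Pixel coordinates are 0-based `(row, col)`;
#' areas convert pixel counts to square micrometres via `pixel_size_um^2`;
#' the bounding box is half-open `[r0, r1) x [c0, c1)`.
#'
#' @param labels Integer label matrix.
#' @param corrected Corrected intensity matrix (same shape).
#' @param pixel_size_um Micrometres per pixel edge.
#' @return A tibble sorted by `label_id` with columns `label_id`,
#'   `centroid_row`, `centroid_col`, `pixel_count`, `area_um2`,
#'   `integrated_intensity`, `mean_intensity`, `bbox_r0`, `bbox_c0`,
#'   `bbox_r1`, `bbox_c1`.
#' @export
measure_objects <- function(labels, corrected, pixel_size_um = 2) {
  if (!all(dim(labels) == dim(corrected)))
    stop("labels and corrected image differ in shape")
  stopifnot(pixel_size_um > 0)
  idx <- which(labels > 0L)
  if (length(idx) == 0L) {
    return(tibble::tibble(
      label_id = integer(), centroid_row = numeric(), centroid_col = numeric(),
      pixel_count = integer(), area_um2 = numeric(),
      integrated_intensity = numeric(), mean_intensity = numeric(),
      bbox_r0 = integer(), bbox_c0 = integer(),
      bbox_r1 = integer(), bbox_c1 = integer()))
  }
  nr <- nrow(labels)
  tibble::tibble(
    label_id = labels[idx],
    row0 = (idx - 1L) %% nr,          # 0-based coordinates
    col0 = (idx - 1L) %/% nr,
    val = corrected[idx]) |>
    dplyr::group_by(.data$label_id) |>
    dplyr::summarise(
      centroid_row = mean(.data$row0),
      centroid_col = mean(.data$col0),
      pixel_count = dplyr::n(),
      integrated_intensity = sum(.data$val),
      mean_intensity = mean(.data$val),
      bbox_r0 = min(.data$row0), bbox_c0 = min(.data$col0),
      bbox_r1 = max(.data$row0) + 1L, bbox_c1 = max(.data$col0) + 1L,
      .groups = "drop") |>
    dplyr::mutate(area_um2 = .data$pixel_count * pixel_size_um^2) |>
    dplyr::select("label_id", "centroid_row", "centroid_col", "pixel_count",
                  "area_um2", "integrated_intensity", "mean_intensity",
                  "bbox_r0", "bbox_c0", "bbox_r1", "bbox_c1") |>
    dplyr::arrange(.data$label_id)
}

#' Remove objects below a minimum area
#'
#' "Below" is strict: an object of exactly `min_area_um2` is retained.
#'
#' @param objects Object tibble from [measure_objects()].
#' @param min_area_um2 Area cutoff in square micrometres (default 50).
#' @return Filtered object tibble.
#' @export
area_filter <- function(objects, min_area_um2 = 50) {
  stopifnot(min_area_um2 >= 0)
  dplyr::filter(objects, .data$area_um2 >= min_area_um2)
}

# Windowed sums via an integral image; windows are clipped at the border and
# the per-pixel in-bounds count is returned alongside.
box_sums <- function(x, h) {
  nr <- nrow(x); nc <- ncol(x)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- apply(apply(x, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  sums <- S[r2 + 1L, c2 + 1L] - S[r1, c2 + 1L] - S[r2 + 1L, c1] + S[r1, c1]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  list(sum = sums, n = counts)
}

#' Phase-contrast confluence mask
#'
#' Segments cell-covered area in a phase-contrast frame from its local
#' texture: the local intensity variance in a square window (half-width
#' half the top-hat pixel radius) is thresholded by Otsu's method, the
#' threshold floored at four times the 5th-percentile variance so a
#' texture-free noise field yields an empty mask, the mask is
#' morphologically closed (disk 2 px), eroded to undo the spatial spread of
#' the variance response, and components below `min_object_area_um2` are
#' dropped. Feeds confluence reporting only, never the fluorescence metrics.
#'
#' @param phase Phase-channel intensity matrix.
#' @param params An [analysis_params()] object.
#' @param pixel_size_um Micrometres per pixel edge.
#' @return A list with `mask` (logical matrix) and `confluence`
#'   (foreground fraction in `[0, 1]`).
#' @export
confluence_mask <- function(phase, params = analysis_params(),
                            pixel_size_um = 2) {
  stopifnot(is.matrix(phase))
  r_px <- max(1L, round(params$tophat_radius_um / pixel_size_um))
  h <- max(1L, ceiling(r_px / 2))
  bs <- box_sums(phase, h)
  m1 <- bs$sum / bs$n
  v <- pmax(box_sums(phase^2, h)$sum / bs$n - m1^2, 0)
  if (max(v) <= 0) {
    warning("constant phase image: degenerate confluence threshold, returning 0")
    return(list(mask = matrix(FALSE, nrow(phase), ncol(phase)), confluence = 0))
  }
  # floor at 4x the low-quantile variance: a texture-free noise field has a
  # tightly concentrated variance map (max/q05 ~ 2), so Otsu alone — which
  # always splits a unimodal histogram — would hallucinate confluence there
  thr <- max(EBImage::otsu(v, range = c(0, max(v))),
             4 * stats::quantile(v, 0.05, names = FALSE))
  mask <- v >= thr
  mask <- erode_disc(dilate_disc(mask * 1, 2L), 2L) >= 1   # closing
  # the variance response extends ~h px beyond the texture edge, but Otsu
  # already cuts ~2 px into that soft shoulder: erode by the remainder
  er <- max(0L, h - 2L)
  if (er > 0L) mask <- erode_disc(mask, er) >= 1
  lab <- label_connected(mask)
  if (max(lab) > 0L) {
    counts <- tabulate(lab[lab > 0L])
    keep <- which(counts * pixel_size_um^2 >= params$min_object_area_um2)
    mask <- matrix(lab %in% keep & lab > 0L, nrow(phase), ncol(phase))
  }
  list(mask = mask, confluence = mean(mask))
}

#' Run the full per-frame pipeline
#'
#' Fluorescence frames go through top-hat correction, inclusive
#' thresholding, 8-connected labeling, edge-split declumping, measurement
#' and the area filter; phase frames go through the confluence mask.
#'
#' @param frame A [phago_frame()].
#' @param params An [analysis_params()] object.
#' @return For fluorescence frames, a list with `objects` (measured object
#'   tibble, frame metadata prepended) and `metrics` (one-row tibble:
#'   `well_id`, `image_index`, `time_min`, `channel`, `object_count`,
#'   `total_area_um2`, `total_integrated_intensity`). For phase frames, a
#'   list with `confluence` and `metrics` (one-row tibble with
#'   `confluence_fraction`).
#' @export
analyze_frame <- function(frame, params = analysis_params()) {
  stopifnot(inherits(frame, "phago_frame"))
  if (frame$channel == "phase") {
    cm <- confluence_mask(frame$pixels, params, frame$pixel_size_um)
    return(list(
      confluence = cm,
      metrics = tibble::tibble(
        well_id = frame$well_id, image_index = frame$image_index,
        time_min = frame$time_min, channel = frame$channel,
        confluence_fraction = cm$confluence)))
  }
  corrected <- tophat_correct(frame$pixels, params$tophat_radius_um,
                              frame$pixel_size_um)
  labels <- label_connected(
    threshold_mask(corrected, params$threshold_corrected_units))
  labels <- edge_split(labels, corrected, params, frame$pixel_size_um)
  objects <- measure_objects(labels, corrected, frame$pixel_size_um)
  if (params$apply_area_filter_to_fluorescence)
    objects <- area_filter(objects, params$min_object_area_um2)
  objects <- dplyr::mutate(
    objects,
    well_id = frame$well_id, image_index = frame$image_index,
    time_min = frame$time_min, channel = frame$channel,
    .before = 1L)
  list(
    objects = objects,
    metrics = tibble::tibble(
      well_id = frame$well_id, image_index = frame$image_index,
      time_min = frame$time_min, channel = frame$channel,
      object_count = nrow(objects),
      total_area_um2 = sum(objects$area_um2),
      total_integrated_intensity = sum(objects$integrated_intensity)))
}
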