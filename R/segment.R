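#' Global median intensity threshold
#'
#' The median intensity over the full frames x height x width sample of the
#' movie. Pixels whose temporal-mean intensity falls below this value are
#' typically image background and are discarded by [active_pixel_mask()].
#'
#' @param movie a [movie_stack()].
#' @return Scalar intensity threshold.
#' @export
global_median_threshold <- function(movie) {
  stopifnot(inherits(movie, "movie_stack"))
  stats::median(movie$data)
}

#' Active-pixel mask
#'
#' Retains pixels whose temporal-mean intensity is at or above the
#' threshold (ties are kept).
#'
#' @param movie a [movie_stack()].
#' @param threshold intensity threshold, by default from
#'   [global_median_threshold()].
#' @return Logical matrix (height x width), `TRUE` for retained pixels.
#' @export
active_pixel_mask <- function(movie, threshold = global_median_threshold(movie)) {
  stopifnot(inherits(movie, "movie_stack"))
  mean_img <- apply(movie$data, c(2, 3), mean)
  mask <- mean_img >= threshold
  if (!any(mask)) stop_ft("no pixels above threshold")
  mask
}

# Per-pixel time-series matrix (pixels x frames) for masked pixels,
# together with their (row, col) coordinates.
pixel_series <- function(movie, mask) {
  idx <- which(mask, arr.ind = TRUE)
  nf <- n_frames(movie)
  m <- matrix(0, nrow(idx), nf)
  for (t in seq_len(nf)) {
    fr <- movie$data[t, , ]
    m[, t] <- fr[idx]
  }
  list(series = m, coords = idx)
}

#' K-means clustering of pixel activity
#'
#' Clusters the z-scored per-pixel time series of the masked pixels into
#' `k` groups (10 restarts, best inertia, seeded) and retains the members
#' of the largest cluster — in practice the pixels within active neurons.
#' Cluster-size ties go to the lowest cluster index. Pixels with zero
#' temporal variance get an all-zero feature vector. If the masked pixels
#' contain fewer distinct feature vectors than `k`, the cluster count is
#' reduced to the number of distinct vectors.
#'
#' @param movie a [movie_stack()].
#' @param mask logical matrix from [active_pixel_mask()].
#' @param k number of clusters (default 3).
#' @param seed integer seed; the result is deterministic given the seed and
#'   invariant to pixel order.
#' @param nstart number of k-means restarts (default 10).
#' @return Logical matrix like `mask`, `TRUE` for the retained cluster.
#' @export
kmeans_activity_cluster <- function(movie, mask, k = 3, seed = 1, nstart = 10) {
  stopifnot(inherits(movie, "movie_stack"))
  px <- pixel_series(movie, mask)
  n <- nrow(px$series)
  if (n < k) stop_ft("mask has ", n, " pixels, fewer than k = ", k)
  sds <- apply(px$series, 1, stats::sd)
  feat <- px$series
  nzv <- sds > 0
  feat[nzv, ] <- (feat[nzv, , drop = FALSE] -
                    rowMeans(feat[nzv, , drop = FALSE])) / sds[nzv]
  feat[!nzv, ] <- 0
  # order-invariant: cluster distinct feature rows, map members back
  key <- apply(round(feat, 12), 1, paste, collapse = ",")
  ukey <- sort(unique(key))
  k_eff <- min(k, length(ukey))
  if (k_eff < 2L) {
    cl <- rep(1L, n)
  } else {
    ufeat <- feat[match(ukey, key), , drop = FALSE]
    km <- with_seed(seed,
      stats::kmeans(ufeat, centers = k_eff, nstart = nstart, iter.max = 100))
    # relabel clusters canonically (by first occurrence in sorted key order)
    cl <- km$cluster[match(key, ukey)]
    cl <- as.integer(factor(cl, levels = unique(km$cluster)))
  }
  sizes <- tabulate(cl)
  winner <- which(sizes == max(sizes))[1]  # tie -> lowest index
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[px$coords[cl == winner, , drop = FALSE]] <- TRUE
  out
}

# Gaussian blur of a matrix (separable kernel, reflective borders).
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  kx <- stats::dnorm(-half:half, sd = sigma)
  kx <- kx / sum(kx)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(half)]), v, rev(v[(n - half + 1):n]))
    stats::filter(vp, kx, sides = 2)[(half + 1):(half + n)]
  }
  tmp <- apply(img, 2, pad_conv)
  t(apply(tmp, 1, pad_conv))
}

# Local maxima of img within mask with a minimum separation (greedy
# suppression, highest first; deterministic tie-break by index).
local_maxima <- function(img, mask, min_sep = 3) {
  d <- dim(img)
  cand <- which(mask, arr.ind = TRUE)
  is_max <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rr <- max(1, r - 1):min(d[1], r + 1)
    cc <- max(1, c - 1):min(d[2], c + 1)
    is_max[i] <- img[r, c] >= max(img[rr, cc])
  }
  pk <- cand[is_max, , drop = FALSE]
  if (nrow(pk) == 0) return(pk)
  o <- order(-img[pk], pk[, 1], pk[, 2])
  pk <- pk[o, , drop = FALSE]
  keep <- logical(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kept <- pk[keep, , drop = FALSE]
    d2 <- (kept[, 1] - pk[i, 1])^2 + (kept[, 2] - pk[i, 2])^2
    keep[i] <- all(d2 >= min_sep^2)
  }
  pk[keep, , drop = FALSE]
}

#' Watershed split of the retained pixel set into terminal ROIs
#'
#' Splits the retained active-pixel set into ROIs corresponding to
#' individual axon terminals. The watershed surface is the
#' Gaussian-smoothed temporal-mean image restricted to the retained set;
#' seeds are its local maxima with a minimum separation of 3 px, and
#' basins are grown with a geodesic propagation. ROIs smaller than
#' `min_roi_px` are removed.
#'
#' @param retained logical matrix from [kmeans_activity_cluster()].
#' @param movie a [movie_stack()].
#' @param min_roi_px minimum ROI size in pixels (default 4).
#' @param sigma_smooth Gaussian smoothing sigma in px (default 1).
#' @param min_sep_px minimum seed separation in px (default 3).
#' @return A `roi_set`: list with `labels` (integer matrix, 0 = background),
#'   `roi_ids`, `n_pixels`, and `centroids` (data frame: roi_id, row, col).
#' @export
watershed_split <- function(retained, movie, min_roi_px = 4,
                            sigma_smooth = 1, min_sep_px = 3) {
  stopifnot(inherits(movie, "movie_stack"))
  if (!any(retained)) stop_ft("retained pixel set is empty")
  mean_img <- apply(movie$data, c(2, 3), mean)
  surf <- gauss_blur(mean_img, sigma_smooth)
  pk <- local_maxima(surf, retained, min_sep = min_sep_px)
  if (nrow(pk) == 0) pk <- which(surf == max(surf[retained]) & retained,
                                 arr.ind = TRUE)[1, , drop = FALSE]
  seeds <- matrix(0L, nrow(retained), ncol(retained))
  seeds[pk] <- seq_len(nrow(pk))
  labels <- EBImage::imageData(EBImage::propagate(
    x = surf, seeds = seeds, mask = retained))
  labels <- matrix(as.integer(labels), nrow(retained), ncol(retained))
  labels[!retained] <- 0L
  sizes <- tabulate(labels[labels > 0])
  drop <- which(sizes < min_roi_px)
  if (length(drop)) labels[labels %in% drop] <- 0L
  keep <- sort(unique(labels[labels > 0]))
  if (length(keep) == 0) stop_ft("no ROIs survive size filter")
  relab <- labels
  for (i in seq_along(keep)) relab[labels == keep[i]] <- i
  ids <- seq_along(keep)
  cent <- t(vapply(ids, function(i) {
    xy <- which(relab == i, arr.ind = TRUE)
    c(mean(xy[, 1]), mean(xy[, 2]))
  }, numeric(2)))
  structure(list(labels = relab, roi_ids = ids,
                 n_pixels = tabulate(relab[relab > 0]),
                 centroids = data.frame(roi_id = ids, row = cent[, 1],
                                        col = cent[, 2])),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs, %d px total\n",
              length(x$roi_ids), sum(x$n_pixels)))
  invisible(x)
}

#' Raw fluorescence trace container
#'
#' @param values mean ROI fluorescence per frame (arbitrary units).
#' @param frame_rate_hz frames per second.
#' @param subject_id,group,roi_id optional metadata labels.
#' @param t0_s acquisition start time (seconds).
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(values, frame_rate_hz, subject_id = NA_character_,
                      group = NA_character_, roi_id = NA_integer_, t0_s = 0) {
  if (!all(is.finite(values))) stop_ft("trace values must be finite")
  structure(list(values = as.numeric(values),
                 frame_rate_hz = frame_rate_hz, t0_s = t0_s,
                 subject_id = subject_id, group = group, roi_id = roi_id),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %d frames @ %.3g fps (subject %s, roi %s)\n",
              length(x$values), x$frame_rate_hz,
              as.character(x$subject_id), as.character(x$roi_id)))
  invisible(x)
}

#' Extract per-ROI traces
#'
#' The mean intensity within each ROI for each frame, as one
#' [raw_trace()] per ROI.
#'
#' @param movie a [movie_stack()].
#' @param rois a `roi_set` from [watershed_split()].
#' @param subject_id,group metadata propagated onto each trace.
#' @return A list of [raw_trace()] objects, one per ROI.
#' @export
extract_traces <- function(movie, rois, subject_id = NA_character_,
                           group = NA_character_) {
  stopifnot(inherits(movie, "movie_stack"), inherits(rois, "roi_set"))
  if (!identical(dim(rois$labels), dim(movie$data)[2:3]))
    stop_ft("ROI label image does not match movie dimensions")
  lapply(rois$roi_ids, function(id) {
    idx <- which(rois$labels == id, arr.ind = TRUE)
    vals <- vapply(seq_len(n_frames(movie)), function(t) {
      fr <- movie$data[t, , ]
      mean(fr[idx])
    }, numeric(1))
    raw_trace(vals, movie$frame_rate_hz, subject_id = subject_id,
              group = group, roi_id = id, t0_s = movie$t0_s)
  })
}

#' Pooled single-ROI trace
#'
#' Treats the whole retained pixel set as one ROI (bath-application mode)
#' and returns its mean-intensity time series. Equals the
#' pixel-count-weighted mean of [extract_traces()] over any partition of
#' the same pixel set.
#'
#' @param movie a [movie_stack()].
#' @param retained logical pixel mask.
#' @param subject_id,group metadata labels.
#' @return A single [raw_trace()].
#' @export
pooled_trace <- function(movie, retained, subject_id = NA_character_,
                         group = NA_character_) {
  stopifnot(inherits(movie, "movie_stack"))
  if (!any(retained)) stop_ft("retained pixel set is empty")
  idx <- which(retained, arr.ind = TRUE)
  vals <- vapply(seq_len(n_frames(movie)), function(t) {
    fr <- movie$data[t, , ]
    mean(fr[idx])
  }, numeric(1))
  raw_trace(vals, movie$frame_rate_hz, subject_id = subject_id,
            group = group, roi_id = 1L, t0_s = movie$t0_s)
}

#' Segment a movie into terminal ROIs
#'
#' Convenience wrapper running the full discovery chain:
#' global-median threshold, active-pixel mask, k-means activity clustering
#' and (optionally) the watershed split.
#'
#' @param movie a [movie_stack()].
#' @param k,seed,min_roi_px see the individual stages.
#' @param split logical: split into per-terminal ROIs (`TRUE`, visual mode)
#'   or keep one pooled ROI (`FALSE`, bath mode).
#' @return For `split = TRUE` a `roi_set`; otherwise the retained logical
#'   mask.
#' @export
segment_movie <- function(movie, k = 3, seed = 1, min_roi_px = 4,
                          split = TRUE) {
  thr <- global_median_threshold(movie)
  mask <- active_pixel_mask(movie, thr)
  retained <- kmeans_activity_cluster(movie, mask, k = k, seed = seed)
  if (split) watershed_split(retained, movie, min_roi_px = min_roi_px)
  else retained
}
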