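#' Movie stack container
#'
#' A `movie_stack` holds a single-channel fluorescence movie as a numeric
#' array of dimension frames x height x width, together with its frame rate
#' and acquisition start time on the experiment clock.
#'
#' @param data numeric array, frames x height x width; finite, non-negative.
#' @param frame_rate_hz frames per second (> 0).
#' @param t0_s acquisition start time in seconds (default 0).
#'
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(data, frame_rate_hz, t0_s = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_ft("movie data must be a 3-d array (frames x height x width)")
  if (dim(data)[1] < 2L)
    stop_ft("a movie must contain at least 2 frames")
  if (!all(is.finite(data)) || any(data < 0))
    stop_ft("movie intensities must be finite and non-negative")
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      !is.finite(frame_rate_hz) || frame_rate_hz <= 0)
    stop_ft("frame_rate_hz must be a single positive number")
  structure(
    list(data = data, frame_rate_hz = as.numeric(frame_rate_hz),
         t0_s = as.numeric(t0_s)),
    class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> %d frames, %d x %d px, %.3g fps, %.1f s\n",
              d[1], d[2], d[3], x$frame_rate_hz, d[1] / x$frame_rate_hz))
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

n_frames <- function(movie) dim(movie$data)[1]

#' Read a movie stack from a multi-page TIFF
#'
#' The frame rate is taken from the `frame_rate_hz` argument when given,
#' otherwise from a YAML sidecar file `<path>.yaml` with key
#' `frame_rate_hz` (written by [write_movie()]).
#'
#' @param path path to a single-channel multi-page TIFF.
#' @param frame_rate_hz frames per second; overrides any sidecar metadata.
#' @return A [movie_stack()].
#' @export
read_movie <- function(path, frame_rate_hz = NULL) {
  if (!file.exists(path)) stop_ft("cannot read movie: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop_ft("movie TIFF must contain at least 2 frames, found ", length(pages))
  if (length(dim(pages[[1]])) > 2L)
    stop_ft("multi-channel TIFF input is not supported (single channel required)")
  meta <- list()
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) meta <- yaml::read_yaml(sidecar)
  t0_s <- if (!is.null(meta$t0_s)) meta$t0_s else 0
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  if (is.null(frame_rate_hz)) frame_rate_hz <- meta$frame_rate_hz
  if (is.null(frame_rate_hz))
    stop_ft("frame rate missing: supply frame_rate_hz or a '", basename(sidecar),
            "' sidecar with key 'frame_rate_hz'")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop_ft("invalid frame_rate_hz metadata: must be a positive number")
  d <- dim(pages[[1]])
  data <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), d))
      stop_ft("all frames must share dimensions")
    data[i, , ] <- pages[[i]] * scale
  }
  movie_stack(data, frame_rate_hz = frame_rate_hz, t0_s = t0_s)
}

#' Write a movie stack to a multi-page TIFF
#'
#' Intensities are stored as 32-bit floats scaled into [0, 1]; the scale
#' factor, frame rate and start time go into a YAML sidecar `<path>.yaml`
#' so that [read_movie()] round-trips the stack.
#'
#' @param movie a [movie_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  mx <- max(movie$data)
  scale <- if (mx > 0) 2^ceiling(log2(mx)) else 1
  pages <- lapply(seq_len(n_frames(movie)),
                  function(i) movie$data[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  yaml::write_yaml(list(frame_rate_hz = movie$frame_rate_hz,
                        t0_s = movie$t0_s,
                        intensity_scale = scale),
                   paste0(path, ".yaml"))
  invisible(path)
}

# Phase-correlation displacement (dy, dx) of `frame` relative to `ref`,
# with parabolic sub-pixel refinement of the correlation peak.
phase_correlate <- function(ref, frame, subpixel = TRUE) {
  F1 <- stats::fft(ref)
  F2 <- stats::fft(frame)
  R <- F1 * Conj(F2)
  mag <- Mod(R)
  # regularized whitening: frequencies with negligible energy carry no
  # shift information on smooth microscopy images and must not dominate
  r <- Re(stats::fft(R / (mag + 1e-2 * max(mag)), inverse = TRUE))
  d <- dim(r)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  # wrap indices to signed shifts
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  dy <- wrap(pk[1], d[1]); dx <- wrap(pk[2], d[2])
  if (subpixel) {
    parab <- function(m1, m0, p1) {
      den <- m1 - 2 * m0 + p1
      if (abs(den) < .Machine$double.eps) 0 else 0.5 * (m1 - p1) / den
    }
    iy <- pk[1]; ix <- pk[2]
    ym <- r[(iy - 2) %% d[1] + 1, ix]; yp <- r[iy %% d[1] + 1, ix]
    xm <- r[iy, (ix - 2) %% d[2] + 1]; xp <- r[iy, ix %% d[2] + 1]
    dy <- dy + parab(ym, r[iy, ix], yp)
    dx <- dx + parab(xm, r[iy, ix], xp)
  }
  c(dy = dy, dx = dx)
}

# Translate a frame by (dy, dx) (content moves by +dy rows, +dx cols),
# bilinear interpolation for fractional shifts, median fill outside.
shift_frame <- function(frame, dy, dx, fill = stats::median(frame)) {
  d <- dim(frame)
  if (dy == 0 && dx == 0) return(frame)
  # sample source coordinates
  rows <- seq_len(d[1]) - dy
  cols <- seq_len(d[2]) - dx
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  idx <- function(i, n) {
    out <- i; out[i < 1 | i > n] <- NA_integer_; out
  }
  r0i <- idx(r0, d[1]); r1i <- idx(r0 + 1, d[1])
  c0i <- idx(c0, d[2]); c1i <- idx(c0 + 1, d[2])
  get <- function(ri, ci) {
    m <- matrix(fill, d[1], d[2])
    ok_r <- !is.na(ri); ok_c <- !is.na(ci)
    if (any(ok_r) && any(ok_c))
      m[ok_r, ok_c] <- frame[ri[ok_r], ci[ok_c], drop = FALSE]
    m
  }
  if (all(fr == 0) && all(fc == 0)) return(get(r0i, c0i))
  wr <- matrix(fr, d[1], d[2]); wc <- matrix(fc, d[1], d[2], byrow = TRUE)
  get(r0i, c0i) * (1 - wr) * (1 - wc) + get(r1i, c0i) * wr * (1 - wc) +
    get(r0i, c1i) * (1 - wr) * wc + get(r1i, c1i) * wr * wc
}

#' Rigid in-plane motion correction
#'
#' Corrects in-plane brain movement by phase-correlation rigid translation
#' of every frame against a reference image (default: the temporal mean).
#' Shifts are estimated to sub-pixel precision by parabolic interpolation of
#' the correlation peak and applied by bilinear interpolation
#' (`subpixel = FALSE` rounds to integer pixels). Pixels shifted in from
#' outside the frame are filled with the frame median so the global-median
#' threshold downstream is not biased.
#'
#' @param movie a [movie_stack()].
#' @param reference frame index used as registration target, or `"mean"`
#'   (default) for the temporal-mean image.
#' @param subpixel logical; apply fractional shifts (default `TRUE`).
#' @param max_shift_px largest plausible displacement; estimated shifts
#'   beyond this are treated as degenerate correlations and set to zero.
#' @return A list with elements `movie` (registered [movie_stack()]) and
#'   `shifts` (data frame: frame, dy, dx — the applied shifts).
#' @export
register_rigid <- function(movie, reference = "mean", subpixel = TRUE,
                           max_shift_px = Inf) {
  stopifnot(inherits(movie, "movie_stack"))
  nf <- n_frames(movie)
  ref <- if (identical(reference, "mean")) {
    apply(movie$data, c(2, 3), mean)
  } else {
    stopifnot(is.numeric(reference), reference >= 1, reference <= nf)
    movie$data[reference, , ]
  }
  out <- movie$data
  dy <- numeric(nf); dx <- numeric(nf)
  for (i in seq_len(nf)) {
    s <- phase_correlate(ref, movie$data[i, , ], subpixel = subpixel)
    if (!all(is.finite(s)) || any(abs(s) > max_shift_px)) s <- c(0, 0)
    s[abs(s) < 1e-6] <- 0
    if (!subpixel) s <- round(s)
    dy[i] <- s[1]; dx[i] <- s[2]
    if (dy[i] != 0 || dx[i] != 0)
      out[i, , ] <- shift_frame(movie$data[i, , ], dy[i], dx[i])
  }
  if (is.numeric(reference)) { dy[reference] <- 0; dx[reference] <- 0 }
  list(movie = movie_stack(out, movie$frame_rate_hz, movie$t0_s),
       shifts = data.frame(frame = seq_len(nf), dy = dy, dx = dx))
}

#' Per-recording motion score
#'
#' Root-mean-square of the applied registration shifts, reported as a QC
#' aid. Recordings with out-of-plane movement must be judged by eye; this
#' score is advisory and nothing is ever auto-discarded.
#'
#' @param shifts the shift table from [register_rigid()].
#' @return RMS displacement in pixels.
#' @export
motion_score <- function(shifts) {
  sqrt(mean(shifts$dy^2 + shifts$dx^2))
}
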