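#' @keywords internal
"_PACKAGE"

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_ft <- function(...) stop(..., call. = FALSE)

# Linear-interpolation sampler for a trace at arbitrary times (seconds).
sample_trace <- function(values, frame_rate_hz, times_s, t0_s = 0) {
  t_frames <- t0_s + (seq_along(values) - 1) / frame_rate_hz
  stats::approx(t_frames, values, xout = times_s, rule = 1)$y
}

frame_times <- function(n, frame_rate_hz, t0_s = 0) {
  t0_s + (seq_len(n) - 1) / frame_rate_hz
}
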