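# Small deterministic fixtures built in code.

# Constant-intensity movie.
const_movie <- function(value = 7, nf = 4, h = 4, w = 4, fps = 10) {
  movie_stack(array(value, dim = c(nf, h, w)), frame_rate_hz = fps)
}

# Movie from an explicit frames x h x w array.
movie_from <- function(arr, fps = 10) movie_stack(arr, frame_rate_hz = fps)

# RMS helper.
rms <- function(x) sqrt(mean(x^2))

# Periodogram power near a frequency (Hz).
band_power <- function(x, fs, f0, half_width = 0.005) {
  sp <- stats::spec.pgram(stats::ts(x - mean(x), frequency = fs),
                          plot = FALSE, detrend = TRUE)
  sel <- abs(sp$freq - f0) <= half_width
  sum(sp$spec[sel])
}

# Independent exact Wilcoxon two-tailed p via the null rank-sum
# distribution (dwilcox), for cross-checking the enumeration route.
wilcox_exact_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  ns <- min(n1, n2)
  w <- if (n1 <= n2) sum(r[seq_len(n1)]) else sum(r[n1 + seq_len(n2)])
  u <- w - ns * (ns + 1) / 2
  nl <- max(n1, n2)
  # two-tailed by doubling the smaller tail (symmetric null)
  lo <- stats::pwilcox(u, ns, nl)
  hi <- 1 - stats::pwilcox(u - 1, ns, nl)
  min(1, 2 * min(lo, hi))
}

# Hand-computed balanced mixed-design ANOVA (between: group, within:
# epoch) from cell means -- the general-linear-model oracle.
rm_anova_oracle <- function(tab) {
  tab$subject <- factor(tab$subject); tab$group <- factor(tab$group)
  tab$epoch <- factor(tab$epoch)
  y <- tab$value
  grand <- mean(y)
  a <- nlevels(tab$group); k <- nlevels(tab$epoch)
  n <- nlevels(tab$subject) / a   # equal group sizes assumed
  subj_mean <- tapply(y, tab$subject, mean)
  group_of <- tapply(as.character(tab$group), tab$subject, `[`, 1)
  group_mean <- tapply(y, tab$group, mean)
  epoch_mean <- tapply(y, tab$epoch, mean)
  cell_mean <- tapply(y, list(tab$group, tab$epoch), mean)
  ss_total <- sum((y - grand)^2)
  ss_between_subj <- k * sum((subj_mean - grand)^2)
  ss_group <- n * k * sum((group_mean - grand)^2)
  ss_subj <- ss_between_subj - ss_group
  ss_epoch <- a * n * sum((epoch_mean - grand)^2)
  ss_int <- n * sum((sweep(sweep(cell_mean, 1, group_mean), 2, epoch_mean) +
                       grand)^2)
  ss_err <- ss_total - ss_between_subj - ss_epoch - ss_int
  df_group <- a - 1; df_subj <- a * (n - 1)
  df_epoch <- k - 1; df_int <- (a - 1) * (k - 1)
  df_err <- a * (n - 1) * (k - 1)
  F_group <- (ss_group / df_group) / (ss_subj / df_subj)
  F_epoch <- (ss_epoch / df_epoch) / (ss_err / df_err)
  F_int <- (ss_int / df_int) / (ss_err / df_err)
  list(F = c(group = F_group, epoch = F_epoch, interaction = F_int),
       p = c(group = stats::pf(F_group, df_group, df_subj, lower.tail = FALSE),
             epoch = stats::pf(F_epoch, df_epoch, df_err, lower.tail = FALSE),
             interaction = stats::pf(F_int, df_int, df_err, lower.tail = FALSE)),
       ss = c(total = ss_total, group = ss_group, subj = ss_subj,
              epoch = ss_epoch, interaction = ss_int, error = ss_err))
}

# Greedy nearest matching of estimated centroids to true centers;
# returns matched distances (px).
match_centroids <- function(est, truth) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  d <- outer(seq_len(nrow(est)), seq_len(nrow(truth)), Vectorize(function(i, j)
    sqrt(sum((est[i, ] - truth[j, ])^2))))
  out <- numeric(0)
  while (length(d) && nrow(d) >= 1 && ncol(d) >= 1 && is.finite(min(d))) {
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    out <- c(out, d[ij[1], ij[2]])
    d[ij[1], ] <- Inf; d[, ij[2]] <- Inf
    if (all(!is.finite(d))) break
  }
  out
}
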