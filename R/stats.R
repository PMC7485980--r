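#' Two-tailed Wilcoxon rank-sum test
#'
#' Exact two-tailed p by full enumeration of rank assignments when the
#' combined sample size is at most 12 and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#' The reported statistic is the rank sum of the smaller group.
#'
#' @param x,y numeric samples (each n >= 1).
#' @param exact_max_n combined-size limit for the exact enumeration
#'   (default 12; at most choose(12, 6) = 924 assignments).
#' @return An object of class `ranksum_result`: `statistic` (rank sum of
#'   the smaller group), `p_value`, `method` (`"exact"` or
#'   `"normal-approximation"`), `n1`, `n2`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 12) {
  stopifnot(length(x) >= 1, length(y) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  small_is_x <- n1 <= n2
  w_small <- if (small_is_x) sum(rk[seq_len(n1)]) else sum(rk[n1 + seq_len(n2)])
  ties <- any(duplicated(pooled))
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both groups; p = 1", call. = FALSE)
    res <- list(statistic = w_small, p_value = 1,
                method = "normal-approximation", n1 = n1, n2 = n2)
    class(res) <- "ranksum_result"
    return(res)
  }
  if (!ties && (n1 + n2) <= exact_max_n) {
    # full enumeration of which ranks go to the smaller group
    ns <- min(n1, n2)
    combos <- utils::combn(n1 + n2, ns)
    sums <- colSums(matrix(seq_len(n1 + n2)[combos], nrow = ns))
    mu <- ns * (n1 + n2 + 1) / 2
    p <- mean(abs(sums - mu) >= abs(w_small - mu))
    method <- "exact"
  } else {
    ns <- min(n1, n2); nl <- max(n1, n2); N <- n1 + n2
    mu <- ns * (N + 1) / 2
    tie_tab <- table(pooled)
    sigma2 <- ns * nl / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- w_small - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)  # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  res <- list(statistic = w_small, p_value = min(1, p), method = method,
              n1 = n1, n2 = n2)
  class(res) <- "ranksum_result"
  res
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf(paste0("Two-tailed Wilcoxon rank-sum test (%s)\n",
                     "  n1 = %d, n2 = %d, rank sum (smaller group) = %g\n",
                     "  p = %.4g\n"),
              x$method, x$n1, x$n2, x$statistic, x$p_value))
  invisible(x)
}

#' Sidak multiple-comparison adjustment
#'
#' Adjusted p = 1 - (1 - p)^m, clipped to [0, 1].
#'
#' @param p raw p-value(s) in [0, 1].
#' @param m number of comparisons (>= 1).
#' @return Adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, pmax(0, 1 - (1 - p)^m))
}

#' Two-way repeated-measures ANOVA (mixed design)
#'
#' Classical mixed-design ANOVA with one between-subject factor (group)
#' and one within-subject factor (epoch), by the standard sums-of-squares
#' decomposition with sphericity assumed for the primary p-values;
#' Greenhouse-Geisser corrected p-values are reported as an auxiliary
#' column. Per-epoch pairwise group comparisons (two-sample pooled t)
#' are Sidak-adjusted over the number of epochs.
#'
#' @param table data frame with columns `subject`, `group`, `epoch`,
#'   `value`. Subjects missing any epoch are dropped with a warning.
#' @return An object of class `rm_anova_result` with an `effects` data
#'   frame (effect, df1, df2, F, p, p_gg) and a `pairwise` data frame
#'   (epoch, t, p_raw, p_sidak).
#' @export
rm_two_way_anova <- function(table) {
  stopifnot(all(c("subject", "group", "epoch", "value") %in% names(table)))
  d <- data.frame(subject = factor(table$subject),
                  group = factor(table$group),
                  epoch = factor(table$epoch),
                  value = as.numeric(table$value))
  n_ep <- nlevels(d$epoch)
  cnt <- table(d$subject)
  incomplete <- names(cnt)[cnt != n_ep]
  if (length(incomplete)) {
    warning("dropping subjects with missing epochs: ",
            paste(incomplete, collapse = ", "), call. = FALSE)
    d <- droplevels(d[!(as.character(d$subject) %in% incomplete), ])
  }
  per_group <- rowSums(table(d$group, d$subject) > 0)
  if (any(per_group < 2))
    stop_ft("each group needs at least 2 subjects; got: ",
            paste(per_group, collapse = ", "))
  fit <- stats::aov(value ~ group * epoch + Error(subject), data = d)
  sm <- summary(fit)
  between <- sm[["Error: subject"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  g_row <- trimws(rownames(between)) == "group"
  e_row <- trimws(rownames(within)) == "epoch"
  i_row <- trimws(rownames(within)) == "group:epoch"
  eff <- data.frame(
    effect = c("group", "epoch", "group:epoch"),
    df1 = c(between$Df[g_row], within$Df[e_row], within$Df[i_row]),
    df2 = c(between$Df[trimws(rownames(between)) == "Residuals"],
            rep(within$Df[trimws(rownames(within)) == "Residuals"], 2)),
    F = c(between$`F value`[g_row], within$`F value`[e_row],
          within$`F value`[i_row]),
    p = c(between$`Pr(>F)`[g_row], within$`Pr(>F)`[e_row],
          within$`Pr(>F)`[i_row]))
  # Greenhouse-Geisser epsilon from the pooled within-group covariance of
  # the subject x epoch matrix
  wide <- stats::reshape(d, idvar = c("subject", "group"),
                         timevar = "epoch", direction = "wide")
  m <- as.matrix(wide[, grep("^value\\.", names(wide)), drop = FALSE])
  cov_list <- lapply(split(as.data.frame(m), wide$group), function(x) {
    if (nrow(x) < 2) return(NULL)
    stats::cov(as.matrix(x)) * (nrow(x) - 1)
  })
  cov_list <- Filter(Negate(is.null), cov_list)
  S <- Reduce(`+`, cov_list) / (nrow(m) - length(cov_list))
  k <- ncol(S)
  C <- diag(k) - matrix(1 / k, k, k)
  E <- C %*% S %*% C
  eps <- sum(diag(E))^2 / ((k - 1) * sum(E * E))
  eps <- min(1, max(1 / (k - 1), eps))
  eff$p_gg <- eff$p
  for (r in 2:3) {
    eff$p_gg[r] <- stats::pf(eff$F[r], eff$df1[r] * eps, eff$df2[r] * eps,
                             lower.tail = FALSE)
  }
  # per-epoch pairwise group comparison (two groups), Sidak-adjusted
  pw <- NULL
  if (nlevels(d$group) == 2) {
    lv <- levels(d$group)
    pw <- do.call(rbind, lapply(levels(d$epoch), function(ep) {
      a <- d$value[d$epoch == ep & d$group == lv[1]]
      b <- d$value[d$epoch == ep & d$group == lv[2]]
      tt <- tryCatch(stats::t.test(a, b, var.equal = TRUE),
                     error = function(e) NULL)
      p <- if (is.null(tt) || !is.finite(tt$p.value)) NA_real_ else tt$p.value
      data.frame(epoch = ep,
                 t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 p_raw = p,
                 p_sidak = if (is.na(p)) NA_real_ else sidak_adjust(p, n_ep))
    }))
  }
  res <- list(effects = eff, pairwise = pw, gg_epsilon = eps,
              n_subjects = nrow(m), n_epochs = n_ep)
  class(res) <- "rm_anova_result"
  res
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat("Two-way repeated-measures ANOVA (between: group, within: epoch)\n")
  cat(sprintf("  %d subjects x %d epochs, GG epsilon = %.3f\n",
              x$n_subjects, x$n_epochs, x$gg_epsilon))
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-12s F(%d, %d) = %8.3f  p = %.4g  (GG p = %.4g)\n",
                e$effect[i], e$df1[i], e$df2[i], e$F[i], e$p[i], e$p_gg[i]))
  if (!is.null(x$pairwise)) {
    cat("  Sidak-adjusted per-epoch group comparisons:\n")
    p <- x$pairwise
    for (i in seq_len(nrow(p)))
      cat(sprintf("    epoch %s: t = %6.2f  p_sidak = %.4g\n",
                  p$epoch[i], p$t[i], p$p_sidak[i]))
  }
  invisible(x)
}
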