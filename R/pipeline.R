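# A recording for the pipeline entry points: either a movie plus
# metadata, or a ready-made raw trace. Internal normalizer.
as_recording_trace <- function(rec, mode, k, seed, min_roi_px, log) {
  if (inherits(rec$movie, "movie_stack")) {
    reg <- register_rigid(rec$movie)
    if (mode == "bath") {
      retained <- segment_movie(reg$movie, k = k, seed = seed,
                                min_roi_px = min_roi_px, split = FALSE)
      tr <- pooled_trace(reg$movie, retained, subject_id = rec$subject_id,
                         group = rec$group)
      list(trace = tr, motion = motion_score(reg$shifts))
    } else {
      rois <- segment_movie(reg$movie, k = k, seed = seed,
                            min_roi_px = min_roi_px, split = TRUE)
      trs <- extract_traces(reg$movie, rois, subject_id = rec$subject_id,
                            group = rec$group)
      list(traces = trs, motion = motion_score(reg$shifts))
    }
  } else if (inherits(rec$trace, "raw_trace")) {
    if (mode == "bath") list(trace = rec$trace, motion = NA_real_)
    else list(traces = list(rec$trace), motion = NA_real_)
  } else {
    stop_ft("recording must carry a 'movie' (movie_stack) or 'trace' (raw_trace)")
  }
}

#' Run the bath-application pipeline
#'
#' Per recording: rigid registration, segmentation to one pooled ROI,
#' optional 0.04 Hz motion notch, and dF/F against the first-60-s
#' baseline. Groups are summarized as mean +/- SEM traces and compared by
#' a two-tailed Wilcoxon rank-sum test on per-fly dF/F at a comparison
#' timepoint (default: the final sample). Recordings that fail
#' segmentation are skipped with a logged reason; nothing is
#' auto-discarded for motion.
#'
#' @param recordings list of recordings; each a list with `subject_id`,
#'   `group`, and either `movie` ([movie_stack()]) or `trace`
#'   ([raw_trace()]), plus optional `motion_notch` (logical).
#' @param baseline_duration_s bath baseline window (default 60 s).
#' @param comparison_time_s timepoint for the group comparison (s);
#'   `NULL` = final sample.
#' @param k,seed,min_roi_px segmentation parameters.
#' @return An object of class `bath_run`: per-fly `dff` traces, `groups`,
#'   `comparison` (per-fly values + `ranksum_result`), `log`.
#' @export
run_bath <- function(recordings, baseline_duration_s = 60,
                     comparison_time_s = NULL, k = 3, seed = 1,
                     min_roi_px = 4) {
  stopifnot(length(recordings) >= 1)
  dffs <- list(); log <- character(0)
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    sid <- if (!is.null(rec$subject_id)) rec$subject_id else paste0("fly", i)
    res <- tryCatch(
      as_recording_trace(rec, "bath", k, seed, min_roi_px),
      error = function(e) e)
    if (inherits(res, "error")) {
      log <- c(log, sprintf("skip %s: segmentation failed: %s", sid,
                            conditionMessage(res)))
      next
    }
    tr <- res$trace
    tr$subject_id <- sid
    tr$group <- rec$group
    advice <- motion_oscillation_advisory(tr)
    do_notch <- isTRUE(rec$motion_notch)
    if (do_notch) tr <- remove_motion_oscillation(tr)
    if (!do_notch && isTRUE(advice$advise))
      log <- c(log, sprintf(
        "advisory %s: 0.04 Hz oscillation detected (peak %.1fx median); motion notch not applied",
        sid, advice$peak_ratio))
    d <- tryCatch(dff_bath(tr, baseline_duration_s), error = function(e) e)
    if (inherits(d, "error")) {
      log <- c(log, sprintf("skip %s: %s", sid, conditionMessage(d)))
      next
    }
    dffs[[sid]] <- d
  }
  if (length(dffs) == 0) stop_ft("no recordings survived the pipeline")
  groups <- vapply(dffs, `[[`, character(1), "group")
  # per-fly comparison value
  vals <- vapply(dffs, function(d) {
    if (is.null(comparison_time_s)) d$values[length(d$values)]
    else sample_trace(d$values, d$frame_rate_hz, comparison_time_s, d$t0_s)
  }, numeric(1))
  glv <- unique(groups)
  comparison <- list(values = data.frame(subject_id = names(dffs),
                                         group = groups, value = vals))
  if (length(glv) == 2) {
    n_per <- table(groups)
    if (any(n_per < 2))
      log <- c(log, "small-n warning: a group has a single fly; rank-sum p is unreliable")
    comparison$test <- wilcoxon_rank_sum(vals[groups == glv[1]],
                                         vals[groups == glv[2]])
  }
  res <- list(dff = dffs, groups = groups, comparison = comparison,
              comparison_time_s = comparison_time_s, log = log)
  class(res) <- "bath_run"
  res
}

#' @export
print.bath_run <- function(x, ...) {
  cat(sprintf("<bath_run> %d flies (%s)\n", length(x$dff),
              paste(sprintf("%s: %d", names(table(x$groups)),
                            table(x$groups)), collapse = ", ")))
  agg <- stats::aggregate(value ~ group, data = x$comparison$values, mean)
  sem <- stats::aggregate(value ~ group, data = x$comparison$values,
                          function(v) stats::sd(v) / sqrt(length(v)))
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %s: dF/F = %.3f +/- %.3f SEM at comparison timepoint\n",
                agg$group[i], agg$value[i], sem$value[i]))
  if (!is.null(x$comparison$test))
    cat(sprintf("  Wilcoxon rank sum: p = %.4g (%s)\n",
                x$comparison$test$p_value, x$comparison$test$method))
  for (l in x$log) cat("  [log] ", l, "\n", sep = "")
  invisible(x)
}

#' Group mean +/- SEM dF/F trace
#'
#' @param run a `bath_run`.
#' @param group group label.
#' @return Data frame: time_s, mean, sem, n.
#' @export
group_mean_trace <- function(run, group) {
  stopifnot(inherits(run, "bath_run"))
  sel <- run$dff[run$groups == group]
  if (length(sel) == 0) stop_ft("no flies in group ", group)
  m <- do.call(cbind, lapply(sel, `[[`, "values"))
  data.frame(time_s = frame_times(nrow(m), sel[[1]]$frame_rate_hz,
                                  sel[[1]]$t0_s),
             mean = rowMeans(m),
             sem = apply(m, 1, stats::sd) / sqrt(ncol(m)),
             n = ncol(m))
}

#' Run the visual-experiment pipeline
#'
#' Per fly: registration, segmentation to terminal ROIs, per-ROI traces
#' averaged across ROIs, dF/F against the epoch-1 inter-stimulus
#' baseline, stimulus-locked epoch averages per polarity, transient
#' kinetics per epoch and epoch-1-normalized deltas. Groups are compared
#' per metric by two-way repeated-measures ANOVA with Sidak-adjusted
#' per-epoch tests. A basal-calcium side channel (stimulus bands notched
#' out) is returned per fly.
#'
#' @param recordings list of recordings as in [run_bath()].
#' @param protocol a [stimulus_protocol()].
#' @param k,seed,min_roi_px segmentation parameters.
#' @param w_post primary-extremum search window (s).
#' @return An object of class `visual_run`: `metrics` (tidy data frame:
#'   subject_id, group, epoch, polarity, metric, value, valid), `deltas`
#'   (epoch-1-normalized), `anova` (list of `rm_anova_result` per
#'   polarity:metric), `basal` (per-fly stimulus-band-filtered dF/F),
#'   `log`.
#' @export
run_visual <- function(recordings, protocol, k = 3, seed = 1,
                       min_roi_px = 4, w_post = 2) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  metrics <- NULL; basal <- list(); log <- character(0)
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    sid <- if (!is.null(rec$subject_id)) rec$subject_id else paste0("fly", i)
    grp <- rec$group
    res <- tryCatch(
      as_recording_trace(rec, "visual", k, seed, min_roi_px),
      error = function(e) e)
    if (inherits(res, "error")) {
      log <- c(log, sprintf("skip %s: segmentation failed: %s", sid,
                            conditionMessage(res)))
      next
    }
    dffs <- lapply(res$traces, dff_visual, protocol = protocol)
    d <- average_across_rois(dffs)
    d$subject_id <- sid; d$group <- grp
    basal[[sid]] <- remove_stimulus_band(d)
    for (ep in seq_len(protocol$n_epochs)) {
      for (pol in c("dark", "light")) {
        resp <- tryCatch(
          stimulus_locked_epoch_average(d, protocol, ep, pol),
          error = function(e) e, warning = function(w) w)
        if (inherits(resp, "warning")) {
          log <- c(log, sprintf("%s epoch %d %s: %s", sid, ep, pol,
                                conditionMessage(resp)))
          resp <- suppressWarnings(
            tryCatch(stimulus_locked_epoch_average(d, protocol, ep, pol),
                     error = function(e) e))
        }
        if (inherits(resp, "error")) {
          log <- c(log, sprintf("skip %s epoch %d %s: %s", sid, ep, pol,
                                conditionMessage(resp)))
          next
        }
        mt <- transient_metrics(resp, w_post = w_post)
        metrics <- rbind(metrics,
                         cbind(data.frame(subject_id = sid, group = grp), mt))
      }
    }
  }
  if (is.null(metrics)) stop_ft("no recordings survived the pipeline")
  for (j in seq_len(nrow(metrics)))
    if (!metrics$valid[j])
      log <- c(log, sprintf("invalid metric: %s epoch %d %s %s",
                            metrics$subject_id[j], metrics$epoch[j],
                            metrics$polarity[j], metrics$metric[j]))
  # epoch-1-normalized deltas per subject/polarity/metric
  deltas <- do.call(rbind, lapply(
    split(metrics, list(metrics$subject_id, metrics$polarity), drop = TRUE),
    function(dd) {
      nd <- epoch1_normalize(dd)
      cbind(data.frame(subject_id = dd$subject_id[1], group = dd$group[1],
                       polarity = dd$polarity[1]), nd)
    }))
  rownames(deltas) <- NULL
  # RM-ANOVA per polarity:metric on the deltas when 2 groups present
  anovas <- list()
  if (length(unique(metrics$group)) == 2) {
    for (key in unique(paste(deltas$polarity, deltas$metric, sep = ":"))) {
      dd <- deltas[paste(deltas$polarity, deltas$metric, sep = ":") == key, ]
      # subjects with any invalid epoch are dropped for this metric
      bad_subj <- unique(dd$subject_id[!dd$valid])
      if (length(bad_subj)) {
        log <- c(log, sprintf("anova %s: dropping subjects with invalid values: %s",
                              key, paste(bad_subj, collapse = ", ")))
        dd <- dd[!(dd$subject_id %in% bad_subj), ]
      }
      if (nrow(dd) == 0) next
      tab <- data.frame(subject = dd$subject_id, group = dd$group,
                        epoch = dd$epoch, value = dd$delta)
      an <- tryCatch(rm_two_way_anova(tab), error = function(e) e)
      if (inherits(an, "error")) {
        log <- c(log, sprintf("anova %s: %s", key, conditionMessage(an)))
      } else anovas[[key]] <- an
    }
  }
  res <- list(metrics = metrics, deltas = deltas, anova = anovas,
              basal = basal, log = log)
  class(res) <- "visual_run"
  res
}

#' @export
print.visual_run <- function(x, ...) {
  flies <- unique(x$metrics$subject_id)
  cat(sprintf("<visual_run> %d flies, %d metric rows\n", length(flies),
              nrow(x$metrics)))
  for (key in names(x$anova)) {
    e <- x$anova[[key]]$effects
    i <- e$effect == "group:epoch"
    cat(sprintf("  %-32s time x group interaction: F = %6.2f, p = %.4g\n",
                key, e$F[i], e$p[i]))
  }
  if (length(x$log)) cat(sprintf("  %d log entries\n", length(x$log)))
  invisible(x)
}
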