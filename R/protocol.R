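#' Stimulus and perfusion protocol
#'
#' Describes a full-field flash experiment: flash onset times and
#' polarities, epoch structure, and perfusion timing. The default design
#' is six 60-s epochs each containing 12 flashes (6 light + 6 dark,
#' shuffled) at 5-s spacing; each flash lasts 100 ms before the display
#' returns to mid-intensity grey.
#'
#' @param flash_onsets_s strictly increasing flash onset times (s).
#' @param polarities character vector, `"light"` or `"dark"`, per flash.
#' @param flash_duration_s flash duration (default 0.1 s).
#' @param inter_onset_s onset spacing (default 5 s).
#' @param epoch_length_s epoch length (default 60 s).
#' @param n_epochs number of epochs (default 6).
#' @param perfusion_switch_s time the perfusion input is switched (s).
#' @param perfusion_arrival_delay_s dead time for the new solution to reach
#'   the tissue: ~105 s for the gravity rig, ~45 s for the valve rig.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(flash_onsets_s, polarities,
                              flash_duration_s = 0.1, inter_onset_s = 5,
                              epoch_length_s = 60, n_epochs = 6,
                              perfusion_switch_s = 60,
                              perfusion_arrival_delay_s = 45) {
  if (length(flash_onsets_s) != length(polarities))
    stop_ft("one polarity per flash onset required")
  if (is.unsorted(flash_onsets_s, strictly = TRUE))
    stop_ft("flash onsets must be strictly increasing")
  if (!all(polarities %in% c("light", "dark")))
    stop_ft("polarities must be 'light' or 'dark'")
  if (any(flash_onsets_s < 0 | flash_onsets_s >= n_epochs * epoch_length_s))
    stop_ft("all onsets must lie within n_epochs * epoch_length_s")
  structure(list(flash_onsets_s = as.numeric(flash_onsets_s),
                 polarities = as.character(polarities),
                 flash_duration_s = flash_duration_s,
                 inter_onset_s = inter_onset_s,
                 epoch_length_s = epoch_length_s, n_epochs = n_epochs,
                 perfusion_switch_s = perfusion_switch_s,
                 perfusion_arrival_delay_s = perfusion_arrival_delay_s),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(paste0("<stimulus_protocol> %d flashes (%d light / %d dark), ",
                     "%d x %.0f s epochs, switch %.0f s + %.0f s delay\n"),
              length(x$flash_onsets_s), sum(x$polarities == "light"),
              sum(x$polarities == "dark"), x$n_epochs, x$epoch_length_s,
              x$perfusion_switch_s, x$perfusion_arrival_delay_s))
  invisible(x)
}

#' Epoch index of each flash
#' @param protocol a [stimulus_protocol()].
#' @return Integer vector mapping each flash to its 1-based epoch.
#' @export
flash_epochs <- function(protocol) {
  pmin(protocol$n_epochs,
       floor(protocol$flash_onsets_s / protocol$epoch_length_s) + 1L)
}

#' Generate a shuffled flash protocol
#'
#' Builds the standard design: `n_epochs` epochs of `epoch_length_s`, each
#' containing 12 onsets at `inter_onset_s` spacing whose polarities are a
#' seeded shuffle of 6 light + 6 dark. The first onset of each epoch falls
#' 3 s after the epoch start so that every flash has a 0.5-s pre-stimulus
#' window and every inter-flash gap provides a 2.5-s baseline segment
#' inside the epoch. The perfusion switch occurs at the end of epoch 1;
#' the arrival delay depends on the rig.
#'
#' @param seed integer seed for the polarity shuffles.
#' @param rig `"valve"` (45-s arrival delay) or `"gravity"` (105 s).
#' @param n_epochs,epoch_length_s,inter_onset_s,flash_duration_s design
#'   parameters (defaults: 6, 60, 5, 0.1).
#' @return A [stimulus_protocol()].
#' @export
make_protocol <- function(seed = 1, rig = c("valve", "gravity"),
                          n_epochs = 6, epoch_length_s = 60,
                          inter_onset_s = 5, flash_duration_s = 0.1) {
  rig <- match.arg(rig)
  per_epoch <- floor(epoch_length_s / inter_onset_s)
  onsets <- polarity <- NULL
  pol_pool <- rep(c("light", "dark"), each = per_epoch / 2)
  pols <- with_seed(seed, {
    lapply(seq_len(n_epochs), function(e) sample(pol_pool))
  })
  for (e in seq_len(n_epochs)) {
    t0 <- (e - 1) * epoch_length_s
    onsets <- c(onsets, t0 + 3 + inter_onset_s * (seq_len(per_epoch) - 1))
    polarity <- c(polarity, pols[[e]])
  }
  stimulus_protocol(
    flash_onsets_s = onsets, polarities = polarity,
    flash_duration_s = flash_duration_s, inter_onset_s = inter_onset_s,
    epoch_length_s = epoch_length_s, n_epochs = n_epochs,
    perfusion_switch_s = epoch_length_s,
    perfusion_arrival_delay_s = if (rig == "gravity") 105 else 45)
}

#' Read/write a protocol as YAML
#' @param protocol a [stimulus_protocol()].
#' @param path file path.
#' @return `read_protocol` returns a [stimulus_protocol()];
#'   `write_protocol` returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  yaml::write_yaml(list(
    epoch_length_s = protocol$epoch_length_s, n_epochs = protocol$n_epochs,
    flash_duration_s = protocol$flash_duration_s,
    inter_onset_s = protocol$inter_onset_s,
    perfusion_switch_s = protocol$perfusion_switch_s,
    perfusion_arrival_delay_s = protocol$perfusion_arrival_delay_s,
    onsets = lapply(seq_along(protocol$flash_onsets_s), function(i)
      list(t = protocol$flash_onsets_s[i], polarity = protocol$polarities[i]))),
    path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  stimulus_protocol(
    flash_onsets_s = vapply(y$onsets, `[[`, numeric(1), "t"),
    polarities = vapply(y$onsets, `[[`, character(1), "polarity"),
    flash_duration_s = y$flash_duration_s, inter_onset_s = y$inter_onset_s,
    epoch_length_s = y$epoch_length_s, n_epochs = y$n_epochs,
    perfusion_switch_s = y$perfusion_switch_s,
    perfusion_arrival_delay_s = y$perfusion_arrival_delay_s)
}
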