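#' Epoch container
#'
#' @param data numeric array `trial x channel x time` (microvolts).
#' @param channels channel names (length = dim 2).
#' @param scalp logical vector marking scalp (vs EOG) channels.
#' @param times_ms epoch time axis in ms relative to stimulus onset.
#' @param sfreq sampling rate in Hz.
#' @param info data.frame of per-trial annotations (block, trial,
#'   condition, responded, rt_ms, and rejection flags once set).
#' @return an object of class `epoch_set`.
#' @export
new_epoch_set <- function(data, channels, scalp, times_ms, sfreq, info) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(channels),
            dim(data)[3] == length(times_ms), dim(data)[1] == nrow(info))
  if (!any(times_ms < 0)) stop_input("baseline window must lie inside the epoch")
  structure(list(data = data, channels = channels, scalp = scalp,
                 times_ms = times_ms, sfreq = sfreq, info = info),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%.1f..%.1f ms @ %g Hz)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times_ms), max(x$times_ms), x$sfreq))
  if (!is.null(x$info$reject_artifact)) {
    cat(sprintf("  flagged: %d artifact, %d behavioral\n",
                sum(x$info$reject_artifact),
                sum(x$info$reject_behavior %||% FALSE)))
  }
  invisible(x)
}

#' Regress EOG activity out of scalp channels
#'
#' Removes the least-squares contribution of the EOG channels from every
#' scalp channel (ocular artifact correction by multiple regression). For
#' epoched input the regression is fitted on all epochs jointly and applied
#' per epoch. EOG channels that are exactly zero contribute nothing and
#' get a zero coefficient; a constant non-zero EOG channel makes the fit
#' singular and is rejected.
#'
#' @param x continuous data matrix (samples x channels, named columns) or
#'   an `epoch_set`.
#' @param eog names of the EOG channels (default: the standard four).
#' @param prewhiten estimate the coefficients on first-differenced data
#'   (default TRUE for continuous input). The EEG background is strongly
#'   autocorrelated; differencing whitens it and sharpens the propagation
#'   estimates without changing the model (the contamination is linear in
#'   the EOG either way). The correction itself is always applied to the
#'   raw data.
#' @return list with `corrected` (same shape as `x`) and `coefficients`
#'   (EOG x scalp matrix of propagation estimates).
#' @export
regress_eog <- function(x, eog = c("EOGvu", "EOGvl", "EOGhl", "EOGhr"),
                        prewhiten = TRUE) {
  if (inherits(x, "epoch_set")) {
    eog <- intersect(eog, x$channels)
    if (!length(eog)) stop_input("no EOG channel present")
    d <- dim(x$data)
    flat <- matrix(aperm(x$data, c(3, 1, 2)), d[1] * d[3], d[2])
    colnames(flat) <- x$channels
    fit <- regress_eog(flat, eog, prewhiten = FALSE) # epochs: plain LS
    corr <- x
    arr <- array(fit$corrected, dim = c(d[3], d[1], d[2]))
    corr$data <- aperm(arr, c(2, 3, 1))
    dimnames(corr$data) <- dimnames(x$data)
    return(list(corrected = corr, coefficients = fit$coefficients))
  }
  if (is.null(colnames(x))) stop_input("continuous data must have channel names")
  eog <- intersect(eog, colnames(x))
  if (!length(eog)) stop_input("no EOG channel present")
  scalp <- setdiff(colnames(x), eog)
  E <- x[, eog, drop = FALSE]
  keep <- apply(E, 2, function(col) stats::var(col) > 0)
  zero <- apply(E, 2, function(col) all(col == 0))
  if (any(!keep & !zero)) {
    stop_input("constant EOG channel(s): %s (singular fit)",
               paste(eog[!keep & !zero], collapse = ", "))
  }
  beta <- matrix(0, length(eog), length(scalp),
                 dimnames = list(eog, scalp))
  corrected <- x
  if (any(keep)) {
    Y <- x[, scalp, drop = FALSE]
    if (prewhiten) {
      Ed <- diff(E[, keep, drop = FALSE])
      Yd <- diff(Y)
    } else {
      Ed <- scale(E[, keep, drop = FALSE], center = TRUE, scale = FALSE)
      Yd <- scale(Y, center = TRUE, scale = FALSE)
    }
    b <- solve(crossprod(Ed), crossprod(Ed, Yd))
    beta[keep, ] <- b
    Ek <- scale(E[, keep, drop = FALSE], center = TRUE, scale = FALSE)
    corrected[, scalp] <- Y - Ek %*% b
  }
  list(corrected = corrected, coefficients = beta)
}

#' Zero-phase low-pass filter
#'
#' Forward-backward (zero phase lag) Butterworth low-pass. The default
#' 4th-order design corresponds to a 24 dB/octave roll-off.
#'
#' @param x continuous matrix (samples x channels), numeric vector, or
#'   `epoch_set`.
#' @param sfreq sampling rate in Hz (taken from the `epoch_set` if given).
#' @param cutoff_hz cutoff frequency; must be below the Nyquist frequency.
#' @param order filter order (default 4).
#' @return filtered data of the same shape.
#' @export
lowpass_zero_phase <- function(x, sfreq = NULL, cutoff_hz = 25, order = 4) {
  if (inherits(x, "epoch_set")) {
    sfreq <- x$sfreq
    check_cutoff(cutoff_hz, sfreq)
    bf <- signal::butter(order, cutoff_hz / (sfreq / 2), type = "low")
    npad <- ceiling(3 * order * sfreq / cutoff_hz)
    d <- dim(x$data)
    out <- x
    for (i in seq_len(d[1])) {
      out$data[i, , ] <- t(apply(x$data[i, , , drop = TRUE], 1,
                                 function(v) filtfilt_padded(bf, v, npad)))
    }
    return(out)
  }
  check_cutoff(cutoff_hz, sfreq)
  bf <- signal::butter(order, cutoff_hz / (sfreq / 2), type = "low")
  npad <- ceiling(3 * order * sfreq / cutoff_hz)
  if (is.matrix(x)) {
    apply(x, 2, function(col) filtfilt_padded(bf, col, npad))
  } else {
    filtfilt_padded(bf, x, npad)
  }
}

# forward-backward filtering with odd-symmetric edge padding, so constant
# signals pass unchanged and edge transients decay inside the padding
filtfilt_padded <- function(bf, x, npad) {
  n <- length(x)
  npad <- min(n - 1, npad)
  if (npad < 1) return(signal::filtfilt(bf, x))
  front <- 2 * x[1] - x[seq(npad + 1, 2)]
  back <- 2 * x[n] - x[seq(n - 1, n - npad)]
  y <- signal::filtfilt(bf, c(front, x, back))
  y[npad + seq_len(n)]
}

check_cutoff <- function(cutoff_hz, sfreq) {
  if (is.null(sfreq)) stop_input("sfreq must be supplied")
  if (cutoff_hz >= sfreq / 2) {
    stop_input("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
               cutoff_hz, sfreq / 2)
  }
}

#' Extract fixed-length epochs from continuous data
#'
#' Cuts stimulus-locked epochs on the left-closed sample grid (-100..750 ms
#' at 512 Hz yields 436 samples). Events whose epoch would exceed the
#' recording edges are skipped with a warning.
#'
#' @param continuous samples x channels matrix with channel names.
#' @param events data.frame with at least `onset_sample`, `condition`,
#'   `trial` (and optionally `block`, behavior columns).
#' @param config a `gonogo_config` supplying `sfreq` and `epoch_window`.
#' @param montage montage used to mark scalp vs EOG channels.
#' @return an `epoch_set`.
#' @export
extract_epochs <- function(continuous, events, config,
                           montage = gonogo_montage()) {
  offs <- epoch_offsets(config)
  n <- nrow(continuous)
  ok <- events$onset_sample + offs[1] >= 1 &
    events$onset_sample + offs[length(offs)] <= n
  if (any(!ok)) {
    warning(sprintf("%d event(s) too close to the recording edge; skipped",
                    sum(!ok)))
  }
  ev <- events[ok, , drop = FALSE]
  chs <- colnames(continuous)
  arr <- array(NA_real_, dim = c(nrow(ev), length(chs), length(offs)),
               dimnames = list(NULL, chs, NULL))
  for (i in seq_len(nrow(ev))) {
    arr[i, , ] <- t(continuous[ev$onset_sample[i] + offs, , drop = FALSE])
  }
  scalp_names <- scalp_channels(montage)
  new_epoch_set(arr, chs, chs %in% scalp_names,
                epoch_times_ms(config), config$sfreq, ev)
}

#' Baseline-correct epochs over the prestimulus window
#'
#' Subtracts, per epoch and channel, the mean over all samples before
#' stimulus onset (the -100..0 ms window), so the prestimulus mean is zero.
#'
#' @param epochs an `epoch_set`.
#' @return the baselined `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  pre <- epochs$times_ms < 0
  if (!any(pre)) stop_input("no prestimulus samples to baseline on")
  base <- apply(epochs$data[, , pre, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base) # recycles over time (dim 3)
  epochs
}

#' Flag epochs containing amplitude artifacts
#'
#' An epoch is flagged iff any scalp-channel sample exceeds the threshold
#' in absolute amplitude; EOG channels are ignored by the rule.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv rejection threshold in microvolts (default 75).
#' @return the `epoch_set` with a logical `reject_artifact` column in
#'   `$info`.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 75) {
  if (threshold_uv <= 0) stop_input("threshold must be positive")
  sc <- epochs$data[, epochs$scalp, , drop = FALSE]
  peak <- apply(abs(sc), 1, max)
  epochs$info$reject_artifact <- peak > threshold_uv
  epochs
}

#' Flag behaviorally invalid trials
#'
#' Applies the behavioral exclusion rules: NoGo trials with a response
#' (commission errors), Go trials without a response (omission errors),
#' and Go trials whose reaction time falls outside the individual mean
#' +/- 1.5 SD. The RT mean and SD are computed per subject and session
#' with both blocks pooled; a degenerate SD of 0 yields no RT exclusions.
#'
#' @param epochs an `epoch_set` whose `$info` carries `condition`,
#'   `responded` and `rt_ms`.
#' @param rt_sd_mult RT exclusion bound in SD units (default 1.5).
#' @return the `epoch_set` with `reject_behavior` and `behavior_reason`
#'   columns in `$info`.
#' @export
select_valid_trials <- function(epochs, rt_sd_mult = 1.5) {
  info <- epochs$info
  need <- c("condition", "responded", "rt_ms")
  if (!all(need %in% names(info))) {
    stop_input("behavioral annotations (%s) missing", paste(need, collapse = ", "))
  }
  go_resp <- info$condition == "go" & info$responded
  rts <- info$rt_ms[go_resp]
  if (!length(rts)) stop_input("no valid Go reaction times for this subject")
  m <- mean(rts)
  s <- stats::sd(rts)
  if (length(rts) == 1L || is.na(s)) s <- 0
  lo <- m - rt_sd_mult * s
  hi <- m + rt_sd_mult * s
  reason <- rep(NA_character_, nrow(info))
  reject <- logical(nrow(info))
  commission <- info$condition == "nogo" & info$responded
  omission <- info$condition == "go" & !info$responded
  rt_out <- go_resp & s > 0 & (info$rt_ms < lo | info$rt_ms > hi)
  reject[commission] <- TRUE; reason[commission] <- "commission"
  reject[omission] <- TRUE; reason[omission] <- "omission"
  reject[rt_out] <- TRUE
  reason[rt_out] <- ifelse(info$rt_ms[rt_out] < lo, "fast_rt", "delayed_rt")
  epochs$info$reject_behavior <- reject
  epochs$info$behavior_reason <- reason
  attr(epochs, "rt_bounds") <- c(lower = lo, upper = hi, mean = m, sd = s)
  epochs
}

accepted_mask <- function(epochs) {
  rej_a <- epochs$info$reject_artifact %||% logical(nrow(epochs$info))
  rej_b <- epochs$info$reject_behavior %||% logical(nrow(epochs$info))
  !(rej_a | rej_b)
}

#' Average accepted epochs and half-sample to 256 Hz
#'
#' Computes, per block x condition, the mean scalp waveform over unflagged
#' epochs and decimates the time axis by 2 (every second sample, no
#' anti-alias refilter: the data are already low-passed at 25 Hz). Empty
#' cells are dropped with a warning.
#'
#' @param epochs an `epoch_set` with rejection flags.
#' @return list of class `average_erp_list`; each element has `block`,
#'   `condition`, `data` (scalp channel x time matrix, microvolts),
#'   `n_accepted`, and the decimated `times_ms`.
#' @export
average_and_downsample <- function(epochs) {
  keep_t <- seq(1, length(epochs$times_ms), by = 2)
  times <- epochs$times_ms[keep_t]
  ok <- accepted_mask(epochs)
  info <- epochs$info
  if (is.null(info$block)) info$block <- 1L
  out <- list()
  for (b in sort(unique(info$block))) {
    for (cond in c("go", "nogo")) {
      sel <- ok & info$block == b & info$condition == cond
      if (!any(sel)) {
        warning(sprintf("no accepted trials in block %s, condition %s; cell dropped",
                        b, cond))
        next
      }
      avg <- apply(epochs$data[sel, epochs$scalp, keep_t, drop = FALSE],
                   c(2, 3), mean)
      rownames(avg) <- epochs$channels[epochs$scalp]
      out[[length(out) + 1L]] <- list(block = b, condition = cond,
                                      data = avg, n_accepted = sum(sel),
                                      times_ms = times)
    }
  }
  structure(out, class = "average_erp_list", times_ms = times)
}

#' Preprocess one simulated session into average ERPs
#'
#' Runs the full per-session chain: EOG regression, 25 Hz zero-phase
#' low-pass, epoch extraction, baseline correction, amplitude artifact
#' rejection, behavioral trial selection (RT bounds pooled over blocks),
#' and averaging with half-sampling.
#'
#' @param session a `gonogo_session`.
#' @param cutoff_hz low-pass cutoff (default 25).
#' @param threshold_uv artifact threshold (default from the config).
#' @param keep_epochs return the flagged `epoch_set` too (memory heavy).
#' @return list with `averages` (an `average_erp_list`), `info`
#'   (per-trial flags), `eog_coefficients`, and optionally `epochs`.
#' @export
preprocess_session <- function(session, cutoff_hz = 25, threshold_uv = NULL,
                               keep_epochs = FALSE) {
  cfg <- session$config
  threshold_uv <- threshold_uv %||% cfg$reject_uv
  eog <- eog_channels(session$montage)
  # one ocular correction per recording session: fit on all blocks jointly
  lens <- vapply(session$blocks, function(b) nrow(b$continuous), 0L)
  fit <- regress_eog(do.call(rbind, lapply(session$blocks,
                                           `[[`, "continuous")), eog)
  ep_list <- vector("list", length(session$blocks))
  at <- 0L
  for (b in seq_along(session$blocks)) {
    blk <- session$blocks[[b]]
    corr <- fit$corrected[at + seq_len(lens[b]), , drop = FALSE]
    at <- at + lens[b]
    filt <- lowpass_zero_phase(corr, cfg$sfreq, cutoff_hz)
    colnames(filt) <- colnames(blk$continuous)
    ev <- blk$events
    ev$block <- b
    ev$responded <- blk$behavior$responded
    ev$rt_ms <- blk$behavior$rt_ms
    ep_list[[b]] <- extract_epochs(filt, ev, cfg, session$montage)
  }
  epochs <- bind_epoch_sets(ep_list)
  epochs <- baseline_correct(epochs)
  epochs <- reject_artifacts(epochs, threshold_uv)
  epochs <- select_valid_trials(epochs)
  out <- list(averages = average_and_downsample(epochs),
              info = epochs$info,
              eog_coefficients = fit$coefficients,
              rt_bounds = attr(epochs, "rt_bounds"))
  if (keep_epochs) out$epochs <- epochs
  out
}

bind_epoch_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  data <- do.call(abind3, lapply(sets, `[[`, "data"))
  info <- do.call(rbind, lapply(sets, `[[`, "info"))
  new_epoch_set(data, sets[[1]]$channels, sets[[1]]$scalp,
                sets[[1]]$times_ms, sets[[1]]$sfreq, info)
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  args <- list(...)
  d <- dim(args[[1]])
  out <- array(NA_real_, dim = c(sum(vapply(args, function(a) dim(a)[1], 0L)),
                                 d[2], d[3]),
               dimnames = c(list(NULL), dimnames(args[[1]])[2:3]))
  at <- 0L
  for (a in args) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
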