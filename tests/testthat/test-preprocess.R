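make_continuous <- function(n = 2048, sfreq = 512) {
  t <- seq_len(n) / sfreq
  clean <- cbind(Cz = sin(2 * pi * 4 * t), Pz = cos(2 * pi * 6 * t))
  eog <- cbind(EOGvu = sin(2 * pi * 2 * t)) # orthogonal over full periods
  list(t = t, clean = clean, eog = eog)
}

test_that("exact linear EOG contamination is removed", {
  d <- make_continuous()
  x <- cbind(d$clean + 0.2 * d$eog[, "EOGvu"], d$eog)
  colnames(x) <- c("Cz", "Pz", "EOGvu")
  fit <- regress_eog(x, "EOGvu", prewhiten = FALSE)
  expect_equal(fit$corrected[, c("Cz", "Pz")], d$clean, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["EOGvu", ]), c(0.2, 0.2),
               tolerance = 1e-6)
  # prewhitened estimation recovers the same coefficients (finite-sample
  # leakage from differencing only)
  fitw <- regress_eog(x, "EOGvu")
  expect_equal(unname(fitw$coefficients["EOGvu", ]), c(0.2, 0.2),
               tolerance = 0.02)
})

test_that("zero EOG leaves the data unchanged; a constant EOG channel is singular", {
  d <- make_continuous()
  x <- cbind(d$clean, EOGvu = rep(0, nrow(d$clean)))
  fit <- regress_eog(x, "EOGvu")
  expect_equal(fit$corrected, x)
  expect_equal(unname(fit$coefficients["EOGvu", ]), c(0, 0))
  x2 <- cbind(d$clean, EOGvu = rep(2.5, nrow(d$clean)))
  expect_error(regress_eog(x2, "EOGvu"), "singular")
  expect_error(regress_eog(d$clean, "EOGvu"), "no EOG")
})

test_that("planted blink propagation weights are recovered at default SNR", {
  cfg <- simulate_config(seed = 31)
  mont <- gonogo_montage()
  sess <- simulate_session(cfg, default_component_templates(), "placebo", 1,
                           mont)
  beta_true <- erpca:::blink_propagation(mont)
  cont <- do.call(rbind, lapply(sess$blocks, `[[`, "continuous"))
  bhat <- t(regress_eog(cont, eog_channels(mont))$coefficients)
  err <- sqrt(sum((bhat - beta_true)^2) / sum(beta_true^2))
  expect_lt(err, 0.05)
})

test_that("low-pass filter is zero-phase with the designed roll-off", {
  sfreq <- 512
  n <- 4096
  t <- seq_len(n) / sfreq
  # DC passes unchanged
  dc <- rep(3.3, n)
  expect_equal(lowpass_zero_phase(dc, sfreq, 25), dc, tolerance = 1e-6)
  # 5 Hz sine: no phase lag (peaks aligned), unit gain
  s5 <- sin(2 * pi * 5 * t)
  f5 <- lowpass_zero_phase(s5, sfreq, 25)
  mid <- 1000:3000
  expect_equal(f5[mid], s5[mid], tolerance = 1e-3)
  # attenuation at 50 Hz matches the squared Butterworth transfer function
  s50 <- sin(2 * pi * 50 * t)
  f50 <- lowpass_zero_phase(s50, sfreq, 25)
  gain <- max(abs(f50[mid])) / max(abs(s50[mid]))
  bf <- signal::butter(4, 25 / (sfreq / 2), type = "low")
  z <- exp(-1i * 2 * pi * 50 / sfreq * (seq_along(bf$b) - 1))
  H <- sum(bf$b * z) / sum(bf$a * z) # transfer function at 50 Hz
  expect_equal(gain, abs(H)^2, tolerance = 0.01) # |H|^2: forward-backward
  expect_lt(gain, 0.01)
  expect_error(lowpass_zero_phase(s5, sfreq, 300), "Nyquist")
})

test_that("epoch extraction follows the sample-count convention and skips edge events", {
  cfg <- simulate_config(seed = 2, n_subjects = 1, tones_per_block = 10)
  mont <- gonogo_montage()
  n <- 7000
  cont <- matrix(0, n, 23)
  colnames(cont) <- mont$channel
  ev <- data.frame(trial = 1:3, block = 1,
                   condition = c("go", "nogo", "go"),
                   onset_sample = c(30, 3000, 6900)) # 1st and 3rd near edges
  expect_warning(eps <- extract_epochs(cont, ev, cfg, mont), "skipped")
  expect_equal(dim(eps$data), c(1, 23, 436))
  # only a NoGo trial survives, so the Go cell is dropped with a warning
  expect_warning(avg <- average_and_downsample(reject_artifacts(eps)),
                 "cell dropped")
  expect_equal(ncol(avg[[1]]$data), 218)
})

test_that("baseline correction zeroes the prestimulus mean and removes constant offsets", {
  cfg <- simulate_config(seed = 4, n_subjects = 1, tones_per_block = 4)
  sess <- simulate_session(cfg, default_component_templates(), "placebo", 1)
  blk <- sess$blocks[[1]]
  ev <- blk$events
  eps <- extract_epochs(blk$continuous, ev, cfg)
  eps$data[2, , ] <- 7.5 # constant-offset epoch
  b <- baseline_correct(eps)
  pre <- b$times_ms < 0
  base_means <- apply(b$data[, , pre, drop = FALSE], c(1, 2), mean)
  expect_equal(max(abs(base_means)), 0, tolerance = 1e-10)
  expect_equal(max(abs(b$data[2, , ])), 0, tolerance = 1e-12)
})

test_that("amplitude artifact rule flags scalp excursions only", {
  cfg <- simulate_config(seed = 4, n_subjects = 1, tones_per_block = 4)
  mont <- gonogo_montage()
  arr <- array(0, dim = c(3, 23, 436))
  dimnames(arr)[[2]] <- mont$channel
  arr[1, which(mont$channel == "Cz"), 100] <- 76 # one sample over threshold
  arr[2, , ] <- 74.9 # everywhere just under
  arr[3, which(mont$channel == "EOGvu"), ] <- 80 # EOG-only excursion
  eps <- new_epoch_set(arr, mont$channel, mont$type == "scalp",
                       erpca:::epoch_times_ms(cfg), 512,
                       data.frame(block = 1, trial = 1:3,
                                  condition = c("go", "go", "nogo")))
  flagged <- reject_artifacts(eps, 75)
  expect_equal(flagged$info$reject_artifact, c(TRUE, FALSE, FALSE))
  expect_error(reject_artifacts(eps, -5), "positive")
})

test_that("behavioral exclusion applies the individual RT bounds", {
  rts <- c(280, 290, 300, 310, 320, 400)
  info <- data.frame(block = 1, trial = 1:8,
                     condition = c(rep("go", 6), "nogo", "go"),
                     responded = c(rep(TRUE, 6), TRUE, FALSE),
                     rt_ms = c(rts, 250, NA))
  arr <- array(0, dim = c(8, 2, 52))
  eps <- new_epoch_set(arr, c("Cz", "Pz"), c(TRUE, TRUE),
                       seq(-99.6, 99, length.out = 52), 512, info)
  out <- select_valid_trials(eps)
  bounds <- attr(out, "rt_bounds")
  expect_equal(unname(bounds["mean"]), 316.6667, tolerance = 1e-4)
  expect_equal(unname(bounds["sd"]), 43.2049, tolerance = 1e-4)
  expect_equal(unname(bounds["lower"]), 251.8594, tolerance = 1e-3)
  expect_equal(unname(bounds["upper"]), 381.4740, tolerance = 1e-3)
  # the 400 ms trial is excluded as delayed; 5 Go trials retained
  expect_equal(out$info$reject_behavior,
               c(rep(FALSE, 5), TRUE, TRUE, TRUE))
  expect_equal(out$info$behavior_reason[6:8],
               c("delayed_rt", "commission", "omission"))
  expect_equal(sum(out$info$condition == "go" & !out$info$reject_behavior), 5)
})

test_that("degenerate RT spread excludes nothing; absent Go RTs are an error", {
  info <- data.frame(block = 1, trial = 1:4, condition = "go",
                     responded = TRUE, rt_ms = rep(300, 4))
  arr <- array(0, dim = c(4, 1, 52))
  eps <- new_epoch_set(arr, "Cz", TRUE, seq(-99.6, 99, length.out = 52),
                       512, info)
  out <- select_valid_trials(eps)
  expect_false(any(out$info$reject_behavior))
  eps$info$responded <- FALSE
  expect_error(select_valid_trials(eps), "no valid Go")
})

test_that("artifact and behavioral flags commute", {
  cfg <- small_config()
  sess <- simulate_session(cfg, default_component_templates(), "placebo", 1)
  blk <- sess$blocks[[1]]
  ev <- blk$events
  ev$block <- 1
  ev$responded <- blk$behavior$responded
  ev$rt_ms <- blk$behavior$rt_ms
  eps <- baseline_correct(extract_epochs(blk$continuous, ev, cfg))
  ab <- select_valid_trials(reject_artifacts(eps, 40))
  ba <- reject_artifacts(select_valid_trials(eps), 40)
  expect_identical(ab$info$reject_artifact, ba$info$reject_artifact)
  expect_identical(ab$info$reject_behavior, ba$info$reject_behavior)
  expect_identical(erpca:::accepted_mask(ab), erpca:::accepted_mask(ba))
})

test_that("averaging yields per-cell means at 256 Hz and full sessions give 4 cells", {
  cfg <- small_config()
  pp <- preprocess_session(simulate_session(cfg, default_component_templates(),
                                            "placebo", 1), keep_epochs = TRUE)
  expect_length(pp$averages, 4) # 2 blocks x 2 conditions per session
  cells <- sapply(pp$averages, function(a) paste(a$block, a$condition))
  expect_setequal(cells, c("1 go", "1 nogo", "2 go", "2 nogo"))
  for (a in pp$averages) {
    expect_equal(dim(a$data), c(19, 218))
    expect_lte(a$n_accepted, cfg$tones_per_block / 2)
  }
  # identical epochs average to any single epoch
  eps <- pp$epochs
  one <- eps$data[rep(1, 4), , ]
  info <- eps$info[rep(1, 4), ]
  info$trial <- 1:4
  info$reject_artifact <- info$reject_behavior <- FALSE
  same <- new_epoch_set(one, eps$channels, eps$scalp, eps$times_ms, 512, info)
  avg <- suppressWarnings(average_and_downsample(same)) # other cells empty
  keep <- seq(1, 436, 2)
  expect_equal(avg[[1]]$data,
               eps$data[1, eps$scalp, keep],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("behavioral exclusion counts match the configured generator rates", {
  cfg <- simulate_config(n_subjects = 1, tones_per_block = 300,
                         omission_rate = 0.05, commission_rate = 0.04,
                         seed = 19)
  pp <- preprocess_session(simulate_session(cfg,
                                            default_component_templates(),
                                            "placebo", 1))
  info <- pp$info
  n_go <- sum(info$condition == "go")
  n_nogo <- sum(info$condition == "nogo")
  p_om <- sum(info$behavior_reason == "omission", na.rm = TRUE) / n_go
  p_co <- sum(info$behavior_reason == "commission", na.rm = TRUE) / n_nogo
  expect_lt(abs(p_om - 0.05), 3 * sqrt(0.05 * 0.95 / n_go))
  expect_lt(abs(p_co - 0.04), 3 * sqrt(0.04 * 0.96 / n_nogo))
  # RT-window exclusions exist but stay modest; artifact rate a few percent
  p_rt <- mean(info$behavior_reason %in% c("fast_rt", "delayed_rt"))
  expect_true(p_rt > 0.02 && p_rt < 0.15)
  expect_lt(mean(info$reject_artifact), 0.10)
})

test_that("filtering commutes with epoching away from the recording edges", {
  cfg <- simulate_config(seed = 8, n_subjects = 1, tones_per_block = 6)
  sess <- simulate_session(cfg, default_component_templates(), "placebo", 1)
  blk <- sess$blocks[[1]]
  ev <- blk$events
  ev$block <- 1
  # (a) filter the whole continuous recording, then epoch
  a <- extract_epochs(lowpass_zero_phase(blk$continuous, cfg$sfreq, 25),
                      ev, cfg)
  # (b) cut generously padded segments, filter each, trim to the epoch
  offs <- erpca:::epoch_offsets(cfg)
  pad <- 256
  inner <- ev[ev$onset_sample + offs[1] - pad >= 1 &
                ev$onset_sample + offs[length(offs)] + pad <=
                nrow(blk$continuous), ]
  for (i in seq_len(nrow(inner))) {
    rows <- inner$onset_sample[i] + (offs[1] - pad):(offs[length(offs)] + pad)
    seg <- lowpass_zero_phase(blk$continuous[rows, ], cfg$sfreq, 25)
    trimmed <- t(seg[pad + seq_along(offs), ])
    j <- which(a$info$trial == inner$trial[i])
    expect_equal(max(abs(a$data[j, , ] - trimmed)), 0, tolerance = 1e-3)
  }
})
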