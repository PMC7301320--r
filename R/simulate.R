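#' Generator configuration for synthetic Go/NoGo crossover sessions
#'
#' Collects every parameter of the synthetic EEG generator: task design,
#' sampling, noise, ocular artifact, reaction-time and behavioral-error
#' models, between-subject amplitude spread, and the master seed. The seed
#' fully determines the generated data.
#'
#' @param n_subjects number of participants (default 24).
#' @param blocks_per_session task blocks per session (default 2).
#' @param tones_per_block tones per block (default 150); must be even when
#'   `go_prop = 0.5`.
#' @param go_prop proportion of Go (target) tones (default 0.5).
#' @param soa_ms fixed stimulus-onset asynchrony in ms (default 1100).
#' @param sfreq sampling rate in Hz (default 512).
#' @param epoch_window epoch limits in ms relative to stimulus onset
#'   (default `c(-100, 750)`); its span must not exceed `soa_ms`.
#' @param ar_coef AR(1) coefficient of the temporal noise model at `sfreq`
#'   (default 0.9).
#' @param noise_sd marginal standard deviation of single-trial EEG noise in
#'   microvolts (default 17).
#' @param spatial_scale length scale (layout units) of the exponential
#'   between-channel noise correlation (default 1).
#' @param blink_rate blink rate per second (default 0.1).
#' @param blink_amp blink source amplitude in microvolts at the upper
#'   vertical EOG channel (default 150).
#' @param ocular_sd amplitude (microvolts) of each EOG channel's
#'   independent ocular activity (default 25).
#' @param eog_sensor_sd EOG sensor noise sd in microvolts (default 5).
#' @param rt_mu,rt_sigma,rt_tau ex-Gaussian reaction-time parameters in ms
#'   (defaults 255, 35, 60; mean 315 ms, sd ~69 ms).
#' @param omission_rate probability of a missed Go response (default 0.021).
#' @param commission_rate probability of a NoGo button press (default 0.014).
#' @param subject_sdlog log-normal sd of the per-subject amplitude factor
#'   (default 0.3).
#' @param component_sdlog log-normal sd of the per-subject, per-component
#'   amplitude factors (default 0.6). These individual differences in
#'   single component expression are constant across a subject's two
#'   sessions and make the components' case amplitudes vary
#'   semi-independently, as in real ERP data; 0 disables them.
#' @param component_block_sdlog log-normal sd of per-block state
#'   fluctuations in each component's amplitude (default 0.25; 0
#'   disables them).
#' @param reject_uv artifact rejection threshold in microvolts (default 75).
#' @param drug_labels the two arms of the crossover
#'   (fixed design: `c("placebo", "caffeine")`).
#' @param seed master seed (positive integer).
#' @return a validated list of class `gonogo_config`.
#' @export
simulate_config <- function(n_subjects = 24, blocks_per_session = 2,
                            tones_per_block = 150, go_prop = 0.5,
                            soa_ms = 1100, sfreq = 512,
                            epoch_window = c(-100, 750),
                            ar_coef = 0.9, noise_sd = 17, spatial_scale = 1,
                            blink_rate = 0.1, blink_amp = 150,
                            ocular_sd = 25, eog_sensor_sd = 5,
                            rt_mu = 255, rt_sigma = 35, rt_tau = 60,
                            omission_rate = 0.021, commission_rate = 0.014,
                            subject_sdlog = 0.3, component_sdlog = 0.6,
                            component_block_sdlog = 0.25, reject_uv = 75,
                            drug_labels = c("placebo", "caffeine"),
                            seed = 1L) {
  cfg <- list(n_subjects = n_subjects, blocks_per_session = blocks_per_session,
              tones_per_block = tones_per_block, go_prop = go_prop,
              soa_ms = soa_ms, sfreq = sfreq, epoch_window = epoch_window,
              ar_coef = ar_coef, noise_sd = noise_sd,
              spatial_scale = spatial_scale, blink_rate = blink_rate,
              blink_amp = blink_amp, ocular_sd = ocular_sd,
              eog_sensor_sd = eog_sensor_sd, rt_mu = rt_mu,
              rt_sigma = rt_sigma, rt_tau = rt_tau,
              omission_rate = omission_rate,
              commission_rate = commission_rate,
              subject_sdlog = subject_sdlog,
              component_sdlog = component_sdlog,
              component_block_sdlog = component_block_sdlog,
              reject_uv = reject_uv,
              drug_labels = drug_labels, seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "gonogo_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$go_prop < 0 || cfg$go_prop > 1) {
    stop_input("go_prop must lie in [0, 1]")
  }
  rates <- c(cfg$omission_rate, cfg$commission_rate)
  if (any(rates < 0 | rates > 1)) stop_input("error rates must lie in [0, 1]")
  if (cfg$go_prop == 0.5 && cfg$tones_per_block %% 2 != 0) {
    stop_input("tones_per_block must be even when go_prop = 0.5")
  }
  if (diff(cfg$epoch_window) > cfg$soa_ms) {
    stop_input("epoch window (%g ms) exceeds the SOA (%g ms)",
               diff(cfg$epoch_window), cfg$soa_ms)
  }
  if (length(cfg$drug_labels) != 2) {
    stop_input("the design is a 2-level crossover; got %d drug labels",
               length(cfg$drug_labels))
  }
  if (cfg$n_subjects < 1 || cfg$tones_per_block < 1) {
    stop_input("n_subjects and tones_per_block must be positive")
  }
  invisible(cfg)
}

# epoch sample offsets relative to the onset sample: left-closed grid with
# 436 samples for -100..750 ms at 512 Hz (-99.6 .. 750.0 ms)
epoch_offsets <- function(cfg) {
  lo <- as.integer(ceiling(cfg$epoch_window[1] * cfg$sfreq / 1000))
  n <- floor(diff(cfg$epoch_window) * cfg$sfreq / 1000) + 1L
  seq(lo, length.out = n)
}

epoch_times_ms <- function(cfg) epoch_offsets(cfg) * 1000 / cfg$sfreq

#' Simulate one block's randomized tone sequence
#'
#' Draws the within-block random order of Go and NoGo tones with a fixed
#' stimulus-onset asynchrony. The Go count is `round(go_prop * tones)`.
#'
#' @param config a `gonogo_config`.
#' @param block block index (1-based).
#' @param subject,drug identify the sub-stream so each block of each
#'   session gets its own deterministic sequence.
#' @return a data.frame with columns `trial`, `tone_hz`, `condition`
#'   (`"go"`/`"nogo"`), `is_target`, `onset_ms`, `onset_sample`.
#' @export
simulate_task_sequence <- function(config, block = 1, subject = 1,
                                   drug = "placebo") {
  validate_config(config)
  n <- config$tones_per_block
  n_go <- round(config$go_prop * n)
  didx <- match(drug, config$drug_labels)
  if (is.na(didx)) stop_input("unknown drug label '%s'", drug)
  cond <- with_seed(derive_seed(config$seed, subject, didx, block, 1), {
    sample(rep(c("go", "nogo"), c(n_go, n - n_go)))
  })
  onset_ms <- (seq_len(n) - 1) * config$soa_ms
  pad <- -epoch_offsets(config)[1] + 1L # samples before the first onset
  data.frame(trial = seq_len(n),
             tone_hz = ifelse(cond == "go", 1000, 1500),
             condition = cond,
             is_target = cond == "go",
             onset_ms = onset_ms,
             onset_sample = pad + round(onset_ms * config$sfreq / 1000),
             stringsAsFactors = FALSE)
}

# spatial mixing matrix for scalp noise: exp(-d / scale) channel correlation
scalp_mixing <- function(montage, scale) {
  sc <- montage[montage$type == "scalp", ]
  d <- as.matrix(stats::dist(cbind(sc$x, sc$y)))
  C <- exp(-d / scale)
  t(chol(C))
}

# AR(1) noise matrix (n x k), marginal sd `sd`
ar1_noise <- function(n, k, phi, sd) {
  innov_sd <- sd * sqrt(1 - phi^2)
  w <- matrix(stats::rnorm(n * k, sd = innov_sd), n, k)
  apply(w, 2, function(col) as.numeric(stats::filter(col, phi, "recursive")))
}

# frontally weighted blink propagation coefficients (scalp x EOG channels)
blink_propagation <- function(montage) {
  sc <- montage[montage$type == "scalp", ]
  p <- exp(-((sc$x - 0)^2 + (sc$y - 1.05)^2) / (2 * 0.7^2))
  beta <- cbind(EOGvu = 0.40 * p, EOGvl = -0.15 * p,
                EOGhl = 0.05 * p * pmax(-sc$x, 0),
                EOGhr = 0.05 * p * pmax(sc$x, 0))
  rownames(beta) <- sc$channel
  beta
}

# smooth blink source time course: unit-amplitude Gaussians at blink times
blink_source <- function(n_samples, sfreq, rate, seed) {
  with_seed(seed, {
    n_blinks <- stats::rpois(1, rate * n_samples / sfreq)
    s <- numeric(n_samples)
    if (n_blinks > 0) {
      at <- sort(stats::runif(n_blinks, 1, n_samples))
      width <- 0.040 * sfreq # 40 ms sd
      idx <- seq_len(n_samples)
      for (a in at) s <- s + exp(-((idx - a)^2) / (2 * width^2))
    }
    s
  })
}

#' Simulate one subject's session (one drug arm, all blocks)
#'
#' Produces continuous 23-channel recordings (19 scalp + 4 EOG) per block,
#' trial events, per-trial behavior, and the planted ground truth. The
#' clean signal of each trial is the sum over templates of temporal shape x
#' topographic weight x condition multiplier x drug multiplier x subject
#' factor; spatially correlated AR(1) noise, blink/ocular activity on the
#' EOG channels, and their frontally weighted propagation to the scalp are
#' added on top.
#'
#' @param config a `gonogo_config`.
#' @param templates list of `erp_component_template`s.
#' @param drug `"placebo"` or `"caffeine"` (must be one of
#'   `config$drug_labels`).
#' @param subject subject index.
#' @param montage an `erp_montage`.
#' @param subject_factor multiplicative subject amplitude factor; by
#'   default drawn log-normally (same value in both arms of a subject).
#' @return an object of class `gonogo_session`: a list with `blocks`
#'   (each `continuous` matrix (samples x channels), `events`, `behavior`),
#'   and `ground_truth` (templates, subject factor, EOG propagation
#'   coefficients, noiseless per-condition epoch signals).
#' @export
simulate_session <- function(config, templates = default_component_templates(),
                             drug = "placebo", subject = 1,
                             montage = gonogo_montage(),
                             subject_factor = NULL) {
  validate_config(config)
  didx <- match(drug, config$drug_labels)
  if (is.na(didx)) stop_input("unknown drug label '%s'", drug)
  if (is.null(subject_factor)) {
    subject_factor <- subject_amplitude_factors(config)[subject]
  }
  comp_f <- component_amplitude_factors(config, templates, subject)
  sc_names <- scalp_channels(montage)
  eog_names <- eog_channels(montage)
  n_scalp <- length(sc_names)
  mix <- scalp_mixing(montage, config$spatial_scale)
  beta <- blink_propagation(montage)[, eog_names, drop = FALSE]

  # signal segment per condition covering one SOA around each onset
  seg_off <- seq(epoch_offsets(config)[1],
                 length.out = round(config$soa_ms * config$sfreq / 1000))
  seg_t <- seg_off * 1000 / config$sfreq
  drg <- if (didx == 1) "placebo" else "caffeine"

  blocks <- vector("list", config$blocks_per_session)
  block_factors <- vector("list", config$blocks_per_session)
  for (b in seq_len(config$blocks_per_session)) {
    bsd <- config$component_block_sdlog %||% 0
    h <- if (bsd > 0) {
      with_seed(derive_seed(config$seed, subject, didx, b, 7), {
        stats::setNames(exp(stats::rnorm(length(comp_f), -bsd^2 / 2, bsd)),
                        names(comp_f))
      })
    } else stats::setNames(rep(1, length(comp_f)), names(comp_f))
    block_factors[[b]] <- h
    seg <- list(go = t(template_signal(templates, seg_t, "go", drg,
                                       subject_factor,
                                       comp_f * h))[, sc_names, drop = FALSE],
                nogo = t(template_signal(templates, seg_t, "nogo", drg,
                                         subject_factor,
                                         comp_f * h))[, sc_names,
                                                      drop = FALSE])
    ev <- simulate_task_sequence(config, b, subject, drug)
    n_samples <- max(ev$onset_sample) + max(seg_off) + 1L
    seed_b <- derive_seed(config$seed, subject, didx, b, 2)
    cont <- with_seed(seed_b, {
      noise <- ar1_noise(n_samples, n_scalp, config$ar_coef,
                         config$noise_sd) %*% t(mix)
      colnames(noise) <- sc_names
      # EOG channels: shared blink source + independent ocular + sensor noise
      sv <- blink_source(n_samples, config$sfreq, config$blink_rate,
                         derive_seed(config$seed, subject, didx, b, 3))
      gains <- c(EOGvu = 1, EOGvl = -0.6, EOGhl = 0.12, EOGhr = 0.12)
      eog <- outer(sv * config$blink_amp, gains) +
        ar1_noise(n_samples, length(eog_names), 0.95, config$ocular_sd) +
        matrix(stats::rnorm(n_samples * length(eog_names),
                            sd = config$eog_sensor_sd),
               n_samples, length(eog_names))
      colnames(eog) <- eog_names
      scalp <- noise + eog %*% t(beta)
      for (i in seq_len(nrow(ev))) {
        rows <- ev$onset_sample[i] + seg_off
        scalp[rows, ] <- scalp[rows, ] + seg[[ev$condition[i]]]
      }
      cbind(scalp, eog)
    })
    beh <- with_seed(derive_seed(config$seed, subject, didx, b, 4), {
      responded <- ifelse(ev$condition == "go",
                          stats::runif(nrow(ev)) > config$omission_rate,
                          stats::runif(nrow(ev)) < config$commission_rate)
      rt <- rep(NA_real_, nrow(ev))
      rt[responded] <- rexgauss(sum(responded), config$rt_mu,
                                config$rt_sigma, config$rt_tau)
      data.frame(block = b, trial = ev$trial, condition = ev$condition,
                 responded = responded, rt_ms = rt)
    })
    blocks[[b]] <- list(continuous = cont, events = ev, behavior = beh)
  }

  ep_t <- epoch_times_ms(config)
  gt_clean <- list(
    go = template_signal(templates, ep_t, "go", drg, subject_factor,
                         comp_f)[sc_names, , drop = FALSE],
    nogo = template_signal(templates, ep_t, "nogo", drg, subject_factor,
                           comp_f)[sc_names, , drop = FALSE])
  structure(list(subject = subject, drug = drug, config = config,
                 montage = montage, blocks = blocks,
                 ground_truth = list(templates = templates,
                                     subject_factor = subject_factor,
                                     component_factors = comp_f,
                                     block_factors = block_factors,
                                     eog_propagation = beta,
                                     clean_epoch = gt_clean,
                                     epoch_times_ms = ep_t)),
            class = "gonogo_session")
}

#' Per-subject, per-component amplitude factors
#'
#' Individual differences in the expression of single components:
#' log-normal factors (sd `component_sdlog`), drawn once per subject and
#' template label, identical in both arms of the crossover.
#'
#' @param config a `gonogo_config`.
#' @param templates template library (defines the labels).
#' @param subject subject index.
#' @return named numeric vector of factors, one per template.
#' @export
component_amplitude_factors <- function(config, templates, subject) {
  sdl <- config$component_sdlog %||% 0
  labs <- vapply(templates, `[[`, "", "label")
  if (sdl == 0) {
    return(stats::setNames(rep(1, length(labs)), labs))
  }
  with_seed(derive_seed(config$seed, subject, 0, 0, 6), {
    stats::setNames(exp(stats::rnorm(length(labs), -sdl^2 / 2, sdl)), labs)
  })
}

#' Per-subject log-normal amplitude factors
#'
#' @param config a `gonogo_config`.
#' @return numeric vector of length `n_subjects`, deterministic in the seed.
#' @export
subject_amplitude_factors <- function(config) {
  with_seed(derive_seed(config$seed, 0, 0, 0, 5), {
    exp(stats::rnorm(config$n_subjects, -config$subject_sdlog^2 / 2,
                     config$subject_sdlog))
  })
}

#' Simulate a full crossover study
#'
#' Generates every subject x drug session. Intended for small designs in
#' tests and examples; `run_pipeline()` streams subjects one at a time to
#' bound memory for full-size studies.
#'
#' @inheritParams simulate_session
#' @return list with `sessions[[subject]][[drug]]` and `subject_factors`.
#' @export
simulate_study <- function(config, templates = default_component_templates(),
                           montage = gonogo_montage()) {
  f <- subject_amplitude_factors(config)
  sessions <- lapply(seq_len(config$n_subjects), function(s) {
    out <- lapply(config$drug_labels, function(d) {
      simulate_session(config, templates, d, s, montage, f[s])
    })
    names(out) <- config$drug_labels
    out
  })
  list(sessions = sessions, subject_factors = f)
}

#' Expected per-average measurement noise of a component amplitude
#'
#' Standard deviation (microvolts) of the noise remaining in a per-subject
#' component amplitude after averaging the accepted trials of all blocks:
#' `noise_sd / sqrt(expected accepted trials per condition and session)`.
#' Used by the amplitude-level simulation mode.
#'
#' @param config a `gonogo_config`.
#' @param acceptance expected acceptance fraction (default 0.88, the
#'   approximate Go acceptance under the default behavioral model).
#' @return numeric scalar in microvolts.
#' @export
measurement_noise_sd <- function(config, acceptance = 0.88) {
  n_avg <- config$go_prop * config$tones_per_block *
    config$blocks_per_session * acceptance
  config$noise_sd / sqrt(n_avg)
}

#' Amplitude-level simulation of component measurements
#'
#' Draws per-subject, per-drug component amplitude tables over a 9-site
#' grid directly at the measurement level: planted topography x subject
#' factor x drug multiplier plus Gaussian measurement noise whose sd is
#' derived from the generator's single-trial noise via
#' [measurement_noise_sd()]. This mode exists so that statistical
#' calibration (type-I error, power) can use thousands of replicates.
#'
#' @param config a `gonogo_config`.
#' @param template the planted `erp_component_template`.
#' @param grid 3 x 3 site grid (see [site_grid()]).
#' @param condition `"go"` or `"nogo"`.
#' @param caffeine_mult drug multiplier applied in the caffeine arm
#'   (1 = null).
#' @param seed replicate seed.
#' @return array `subject x drug x site` of amplitudes in microvolts.
#' @export
simulate_component_amplitudes <- function(config, template,
                                          grid = site_grid(),
                                          condition = "go",
                                          caffeine_mult = 1, seed = 1L) {
  sites <- as.vector(t(grid))
  topo <- template_signed_topography(template)[sites] * template$amplitude_uv *
    sign(template$amplitude_uv) * template[[condition]]
  # i.e. amplitude_uv * topography at the grid sites, for this condition
  sd_meas <- measurement_noise_sd(config)
  n <- config$n_subjects
  sdl <- sqrt(config$subject_sdlog^2 + (config$component_sdlog %||% 0)^2 +
                (config$component_block_sdlog %||% 0)^2 /
                  config$blocks_per_session)
  with_seed(seed, {
    f <- exp(stats::rnorm(n, -sdl^2 / 2, sdl))
    arr <- array(NA_real_, dim = c(n, 2, length(sites)),
                 dimnames = list(NULL, config$drug_labels, sites))
    for (d in 1:2) {
      mult <- if (d == 2) caffeine_mult else 1
      arr[, d, ] <- outer(f * mult, topo) +
        matrix(stats::rnorm(n * length(sites), sd = sd_meas), n)
    }
    arr
  })
}
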