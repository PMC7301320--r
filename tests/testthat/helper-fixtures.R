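# shared fixtures and independent oracles; expensive objects are computed
# once per test run and cached

.fixtures <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# a small, fast study configuration for structural tests
small_config <- function(...) {
  simulate_config(n_subjects = 3, tones_per_block = 16, seed = 5, ...)
}

# a noise-free configuration: deterministic planted signal only
clean_config <- function(...) {
  simulate_config(n_subjects = 2, tones_per_block = 8, noise_sd = 0,
                  blink_rate = 0, ocular_sd = 0, eog_sensor_sd = 0,
                  subject_sdlog = 0, component_sdlog = 0,
                  component_block_sdlog = 0, omission_rate = 0,
                  commission_rate = 0, seed = 9, ...)
}

# full-size default study (24 subjects, 150 tones), preprocessed and
# decomposed; shared by the reconstitution, split-half, regression and
# recovery checks
default_run <- function() {
  cache_get("default_run", run_pipeline(simulate_config(seed = 101)))
}

# placebo Go decomposition only, for the parameter-recovery suite
recovery_go_pca <- function(seed) {
  cache_get(paste0("recovery_go_", seed), {
    if (seed == 101) {
      res <- default_run()
      list(pca = res$pca$placebo_go,
           cm = build_case_matrix(res$averages, "placebo", "go"))
    } else {
      cfg <- simulate_config(seed = seed)
      tpl <- default_component_templates()
      mont <- gonogo_montage()
      f <- subject_amplitude_factors(cfg)
      entries <- lapply(seq_len(cfg$n_subjects), function(s) {
        sess <- simulate_session(cfg, tpl, "placebo", s, mont, f[s])
        list(subject = s, drug = "placebo",
             averages = preprocess_session(sess)$averages)
      })
      avg <- build_average_set(entries, scalp_channels(mont),
                               attr(entries[[1]]$averages, "times_ms"))
      cm <- build_case_matrix(avg, "placebo", "go")
      list(pca = erp_pca(cm), cm = cm)
    }
  })
}

# best absolute temporal congruence between a planted template and any of
# the first `k` factors of a decomposition
best_temporal_recovery <- function(pca, template, k = 12) {
  shape <- template_waveform(template, pca$times_ms)
  max(apply(pca$loadings[, seq_len(min(k, ncol(pca$loadings))), drop = FALSE],
            2, function(L) abs(tucker_congruence(L, shape))))
}

best_recovery_factor <- function(pca, template, k = 12) {
  shape <- template_waveform(template, pca$times_ms)
  cc <- apply(pca$loadings[, seq_len(min(k, ncol(pca$loadings))),
                           drop = FALSE],
              2, function(L) abs(tucker_congruence(L, shape)))
  which.max(cc)
}

# ---- independent oracles -------------------------------------------------

# brute-force repeated-measures contrast F: per-subject scores recomputed
# with explicit loops, F from the intercept t of lm()
oracle_contrast_F <- function(amps, spec) {
  coefs <- as.vector(t(spec$cells))
  n <- if (length(dim(amps)) == 3) dim(amps)[1] else nrow(amps)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_along(coefs)) {
      acc <- acc + coefs[j] *
        (if (length(dim(amps)) == 3) {
          amps[i, "caffeine", j] - amps[i, "placebo", j]
        } else amps[i, j])
    }
    scores[i] <- acc
  }
  fit <- summary(stats::lm(scores ~ 1))
  unname(fit$coefficients[1, "t value"]^2)
}

# grid-search oracle for the 2-factor Varimax rotation angle
oracle_varimax_angle <- function(L, step = 0.01 * pi / 180) {
  stopifnot(ncol(L) == 2)
  angles <- seq(0, pi / 2, by = step)
  crit <- vapply(angles, function(a) {
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    varimax_criterion(L %*% R)
  }, 0)
  angles[which.max(crit)]
}

# 2-factor loading matrix in perfect simple structure, then mixed by a
# known rotation angle
make_mixed_loadings <- function(angle, n = 40) {
  L0 <- cbind(c(stats::dnorm(seq(-3, 3, length.out = n)), rep(0, n)),
              c(rep(0, n), stats::dnorm(seq(-3, 3, length.out = n))))
  R <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2, 2)
  list(true = L0, mixed = L0 %*% R, angle = angle)
}

# minimal erp_pca-shaped object for rule-level tests (selection, labelling)
fake_pca <- function(pct, labels = NULL, loadings = NULL, scores = NULL,
                     keys = NULL, peaks = NULL, times = NULL,
                     tag = c(drug = "placebo", condition = "go")) {
  nf <- length(pct)
  structure(list(pct_variance = pct, labels = labels,
                 loadings = loadings, scores = scores, keys = keys,
                 peak_latency_ms = peaks, times_ms = times,
                 selected = NULL, tag = tag,
                 total_variance = 100, n_cases = if (!is.null(scores))
                   nrow(scores) else 0),
            class = "erp_pca")
}

# synthetic average set with the paper's design dimensions but dummy data
dummy_average_set <- function(n_subjects, blocks = 2, seed = 1) {
  mont <- gonogo_montage()
  chs <- scalp_channels(mont)
  times <- seq(-99.6, 750, length.out = 218)
  set.seed(seed)
  entries <- list()
  for (s in seq_len(n_subjects)) for (d in c("placebo", "caffeine")) {
    cells <- list()
    for (b in seq_len(blocks)) for (cond in c("go", "nogo")) {
      cells[[length(cells) + 1L]] <-
        list(block = b, condition = cond,
             data = matrix(rnorm(19 * 218), 19, 218,
                           dimnames = list(chs, NULL)),
             n_accepted = 70, times_ms = times)
    }
    entries[[length(entries) + 1L]] <-
      list(subject = s, drug = d,
           averages = structure(cells, times_ms = times))
  }
  build_average_set(entries, chs, times,
                    blocks = as.character(seq_len(blocks)))
}

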