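#' Run the full condition-wise temporal-PCA pipeline
#'
#' Executes the whole analysis on a simulated crossover study: per-subject
#' session simulation, preprocessing to average ERPs, the four separate
#' temporal PCAs (placebo/caffeine x Go/NoGo), component selection and
#' labelling (placebo floors first, caffeine with the fallback rule),
#' cross-drug component matching, reconstitution checks, the two-step
#' planned-contrast statistics per matched component, and the behavioral
#' test battery. Subjects are streamed one at a time so full-size studies
#' stay within memory.
#'
#' @param config a `gonogo_config` (the seed fully determines the run).
#' @param templates planted component library.
#' @param montage an `erp_montage`.
#' @param floor,fallback component selection floors in percent variance.
#' @param alpha significance level for the defining topography.
#' @param cutoff_hz low-pass cutoff (default 25).
#' @param out_dir if non-NULL, result tables are written there as CSV/JSON.
#' @param verbose print progress.
#' @return an object of class `gonogo_pipeline` (a list with `config`,
#'   `averages`, `pca` (list by drug/condition tag), `matches`,
#'   `contrasts`, `reconstitution`, `behavior`, `behavior_tests`,
#'   `eog_recovery`).
#' @export
run_pipeline <- function(config = simulate_config(),
                         templates = default_component_templates(),
                         montage = gonogo_montage(),
                         floor = 2, fallback = 1, alpha = 0.05,
                         cutoff_hz = 25, out_dir = NULL, verbose = FALSE) {
  validate_config(config)
  if (!identical(sort(config$drug_labels), sort(c("placebo", "caffeine")))) {
    stop_input("the pipeline analyzes a placebo/caffeine crossover; got: %s",
               paste(config$drug_labels, collapse = ", "))
  }
  f <- subject_amplitude_factors(config)
  entries <- list()
  logs <- list()
  eog_err <- numeric(0)
  beta_true <- blink_propagation(montage)
  for (s in seq_len(config$n_subjects)) {
    for (drug in config$drug_labels) {
      if (verbose) message(sprintf("subject %d, %s", s, drug))
      sess <- simulate_session(config, templates, drug, s, montage, f[s])
      pp <- preprocess_session(sess, cutoff_hz = cutoff_hz)
      entries[[length(entries) + 1L]] <-
        list(subject = s, drug = drug, averages = pp$averages)
      li <- pp$info[, c("block", "condition", "responded", "rt_ms")]
      li$subject <- s
      li$drug <- drug
      logs[[length(logs) + 1L]] <- li
      bhat <- t(pp$eog_coefficients) # scalp x eog
      eog_err <- c(eog_err, sqrt(sum((bhat - beta_true)^2) /
                                   sum(beta_true^2)))
    }
  }
  times <- attr(entries[[1]]$averages, "times_ms")
  avg <- build_average_set(entries, scalp_channels(montage), times,
                           config$drug_labels,
                           as.character(seq_len(config$blocks_per_session)))
  pcas <- list()
  matches <- list()
  contrasts <- list()
  recon <- list()
  for (cond in c("go", "nogo")) {
    cm_p <- build_case_matrix(avg, "placebo", cond)
    pca_p <- erp_pca(cm_p)
    pca_p <- select_components(pca_p, floor = floor, fallback = fallback)
    pca_p <- label_components(pca_p, templates, which = "selected")
    cm_c <- build_case_matrix(avg, "caffeine", cond)
    pca_c <- erp_pca(cm_c)
    pca_c$selected <- pca_c$pct_variance >= floor # provisional, for labelling
    pca_c <- label_components(pca_c, templates, which = "all",
                              min_pct = fallback)
    pca_c <- select_components(pca_c, floor = floor, fallback = fallback,
                               reference = pca_p)
    pcas[[paste0("placebo_", cond)]] <- pca_p
    pcas[[paste0("caffeine_", cond)]] <- pca_c
    recon[[paste0("placebo_", cond)]] <-
      reconstitute(pca_p, cm_p)$correlations
    recon[[paste0("caffeine_", cond)]] <-
      reconstitute(pca_c, cm_c)$correlations
    mt <- match_components(pca_p, pca_c)
    matches[[cond]] <- mt
    if (nrow(mt)) {
      for (i in which(mt$class != "unmatched")) {
        lb <- mt$label[i]
        grid <- site_grid(montage, if (lb == "PN") "temporal" else "core")
        sites <- as.vector(t(grid))
        mp <- component_amplitude_map(pca_p, mt$placebo_factor[i], sites)
        mc <- component_amplitude_map(pca_c, mt$caffeine_factor[i], sites)
        amps <- array(NA_real_, dim = c(nrow(mp), 2, length(sites)),
                      dimnames = list(rownames(mp),
                                      c("placebo", "caffeine"), sites))
        amps[, "placebo", ] <- mp
        amps[, "caffeine", ] <- mc
        contrasts[[paste(cond, lb)]] <-
          c(list(condition = cond, label = lb, amplitudes = amps),
            component_contrast_analysis(amps, grid, alpha))
      }
    }
  }
  behavior_log <- do.call(rbind, logs)
  behavior <- summarize_behavior(behavior_log)
  res <- structure(list(config = config, templates = templates,
                        montage = montage, averages = avg, pca = pcas,
                        matches = matches, contrasts = contrasts,
                        reconstitution = recon,
                        behavior = behavior,
                        behavior_tests = behavioral_tests(behavior),
                        behavior_log = behavior_log,
                        eog_recovery = eog_err,
                        subject_factors = f),
                   class = "gonogo_pipeline")
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @export
print.gonogo_pipeline <- function(x, ...) {
  cat(sprintf("Go/NoGo temporal-PCA pipeline: %d subjects, seed %d\n",
              x$config$n_subjects, x$config$seed))
  for (cond in c("go", "nogo")) {
    p <- x$pca[[paste0("placebo_", cond)]]
    sel <- which(p$selected)
    cat(sprintf("\n%s placebo PCA: %d selected components (%.1f%% variance):\n",
                toupper(cond), length(sel), sum(p$pct_variance[sel])))
    print(data.frame(label = p$labels[sel],
                     pct = round(p$pct_variance[sel], 1),
                     peak_ms = round(p$peak_latency_ms[sel])),
          row.names = FALSE)
    if (nrow(x$matches[[cond]])) {
      cat(sprintf("%s matches: %s\n", cond,
                  paste(sprintf("%s (%s)", x$matches[[cond]]$label,
                                x$matches[[cond]]$class), collapse = ", ")))
    }
  }
  sig <- unlist(lapply(x$contrasts, function(cc) {
    sum(cc$drug$p < 0.05)
  }))
  cat(sprintf("\nDrug contrasts with p < 0.05: %d across %d components\n",
              sum(sig), length(x$contrasts)))
  invisible(x)
}

#' Write pipeline result tables
#'
#' Writes the variance/selection table per PCA, loadings, match tables,
#' contrast tables, reconstitution correlations, behavioral summary and
#' tests, and the configuration (JSON) into a directory. Re-running the
#' pipeline with the same config and seed regenerates identical files.
#'
#' @param result a `gonogo_pipeline`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  for (nm in names(result$pca)) {
    p <- result$pca[[nm]]
    utils::write.csv(data.frame(factor = colnames(p$loadings),
                                pct_variance = p$pct_variance,
                                peak_ms = p$peak_latency_ms,
                                label = p$labels %||% NA,
                                selected = p$selected %||% NA),
                     file.path(dir, paste0("variance_", nm, ".csv")),
                     row.names = FALSE)
    sel <- which(p$selected %||% logical(0))
    if (length(sel)) {
      ld <- data.frame(time_ms = p$times_ms, p$loadings[, sel, drop = FALSE])
      names(ld)[-1] <- p$labels[sel]
      utils::write.csv(ld, file.path(dir, paste0("loadings_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  for (cond in names(result$matches)) {
    utils::write.csv(result$matches[[cond]],
                     file.path(dir, paste0("match_", cond, ".csv")),
                     row.names = FALSE)
  }
  ctr <- do.call(rbind, lapply(result$contrasts, function(cc) {
    top <- cc$topography
    top$step <- "placebo_topography"
    top$sided <- "two"
    top$rule <- NA_character_
    drg <- cc$drug
    drg$step <- "caffeine_effect"
    out <- rbind(top, drg)
    out$condition <- cc$condition
    out$component <- cc$label
    out
  }))
  if (!is.null(ctr)) {
    utils::write.csv(ctr, file.path(dir, "contrasts.csv"), row.names = FALSE)
  }
  rec <- do.call(rbind, lapply(names(result$reconstitution), function(nm) {
    data.frame(pca = nm, channel = names(result$reconstitution[[nm]]),
               correlation = as.numeric(result$reconstitution[[nm]]))
  }))
  utils::write.csv(rec, file.path(dir, "reconstitution.csv"), row.names = FALSE)
  utils::write.csv(result$behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  utils::write.csv(result$behavior_tests,
                   file.path(dir, "behavior_tests.csv"), row.names = FALSE)
  invisible(dir)
}
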