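#' Planned topographic (and drug) contrast specifications
#'
#' Builds the planned single-df contrasts over the 3 x 3 site grid:
#' sagittal mains F>P (frontal vs parietal) and C>F/P (central vs the
#' frontoparietal mean), lateral mains L>R and M>L/R (midline vs the
#' hemispheric mean), their four products, and, with `drug = TRUE`, the
#' Drug main effect and Drug x each topographic term. Main-effect cell
#' coefficients are the row/column weights averaged over the other factor
#' (so F>P is +1/3 per frontal cell and -1/3 per parietal cell);
#' interaction coefficients are the elementwise products of the two main
#' coefficient maps. Every coefficient map sums to zero.
#'
#' @param grid 3 x 3 site grid from [site_grid()].
#' @param drug include the drug terms (default TRUE).
#' @return list of contrast specs, each with `name`, `cells` (3 x 3
#'   coefficient matrix), `drug` (does the contrast involve the drug
#'   factor) and `type` (`"global"`, `"topographic"`, `"drug_topographic"`).
#' @export
build_contrasts <- function(grid = site_grid(), drug = TRUE) {
  sag <- list(`F>P` = c(1, 0, -1), `C>F/P` = c(-0.5, 1, -0.5))
  lat <- list(`L>R` = c(1, 0, -1), `M>L/R` = c(-0.5, 1, -0.5))
  cellmat <- function(rw, cw) outer(rw, cw)
  specs <- list()
  mains <- list()
  for (sn in names(sag)) {
    m <- cellmat(sag[[sn]], rep(1 / 3, 3))
    mains[[sn]] <- m
    specs[[sn]] <- list(name = sn, cells = m, drug = FALSE,
                        type = "topographic")
  }
  for (ln in names(lat)) {
    m <- cellmat(rep(1 / 3, 3), lat[[ln]])
    mains[[ln]] <- m
    specs[[ln]] <- list(name = ln, cells = m, drug = FALSE,
                        type = "topographic")
  }
  for (sn in names(sag)) for (ln in names(lat)) {
    nm <- paste(sn, "x", ln)
    specs[[nm]] <- list(name = nm, cells = mains[[sn]] * mains[[ln]],
                        drug = FALSE, type = "topographic")
  }
  if (drug) {
    topo_names <- names(specs)
    specs[["Drug"]] <- list(name = "Drug", cells = matrix(1 / 9, 3, 3),
                            drug = TRUE, type = "global")
    for (nm in topo_names) {
      dn <- paste("Drug x", nm)
      specs[[dn]] <- list(name = dn, cells = specs[[nm]]$cells, drug = TRUE,
                          type = "drug_topographic", topo = nm)
    }
  }
  for (nm in names(specs)) {
    dimnames(specs[[nm]]$cells) <- dimnames(grid)
    specs[[nm]]$sites <- grid
  }
  specs
}

#' Test one planned contrast on a component amplitude table
#'
#' Computes per-subject contrast scores (the coefficient-weighted cell
#' sums; for drug terms the caffeine-minus-placebo difference map is
#' used), then the repeated-measures F as the squared one-sample t on the
#' scores, with df = (1, n-1), a two-sided p, and partial eta-squared
#' `F / (F + df_error)`.
#'
#' @param amps for non-drug contrasts a subject x 9 matrix (columns in
#'   row-major grid order); for drug contrasts a subject x drug x 9 array
#'   with drug levels `placebo`, `caffeine`.
#' @param spec one element of [build_contrasts()].
#' @return a one-row data.frame of class `contrast_result` with the
#'   per-subject `scores` attached as an attribute.
#' @export
contrast_test <- function(amps, spec) {
  coefs <- as.vector(t(spec$cells)) # row-major: matches site order
  if (spec$drug) {
    if (length(dim(amps)) != 3) {
      stop_input("drug contrasts need a subject x drug x site array")
    }
    if (any(is.na(amps))) stop_input("missing cells in the amplitude table")
    diffmap <- amps[, "caffeine", ] - amps[, "placebo", ]
    scores <- as.numeric(diffmap %*% coefs)
  } else {
    amps <- as.matrix(amps)
    if (any(is.na(amps))) stop_input("missing cells in the amplitude table")
    scores <- as.numeric(amps %*% coefs)
  }
  n <- length(scores)
  if (n < 2) stop_input("need at least 2 subjects")
  # round-off guard: scores that vanish at machine precision are zero
  eps <- max(abs(amps), 1) * length(coefs) * .Machine$double.eps * 32
  if (max(abs(scores)) < eps) scores[] <- 0
  m <- mean(scores)
  s <- stats::sd(scores)
  if (s < eps) s <- 0
  t <- if (s == 0) {
    if (abs(m) < eps) 0 else sign(m) * Inf
  } else m / (s / sqrt(n))
  Fv <- t^2
  df2 <- n - 1L
  p <- 2 * stats::pt(-abs(t), df2)
  out <- data.frame(contrast = spec$name, estimate = m, t = t, F = Fv,
                    df1 = 1L, df2 = df2, p = p, sided = "two",
                    eta_p2 = if (is.infinite(Fv)) 1 else Fv / (Fv + df2),
                    stringsAsFactors = FALSE)
  attr(out, "scores") <- scores
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Apply the directional (one-sided) testing rules to drug contrasts
#'
#' Observed increases in the global (Drug main) effect or in interactions
#' of Drug with the component's defining topography (the significant
#' placebo-condition contrasts) are tested one-sided (p halved);
#' unpredicted decreases and non-defining interactions keep their
#' two-sided p. The predicted direction of each term is the sign of the
#' corresponding placebo topographic estimate (for the Drug main: the
#' sign of the placebo grand-mean amplitude), i.e. amplification of the
#' component as expressed in placebo.
#'
#' @param drug_results data.frame of drug-term results from
#'   [contrast_test()] (one row per contrast).
#' @param placebo_results data.frame of placebo topographic results.
#' @param defining character vector naming the defining topographic
#'   contrasts (typically those significant in placebo).
#' @param global_direction sign (+1/-1) of the component's placebo
#'   grand-mean amplitude, the predicted direction of the Drug main.
#' @return `drug_results` with adjusted `p`, a `sided` column, and a
#'   `rule` column tracing the decision per contrast.
#' @export
apply_sidedness <- function(drug_results, placebo_results, defining,
                            global_direction = 1) {
  out <- drug_results
  out$rule <- NA_character_
  for (i in seq_len(nrow(out))) {
    nm <- out$contrast[i]
    if (nm == "Drug") {
      predicted <- sign(global_direction)
      eligible <- TRUE
      why <- "global"
    } else {
      topo <- sub("^Drug x ", "", nm)
      eligible <- topo %in% defining
      row <- placebo_results[placebo_results$contrast == topo, ]
      predicted <- if (nrow(row)) sign(row$estimate[1]) else 0
      why <- if (eligible) "defining" else "non-defining"
    }
    observed <- sign(out$estimate[i])
    if (eligible && predicted != 0 && observed == predicted) {
      out$p[i] <- out$p[i] / 2
      out$sided[i] <- "one"
      out$rule[i] <- paste0(why, ", observed increase -> one-sided")
    } else if (eligible) {
      out$sided[i] <- "two"
      out$rule[i] <- paste0(why, ", unpredicted direction -> two-sided")
    } else {
      out$sided[i] <- "two"
      out$rule[i] <- "non-defining -> two-sided"
    }
  }
  out
}

#' Two-step planned-contrast analysis of one component
#'
#' Step 1 examines the component's topography in the placebo condition
#' (the 8 planned topographic contrasts); the significant ones form the
#' defining topography. Step 2 tests the drug terms (Drug main and Drug x
#' topography) on the placebo/caffeine amplitude tables, applying the
#' one-sided rule to observed increases in global or defining terms.
#'
#' @param amps subject x drug x 9 array of component amplitudes
#'   (microvolts) over the grid sites.
#' @param grid the 3 x 3 site grid the columns of `amps` follow
#'   (row-major order).
#' @param alpha significance level defining the step-1 topography
#'   (default 0.05).
#' @return list with `topography` (step-1 results), `drug` (step-2
#'   results with sidedness applied), `defining`, `global_direction`.
#' @export
component_contrast_analysis <- function(amps, grid = site_grid(),
                                        alpha = 0.05) {
  specs <- build_contrasts(grid, drug = TRUE)
  topo_specs <- Filter(function(s) !s$drug, specs)
  drug_specs <- Filter(function(s) s$drug, specs)
  plac <- amps[, "placebo", ]
  topo <- do.call(rbind, lapply(topo_specs, function(s) contrast_test(plac, s)))
  defining <- topo$contrast[topo$p < alpha]
  gdir <- sign(mean(plac))
  drug <- do.call(rbind, lapply(drug_specs, function(s) contrast_test(amps, s)))
  drug <- apply_sidedness(drug, topo, defining, gdir)
  rownames(topo) <- rownames(drug) <- NULL
  list(topography = topo, drug = drug, defining = defining,
       global_direction = gdir)
}

#' Behavioral test battery
#'
#' Paired one-tailed t-tests (df = n - 1) of the caffeine effect on each
#' behavioral measure: Go omission, fast-RT and delayed-RT error
#' percentages, NoGo commission percentage, mean Go RT, and RT
#' variability (within-subject SD). The tests are directional for the
#' expected caffeine-related reduction: t is computed on placebo minus
#' caffeine and the one-tailed p is `P(T >= t)`.
#'
#' @param behavior data.frame with columns `subject`, `drug`, and the six
#'   measures `omission_pct`, `fast_rt_pct`, `delayed_rt_pct`,
#'   `commission_pct`, `rt_mean`, `rt_sd`.
#' @return data.frame mirroring the behavioral summary table: per measure
#'   the placebo and caffeine means (SDs), t, df, and one-tailed p.
#' @export
behavioral_tests <- function(behavior) {
  measures <- c("omission_pct", "fast_rt_pct", "delayed_rt_pct",
                "commission_pct", "rt_mean", "rt_sd")
  miss <- setdiff(c("subject", "drug", measures), names(behavior))
  if (length(miss)) stop_input("missing columns: %s", paste(miss, collapse = ", "))
  p <- behavior[behavior$drug == "placebo", ]
  c_ <- behavior[behavior$drug == "caffeine", ]
  p <- p[order(p$subject), ]
  c_ <- c_[order(c_$subject), ]
  if (!identical(p$subject, c_$subject)) {
    stop_input("placebo and caffeine rows must pair by subject")
  }
  n <- nrow(p)
  if (n < 2) stop_input("need at least 2 subjects")
  rows <- lapply(measures, function(mv) {
    d <- p[[mv]] - c_[[mv]]
    sd_d <- stats::sd(d)
    t <- if (sd_d == 0) {
      if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else mean(d) / (sd_d / sqrt(n))
    data.frame(measure = mv,
               placebo_mean = mean(p[[mv]]), placebo_sd = stats::sd(p[[mv]]),
               caffeine_mean = mean(c_[[mv]]), caffeine_sd = stats::sd(c_[[mv]]),
               t = t, df = n - 1L,
               p_one_tailed = stats::pt(t, n - 1L, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize per-trial behavior into the test battery's measures
#'
#' @param logs data.frame of per-trial behavior with columns `subject`,
#'   `drug`, `condition`, `responded`, `rt_ms`.
#' @param rt_sd_mult bound (in SD units) defining fast/delayed RT errors
#'   (default 1.5, matching the trial-exclusion rule).
#' @return data.frame with one row per subject x drug and the six
#'   behavioral measures (percent scale for the error rates).
#' @export
summarize_behavior <- function(logs, rt_sd_mult = 1.5) {
  split_by <- interaction(logs$subject, logs$drug, drop = TRUE)
  rows <- lapply(split(logs, split_by), function(d) {
    go <- d[d$condition == "go", ]
    nogo <- d[d$condition == "nogo", ]
    rts <- go$rt_ms[go$responded]
    m <- mean(rts)
    s <- stats::sd(rts)
    data.frame(subject = d$subject[1], drug = d$drug[1],
               omission_pct = 100 * mean(!go$responded),
               fast_rt_pct = 100 * sum(rts < m - rt_sd_mult * s) / nrow(go),
               delayed_rt_pct = 100 * sum(rts > m + rt_sd_mult * s) / nrow(go),
               commission_pct = 100 * mean(nogo$responded),
               rt_mean = m, rt_sd = s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$drug, out$subject), ]
}
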