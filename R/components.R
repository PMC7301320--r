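#' Assemble per-subject averages into a study-level set
#'
#' @param entries list of lists, one per subject x drug, each with
#'   `subject`, `drug`, and `averages` (an `average_erp_list` from
#'   [average_and_downsample()]).
#' @param channels scalp channel names.
#' @param times_ms decimated time axis.
#' @param drug_labels,blocks design levels.
#' @return an `average_erp_set`: list with 6-d `data` array
#'   `[subject, block, drug, condition, channel, time]`, `counts` array,
#'   `times_ms`, `channels`.
#' @export
build_average_set <- function(entries, channels, times_ms,
                              drug_labels = c("placebo", "caffeine"),
                              blocks = c("1", "2")) {
  subjects <- sort(unique(vapply(entries, function(e) e$subject, 0)))
  dn <- list(subject = as.character(subjects), block = blocks,
             drug = drug_labels, condition = c("go", "nogo"),
             channel = channels, time = NULL)
  data <- array(NA_real_, dim = c(length(subjects), length(blocks),
                                  length(drug_labels), 2, length(channels),
                                  length(times_ms)),
                dimnames = c(dn[1:5], list(NULL)))
  counts <- array(NA_real_, dim = dim(data)[1:4], dimnames = dn[1:4])
  for (e in entries) {
    s <- as.character(e$subject)
    for (cell in e$averages) {
      b <- as.character(cell$block)
      data[s, b, e$drug, cell$condition, , ] <- cell$data[channels, ]
      counts[s, b, e$drug, cell$condition] <- cell$n_accepted
    }
  }
  structure(list(data = data, counts = counts, times_ms = times_ms,
                 channels = channels), class = "average_erp_set")
}

#' Select components by variance floors
#'
#' Primary rule: all factors with rotated variance at or above the primary
#' floor (default 2%) are selected, in decreasing order of variance. For a
#' non-reference decomposition (the caffeine PCA), a factor whose label
#' matches a component selected in the reference (placebo) decomposition
#' is additionally selected if its variance exceeds the fallback floor
#' (default 1%).
#'
#' @param pca an `erp_pca` (labelled first if `reference` is used).
#' @param floor primary variance floor in percent (default 2).
#' @param fallback fallback floor in percent (default 1); must be below
#'   `floor`.
#' @param reference a labelled, selected `erp_pca` whose selected labels
#'   trigger the fallback rule.
#' @return the `erp_pca` with its `selected` logical vector set.
#' @export
select_components <- function(pca, floor = 2, fallback = 1,
                              reference = NULL) {
  if (fallback >= floor) stop_input("fallback floor must be below the primary floor")
  sel <- pca$pct_variance >= floor
  if (!is.null(reference)) {
    if (is.null(reference$labels) || is.null(reference$selected)) {
      stop_input("reference decomposition must be labelled and selected")
    }
    if (is.null(pca$labels)) {
      stop_input("label the decomposition before reference-based selection")
    }
    ref_labels <- setdiff(reference$labels[reference$selected], "unknown")
    for (lb in ref_labels) {
      if (any(sel & pca$labels == lb)) next
      cand <- which(pca$labels == lb & pca$pct_variance > fallback)
      if (length(cand)) sel[cand[which.max(pca$pct_variance[cand])]] <- TRUE
    }
  }
  pca$selected <- sel
  pca
}

#' Per-subject component amplitude map
#'
#' Component amplitude at a channel is the factor score of that channel's
#' case times the loading value at the factor's peak-loading latency (in
#' microvolts), averaged over blocks within subject.
#'
#' @param pca an `erp_pca` fitted on a case matrix with keys.
#' @param factor factor index or name.
#' @param channels channels to map (default: all channels in the keys).
#' @return subject x channel matrix of amplitudes (microvolts), with a
#'   `"grand_mean"` attribute (the channel means).
#' @export
component_amplitude_map <- function(pca, factor, channels = NULL) {
  if (is.null(pca$keys)) stop_input("decomposition carries no case keys")
  f <- if (is.character(factor)) match(factor, colnames(pca$loadings)) else factor
  if (is.na(f) || f < 1 || f > ncol(pca$loadings)) {
    stop_input("unknown factor '%s'", factor)
  }
  keys <- pca$keys
  channels <- channels %||% unique(keys$channel)
  missing <- setdiff(channels, unique(keys$channel))
  if (length(missing)) {
    stop_input("channel(s) absent from the decomposition: %s",
               paste(missing, collapse = ", "))
  }
  peak_idx <- which.max(abs(pca$loadings[, f]))
  peak_loading <- pca$loadings[peak_idx, f]
  sc <- pca$scores[, f]
  subjects <- unique(keys$subject)
  out <- matrix(NA_real_, length(subjects), length(channels),
                dimnames = list(subjects, channels))
  for (i in seq_along(subjects)) {
    for (j in seq_along(channels)) {
      sel <- keys$subject == subjects[i] & keys$channel == channels[j]
      out[i, j] <- mean(sc[sel]) * peak_loading
    }
  }
  attr(out, "grand_mean") <- colMeans(out)
  out
}

grand_mean_map <- function(pca, factor, channels = NULL) {
  attr(component_amplitude_map(pca, factor, channels), "grand_mean")
}

#' Label components against the processing-schema template library
#'
#' Each candidate factor is assigned the schema label (N1-1, PN, P2/N2b,
#' P3a, P3b, SW1, SW2, LP) that maximizes a combined score: the factor's
#' peak latency must fall in the label's latency window, and within-window
#' candidates are ranked by Tucker congruence between the factor's
#' grand-mean amplitude map and the template's signed topography. Labels
#' are assigned greedily (best score first, each label used once); ties
#' are broken by factor variance. Factors with no feasible label are
#' `"unknown"`.
#'
#' @param pca an `erp_pca` with case keys.
#' @param templates template library (condition multipliers of the PCA's
#'   condition tag decide which labels are available).
#' @param windows named list of latency windows (ms), see
#'   [default_label_windows()].
#' @param which `"selected"` (default) labels only selected factors (run
#'   [select_components()] first), `"all"` labels every factor, or a
#'   numeric vector of factor indices.
#' @param min_pct when `which = "all"`, only factors above this variance
#'   (percent) are considered (default 0.5).
#' @return the `erp_pca` with its `labels` character vector set.
#' @export
label_components <- function(pca, templates = default_component_templates(),
                             windows = default_label_windows(),
                             which = c("selected", "all"), min_pct = 0.5) {
  nf <- ncol(pca$loadings)
  cand <- if (is.numeric(which)) {
    which
  } else if (match.arg(which) == "selected") {
    if (is.null(pca$selected)) stop_input("run select_components() first")
    which(pca$selected)
  } else {
    which(pca$pct_variance >= min_pct)
  }
  condition <- if (!is.null(pca$tag)) unname(pca$tag["condition"]) else NULL
  labels <- rep("unknown", nf)
  avail <- names(templates)
  if (!is.null(condition)) {
    avail <- avail[vapply(templates, function(tp) tp[[condition]] > 0, TRUE)]
  }
  scores <- matrix(-Inf, nf, length(avail), dimnames = list(NULL, avail))
  for (f in cand) {
    map <- grand_mean_map(pca, f)
    for (lb in avail) {
      w <- windows[[lb]]
      if (is.null(w) || pca$peak_latency_ms[f] < w[1] ||
          pca$peak_latency_ms[f] > w[2]) next
      topo <- template_signed_topography(templates[[lb]])
      # factor maps average to zero over cases, so compare channel-centered
      topo <- topo - mean(topo)
      scores[f, lb] <- tucker_congruence(map[names(topo)], topo)
    }
  }
  repeat {
    if (!any(is.finite(scores))) break
    best <- max(scores[is.finite(scores)])
    hits <- which(scores == best, arr.ind = TRUE)
    if (nrow(hits) > 1) { # tie: higher-variance factor wins
      hits <- hits[order(pca$pct_variance[hits[, 1]], decreasing = TRUE), ,
                   drop = FALSE]
    }
    f <- hits[1, 1]
    lb <- colnames(scores)[hits[1, 2]]
    labels[f] <- lb
    scores[f, ] <- -Inf
    scores[, lb] <- -Inf
  }
  pca$labels <- labels
  pca$label_scores <- NULL
  pca
}

#' Reconstitute grand-mean waveforms from selected components
#'
#' Sums the selected components back into per-site grand-mean waveforms
#' and correlates them with the raw grand means, mirroring the
#' raw-vs-reconstituted comparison used to validate the decomposition.
#' With all factors selected the correlation is 1 at every site; with an
#' empty selection the reconstitution is the column-mean waveform.
#'
#' @param pca an `erp_pca` with case keys.
#' @param x the original case matrix (for the raw grand means).
#' @param selected_only use only selected factors (default TRUE; FALSE
#'   uses all factors).
#' @param channels sites to report (default: all in the keys).
#' @return list with `raw`, `reconstituted` and `difference` (channel x
#'   time matrices) and `correlations` (named per channel).
#' @export
reconstitute <- function(pca, x, selected_only = TRUE, channels = NULL) {
  keys <- pca$keys
  if (is.null(keys)) stop_input("decomposition carries no case keys")
  channels <- channels %||% unique(keys$channel)
  use <- if (selected_only) {
    if (is.null(pca$selected)) stop_input("run select_components() first")
    which(pca$selected)
  } else {
    seq_len(ncol(pca$loadings))
  }
  x <- as.matrix(x)
  nt <- length(pca$times_ms)
  raw <- recon <- matrix(NA_real_, length(channels), nt,
                         dimnames = list(channels, NULL))
  for (j in seq_along(channels)) {
    sel <- keys$channel == channels[j]
    raw[j, ] <- colMeans(x[sel, , drop = FALSE])
    sbar <- colMeans(pca$scores[sel, , drop = FALSE])
    contrib <- if (length(use)) {
      as.numeric(pca$loadings[, use, drop = FALSE] %*% sbar[use])
    } else 0
    recon[j, ] <- pca$center + contrib
  }
  cors <- vapply(seq_along(channels),
                 function(j) stats::cor(raw[j, ], recon[j, ]), 0)
  names(cors) <- channels
  list(raw = raw, reconstituted = recon, difference = raw - recon,
       correlations = cors, times_ms = pca$times_ms)
}
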