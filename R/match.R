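#' Tucker's congruence coefficient
#'
#' `r_c = sum(a*b) / sqrt(sum(a^2) * sum(b^2))`: the cosine similarity
#' between two loading or topography vectors. Invariant to common positive
#' rescaling of either argument; a sign flip of one argument negates it.
#' Conventionally, `r_c >= 0.95` indicates component equality and
#' `0.85 <= r_c < 0.95` similarity.
#'
#' @param a,b numeric vectors of equal length >= 2, not both zero.
#' @return the congruence coefficient in `[-1, 1]`.
#' @export
tucker_congruence <- function(a, b) {
  if (length(a) != length(b)) stop_input("vectors must have equal length")
  if (length(a) < 2) stop_input("vectors must have length >= 2")
  na <- sum(a^2)
  nb <- sum(b^2)
  if (na == 0 || nb == 0) stop_input("congruence undefined for a zero vector")
  sum(a * b) / sqrt(na * nb)
}

#' Topographic Pearson correlation over scalp sites
#'
#' Pearson correlation between two topographic maps over paired sites,
#' with `df = n - 2` (17 for the 19-site montage) and a two-sided p-value
#' from `t = r * sqrt(df / (1 - r^2))`.
#'
#' @param a,b numeric site maps of equal length (>= 3 sites).
#' @return list with `r`, `df`, `t`, `p`.
#' @export
topographic_correlation <- function(a, b) {
  if (length(a) != length(b)) stop_input("maps must have equal length")
  if (length(a) < 3) stop_input("need at least 3 paired sites")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_input("correlation undefined for a constant map")
  }
  r <- stats::cor(a, b)
  df <- length(a) - 2L
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df)
  list(r = r, df = df, t = t, p = p)
}

congruence_class <- function(rc) {
  if (rc >= 0.95) "equality" else if (rc >= 0.85) "similarity" else "unmatched"
}

#' Match components across drug conditions
#'
#' Pairs same-labelled components of the placebo and caffeine
#' decompositions of one stimulus condition. For each pair it reports the
#' Tucker congruence of the temporal loadings, the Tucker congruence and
#' Pearson correlation (df = sites - 2) of the grand-mean topographic
#' maps, and the similarity class from the smaller of the two congruences:
#' `>= 0.95` equality, `0.85 - 0.95` similarity, otherwise unmatched
#' (values in the printed-band gap 0.94-0.95 fall in "similarity").
#' Unmatched pairs are excluded from downstream drug statistics.
#'
#' @param placebo,caffeine labelled and selected `erp_pca` objects of the
#'   same stimulus condition.
#' @param channels sites for the topographic comparison (default: all
#'   scalp sites in the keys).
#' @return a data.frame of class `component_match` with one row per
#'   shared label.
#' @export
match_components <- function(placebo, caffeine, channels = NULL) {
  for (pc in list(placebo, caffeine)) {
    if (is.null(pc$labels) || is.null(pc$selected)) {
      stop_input("both decompositions must be labelled and selected")
    }
    lb <- pc$labels[pc$selected & pc$labels != "unknown"]
    if (anyDuplicated(lb)) {
      stop_input("duplicate component label(s) within one decomposition: %s",
                 paste(unique(lb[duplicated(lb)]), collapse = ", "))
    }
  }
  lab_p <- placebo$labels
  lab_c <- caffeine$labels
  shared <- intersect(lab_p[placebo$selected & lab_p != "unknown"],
                      lab_c[caffeine$selected & lab_c != "unknown"])
  rows <- lapply(shared, function(lb) {
    fp <- which(lab_p == lb & placebo$selected)
    fc <- which(lab_c == lb & caffeine$selected)
    rc_t <- tucker_congruence(placebo$loadings[, fp], caffeine$loadings[, fc])
    mp <- grand_mean_map(placebo, fp, channels)
    mc <- grand_mean_map(caffeine, fc, channels)
    rc_s <- tucker_congruence(mp, mc)
    tc <- topographic_correlation(mp, mc)
    data.frame(label = lb,
               placebo_factor = colnames(placebo$loadings)[fp],
               caffeine_factor = colnames(caffeine$loadings)[fc],
               placebo_pct = placebo$pct_variance[fp],
               caffeine_pct = caffeine$pct_variance[fc],
               rc_temporal = rc_t, rc_topographic = rc_s,
               topo_r = tc$r, topo_df = tc$df, topo_p = tc$p,
               class = congruence_class(min(rc_t, rc_s)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(0))
  class(out) <- c("component_match", "data.frame")
  out
}
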