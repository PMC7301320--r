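#' ERP component template
#'
#' A template describes one planted ERP component: a Gaussian temporal
#' loading (peak latency, width, signed peak amplitude in microvolts), a
#' unitless per-channel topographic weight map (|w| <= 1), and
#' non-negative condition (Go/NoGo) and drug (placebo/caffeine)
#' amplitude multipliers.
#'
#' @param label component label, e.g. `"N1-1"`, `"PN"`, `"P3b"`.
#' @param peak_ms peak latency in ms after stimulus onset; must lie inside
#'   the -100..750 ms epoch window.
#' @param width_ms Gaussian standard deviation in ms.
#' @param amplitude_uv signed peak amplitude in microvolts (negative for
#'   negative-going components).
#' @param topography named numeric vector of per-channel weights over the
#'   scalp channels, bounded by 1 in absolute value.
#' @param go,nogo condition multipliers (>= 0); a multiplier of 0 removes
#'   the component from that condition.
#' @param placebo,caffeine drug multipliers (>= 0); defaults of 1 plant no
#'   drug effect.
#' @param shape `"gaussian"` (default) or `"halfsine"` temporal shape.
#' @return an object of class `erp_component_template`.
#' @export
erp_component_template <- function(label, peak_ms, width_ms, amplitude_uv,
                                   topography, go = 1, nogo = 1,
                                   placebo = 1, caffeine = 1,
                                   shape = c("gaussian", "halfsine")) {
  shape <- match.arg(shape)
  if (peak_ms < -100 || peak_ms > 750) {
    stop_input("template '%s': peak latency %.0f ms outside the epoch window",
               label, peak_ms)
  }
  if (any(abs(topography) > 1 + 1e-12)) {
    stop_input("template '%s': topographic weights must be bounded by 1", label)
  }
  mults <- c(go = go, nogo = nogo, placebo = placebo, caffeine = caffeine)
  if (any(mults < 0)) stop_input("template '%s': multipliers must be >= 0", label)
  if (is.null(names(topography))) stop_input("topography must be named by channel")
  structure(list(label = label, peak_ms = peak_ms, width_ms = width_ms,
                 amplitude_uv = amplitude_uv, topography = topography,
                 go = go, nogo = nogo, placebo = placebo,
                 caffeine = caffeine, shape = shape),
            class = "erp_component_template")
}

#' Evaluate a template's temporal loading shape
#'
#' @param template an `erp_component_template`.
#' @param times_ms numeric vector of times (ms relative to stimulus onset).
#' @return waveform in microvolts at `times_ms` (unit topographic weight,
#'   condition/drug multipliers not applied).
#' @export
template_waveform <- function(template, times_ms) {
  if (template$shape == "gaussian") {
    template$amplitude_uv *
      exp(-((times_ms - template$peak_ms)^2) / (2 * template$width_ms^2))
  } else {
    half <- 2.2 * template$width_ms # half-sine support matched to Gaussian area
    u <- (times_ms - template$peak_ms) / half
    w <- ifelse(abs(u) <= 0.5, cos(pi * u), 0)
    template$amplitude_uv * w
  }
}

# Gaussian spatial focus over montage scalp channels, max weight 1
topography_focus <- function(montage, x, y, width = 0.6) {
  sc <- montage[montage$type == "scalp", ]
  d <- sqrt((sc$x - x)^2 + (sc$y - y)^2)
  w <- exp(-d^2 / (2 * width^2))
  w <- w / max(w)
  names(w) <- sc$channel
  w
}

# rescale a signed map so max |w| = 1
normalize_topography <- function(w) w / max(abs(w))

#' Default planted component set for the Go/NoGo schema
#'
#' Builds the default library of planted components: shared N1-1 and PN,
#' a NoGo-only composite P2/N2b, a NoGo-dominant P3a (reduced in Go), a
#' Go-only P3b, NoGo-only SW1 and LP, and an SW2 present in both
#' conditions. All drug multipliers default to 1, so caffeine and placebo
#' sessions differ only by their noise realisation until an effect is
#' planted explicitly.
#'
#' @param montage an `erp_montage`.
#' @return a named list of `erp_component_template` objects.
#' @export
default_component_templates <- function(montage = gonogo_montage()) {
  f <- function(...) topography_focus(montage, ...)
  tpl <- list(
    erp_component_template("N1-1", 100, 22, -12, f(0, 0.3, 0.8)),
    erp_component_template("PN", 190, 35, -8, normalize_topography(
      pmax(f(-0.8, 0.2, 0.65), f(0.8, 0.2, 0.65), 0.75 * f(0, 0.4, 0.7)))),
    erp_component_template("P2/N2b", 240, 30, 7, normalize_topography(
      f(0, 0, 0.7) - 0.9 * f(0, 0.75, 0.55)), go = 0, nogo = 1),
    erp_component_template("P3a", 310, 40, 10, f(0, 0, 0.65),
                           go = 0.75, nogo = 1),
    erp_component_template("P3b", 400, 60, 15, f(-0.12, -0.5, 0.8),
                           go = 1, nogo = 0),
    erp_component_template("SW1", 470, 50, 7, f(0, 0, 0.95),
                           go = 0, nogo = 1),
    erp_component_template("SW2", 600, 60, 8, normalize_topography(
      f(0, -0.55, 0.75) - f(0, 0.8, 0.55))),
    erp_component_template("LP", 700, 45, 7, f(0, -0.25, 1.0),
                           go = 0, nogo = 1)
  )
  names(tpl) <- vapply(tpl, `[[`, "", "label")
  tpl
}

#' Latency windows used for component labelling
#'
#' @return named list of `c(lo, hi)` latency windows in ms.
#' @export
default_label_windows <- function() {
  list(`N1-1` = c(70, 130), PN = c(130, 260), `P2/N2b` = c(160, 280),
       P3a = c(250, 400), P3b = c(280, 450), SW1 = c(350, 600),
       SW2 = c(450, 750), LP = c(500, 750))
}

# signed planted topography (amplitude sign folded in), for labelling and
# ground-truth comparisons
template_signed_topography <- function(template) {
  sign(template$amplitude_uv) * template$topography
}

# noiseless per-channel x time epoch signal for one condition/drug;
# component_factors: optional named per-template amplitude factors
template_signal <- function(templates, times_ms, condition, drug,
                            subject_factor = 1, component_factors = NULL) {
  stopifnot(condition %in% c("go", "nogo"), drug %in% c("placebo", "caffeine"))
  first <- templates[[1]]
  nch <- length(first$topography)
  sig <- matrix(0, nrow = nch, ncol = length(times_ms),
                dimnames = list(names(first$topography), NULL))
  for (tp in templates) {
    g <- if (is.null(component_factors)) 1 else component_factors[[tp$label]]
    mult <- tp[[condition]] * tp[[drug]] * subject_factor * (g %||% 1)
    if (mult == 0) next
    sig <- sig + outer(tp$topography, template_waveform(tp, times_ms)) * mult
  }
  sig
}
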