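#' 19-channel 10-20 montage with EOG channels
#'
#' Builds the standard 19-site "10-20" scalp montage used throughout the
#' pipeline, plus four electro-oculogram (EOG) channels (above/below the
#' left eye and at the outer canthi). Schematic 2-D layout coordinates
#' (head seen from above, nose up, unit-circle scale) are included for
#' topographic maps and for distance-based spatial models.
#'
#' @return a data.frame of class `erp_montage` with columns `channel`, `x`,
#'   `y`, `type` (`"scalp"` or `"eog"`), `sagittal` (prefrontal/frontal/
#'   central/parietal/occipital for scalp sites) and `lateral`
#'   (left/midline/right).
#' @examples
#' m <- gonogo_montage()
#' sum(m$type == "scalp") # 19
#' @export
gonogo_montage <- function() {
  scalp <- data.frame(
    channel = c("Fp1", "Fp2",
                "F7", "F3", "Fz", "F4", "F8",
                "T7", "C3", "Cz", "C4", "T8",
                "P7", "P3", "Pz", "P4", "P8",
                "O1", "O2"),
    x = c(-0.31, 0.31,
          -0.81, -0.36, 0, 0.36, 0.81,
          -1.00, -0.50, 0, 0.50, 1.00,
          -0.81, -0.36, 0, 0.36, 0.81,
          -0.31, 0.31),
    y = c(0.95, 0.95,
          0.59, 0.52, 0.50, 0.52, 0.59,
          0.00, 0.00, 0, 0.00, 0.00,
          -0.59, -0.52, -0.50, -0.52, -0.59,
          -0.95, -0.95),
    type = "scalp",
    sagittal = c("prefrontal", "prefrontal",
                 rep("frontal", 5), rep("central", 5), rep("parietal", 5),
                 "occipital", "occipital"),
    stringsAsFactors = FALSE
  )
  eog <- data.frame(
    channel = c("EOGvu", "EOGvl", "EOGhl", "EOGhr"),
    x = c(-0.31, -0.31, -1.1, 1.1),
    y = c(1.15, 0.80, 0.95, 0.95),
    type = "eog",
    sagittal = NA_character_,
    stringsAsFactors = FALSE
  )
  m <- rbind(scalp, eog)
  m$lateral <- ifelse(m$x < 0, "left", ifelse(m$x > 0, "right", "midline"))
  if (anyDuplicated(m[, c("x", "y")])) {
    stop_input("montage layout coordinates must be unique")
  }
  class(m) <- c("erp_montage", "data.frame")
  m
}

#' Scalp channel names of a montage
#' @param montage an `erp_montage`.
#' @return character vector of the 19 scalp channel names in montage order.
#' @export
scalp_channels <- function(montage) {
  montage$channel[montage$type == "scalp"]
}

eog_channels <- function(montage) {
  montage$channel[montage$type == "eog"]
}

#' 3 x 3 electrode grid for planned topographic contrasts
#'
#' Returns the 9-site analysis grid: sagittal rows (frontal, central,
#' parietal) by lateral columns (left, midline, right). The `"core"`
#' variant uses the F3/Fz/F4, C3/Cz/C4, P3/Pz/P4 sites; the
#' `"temporal"` variant (used for the temporally focused Processing
#' Negativity) replaces the hemispheric pairs with the outer-row
#' F7/F8, T7/T8 and P7/P8 sites, keeping the midline column.
#'
#' @param montage an `erp_montage`; the grid channels are checked against it.
#' @param variant `"core"` or `"temporal"`.
#' @return a 3 x 3 character matrix with dimnames
#'   `list(sagittal = c("frontal","central","parietal"),
#'         lateral = c("left","midline","right"))`.
#' @export
site_grid <- function(montage = gonogo_montage(),
                      variant = c("core", "temporal")) {
  variant <- match.arg(variant)
  cells <- if (variant == "core") {
    c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4")
  } else {
    c("F7", "Fz", "F8", "T7", "Cz", "T8", "P7", "Pz", "P8")
  }
  g <- matrix(cells, nrow = 3, byrow = TRUE,
              dimnames = list(sagittal = c("frontal", "central", "parietal"),
                              lateral = c("left", "midline", "right")))
  missing <- setdiff(as.vector(g), scalp_channels(montage))
  if (length(missing)) {
    stop_input("grid channels absent from montage: %s",
               paste(missing, collapse = ", "))
  }
  if (anyDuplicated(as.vector(g))) stop_input("grid channels must be distinct")
  g
}

# Euclidean distances between montage layout positions and a point
montage_distance <- function(montage, x, y) {
  sqrt((montage$x - x)^2 + (montage$y - y)^2)
}
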