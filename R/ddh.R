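# Conversion of GBDP distances to digital DNA:DNA hybridization (dDDH)
# similarities, and type-strain-anchored species/subspecies assignment with
# the advisory G+C-difference check.
#
# The transform is a strictly decreasing logistic
#   y(d) = 1 / (1 + exp(c0 + c1 * d)),  c1 > 0,
# mimicking the GGDC generalized-linear-model calibration. For formula 2
# (identities per HSP length) the default coefficients are derived from two
# published calibration anchors of that model: the canonical species
# boundary (70% dDDH at distance 0.0359) and the subspecies-range anchor
# (79.3% dDDH at distance 0.0242). The constructor verifies the second
# anchor to +/-0.5 dDDH points and stops if it is violated.

DDH_F2_ANCHORS <- data.frame(distance = c(0.0359, 0.0242),
                             ddh = c(0.700, 0.793))

#' Construct a distance-to-dDDH conversion model
#'
#' @param formula GBDP formula the model is calibrated for; a default
#'   calibration exists only for \code{"f2"} (identities per HSP length).
#'   For other formulas, supply \code{c0} and \code{c1} explicitly.
#' @param c0,c1 Optional explicit logistic coefficients
#'   (\code{y(d) = 1/(1 + exp(c0 + c1 d))}, \code{c1 > 0}).
#' @param anchors Two-point calibration table (\code{distance}, \code{ddh})
#'   used when \code{c0}/\code{c1} are not given.
#' @return Object of class \code{ddh_model} with fields \code{formula},
#'   \code{c0}, \code{c1}.
#' @export
ddh_model <- function(formula = "f2", c0 = NULL, c1 = NULL,
                      anchors = NULL) {
  formula <- normalize_formula(formula)
  if (is.null(c0) != is.null(c1))
    stopf("supply both c0 and c1, or neither")
  if (is.null(c0)) {
    if (is.null(anchors)) {
      if (formula != "f2")
        stopf("no default calibration for formula '%s'; supply c0 and c1",
              formula)
      anchors <- DDH_F2_ANCHORS
    }
    stopifnot(nrow(anchors) == 2)
    # c0 + c1 d = -logit(y) at both anchor points
    c1 <- (qlogis(anchors$ddh[1]) - qlogis(anchors$ddh[2])) /
      (anchors$distance[2] - anchors$distance[1])
    c0 <- -qlogis(anchors$ddh[1]) - c1 * anchors$distance[1]
  }
  if (c1 <= 0) stopf("c1 must be positive (mapping must be decreasing)")
  model <- structure(list(formula = formula, c0 = c0, c1 = c1),
                     class = "ddh_model")
  if (formula == "f2") {
    got <- distance_to_ddh(0.0242, model)
    if (abs(got - 0.793) > 0.005)
      stopf(paste("dDDH model fails the calibration anchor:",
                  "d = 0.0242 maps to %.4f, expected 0.793 +/- 0.005"), got)
  }
  model
}

#' @export
print.ddh_model <- function(x, ...) {
  cat(sprintf("<ddh_model> formula '%s': y(d) = 1/(1 + exp(%.4f + %.4f d))\n",
              x$formula, x$c0, x$c1))
  invisible(x)
}

#' Convert an intergenomic distance to a dDDH similarity
#'
#' @param d Distance(s) in \code{[0, 1]}.
#' @param model A \code{\link{ddh_model}}.
#' @return dDDH fraction(s) in \code{(0, 1)}.
#' @export
distance_to_ddh <- function(d, model = ddh_model()) {
  if (any(d < 0 | d > 1)) stopf("distance outside [0, 1]")
  plogis(-(model$c0 + model$c1 * d))
}

#' Inverse of \code{\link{distance_to_ddh}}
#' @param y dDDH fraction(s) in \code{(0, 1)}.
#' @param model A \code{\link{ddh_model}}.
#' @return Distance(s).
#' @export
ddh_to_distance <- function(y, model = ddh_model()) {
  if (any(y <= 0 | y >= 1)) stopf("dDDH outside (0, 1)")
  (-qlogis(y) - model$c0) / model$c1
}

#' Type-strain-anchored species and subspecies assignment
#'
#' For every non-type strain, takes its distance to the type strain,
#' converts it to dDDH and applies the species (default 70\%) and
#' subspecies (default 79\%) thresholds (\code{>=} is "same"). A strain
#' assigned to the species whose G+C content differs from the type strain
#' by more than \code{gc_limit} percentage points is flagged
#' (\code{gc_conflict}); the flag is advisory and never overrides the dDDH
#' call.
#'
#' @param m Labeled symmetric distance matrix (or \code{gbdp_matrix}).
#' @param type_id Label of the type strain.
#' @param model A \code{\link{ddh_model}}.
#' @param species_thr,subsp_thr dDDH thresholds,
#'   \code{0 < species_thr < subsp_thr < 1}.
#' @param gc Optional named numeric vector of G+C fractions (or a list of
#'   \code{\link{genome_record}}s) used for the G+C check.
#' @param gc_limit Advisory within-species G+C difference limit in
#'   percentage points.
#' @return Data frame with one row per non-type strain: \code{strain_id},
#'   \code{distance}, \code{ddh}, \code{gc_diff}, \code{same_species},
#'   \code{same_subspecies}, \code{gc_conflict}.
#' @export
classify_vs_type <- function(m, type_id, model = ddh_model(),
                             species_thr = 0.70, subsp_thr = 0.79,
                             gc = NULL, gc_limit = 1.0) {
  if (inherits(m, "gbdp_matrix")) m <- m$distances
  m <- dist_matrix(m)
  if (!(type_id %in% rownames(m)))
    stopf("type strain '%s' not found in matrix labels", type_id)
  stopifnot(species_thr > 0, species_thr < subsp_thr, subsp_thr < 1)
  if (!is.null(gc) && is.list(gc))
    gc <- vapply(gc, function(g) g$gc_fraction,
                 numeric(1), USE.NAMES = FALSE) |>
      setNames(vapply(gc, function(g) g$strain_id, character(1)))
  others <- setdiff(rownames(m), type_id)
  d <- m[others, type_id]
  y <- distance_to_ddh(d, model)
  gc_diff <- if (is.null(gc)) rep(NA_real_, length(others))
             else abs(gc[others] - gc[[type_id]]) * 100
  same_species <- y >= species_thr
  same_subsp <- y >= subsp_thr
  data.frame(strain_id = others, distance = unname(d), ddh = unname(y),
             gc_diff = unname(gc_diff),
             same_species = unname(same_species),
             same_subspecies = unname(same_subsp),
             gc_conflict = unname(same_species & !is.na(gc_diff) &
                                    gc_diff > gc_limit))
}

#' Histogram of dDDH similarities to the type strain
#'
#' @inheritParams classify_vs_type
#' @param bin_width Width of the half-open dDDH bins \code{[lo, hi)}
#'   covering \code{[0, 1]}.
#' @return Data frame with \code{lo}, \code{hi}, \code{count}; counts
#'   partition the non-type strains.
#' @export
ddh_histogram <- function(m, type_id, model = ddh_model(),
                          bin_width = 0.05) {
  if (inherits(m, "gbdp_matrix")) m <- m$distances
  m <- dist_matrix(m)
  if (!(type_id %in% rownames(m)))
    stopf("type strain '%s' not found in matrix labels", type_id)
  others <- setdiff(rownames(m), type_id)
  y <- distance_to_ddh(m[others, type_id], model)
  lo <- seq(0, 1, by = bin_width)
  if (lo[length(lo)] < 1) lo <- c(lo, lo[length(lo)] + bin_width)
  hi <- lo + bin_width
  idx <- pmin(findInterval(y, lo), length(lo)) # [lo, hi) bins
  data.frame(lo = lo, hi = hi,
             count = tabulate(idx, nbins = length(lo)))
}
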