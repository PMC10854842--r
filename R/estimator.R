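# Recovery correction of fecal profiles and NNLS estimation of the dietary
# mixture. The model: for each marker i, x_f * F_i + x_a * A_i ~= E_i, with
# F, A the component concentrations, E the recovery-corrected fecal
# concentration and x >= 0. The plant proportion of DM intake is
# x_a / (x_a + x_f): any factor common to all corrected E_i (fecal DM to
# intake ratio, uniform recovery) is absorbed by both coefficients and
# cancels in the ratio.

#' Recovery-correct a fecal alkane profile
#'
#' Divides each observed fecal concentration by the diet-specific mean
#' recovery of that alkane, converting the fecal profile back to an
#' intake-equivalent scale. Division (rather than multiplication) is the
#' direction under which the downstream coefficient ratio is a DM-intake
#' proportion.
#'
#' @param animal An [animal_record()].
#' @param recovery A [recovery_table()].
#' @param diet_for_correction Which diet's recovery column to use; defaults
#'   to the animal's own diet. For animals of unknown diet a control-diet
#'   column can be used instead (callers should be aware of the circularity
#'   when the correction diet is itself being estimated).
#' @param markers Markers to correct (defaults to all of the animal's).
#' @return Named numeric vector of corrected concentrations (mg/kg DM,
#'   intake-equivalent), in marker order.
#' @export
correct_excreta <- function(animal, recovery,
                            diet_for_correction = animal$diet_id,
                            markers = names(animal$fecal_conc)) {
  r <- vapply(markers, function(m)
    recovery_lookup(recovery, diet_for_correction, m), numeric(1))
  animal$fecal_conc[markers] / r
}

# Design matrix: one column per component, rows = markers in ascending
# carbon order (so results cannot depend on caller-supplied marker order).
build_design <- function(components, markers) {
  markers <- validate_markers(markers)
  A <- vapply(components, function(p) profile_conc(p, markers),
              numeric(length(markers)))
  A <- matrix(A, nrow = length(markers),
              dimnames = list(markers, names(components)))
  A
}

#' Plant proportion of dry-matter intake from NNLS coefficients
#'
#' The ratio of plant-component coefficient(s) to the coefficient total.
#' With one feed and one plant this is `x_a / (x_a + x_f)`; with several
#' plant components their coefficients are summed in the numerator.
#'
#' @param coefficients Named non-negative numeric vector (one entry per
#'   component).
#' @param plant_components Names of the plant component(s); default: every
#'   component except `"feed"`.
#' @return Proportion in \[0, 1\], or `NA` (undefined, with a warning) when
#'   all coefficients are zero.
#' @export
plant_proportion <- function(coefficients,
                             plant_components = setdiff(names(coefficients),
                                                        "feed")) {
  if (any(coefficients < 0))
    stop_validation("plant_proportion: coefficients must be non-negative")
  missing <- setdiff(plant_components, names(coefficients))
  if (length(missing) > 0)
    stop_validation(paste0("unknown plant component(s): ",
                           paste(missing, collapse = ", ")))
  total <- sum(coefficients)
  if (total == 0) {
    warning("plant proportion undefined: all coefficients are zero")
    return(NA_real_)
  }
  unname(sum(coefficients[plant_components]) / total)
}

#' Estimate the dietary mixture of one animal
#'
#' Builds the marker-by-component design matrix, recovery-corrects the
#' animal's fecal profile, solves the non-negative least-squares system and
#' derives the plant proportion of DM intake.
#'
#' @param animal An [animal_record()].
#' @param components Named list of [alkane_profile()] objects (the candidate
#'   dietary components; conventionally feed first).
#' @param recovery A [recovery_table()].
#' @param markers Marker subset to use (>= number of components; equality
#'   triggers a warning since the fit is then exact).
#' @param diet_for_correction Recovery column; defaults to the animal's own
#'   diet.
#' @param plant_components Passed to [plant_proportion()]; default: every
#'   component except `"feed"`.
#' @return An object of class `estimate_result`: list with `animal_id`,
#'   `diet_id`, `markers` (ascending carbon order), `coefficients`,
#'   `proportion` (`NA` when undefined), `undefined` flag and `residual_ss`.
#' @examples
#' fx <- default_fixtures()
#' flock <- simulate_flock(sim_config(noise_cv = 0, seed = 1))
#' estimate_animal(flock$animals[[40]], fx$components, fx$recovery)
#' @export
estimate_animal <- function(animal, components, recovery,
                            markers = names(animal$fecal_conc),
                            diet_for_correction = animal$diet_id,
                            plant_components = setdiff(names(components),
                                                       "feed")) {
  markers <- validate_markers(markers)
  if (length(markers) < length(components))
    stop_validation(sprintf(
      "need at least as many markers (%d) as components (%d)",
      length(markers), length(components)))
  if (length(markers) == length(components))
    warning("as many markers as components: exact fit, no residual information")
  A <- build_design(components, markers)
  e <- correct_excreta(animal, recovery, diet_for_correction, markers)
  fit <- nnls(A, e)
  p <- withCallingHandlers(
    plant_proportion(fit$x, plant_components),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(list(animal_id = animal$animal_id, diet_id = animal$diet_id,
                 markers = markers, coefficients = fit$x,
                 proportion = p, undefined = is.na(p),
                 residual_ss = fit$residual_ss),
            class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("<estimate_result> %s [%s]\n", x$animal_id,
              paste(x$markers, collapse = "-")))
  print(signif(x$coefficients, 6))
  if (x$undefined) cat("  plant proportion: undefined (all coefficients 0)\n")
  else cat(sprintf("  plant proportion: %.6g\n", x$proportion))
  invisible(x)
}

#' Estimate the dietary mixture for a whole flock
#'
#' Runs [estimate_animal()] over a list of animals and collects the results
#' into a data frame (one row per animal).
#'
#' @inheritParams estimate_animal
#' @param animals List of [animal_record()] objects.
#' @param diet_for_correction Single diet id for all animals, or `NULL`
#'   (default) to use each animal's own diet.
#' @return Data frame with columns `animal_id`, `diet_id`, `markers`
#'   (hyphen-joined), one `x_<component>` column per component,
#'   `proportion`, `residual_ss`, `undefined`.
#' @export
estimate_flock <- function(animals, components, recovery,
                           markers = DEFAULT_MARKERS,
                           diet_for_correction = NULL,
                           plant_components = setdiff(names(components),
                                                      "feed")) {
  rows <- lapply(animals, function(a) {
    est <- estimate_animal(a, components, recovery, markers,
                           diet_for_correction =
                             if (is.null(diet_for_correction)) a$diet_id
                             else diet_for_correction,
                           plant_components = plant_components)
    row <- data.frame(animal_id = est$animal_id, diet_id = est$diet_id,
                      markers = paste(est$markers, collapse = "-"),
                      stringsAsFactors = FALSE)
    for (cn in names(est$coefficients))
      row[[paste0("x_", cn)]] <- est$coefficients[[cn]]
    row$proportion <- est$proportion
    row$residual_ss <- est$residual_ss
    row$undefined <- est$undefined
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
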