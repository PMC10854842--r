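# Scoring predictions against known truth and exhaustive search over
# marker-subset combinations.

#' Bias/variance-decomposed prediction error
#'
#' For prediction errors `e_j = p_hat_j - truth`: bias is `mean(e)`,
#' variance the population variance of `e` (divide by n; this is the only
#' convention under which `mse = bias^2 + variance` holds exactly),
#' `mse = mean(e^2)` and `rmse = sqrt(mse)`.
#'
#' @param predictions Numeric vector of predicted proportions (undefined
#'   estimates must be excluded upstream).
#' @param truth True proportion (scalar).
#' @return An object of class `error_metrics`: list with `n`,
#'   `mean_prediction`, `bias`, `variance`, `mse`, `rmse`.
#' @examples
#' error_metrics(c(0.9, 1.1, 1.3), truth = 1)
#' @export
error_metrics <- function(predictions, truth) {
  predictions <- as.numeric(predictions)
  if (length(predictions) == 0)
    stop_validation("error_metrics: no predictions")
  if (any(!is.finite(predictions)) || !is.finite(truth))
    stop_validation("error_metrics: predictions and truth must be finite")
  e <- predictions - truth
  bias <- mean(e)
  variance <- mean((e - bias)^2)
  mse <- mean(e^2)
  structure(list(n = length(e), mean_prediction = mean(predictions),
                 bias = bias, variance = variance, mse = mse,
                 rmse = sqrt(mse)),
            class = "error_metrics")
}

#' @export
print.error_metrics <- function(x, ...) {
  cat(sprintf("<error_metrics> n = %d\n", x$n))
  cat(sprintf("  mean %.4g | bias %.4g | var %.4g | RMSE %.4g\n",
              x$mean_prediction, x$bias, x$variance, x$rmse))
  invisible(x)
}

#' Enumerate marker subsets
#'
#' All subsets of the marker set of size `min_size` up to the full set,
#' each in ascending carbon order, in a deterministic overall order (by
#' size, then lexicographically by carbon length).
#'
#' @param markers Marker set.
#' @param min_size Smallest subset size (>= number of dietary components
#'   for the downstream system to be over- or exactly determined).
#' @return List of character vectors.
#' @examples
#' length(enumerate_subsets(DEFAULT_MARKERS))  # 26
#' @export
enumerate_subsets <- function(markers, min_size = 2) {
  markers <- validate_markers(markers)
  m <- length(markers)
  if (min_size > m)
    stop_validation(sprintf("min_size (%d) exceeds number of markers (%d)",
                            min_size, m))
  if (min_size < 1) stop_validation("min_size must be >= 1")
  out <- list()
  for (k in seq(min_size, m))
    out <- c(out, combn(markers, k, simplify = FALSE))
  out
}

#' Exhaustive marker-subset evaluation
#'
#' For every marker subset, estimates the plant proportion of every animal,
#' scores each diet group against its known truth, and ranks subsets within
#' each diet by the chosen criterion. The full table is returned, not just
#' the winners; subsets on which every estimate is undefined are flagged
#' (`all_undefined`), never dropped.
#'
#' @inheritParams estimate_flock
#' @param truth_by_diet Named numeric vector mapping `diet_id` to the true
#'   plant proportion (e.g. `c(mixed = 0.01, commercial = 0)`); every diet
#'   present among the animals must have an entry.
#' @param min_size Smallest subset size (default 2).
#' @param criterion Ranking criterion: `"rmse"` (default) or `"abs_bias"`.
#' @return A `combination_report`: data frame with one row per
#'   (subset, diet) holding `markers`, `diet_id`, `n`, `n_undefined`,
#'   `mean_prediction`, `bias`, `variance`, `mse`, `rmse`, `rank`
#'   (within diet, 1 = best) and `all_undefined`.
#' @export
combination_search <- function(animals, components, recovery, truth_by_diet,
                               min_size = 2, criterion = c("rmse", "abs_bias"),
                               markers = DEFAULT_MARKERS,
                               diet_for_correction = NULL,
                               plant_components = setdiff(names(components),
                                                          "feed")) {
  criterion <- match.arg(criterion)
  diets_present <- unique(vapply(animals, function(a) a$diet_id, ""))
  missing <- setdiff(diets_present, names(truth_by_diet))
  if (length(missing) > 0)
    stop_validation(paste0("no truth entry for diet(s): ",
                           paste(missing, collapse = ", ")))
  if (min_size < length(components))
    stop_validation(sprintf(
      "min_size (%d) below number of components (%d): underdetermined system",
      min_size, length(components)))
  subsets <- enumerate_subsets(markers, min_size)
  rows <- list()
  for (s in subsets) {
    # size-|components| subsets fit exactly by design here; the per-animal
    # exact-fit warning is informative for single estimates, noise in a sweep
    est <- withCallingHandlers(
      estimate_flock(animals, components, recovery, markers = s,
                     diet_for_correction = diet_for_correction,
                     plant_components = plant_components),
      warning = function(w) {
        if (grepl("exact fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    for (d in diets_present) {
      g <- est[est$diet_id == d, ]
      ok <- !g$undefined
      base <- data.frame(markers = paste(s, collapse = "-"), diet_id = d,
                         n = sum(ok), n_undefined = sum(!ok),
                         stringsAsFactors = FALSE)
      if (!any(ok)) {
        base$mean_prediction <- NA_real_; base$bias <- NA_real_
        base$variance <- NA_real_; base$mse <- NA_real_; base$rmse <- NA_real_
        base$all_undefined <- TRUE
      } else {
        mt <- error_metrics(g$proportion[ok], truth_by_diet[[d]])
        base$mean_prediction <- mt$mean_prediction; base$bias <- mt$bias
        base$variance <- mt$variance; base$mse <- mt$mse; base$rmse <- mt$rmse
        base$all_undefined <- FALSE
      }
      rows[[length(rows) + 1L]] <- base
    }
  }
  out <- do.call(rbind, rows)
  score <- if (criterion == "rmse") out$rmse else abs(out$bias)
  score <- round(score, 10)   # differences at float-noise level are ties
  out$rank <- NA_integer_
  for (d in diets_present) {
    idx <- out$diet_id == d
    out$rank[idx] <- rank(score[idx], ties.method = "min",
                          na.last = "keep")
  }
  rownames(out) <- NULL
  attr(out, "criterion") <- criterion
  class(out) <- c("combination_report", "data.frame")
  out
}

#' Write a combination report to CSV
#'
#' @param report A [combination_search()] result.
#' @param path Output CSV path.
#' @param digits Significant digits (`NULL` = full precision).
#' @return Invisibly, the path.
#' @export
write_combinations <- function(report, path, digits = NULL) {
  out <- as.data.frame(report)
  if (!is.null(digits))
    for (cl in c("mean_prediction", "bias", "variance", "mse", "rmse"))
      out[[cl]] <- signif(out[[cl]], digits)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
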