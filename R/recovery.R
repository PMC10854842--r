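# Fecal recovery rates: per-animal marker balance, outlier screening, and
# diet-level aggregation into the table used to correct fecal profiles.

#' Per-animal fecal recovery of one alkane
#'
#' Recovery is the standard marker balance: the fraction of ingested marker
#' recovered in the excreta,
#' \deqn{r_i = \frac{E_i \cdot \mathrm{fecal\ DM}}{D_i \cdot \mathrm{DM\ intake}}}
#' where concentrations are mg/kg DM and DM flows g/day (the mg/day
#' conversion factor cancels).
#'
#' @param animal An [animal_record()].
#' @param diet_profile The consumed diet's as-fed profile (analyzed or
#'   mixed), an [alkane_profile()].
#' @param marker Marker label.
#' @return A one-row data frame with columns `animal_id`, `diet_id`,
#'   `alkane`, `intake_mg_d`, `output_mg_d`, `recovery`.
#' @export
animal_recovery <- function(animal, diet_profile, marker) {
  diet_c <- profile_conc(diet_profile, marker)
  if (diet_c == 0)
    stop_validation(sprintf(
      "recovery undefined for %s: dietary concentration is 0", marker))
  intake <- diet_c * animal$dm_intake / 1000
  output <- animal$fecal_conc[[marker]] * animal$fecal_dm_output / 1000
  r <- output / intake
  if (r > 1)
    warning(sprintf("animal '%s', %s: recovery %.3f > 1 (biologically impossible in expectation)",
                    animal$animal_id, marker, r))
  data.frame(animal_id = animal$animal_id, diet_id = animal$diet_id,
             alkane = marker, intake_mg_d = intake, output_mg_d = output,
             recovery = r, stringsAsFactors = FALSE)
}

#' Recovery observations for a whole flock
#'
#' Applies the marker balance of [animal_recovery()] to every animal and
#' every active marker. Recoveries above 1 are allowed (measurement noise)
#' but reported with a single summary warning.
#'
#' @param animals List of [animal_record()] objects.
#' @param diet_profiles Named list mapping `diet_id` to the consumed diet's
#'   [alkane_profile()].
#' @param markers Marker set (defaults to the animals' marker set).
#' @return Data frame with one row per (animal, marker).
#' @export
recovery_observations <- function(animals, diet_profiles, markers = NULL) {
  if (length(animals) == 0)
    return(data.frame(animal_id = character(), diet_id = character(),
                      alkane = character(), intake_mg_d = numeric(),
                      output_mg_d = numeric(), recovery = numeric()))
  if (is.null(markers)) markers <- names(animals[[1]]$fecal_conc)
  markers <- validate_markers(markers)
  rows <- lapply(animals, function(a) {
    dp <- diet_profiles[[a$diet_id]]
    if (is.null(dp))
      stop_validation(sprintf("no diet profile supplied for diet '%s'",
                              a$diet_id))
    do.call(rbind, lapply(markers, function(m)
      suppressWarnings(animal_recovery(a, dp, m))))
  })
  obs <- do.call(rbind, rows)
  n_over <- sum(obs$recovery > 1)
  if (n_over > 0)
    warning(sprintf("%d recovery observation(s) exceed 1", n_over))
  obs
}

#' Whole-profile recovery for one animal
#'
#' Ratio of summed alkane output to summed alkane intake across all active
#' markers; equal to the intake-weighted mean of per-marker recoveries.
#'
#' @inheritParams animal_recovery
#' @param markers Marker set (defaults to the animal's marker set).
#' @return Total recovery (numeric scalar).
#' @export
total_recovery <- function(animal, diet_profile, markers = NULL) {
  if (is.null(markers)) markers <- names(animal$fecal_conc)
  diet_c <- profile_conc(diet_profile, markers)
  intake <- sum(diet_c) * animal$dm_intake / 1000
  if (intake == 0)
    stop_validation(sprintf("animal '%s': total alkane intake is 0",
                            animal$animal_id))
  output <- sum(animal$fecal_conc[markers]) * animal$fecal_dm_output / 1000
  output / intake
}

# Per-animal total recoveries from an observation table.
animal_totals <- function(observations) {
  key <- paste(observations$animal_id, observations$diet_id, sep = "\r")
  intake <- tapply(observations$intake_mg_d, key, sum)
  output <- tapply(observations$output_mg_d, key, sum)
  parts <- do.call(rbind, strsplit(names(intake), "\r", fixed = TRUE))
  data.frame(animal_id = parts[, 1], diet_id = parts[, 2],
             total_recovery = as.numeric(output / intake),
             stringsAsFactors = FALSE)
}

#' Flag animals with anomalous total recovery
#'
#' An animal is flagged when its whole-profile recovery exceeds an absolute
#' threshold, or lies more than `k_mad` median-absolute-deviations from its
#' diet group's median (robust screen; skipped when the group MAD is 0).
#' Flagged animals are meant to be excluded from mean-recovery aggregation,
#' never removed from the raw table.
#'
#' @param observations Observation table from [recovery_observations()].
#' @param threshold Absolute total-recovery threshold (default 0.60).
#' @param k_mad Robust-screen multiplier (default 3.5); `Inf` disables it.
#' @return Character vector of flagged `animal_id`s (possibly empty).
#' @export
flag_outliers <- function(observations, threshold = 0.60, k_mad = 3.5) {
  if (nrow(observations) == 0) return(character())
  tot <- animal_totals(observations)
  flagged <- character()
  for (d in unique(tot$diet_id)) {
    g <- tot[tot$diet_id == d, ]
    if (nrow(g) < 3)
      warning(sprintf("diet '%s': fewer than 3 animals; outlier screen unreliable", d))
    hit <- g$total_recovery > threshold
    if (is.finite(k_mad)) {
      med <- median(g$total_recovery)
      m <- mad(g$total_recovery)
      if (m > 0)
        hit <- hit | abs(g$total_recovery - med) > k_mad * m
    }
    flagged <- c(flagged, g$animal_id[hit])
  }
  sort(unique(flagged))
}

#' Aggregate recovery observations into a diet-level recovery table
#'
#' Per (diet, alkane) cell: arithmetic mean, standard error of the mean and
#' number of included animals, after removing excluded (flagged) animals.
#' A cell left with no animals is an error. With a single animal the SEM is
#' reported as `NA`.
#'
#' @param observations Observation table from [recovery_observations()].
#' @param excluded Character vector of `animal_id`s to exclude.
#' @return A `recovery_table`: data frame with columns `diet_id`, `alkane`,
#'   `mean`, `sem`, `n`.
#' @export
mean_recovery <- function(observations, excluded = character()) {
  cells <- unique(observations[, c("diet_id", "alkane")])
  kept <- observations[!(observations$animal_id %in% excluded), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- cells$diet_id[i]; m <- cells$alkane[i]
    r <- kept$recovery[kept$diet_id == d & kept$alkane == m]
    if (length(r) == 0)
      stop_numerical(sprintf("no animals left in cell (diet %s, %s)", d, m))
    data.frame(diet_id = d, alkane = m, mean = mean(r),
               sem = if (length(r) > 1) sd(r) / sqrt(length(r)) else NA_real_,
               n = length(r), stringsAsFactors = FALSE)
  })
  recovery_table(do.call(rbind, rows))
}

#' Construct a recovery table
#'
#' @param df Data frame with columns `diet_id`, `alkane`, `mean`, and
#'   optionally `sem` and `n`. Means used for correction must be positive.
#' @return The data frame with class `recovery_table`.
#' @export
recovery_table <- function(df) {
  check_columns(df, c("diet_id", "alkane", "mean"), "recovery table")
  if (!"sem" %in% names(df)) df$sem <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_integer_
  if (anyDuplicated(paste(df$diet_id, df$alkane)))
    stop_validation("recovery table has duplicate (diet, alkane) entries")
  rownames(df) <- NULL
  class(df) <- c("recovery_table", "data.frame")
  df
}

#' Look up a mean recovery rate
#'
#' @param recovery A [recovery_table()].
#' @param diet_id,marker Cell coordinates.
#' @return The mean recovery (scalar); a missing or non-positive entry is a
#'   validation error naming the cell.
#' @export
recovery_lookup <- function(recovery, diet_id, marker) {
  hit <- recovery$diet_id == diet_id & recovery$alkane == marker
  if (!any(hit))
    stop_validation(sprintf("no recovery entry for (diet %s, %s)",
                            diet_id, marker))
  r <- recovery$mean[hit][1]
  if (!is.finite(r) || r <= 0)
    stop_validation(sprintf("recovery for (diet %s, %s) is not positive",
                            diet_id, marker))
  r
}

#' Read a recovery table from CSV
#'
#' Expects columns `diet_id`, `alkane`, `mean_recovery`, and optionally
#' `sem`, `n`.
#'
#' @param path CSV file path.
#' @return A [recovery_table()].
#' @export
read_recovery <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("diet_id", "alkane", "mean_recovery"), path)
  names(df)[names(df) == "mean_recovery"] <- "mean"
  recovery_table(df[, intersect(c("diet_id", "alkane", "mean", "sem", "n"),
                                names(df))])
}

#' Write a recovery table to CSV
#'
#' @param recovery A [recovery_table()].
#' @param path Output CSV path.
#' @param digits Significant digits (`NULL` = full precision).
#' @return Invisibly, the path.
#' @export
write_recovery <- function(recovery, path, digits = NULL) {
  out <- data.frame(diet_id = recovery$diet_id, alkane = recovery$alkane,
                    mean_recovery = recovery$mean, sem = recovery$sem,
                    n = recovery$n, stringsAsFactors = FALSE)
  if (!is.null(digits)) {
    out$mean_recovery <- signif(out$mean_recovery, digits)
    out$sem <- signif(out$sem, digits)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
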