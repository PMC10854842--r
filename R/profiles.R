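#' Default marker set
#'
#' The five major odd-chain n-alkanes quantified in plant material, feed and
#' excreta. Internal standards (C24, C34) are chemistry-side and never enter
#' the data model.
#'
#' @format Character vector of marker labels.
#' @export
DEFAULT_MARKERS <- c("C25", "C27", "C29", "C31", "C33")

#' Carbon chain length of an alkane marker
#'
#' @param label Marker label(s) such as `"C29"`.
#' @return Integer vector of chain lengths.
#' @examples
#' alkane_carbon(c("C25", "C33"))
#' @export
alkane_carbon <- function(label) {
  if (!all(grepl("^C[0-9]+$", label)))
    stop_validation(paste0("invalid alkane label(s): ",
                           paste(label[!grepl("^C[0-9]+$", label)],
                                 collapse = ", ")))
  as.integer(sub("^C", "", label))
}

# Validate a marker set: non-empty, duplicate-free, well-formed labels.
# Returns the set sorted by ascending carbon length.
validate_markers <- function(markers) {
  if (length(markers) == 0)
    stop_validation("marker set must be non-empty")
  if (anyDuplicated(markers))
    stop_validation("marker set contains duplicates")
  markers[order(alkane_carbon(markers))]
}

#' Construct an alkane concentration profile
#'
#' A profile holds the n-alkane concentrations (mg/kg DM) of one dietary
#' component (a feed, a plant, or an analyzed mixture).
#'
#' @param component Component name, e.g. `"feed"` or `"alfalfa"`.
#' @param concentrations Named numeric vector, names are marker labels,
#'   values are concentrations in mg/kg DM. All values must be finite and
#'   non-negative.
#' @return An object of class `alkane_profile`.
#' @examples
#' alkane_profile("feed", c(C25 = 1.18, C27 = 1.59, C29 = 2.58,
#'                          C31 = 1.79, C33 = 1.19))
#' @export
alkane_profile <- function(component, concentrations) {
  if (!is.character(component) || length(component) != 1 || !nzchar(component))
    stop_validation("component name must be a single non-empty string")
  if (is.null(names(concentrations)) || any(!nzchar(names(concentrations))))
    stop_validation("concentrations must be a fully named numeric vector")
  validate_markers(names(concentrations))
  conc <- as.numeric(concentrations)
  names(conc) <- names(concentrations)
  if (any(!is.finite(conc)))
    stop_validation(sprintf("non-finite concentration in profile '%s'",
                            component))
  if (any(conc < 0))
    stop_validation(sprintf("negative concentration in profile '%s'",
                            component))
  structure(list(component = component, conc = conc),
            class = "alkane_profile")
}

#' @export
print.alkane_profile <- function(x, ...) {
  cat("<alkane_profile> ", x$component, "\n", sep = "")
  print(round(x$conc, 4))
  invisible(x)
}

# Extract concentrations for a marker set; a missing marker is an error,
# never a silent zero.
profile_conc <- function(profile, markers) {
  missing <- setdiff(markers, names(profile$conc))
  if (length(missing) > 0)
    stop_validation(sprintf("profile '%s' is missing marker(s): %s",
                            profile$component,
                            paste(missing, collapse = ", ")))
  profile$conc[markers]
}

#' Construct a diet specification
#'
#' @param diet_id Diet identifier.
#' @param composition Named numeric vector of inclusion fractions (w/w, DM
#'   basis), names are component names. Fractions must be non-negative and
#'   sum to 1 (tolerance 1e-9).
#' @return An object of class `diet_spec`.
#' @examples
#' diet_spec("mixed", c(feed = 0.99, alfalfa = 0.01))
#' @export
diet_spec <- function(diet_id, composition) {
  if (!is.character(diet_id) || length(diet_id) != 1 || !nzchar(diet_id))
    stop_validation("diet_id must be a single non-empty string")
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop_validation("composition must be a fully named numeric vector")
  if (anyDuplicated(names(composition)))
    stop_validation("duplicate component in diet composition")
  comp <- as.numeric(composition)
  names(comp) <- names(composition)
  if (any(!is.finite(comp)) || any(comp < 0))
    stop_validation(sprintf("diet '%s': inclusion fractions must be finite and >= 0",
                            diet_id))
  if (abs(sum(comp) - 1) > 1e-9)
    stop_validation(sprintf("diet '%s': inclusion fractions sum to %.12g, not 1",
                            diet_id, sum(comp)))
  structure(list(diet_id = diet_id, composition = comp),
            class = "diet_spec")
}

#' Construct a per-animal record
#'
#' One bird's dry-matter intake, total excreta output and fecal alkane
#' concentrations.
#'
#' @param animal_id,diet_id Identifiers.
#' @param dm_intake Dry-matter intake, g DM/day, strictly positive.
#' @param fecal_dm_output Total excreta dry matter, g DM/day, non-negative.
#' @param fecal_conc Named numeric vector of fecal alkane concentrations
#'   (mg/kg DM of excreta), non-negative, one entry per active marker.
#' @return An object of class `animal_record`.
#' @export
animal_record <- function(animal_id, diet_id, dm_intake, fecal_dm_output,
                          fecal_conc) {
  if (!is.numeric(dm_intake) || length(dm_intake) != 1 ||
      !is.finite(dm_intake) || dm_intake <= 0)
    stop_validation(sprintf("animal '%s': dm_intake must be a positive number",
                            animal_id))
  if (!is.numeric(fecal_dm_output) || length(fecal_dm_output) != 1 ||
      !is.finite(fecal_dm_output) || fecal_dm_output < 0)
    stop_validation(sprintf("animal '%s': fecal_dm_output must be >= 0",
                            animal_id))
  if (is.null(names(fecal_conc)))
    stop_validation(sprintf("animal '%s': fecal_conc must be named", animal_id))
  validate_markers(names(fecal_conc))
  fc <- as.numeric(fecal_conc)
  names(fc) <- names(fecal_conc)
  if (any(!is.finite(fc)) || any(fc < 0))
    stop_validation(sprintf("animal '%s': fecal concentrations must be finite and >= 0",
                            animal_id))
  structure(list(animal_id = as.character(animal_id),
                 diet_id = as.character(diet_id),
                 dm_intake = dm_intake,
                 fecal_dm_output = fecal_dm_output,
                 fecal_conc = fc),
            class = "animal_record")
}

#' @export
print.animal_record <- function(x, ...) {
  cat(sprintf("<animal_record> %s (diet %s): intake %.3g g/d, excreta %.3g g/d\n",
              x$animal_id, x$diet_id, x$dm_intake, x$fecal_dm_output))
  print(round(x$fecal_conc, 4))
  invisible(x)
}

# ---- CSV input / output ----------------------------------------------------

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_schema(sprintf("'%s' is missing required column(s): %s",
                        path, paste(missing, collapse = ", ")))
}

#' Read component alkane profiles from CSV
#'
#' Expects columns `component`, `alkane`, `concentration_mg_per_kg_dm`
#' (long format, one row per component x marker).
#'
#' @param path CSV file path.
#' @return Named list of [alkane_profile()] objects, one per distinct
#'   component, in order of first appearance.
#' @export
read_profiles <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("component", "alkane", "concentration_mg_per_kg_dm"),
                path)
  if (nrow(df) == 0) return(list())
  conc <- suppressWarnings(as.numeric(df$concentration_mg_per_kg_dm))
  bad <- which(!is.finite(conc) | conc < 0)
  if (length(bad) > 0)
    stop_validation(sprintf(
      "'%s': invalid (negative or non-numeric) concentration at data row %d",
      path, bad[1]))
  key <- paste(df$component, df$alkane, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop_validation(sprintf("'%s': duplicate (component, alkane) pair: (%s)",
                            path, gsub("\r", ", ", d)))
  }
  comps <- unique(df$component)
  out <- lapply(comps, function(cn) {
    sub <- df[df$component == cn, ]
    alkane_profile(cn, setNames(conc[df$component == cn], sub$alkane))
  })
  names(out) <- comps
  out
}

#' Write component alkane profiles to CSV
#'
#' Inverse of [read_profiles()]; round-trips up to row order and float
#' formatting.
#'
#' @param profiles Named list of [alkane_profile()] objects.
#' @param path Output CSV path.
#' @param digits Significant digits for concentrations (`NULL` = full
#'   precision).
#' @return Invisibly, the path.
#' @export
write_profiles <- function(profiles, path, digits = NULL) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(component = p$component, alkane = names(p$conc),
               concentration_mg_per_kg_dm =
                 if (is.null(digits)) p$conc else signif(p$conc, digits),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(component = character(), alkane = character(),
                       concentration_mg_per_kg_dm = numeric())
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read diet specifications from CSV
#'
#' Expects columns `diet_id`, `component`, `fraction`.
#'
#' @param path CSV file path.
#' @return Named list of [diet_spec()] objects.
#' @export
read_diets <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("diet_id", "component", "fraction"), path)
  ids <- unique(df$diet_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$diet_id == id, ]
    diet_spec(id, setNames(as.numeric(sub$fraction), sub$component))
  })
  names(out) <- ids
  out
}

#' Write diet specifications to CSV
#'
#' @param diets Named list of [diet_spec()] objects.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_diets <- function(diets, path) {
  rows <- do.call(rbind, lapply(diets, function(d) {
    data.frame(diet_id = d$diet_id, component = names(d$composition),
               fraction = d$composition, stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-animal records from CSV
#'
#' Expects columns `animal_id`, `diet_id`, `dm_intake_g_d`,
#' `fecal_dm_output_g_d`, plus one fecal concentration column per marker,
#' named `fecal_<marker>` (e.g. `fecal_C25`).
#'
#' @param path CSV file path.
#' @param markers Active marker set; every `fecal_<marker>` column must be
#'   present.
#' @return List of [animal_record()] objects.
#' @export
read_animals <- function(path, markers = DEFAULT_MARKERS) {
  markers <- validate_markers(markers)
  df <- read.csv(path, stringsAsFactors = FALSE)
  fecal_cols <- paste0("fecal_", markers)
  check_columns(df, c("animal_id", "diet_id", "dm_intake_g_d",
                      "fecal_dm_output_g_d", fecal_cols), path)
  lapply(seq_len(nrow(df)), function(i) {
    animal_record(df$animal_id[i], df$diet_id[i],
                  as.numeric(df$dm_intake_g_d[i]),
                  as.numeric(df$fecal_dm_output_g_d[i]),
                  setNames(as.numeric(df[i, fecal_cols]), markers))
  })
}

#' Write per-animal records to CSV
#'
#' @param animals List of [animal_record()] objects sharing a marker set.
#' @param path Output CSV path.
#' @param digits Significant digits for numeric columns (`NULL` = full
#'   precision).
#' @return Invisibly, the path.
#' @export
write_animals <- function(animals, path, digits = NULL) {
  fmt <- function(x) if (is.null(digits)) x else signif(x, digits)
  rows <- do.call(rbind, lapply(animals, function(a) {
    row <- data.frame(animal_id = a$animal_id, diet_id = a$diet_id,
                      dm_intake_g_d = fmt(a$dm_intake),
                      fecal_dm_output_g_d = fmt(a$fecal_dm_output),
                      stringsAsFactors = FALSE)
    for (m in names(a$fecal_conc))
      row[[paste0("fecal_", m)]] <- fmt(a$fecal_conc[[m]])
    row
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- profile arithmetic ----------------------------------------------------

#' Mix component profiles according to a diet specification
#'
#' Component-wise linear mixing on a DM basis: the mixture concentration of
#' marker i is `sum_c q_c * C_{c,i}` over the components named in the diet.
#'
#' @param components Named list of [alkane_profile()] objects (names must
#'   cover every component in `spec`).
#' @param spec A [diet_spec()].
#' @return An [alkane_profile()] named after the diet.
#' @examples
#' fx <- default_fixtures()
#' mix_profiles(fx$components, diet_spec("mixed", c(feed = 0.99, alfalfa = 0.01)))
#' @export
mix_profiles <- function(components, spec) {
  stopifnot(inherits(spec, "diet_spec"))
  absent <- setdiff(names(spec$composition), names(components))
  if (length(absent) > 0)
    stop_validation(sprintf("diet '%s' names component(s) not supplied: %s",
                            spec$diet_id, paste(absent, collapse = ", ")))
  used <- names(spec$composition)
  markers <- names(components[[used[1]]]$conc)
  mixed <- numeric(length(markers))
  for (cn in used)
    mixed <- mixed + spec$composition[[cn]] * profile_conc(components[[cn]],
                                                           markers)
  alkane_profile(spec$diet_id, setNames(mixed, markers))
}

#' Percent increase of a marker concentration between two profiles
#'
#' Returns `100 * (other_i - base_i) / base_i`, unrounded; round for
#' reporting (the conventional display is the nearest integer,
#' half-to-even).
#'
#' @param base,other [alkane_profile()] objects.
#' @param marker Marker label.
#' @return Percent change (numeric scalar).
#' @examples
#' fx <- default_fixtures()
#' round(percent_increase(fx$components$feed, fx$mixed_analyzed, "C27")) # 38
#' @export
percent_increase <- function(base, other, marker) {
  b <- profile_conc(base, marker)
  o <- profile_conc(other, marker)
  if (b == 0)
    stop_validation(sprintf(
      "percent increase undefined: base concentration of %s is 0", marker))
  unname(100 * (o - b) / b)
}
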