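# Synthetic flock generation: a generative mirror of a restricted-feeding
# marker trial, with every quantity the estimator infers available as
# ground truth.

#' Packaged reference fixtures
#'
#' The measured n-alkane concentration profiles (mg/kg DM) of the
#' commercial layer feed, the dried alfalfa batch and the analyzed 1%-
#' alfalfa mixture, together with the diet-level mean fecal recovery rates
#' of a restricted-fed laying-hen trial. These are the defaults of
#' [sim_config()] and convenient anchors for examples and tests.
#'
#' Note that the analyzed mixed-feed profile differs slightly from the
#' arithmetic 0.99/0.01 mixture of the feed and alfalfa profiles (assay
#' variation); both are provided and neither is forced to equal the other.
#'
#' @return List with elements `components` (named list: `feed`, `alfalfa`
#'   [alkane_profile()]s), `mixed_analyzed` (analyzed mixture profile),
#'   `diets` (named list of [diet_spec()]: `commercial`, `mixed`) and
#'   `recovery` (a [recovery_table()] with per-diet means, SEM and n).
#' @examples
#' default_fixtures()$components$alfalfa
#' @export
default_fixtures <- function() {
  feed <- alkane_profile("feed", c(C25 = 1.18, C27 = 1.59, C29 = 2.58,
                                   C31 = 1.79, C33 = 1.19))
  alfalfa <- alkane_profile("alfalfa", c(C25 = 8.12, C27 = 44.3, C29 = 289,
                                         C31 = 358, C33 = 26.9))
  mixed_analyzed <- alkane_profile("mixed", c(C25 = 1.28, C27 = 2.20,
                                              C29 = 5.69, C31 = 5.13,
                                              C33 = 1.51))
  rec <- recovery_table(data.frame(
    diet_id = rep(c("commercial", "mixed"), each = 5),
    alkane = rep(DEFAULT_MARKERS, 2),
    mean = c(0.439, 0.369, 0.302, 0.297, 0.339,
             0.479, 0.375, 0.372, 0.437, 0.409),
    sem = rep(c(0.0094, 0.0092), each = 5),
    n = rep(c(23L, 24L), each = 5),
    stringsAsFactors = FALSE))
  list(components = list(feed = feed, alfalfa = alfalfa),
       mixed_analyzed = mixed_analyzed,
       diets = list(commercial = diet_spec("commercial", c(feed = 1)),
                    mixed = diet_spec("mixed", c(feed = 0.99,
                                                 alfalfa = 0.01))),
       recovery = rec)
}

#' Simulation configuration
#'
#' Defaults describe a restricted-fed laying-hen trial: two diets (a
#' commercial feed control and a 1% plant inclusion), 24 birds per diet,
#' daily DM intake ~70 +/- 5 g truncated to (0, 80], marker recoveries at
#' the packaged diet-level means, and 5% multiplicative lognormal
#' measurement noise on fecal concentrations.
#'
#' @param components Named list of [alkane_profile()]s (default: packaged
#'   feed and alfalfa profiles).
#' @param diets Named list of [diet_spec()]s (default: `commercial`
#'   \{feed: 1\} and `mixed` \{feed: 0.99, alfalfa: 0.01\}).
#' @param n_per_diet Birds per diet (default 24).
#' @param intake_mean,intake_sd Daily DM intake distribution, g/d (default
#'   70 +/- 5), truncated to `(0, intake_max]`.
#' @param intake_max Upper truncation of intake, g/d (default 80, the
#'   restricted allowance).
#' @param digestibility Whole-diet DM digestibility (default 0.65); sets
#'   `fecal_dm_output = intake * (1 - digestibility)`. The proportion
#'   estimator is invariant to this constant (it cancels in the coefficient
#'   ratio).
#' @param true_recovery A [recovery_table()] of the per-(diet, alkane)
#'   recoveries used to generate fecal output (default: packaged means).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise on fecal concentrations (default 0.05); the noise has mean 1
#'   (mu = -sigma^2/2), so recovery correction stays unbiased to first
#'   order.
#' @param selectivity_shift Added to the formulated plant fraction to give
#'   the realized one (clipped to \[0, 1\]); negative values emulate birds
#'   selecting against the plant (default 0).
#' @param plant_component Name of the plant component the shift applies to
#'   (default `"alfalfa"`).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(components = NULL, diets = NULL, n_per_diet = 24,
                       intake_mean = 70, intake_sd = 5, intake_max = 80,
                       digestibility = 0.65, true_recovery = NULL,
                       noise_cv = 0.05, selectivity_shift = 0,
                       plant_component = "alfalfa", seed = 1) {
  fx <- default_fixtures()
  if (is.null(components)) components <- fx$components
  if (is.null(diets)) diets <- fx$diets
  if (is.null(true_recovery)) true_recovery <- fx$recovery
  if (n_per_diet < 1) stop_validation("n_per_diet must be >= 1")
  if (intake_mean <= 0 || intake_sd < 0 || intake_max <= 0)
    stop_validation("intake parameters must be positive")
  if (digestibility <= 0 || digestibility >= 1)
    stop_validation("digestibility must lie in (0, 1)")
  if (noise_cv < 0) stop_validation("noise_cv must be >= 0")
  if (!inherits(true_recovery, "recovery_table"))
    stop_validation("true_recovery must be a recovery_table")
  structure(list(components = components, diets = diets,
                 n_per_diet = as.integer(n_per_diet),
                 intake_mean = intake_mean, intake_sd = intake_sd,
                 intake_max = intake_max, digestibility = digestibility,
                 true_recovery = true_recovery, noise_cv = noise_cv,
                 selectivity_shift = selectivity_shift,
                 plant_component = plant_component,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Run expr with a private RNG stream seeded from `seed`; the caller's RNG
# state is untouched, and equal seeds give bit-identical draws.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a flock with known ground truth
#'
#' Per bird: DM intake is drawn from a truncated normal; the realized plant
#' fraction is the formulated one plus `selectivity_shift` (clipped to
#' \[0, 1\]); the realized diet profile follows by linear mixing; daily
#' marker intake (mg/d) times the configured true recovery gives fecal
#' marker output; fecal DM is `intake * (1 - digestibility)`; the fecal
#' concentration is output over fecal DM times a mean-1 lognormal noise
#' factor. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return List with `animals` (list of [animal_record()]), `truth` (named
#'   numeric: realized plant fraction per animal) and `diet_profiles`
#'   (named list of realized consumed [alkane_profile()]s per diet,
#'   noise-free).
#' @examples
#' flock <- simulate_flock(sim_config(n_per_diet = 4, seed = 42))
#' flock$truth
#' @export
simulate_flock <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  markers <- names(config$components[[1]]$conc)
  with_seed(config$seed, {
    animals <- list()
    truth <- numeric()
    diet_profiles <- list()
    for (diet in config$diets) {
      comp <- realized_composition(config, diet)
      profile <- mix_profiles(config$components,
                              diet_spec(diet$diet_id, comp))
      diet_profiles[[diet$diet_id]] <- profile
      q_real <- if (config$plant_component %in% names(comp))
        comp[[config$plant_component]] else 0
      for (k in seq_len(config$n_per_diet)) {
        id <- sprintf("%s_%02d", diet$diet_id, k)
        intake <- draw_truncnorm(config$intake_mean, config$intake_sd,
                                 config$intake_max)
        marker_intake <- profile$conc[markers] * intake / 1000      # mg/d
        r <- vapply(markers, function(m)
          recovery_lookup(config$true_recovery, diet$diet_id, m), numeric(1))
        output <- marker_intake * r                                  # mg/d
        fecal_dm <- intake * (1 - config$digestibility)              # g/d
        conc <- output / (fecal_dm / 1000)                           # mg/kg
        if (config$noise_cv > 0) {
          sigma <- sqrt(log(1 + config$noise_cv^2))
          conc <- conc * rlnorm(length(conc), meanlog = -sigma^2 / 2,
                                sdlog = sigma)
        }
        animals[[id]] <- animal_record(id, diet$diet_id, intake, fecal_dm,
                                       setNames(conc, markers))
        truth[id] <- q_real
      }
    }
    list(animals = unname(animals), truth = truth,
         diet_profiles = diet_profiles)
  })
}

# Formulated composition with the selectivity shift applied to the plant
# component; the other components are rescaled proportionally so the
# fractions still sum to 1.
realized_composition <- function(config, diet) {
  comp <- diet$composition
  pc <- config$plant_component
  if (config$selectivity_shift == 0 || !(pc %in% names(comp)))
    return(comp)
  q0 <- comp[[pc]]
  q1 <- min(max(q0 + config$selectivity_shift, 0), 1)
  others <- setdiff(names(comp), pc)
  rest <- sum(comp[others])
  if (rest > 0) comp[others] <- comp[others] * (1 - q1) / rest
  comp[pc] <- q1
  comp
}

draw_truncnorm <- function(mean, sd, upper) {
  if (sd == 0) return(min(mean, upper))
  repeat {
    x <- rnorm(1, mean, sd)
    if (x > 0 && x <= upper) return(x)
  }
}
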