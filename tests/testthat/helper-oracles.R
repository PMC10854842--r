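# Independent oracles and small fixture builders shared across tests.

# Closed-form constrained least squares for a 2-column design: the optimum
# of a convex QP over the non-negative quadrant is either the unconstrained
# solution (when feasible) or the best single-axis projection, so exhaustive
# case analysis over the three boundary cases is exact.
nnls2_oracle <- function(A, b) {
  resid_ss <- function(x) sum((b - A %*% x)^2)
  cands <- list(c(0, 0))
  xt <- tryCatch(as.numeric(solve(crossprod(A), crossprod(A, b))),
                 error = function(e) NULL)
  if (!is.null(xt) && all(xt >= 0)) cands <- c(cands, list(xt))
  for (j in 1:2) {
    a <- A[, j]
    x <- c(0, 0)
    x[j] <- max(0, sum(a * b) / sum(a * a))
    cands <- c(cands, list(x))
  }
  cands[[which.min(vapply(cands, resid_ss, numeric(1)))]]
}

# Random strictly positive 2-component design on the 5 default markers.
random_design <- function() {
  matrix(exp(rnorm(10, mean = 1, sd = 1.5)), nrow = 5,
         dimnames = list(DEFAULT_MARKERS, c("feed", "plant")))
}

random_profile <- function(component = "p") {
  alkane_profile(component,
                 setNames(exp(rnorm(5, 1, 1)), DEFAULT_MARKERS))
}

# A small flock written by hand: intake/excreta chosen so recoveries are
# known exactly from the marker balance.
make_animal <- function(id, diet = "commercial", intake = 70, fecal_dm = 24.5,
                        conc = c(C25 = 1.48, C27 = 1.68, C29 = 2.23,
                                 C31 = 1.52, C33 = 1.15)) {
  animal_record(id, diet, intake, fecal_dm, conc)
}

write_fixture_profiles <- function(path = tempfile(fileext = ".csv")) {
  write_profiles(default_fixtures()$components, path)
  path
}
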