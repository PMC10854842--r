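test_that("per-animal recovery is the marker balance", {
  feed <- default_fixtures()$components$feed
  a <- make_animal("hen", intake = 70, fecal_dm = 25,
                   conc = c(C25 = 0, C27 = 0, C29 = 2.87, C31 = 0, C33 = 0))
  obs <- animal_recovery(a, feed, "C29")
  expect_equal(obs$recovery, (25 * 2.87) / (70 * 2.58), tolerance = 1e-12)
  # zero fecal concentration -> zero recovery
  expect_equal(animal_recovery(a, feed, "C25")$recovery, 0)
  # output mg/d equal to intake mg/d -> recovery 1
  b <- make_animal("hen2", intake = 50, fecal_dm = 50,
                   conc = c(C25 = 1.18, C27 = 1.59, C29 = 2.58, C31 = 1.79,
                            C33 = 1.19))
  expect_equal(animal_recovery(b, feed, "C27")$recovery, 1)
  # dietary concentration of zero leaves recovery undefined
  zero <- alkane_profile("z", c(C25 = 0, C27 = 1, C29 = 1, C31 = 1, C33 = 1))
  expect_error(animal_recovery(a, zero, "C25"), "undefined",
               class = "alkdiet_validation_error")
  # recoveries above 1 are admitted with a warning
  hot <- make_animal("hen3", intake = 10, fecal_dm = 50,
                     conc = c(C25 = 1.18, C27 = 1.59, C29 = 2.58, C31 = 1.79,
                              C33 = 1.19))
  expect_warning(animal_recovery(hot, feed, "C25"), "> 1")
})

test_that("recovery is invariant to jointly rescaling DM flows", {
  feed <- default_fixtures()$components$feed
  a <- make_animal("a", intake = 70, fecal_dm = 24.5)
  a2 <- make_animal("a", intake = 140, fecal_dm = 49)
  for (m in DEFAULT_MARKERS)
    expect_equal(animal_recovery(a, feed, m)$recovery,
                 animal_recovery(a2, feed, m)$recovery, tolerance = 1e-12)
})

test_that("total recovery is the intake-weighted mean of marker recoveries", {
  # two markers with intakes 1 and 3 mg/d and recoveries 0.2 and 0.6:
  # total = (0.2 + 1.8) / 4 = 0.5. Encode via a 2-marker profile.
  diet <- alkane_profile("d", c(C25 = 1, C27 = 3))
  a <- animal_record("a", "d", 1000, 1000,
                     c(C25 = 0.2, C27 = 1.8))  # outputs 0.2, 1.8 mg/d
  expect_equal(total_recovery(a, diet), 0.5, tolerance = 1e-12)

  # constant per-marker recovery r gives total recovery r
  feed <- default_fixtures()$components$feed
  r <- 0.37
  conc <- feed$conc * r * (70 / 24.5)
  a2 <- animal_record("c", "d", 70, 24.5, conc)
  expect_equal(total_recovery(a2, feed), r, tolerance = 1e-12)

  # total recovery always lies between the per-marker extremes
  set.seed(403)
  for (rep in 1:20) {
    diet_p <- random_profile("d")
    a3 <- animal_record("x", "d", 70, 24.5,
                        setNames(exp(rnorm(5, 0, 1)), DEFAULT_MARKERS))
    per <- vapply(DEFAULT_MARKERS, function(m)
      suppressWarnings(animal_recovery(a3, diet_p, m))$recovery, numeric(1))
    tot <- total_recovery(a3, diet_p)
    expect_gte(tot, min(per) - 1e-12)
    expect_lte(tot, max(per) + 1e-12)
  }
})

test_that("outlier screen flags anomalous whole-profile recoveries", {
  feed <- default_fixtures()$components$feed
  # construct four control birds with total recoveries .35/.36/.37/.66;
  # the .66 bird also has the depressed intake of 42 g/d
  mk <- function(id, r, intake = 70) {
    fecal_dm <- intake * 0.35
    animal_record(id, "commercial", intake, fecal_dm,
                  feed$conc * r * (intake / fecal_dm))
  }
  animals <- list(mk("h1", 0.35), mk("h2", 0.36), mk("h3", 0.37),
                  mk("h4", 0.66, intake = 42))
  obs <- recovery_observations(animals, list(commercial = feed))
  expect_equal(flag_outliers(obs), "h4")
  # the flagged bird's own total recovery really is 0.66
  expect_equal(total_recovery(animals[[4]], feed), 0.66, tolerance = 1e-12)

  # no dispersion -> nothing to flag
  same <- list(mk("s1", 0.35), mk("s2", 0.35), mk("s3", 0.35))
  obs2 <- recovery_observations(same, list(commercial = feed))
  expect_identical(flag_outliers(obs2), character())

  # rule disabled entirely
  expect_identical(flag_outliers(obs, threshold = 1.0, k_mad = Inf),
                   character())
  expect_identical(flag_outliers(obs[0, ]), character())
})

test_that("diet-level aggregation gives cell means, SEM and n", {
  obs <- data.frame(animal_id = c("a", "b", "c"), diet_id = "commercial",
                    alkane = "C25", intake_mg_d = 1, output_mg_d = 0.3,
                    recovery = c(0.30, 0.30, 0.30))
  tab <- mean_recovery(obs)
  expect_equal(tab$mean, 0.30)
  expect_equal(tab$sem, 0)
  expect_equal(tab$n, 3L)

  obs2 <- obs[1:2, ]; obs2$recovery <- c(0.2, 0.4)
  tab2 <- mean_recovery(obs2)
  expect_equal(tab2$mean, 0.3)
  expect_equal(tab2$sem, 0.1, tolerance = 1e-12)

  # single animal: value passes through, SEM reported missing
  tab1 <- mean_recovery(obs[1, ])
  expect_equal(tab1$mean, 0.30)
  expect_true(is.na(tab1$sem))

  # excluding every animal in a cell is an error naming the cell
  expect_error(mean_recovery(obs, excluded = c("a", "b", "c")), "C25",
               class = "alkdiet_numerical_error")
})

test_that("estimated mean recoveries recover the generating truth", {
  # flock generated at the packaged recovery means with 5% noise: the
  # estimated cell means must sit within 3 SEM of the generating values
  fx <- default_fixtures()
  flock <- simulate_flock(sim_config(n_per_diet = 23, noise_cv = 0.05,
                                     seed = 207))
  obs <- suppressWarnings(
    recovery_observations(flock$animals, flock$diet_profiles))
  tab <- mean_recovery(obs)
  for (i in seq_len(nrow(tab))) {
    truth <- recovery_lookup(fx$recovery, tab$diet_id[i], tab$alkane[i])
    expect_lt(abs(tab$mean[i] - truth), 3 * tab$sem[i])
  }
})
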