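test_that("profile CSV reader parses components and enforces the contract", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("component,alkane,concentration_mg_per_kg_dm",
               "alfalfa,C29,289", "alfalfa,C31,358", "alfalfa,C25,8.12",
               "alfalfa,C27,44.3", "alfalfa,C33,26.9",
               "feed,C25,1.18", "feed,C27,1.59", "feed,C29,2.58",
               "feed,C31,1.79", "feed,C33,1.19"), path)
  profs <- read_profiles(path)
  expect_named(profs, c("alfalfa", "feed"))
  expect_equal(profs$alfalfa$conc[["C29"]], 289)
  expect_equal(profs$alfalfa$conc[["C31"]], 358)

  # empty body with a valid header is a valid, empty table
  empty <- tempfile(fileext = ".csv")
  writeLines("component,alkane,concentration_mg_per_kg_dm", empty)
  expect_identical(read_profiles(empty), list())

  # negative concentration names the offending row
  bad <- tempfile(fileext = ".csv")
  writeLines(c("component,alkane,concentration_mg_per_kg_dm",
               "feed,C25,1.18", "feed,C27,-1"), bad)
  expect_error(read_profiles(bad), "row 2",
               class = "alkdiet_validation_error")

  # duplicate (component, alkane) pair
  dup <- tempfile(fileext = ".csv")
  writeLines(c("component,alkane,concentration_mg_per_kg_dm",
               "feed,C25,1.18", "feed,C25,1.20"), dup)
  expect_error(read_profiles(dup), "duplicate",
               class = "alkdiet_validation_error")

  # missing column is a schema error naming the column
  nocol <- tempfile(fileext = ".csv")
  writeLines(c("component,alkane", "feed,C25"), nocol)
  expect_error(read_profiles(nocol), "concentration_mg_per_kg_dm",
               class = "alkdiet_schema_error")
})

test_that("profile and animal tables round-trip through CSV", {
  fx <- default_fixtures()
  p1 <- tempfile(fileext = ".csv")
  write_profiles(fx$components, p1)
  back <- read_profiles(p1)
  expect_equal(back$feed$conc, fx$components$feed$conc)
  expect_equal(back$alfalfa$conc, fx$components$alfalfa$conc)

  flock <- simulate_flock(sim_config(n_per_diet = 3, seed = 11))
  p2 <- tempfile(fileext = ".csv")
  write_animals(flock$animals, p2)
  animals <- read_animals(p2)
  expect_length(animals, 6)
  expect_equal(animals[[1]]$fecal_conc, flock$animals[[1]]$fecal_conc)
  expect_equal(animals[[4]]$dm_intake, flock$animals[[4]]$dm_intake)
})

test_that("animal CSV reader enforces invariants at load time", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(paste0("animal_id,diet_id,dm_intake_g_d,fecal_dm_output_g_d,",
                      "fecal_C25,fecal_C27,fecal_C29,fecal_C31,fecal_C33"),
               "hen01,mixed,68.6,24.0,1.7,1.8,6.0,6.4,1.7"), path)
  animals <- read_animals(path)
  expect_length(animals, 1)
  expect_equal(animals[[1]]$dm_intake, 68.6)

  bad <- tempfile(fileext = ".csv")
  writeLines(c(paste0("animal_id,diet_id,dm_intake_g_d,fecal_dm_output_g_d,",
                      "fecal_C25,fecal_C27,fecal_C29,fecal_C31,fecal_C33"),
               "hen01,mixed,0,24.0,1.7,1.8,6.0,6.4,1.7"), bad)
  expect_error(read_animals(bad), "dm_intake",
               class = "alkdiet_validation_error")

  nocol <- tempfile(fileext = ".csv")
  writeLines(c("animal_id,diet_id,dm_intake_g_d,fecal_dm_output_g_d,fecal_C25",
               "hen01,mixed,68.6,24.0,1.7"), nocol)
  expect_error(read_animals(nocol), "fecal_C27",
               class = "alkdiet_schema_error")
})

test_that("flock-sized animal tables load with one record per row", {
  cfgs <- list(sim_config(n_per_diet = 23, seed = 5),
               sim_config(n_per_diet = 24, seed = 5))
  # 23 control + 24 mixed: write both diets from separate configs
  fl1 <- simulate_flock(cfgs[[1]])
  fl2 <- simulate_flock(cfgs[[2]])
  animals <- c(fl1$animals[vapply(fl1$animals, function(a)
    a$diet_id == "commercial", TRUE)],
    fl2$animals[vapply(fl2$animals, function(a) a$diet_id == "mixed", TRUE)])
  path <- tempfile(fileext = ".csv")
  write_animals(animals, path)
  expect_length(read_animals(path), 47)
})

test_that("diet mixing is component-wise linear on a DM basis", {
  fx <- default_fixtures()
  # identity mixtures return the named component unchanged
  one_feed <- mix_profiles(fx$components, diet_spec("d", c(feed = 1)))
  expect_equal(one_feed$conc, fx$components$feed$conc)
  one_alf <- mix_profiles(fx$components, diet_spec("d", c(alfalfa = 1)))
  expect_equal(one_alf$conc, fx$components$alfalfa$conc)

  # measured-profile arithmetic: 0.99 * 2.58 + 0.01 * 289
  mixed <- mix_profiles(fx$components, fx$diets$mixed)
  expect_equal(mixed$conc[["C29"]], 5.4442, tolerance = 1e-12)

  # linearity on random profiles: mix(alpha q + (1-alpha) q') equals the
  # alpha-blend of the two mixtures
  set.seed(401)
  for (rep in 1:10) {
    comps <- list(a = random_profile("a"), b = random_profile("b"))
    q1 <- c(a = 0.3, b = 0.7); q2 <- c(a = 0.9, b = 0.1)
    alpha <- runif(1)
    blend <- alpha * q1 + (1 - alpha) * q2
    m_blend <- mix_profiles(comps, diet_spec("d", blend))
    m1 <- mix_profiles(comps, diet_spec("d", q1))
    m2 <- mix_profiles(comps, diet_spec("d", q2))
    expect_equal(m_blend$conc, alpha * m1$conc + (1 - alpha) * m2$conc,
                 tolerance = 1e-12)
  }

  expect_error(mix_profiles(fx$components["feed"], fx$diets$mixed),
               "alfalfa", class = "alkdiet_validation_error")
})

test_that("percent increase reproduces the profile-shift arithmetic", {
  fx <- default_fixtures()
  feed <- fx$components$feed
  expect_equal(percent_increase(feed, fx$mixed_analyzed, "C27"),
               100 * (2.20 - 1.59) / 1.59, tolerance = 1e-12)
  expect_equal(percent_increase(feed, fx$mixed_analyzed, "C33"),
               100 * (1.51 - 1.19) / 1.19, tolerance = 1e-12)
  expect_equal(percent_increase(feed, feed, "C29"), 0)
  zero <- alkane_profile("z", c(C25 = 0, C27 = 1, C29 = 1, C31 = 1, C33 = 1))
  expect_error(percent_increase(zero, feed, "C25"), "undefined",
               class = "alkdiet_validation_error")

  # monotone in the inclusion fraction whenever the plant is richer
  set.seed(402)
  comps <- default_fixtures()$components
  qs <- seq(0.005, 0.05, by = 0.005)
  incr <- vapply(qs, function(q) {
    m <- mix_profiles(comps, diet_spec("d", c(feed = 1 - q, alfalfa = q)))
    percent_increase(comps$feed, m, "C31")
  }, numeric(1))
  expect_true(all(diff(incr) > 0))
})

test_that("domain constructors reject invalid values", {
  expect_error(alkane_profile("x", c(C25 = -1, C27 = 1, C29 = 1, C31 = 1,
                                     C33 = 1)),
               "negative", class = "alkdiet_validation_error")
  expect_error(diet_spec("d", c(feed = 0.5, alfalfa = 0.4)), "sum",
               class = "alkdiet_validation_error")
  expect_error(animal_record("a", "d", -1, 10, c(C25 = 1)),
               class = "alkdiet_validation_error")
  expect_error(alkane_carbon("X25"), class = "alkdiet_validation_error")
  expect_equal(alkane_carbon(c("C25", "C33")), c(25L, 33L))
})
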