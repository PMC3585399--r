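# Campaign drivers, configuration round-trips and file formats.

test_that("rdf_opt is deterministic and validates its input", {
  expect_error(rdf_opt("Na", 3), "usage")
  t1 <- rdf_opt("Na", 4, nsteps = 30000, seed = 5)
  t2 <- rdf_opt("Na", 4, nsteps = 30000, seed = 5)
  expect_identical(t1, t2)
  expect_true(all(c("ion", "n", "r_opt", "seed") %in% names(t1)))
})

test_that("campaign configurations survive a YAML round trip", {
  cfg <- campaign_config(pairs = list(c("Na", "K"), c("Na", "Li")),
                         n_values = c(4, 6), sites = "LeuT_Na2",
                         kf_grid = c(0, 10, 1000), scale = 0.02, seed = 99)
  f <- tempfile(fileext = ".yaml")
  write_campaign_config(cfg, f)
  cfg2 <- read_campaign_config(f)
  expect_equal(cfg2, cfg)
  expect_error(campaign_config(scale = 0), "scale")
})

test_that("the selectivity curve carries its baseline identity and provenance columns", {
  cur <- rlf_curve(c("Na", "K"), n = 4, kf_grid = c(0), scale = 0.002,
                   seed = 3)
  row <- cur$table[1, ]
  expect_identical(row$ddG_rlf, 0)     # kf = 0 baseline, exact
  expect_true(all(c("seed", "windows", "steps_per_window", "se",
                    "ddG_exchange") %in% names(cur$table)))
  expect_equal(row$ddG_hydr, hydration_ddG("K", "Na"))
  # exchange at kf = 0 is the site leg corrected by hydration only
  expect_equal(row$ddG_exchange, row$dG_site_exchange - row$ddG_hydr,
               tolerance = 1e-12)
})

test_that("XYZ output round-trips coordinates and carries system metadata", {
  sys <- build_abstract_system("K", 4, r_opt = 2.7, kf = 50)
  f <- tempfile(fileext = ".xyz")
  write_xyz(sys, f)
  back <- read_xyz(f)
  expect_equal(back$frames[[1]], unname(sys$coords), tolerance = 1e-6)
  expect_identical(back$elements, sys$atoms$element)
  expect_match(back$comments[1], "ion=K")
  expect_match(back$comments[1], "kf=50")

  tr <- run_dynamics(sys, 500, seed = 1, save_interval = 250)
  f2 <- tempfile(fileext = ".xyz")
  write_xyz(tr, f2)
  expect_length(read_xyz(f2)$frames, 3)
})

test_that("energy series and metadata sidecars are written", {
  sys <- build_toy_oracle(1, kf = 10)
  tr <- run_dynamics(sys, 500, seed = 2)
  fe <- tempfile(fileext = ".csv"); fm <- tempfile(fileext = ".json")
  write_energy_series(tr, fe)
  ser <- read.csv(fe)
  expect_true(all(c("step", "total", "tkin") %in% names(ser)))
  write_run_metadata(tr, fm)
  meta <- jsonlite::read_json(fm)
  expect_equal(meta$seed, 2)
  expect_equal(meta$timestep, 1)
})
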