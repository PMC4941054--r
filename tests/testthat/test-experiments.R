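test_that("fixture response curves hit the liverwort anchor points", {
  curves <- response_curves(fixture_species())
  at <- function(sp, var, x) curves$npp[curves$species == sp &
                                          curves$variable == var &
                                          curves$x == x]
  expect_equal(at("I", "co2", 400), 5, tolerance = 0.1)
  expect_equal(at("II", "co2", 400), 2, tolerance = 0.1)
  # NPP non-decreasing in CO2, non-increasing in O2, for every curve
  for (sp in unique(curves$species)) {
    co2 <- curves[curves$species == sp & curves$variable == "co2", ]
    expect_true(all(diff(co2$npp[order(co2$x)]) >= -1e-9))
    o2 <- curves[curves$species == sp & curves$variable == "o2", ]
    expect_true(all(diff(o2$npp[order(o2$x)]) <= 1e-9))
  }
})

test_that("response curves for run-dominant species and empty pools", {
  run <- tiny_pipeline()
  dom <- dominant_species(run$veg)
  curves <- response_curves(dom)
  expect_true(all(c("co2", "light", "o2") %in% curves$variable))
  expect_warning(empty <- response_curves(dom[0, ]), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("a reduced-scale baseline experiment emits a consistent summary", {
  out_dir <- withr::local_tempdir()
  cfg <- experiment_config("baseline", seed = 11,
                           overrides = list(n_lon = 8, n_lat = 8,
                                            n_species = 6, n_years = 30),
                           output_dir = out_dir)
  res <- run_experiment(cfg)
  s <- res$summary
  expect_equal(nrow(s), 1)
  expect_true(all(c("npp_gt", "gpp_gt", "cover", "biomass_gt",
                    "weathering_km3") %in% names(s)))
  expect_true(all(s[, c("npp_gt", "gpp_gt", "cover", "biomass_gt",
                        "weathering_km3")] >= 0))
  expect_lte(s$npp_gt, s$gpp_gt)
  expect_true(s$cover <= 1)
  # outputs and manifest written
  expect_true(file.exists(file.path(out_dir, "baseline_summary.csv")))
  mf <- readLines(file.path(out_dir, "baseline_manifest.txt"))
  expect_true(any(grepl("seed = 11", mf)))
  expect_true(any(grepl("fingerprint = ", mf)))
})

test_that("experiment configs validate their name", {
  expect_error(experiment_config("warp_drive"), "unknown experiment")
})

test_that("the shipped configuration file round-trips through the reader", {
  path <- system.file("extdata", "default_config.toml",
                      package = "cryptoweather")
  skip_if(path == "", "installed config not found")
  cfg <- read_config(path)
  expect_equal(cfg[names(default_config())], default_config())
})

test_that("configuration fingerprints are stable and discriminating", {
  a <- config_fingerprint(list(x = 1))
  expect_identical(a, config_fingerprint(list(x = 1)))
  expect_false(identical(a, config_fingerprint(list(x = 2))))
})
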