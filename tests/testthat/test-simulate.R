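test_that("pure spectra follow the Gaussian band closed form", {
  grid <- wavenumber_grid(5000, 7000, 4)
  b <- band_set("x", centers = 6000, widths = 100, heights = 1)
  a <- pure_spectrum(b, grid)
  expect_equal(a[grid$points == 6000], 1)
  expect_equal(a[grid$points == 6100], exp(-0.5), tolerance = 1e-12)
  empty <- band_set("none", numeric(0), numeric(0), numeric(0))
  expect_equal(pure_spectrum(empty, grid), rep(0, length(grid$points)))
  expect_true(all(a >= 0))
})

test_that("band library is deterministic and AZ-dominated at label composition", {
  lib1 <- default_library(seed = 3)
  lib2 <- default_library(seed = 3)
  expect_identical(lib1, lib2)
  lib <- default_library()
  # DHA bands are shifted AS bands with reduced heights
  expect_equal(lib$DHA$centers, lib$AS$centers + 30)
  expect_equal(lib$DHA$heights, lib$AS$heights * 0.9)
  # partial absorbance integral (area x label fraction): AZ dominates
  frac <- hgc_formulation()$fractions
  area <- function(b) sum(b$heights * b$widths)
  expect_gt(area(lib$AZ) * frac[["AZ"]], area(lib$AS) * frac[["AS"]])
})

test_that("noise-free mixtures are exact linear combinations", {
  grid <- coarse_grid()
  lib <- toy_library()
  a_pure <- pure_spectrum(lib$AZ, grid)
  b_pure <- pure_spectrum(lib$AS, grid)
  expect_equal(mixture_spectrum(c(AZ = 1), lib, grid, noise_free()), a_pure)
  expect_equal(mixture_spectrum(c(AZ = 0.5, AS = 0.5), lib, grid, noise_free()),
               0.5 * a_pure + 0.5 * b_pure, tolerance = 1e-12)
  expect_error(mixture_spectrum(c(AZ = -0.1, AS = 1.1), lib, grid),
               "negative fraction")
})

test_that("mixture draws are reproducible under a fixed seed", {
  grid <- coarse_grid(); lib <- toy_library()
  set.seed(99); s1 <- mixture_spectrum(c(AZ = 0.7, AS = 0.3), lib, grid)
  set.seed(99); s2 <- mixture_spectrum(c(AZ = 0.7, AS = 0.3), lib, grid)
  expect_identical(s1, s2)
  set.seed(100); s3 <- mixture_spectrum(c(AZ = 0.7, AS = 0.3), lib, grid)
  expect_false(identical(s1, s3))
})

test_that("repack averaging converges to the noise-free expectation", {
  grid <- coarse_grid(); lib <- toy_library()
  # additive-only noise so the per-point standard error is uniform
  nm <- noise_model(gain_sd = 0, offset_sd = 0, slope_sd = 0,
                    additive_sd = 1e-3, weighing_sd = 0)
  tab <- data.frame(level_percent = 100, mass_AZ_mg = 500, mass_AS_mg = 350,
                    mass_placebo_mg = 150, total_mg = 1000,
                    role = "calibration", replicate_id = 1,
                    varied_api = "AZ")
  form <- hgc_formulation()
  reps <- 200
  s <- simulate_set(tab, form, lib, grid, nm, repacks = reps, seed = 5)
  truth <- simulate_set(tab, form, lib, grid, noise_free(), repacks = 1)
  dev <- s$absorbance[1, ] - truth$absorbance[1, ]
  se <- 1e-3 / sqrt(reps)
  expect_lt(sqrt(mean(dev^2)) / se, 1.2)
  expect_gt(sqrt(mean(dev^2)) / se, 0.8)
})

test_that("repack averaging shrinks variance like 1/repacks", {
  grid <- wavenumber_grid(5000, 6000, 50)
  lib <- toy_library()
  nm <- noise_model(0, 0, 0, additive_sd = 1e-3, weighing_sd = 0)
  tab <- data.frame(level_percent = 100, mass_AZ_mg = 500, mass_AS_mg = 350,
                    mass_placebo_mg = 150, total_mg = 1000, role = "x",
                    replicate_id = 1, varied_api = "AZ")
  tab <- tab[rep(1, 300), ]
  tab$replicate_id <- 1:300
  form <- hgc_formulation()
  v1 <- mean(apply(simulate_set(tab, form, lib, grid, nm, repacks = 1,
                                seed = 7)$absorbance, 2, var))
  v4 <- mean(apply(simulate_set(tab, form, lib, grid, nm, repacks = 4,
                                seed = 7)$absorbance, 2, var))
  expect_equal(v1 / v4, 4, tolerance = 0.25)
})

test_that("simulated design sets have the designed shape and metadata", {
  s <- sim_calibration("AZ", seed = 17)
  expect_s3_class(s, "spectra_set")
  expect_equal(nrow(s$absorbance), 54)
  expect_equal(ncol(s$absorbance), 1500)
  expect_equal(as.vector(table(s$meta$level_percent)), rep(6L, 9))
  expect_true(all(s$absorbance >= 0))
  # gravimetric truth stays near nominal (weighing SD 0.15%)
  expect_lt(max(abs(s$meta$true_AZ_pct - s$meta$nominal_AZ_pct) /
                  s$meta$nominal_AZ_pct), 0.02)
  # bit reproducibility
  s2 <- sim_calibration("AZ", seed = 17)
  expect_identical(s$absorbance, s2$absorbance)
})

test_that("repacks = 1 with zero noise equals the plain mixture spectrum", {
  grid <- coarse_grid(); lib <- toy_library()
  tab <- data.frame(level_percent = 100, mass_AZ_mg = 400, mass_AS_mg = 400,
                    mass_placebo_mg = 200, total_mg = 1000, role = "x",
                    replicate_id = 1, varied_api = "AZ")
  s <- simulate_set(tab, hgc_formulation(), lib, grid, noise_free(),
                    repacks = 1)
  direct <- mixture_spectrum(
    c(AZ = 0.4, AS = 0.4), lib, grid, noise_free())
  # placebo has no bands in the toy library, so only the APIs contribute
  expect_equal(unname(s$absorbance[1, ]), direct, tolerance = 1e-12)
})

test_that("spectra sets validate their inputs and bind correctly", {
  grid <- coarse_grid()
  A <- matrix(1, 2, length(grid$points))
  expect_error(spectra_set(grid, A[, -1], data.frame(sample = c("a", "b"))),
               "match grid")
  expect_error(spectra_set(grid, A, data.frame(sample = c("a", "a"))),
               "unique")
  s1 <- spectra_set(grid, A, data.frame(sample = c("a", "b")))
  s2 <- spectra_set(grid, 2 * A, data.frame(sample = c("c", "d"), extra = 1))
  both <- bind_spectra(s1, s2)
  expect_equal(nrow(both$absorbance), 4)
  expect_true("extra" %in% names(both$meta))
})
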