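test_that("relative recovery errors follow the definition", {
  expect_equal(relative_results(100, 100), 0)
  expect_equal(relative_results(100, 103.3), 3.3)
  expect_equal(relative_results(80, 76), -5)
  expect_equal(relative_results(c(80, 120), c(84, 114)), c(5, -5))
  expect_error(relative_results(0, 10), "level must be")
})

test_that("variance components match a hand one-way ANOVA", {
  # all equal: no variance anywhere, bias = the constant
  vc <- variance_components(rep(2.5, 6), rep(1:2, each = 3))
  expect_equal(vc$s2_within, 0)
  expect_equal(vc$s2_between, 0)
  expect_equal(vc$bias, 2.5)
  # 2x2 table with zero within-series spread: s_B^2 = var of series means
  vc <- variance_components(c(1, 1, 3, 3), c("a", "a", "b", "b"))
  expect_equal(vc$s2_within, 0)
  expect_equal(vc$s2_between, 2)  # var(c(1, 3)) with n-1 denominator
  expect_equal(vc$bias, 2)
  # general case against direct mean-square arithmetic
  set.seed(14)
  e <- stats::rnorm(12); s <- rep(1:3, each = 4)
  vc <- variance_components(e, s)
  gm <- mean(e); sm <- tapply(e, s, mean)
  msb <- 4 * sum((sm - gm)^2) / 2
  msw <- sum((e - rep(sm, each = 4))^2) / 9
  expect_equal(vc$s2_within, msw, tolerance = 1e-12)
  expect_equal(vc$s2_between, max(0, (msb - msw) / 4), tolerance = 1e-12)
})

test_that("negative between-series estimates are truncated at zero", {
  # series means close together, large within-series spread
  e <- c(-1, 1, -1.1, 1.1, -0.9, 0.9)
  vc <- variance_components(e, rep(1:3, each = 2))
  expect_equal(vc$s2_between, 0)
})

test_that("unbalanced or degenerate layouts are refused", {
  expect_error(variance_components(1:5, c(1, 1, 1, 2, 2)), "unbalanced")
  expect_error(variance_components(1:2, c(1, 2)), "2 replicates")
  expect_error(variance_components(1:4, rep(1, 4)), "2 series")
})

test_that("tolerance intervals handle degenerate and limiting cases", {
  # no variance: point interval at the bias
  ti <- tolerance_interval(0, 0, 0, 3, 3)
  expect_equal(c(ti$lower, ti$upper), c(0, 0))
  expect_true(ti$lower > -5 && ti$upper < 5)
  # s_B^2 = 0 reduces to the stated R = 0 formulas
  p <- 3; n <- 3; sw2 <- 4; b <- 1
  ti <- tolerance_interval(b, sw2, 0, p, n, beta = 0.95)
  nu0 <- 1 / ((1 / n)^2 / (p - 1) + (1 - 1 / n) / (p * n))
  half0 <- stats::qt(0.975, nu0) * sqrt(sw2) * sqrt(1 + 1 / (p * n))
  expect_equal(ti$df, nu0, tolerance = 1e-12)
  expect_equal(ti$upper - b, half0, tolerance = 1e-12)
  # s_W^2 = 0 uses the between-series-only limit
  ti <- tolerance_interval(0, 0, 9, 4, 3)
  expect_equal(ti$df, 3)
  expect_equal(ti$upper, stats::qt(0.975, 3) * 3 * sqrt(1 + 1 / (4 * 3 * (1 / 3))),
               tolerance = 1e-12)
  expect_error(tolerance_interval(0, 1, 1, 3, 3, beta = 1.2), "beta")
})

test_that("tolerance limits widen with beta and with between-series variance", {
  for (sb2 in c(0, 0.5, 2)) {
    w <- vapply(c(0.8, 0.9, 0.95, 0.99), function(b)
      tolerance_interval(0, 1, sb2, 3, 3, beta = b)$upper, numeric(1))
    expect_true(all(diff(w) > 0))
  }
  for (b in c(0.9, 0.95)) {
    w <- vapply(c(0, 0.25, 1, 4), function(sb2)
      tolerance_interval(0, 1, sb2, 3, 3, beta = b)$upper, numeric(1))
    expect_true(all(diff(w) > 0))
  }
})

test_that("beta-expectation intervals have approximately beta coverage", {
  # 400 simulated studies x 250 future draws at p=3, n=3, s_W=1, s_B=0.5
  set.seed(100)
  p <- 3; n <- 3; sw <- 1; sb <- 0.5
  inside <- 0; total <- 0
  for (i in 1:400) {
    b_s <- stats::rnorm(p, 0, sb)
    obs <- rep(b_s, each = n) + stats::rnorm(p * n, 0, sw)
    vc <- variance_components(obs, rep(1:p, each = n))
    ti <- tolerance_interval(vc$bias, vc$s2_within, vc$s2_between,
                             vc$p, vc$n, beta = 0.95)
    fut <- stats::rnorm(250, 0, sb) + stats::rnorm(250, 0, sw)
    inside <- inside + sum(fut >= ti$lower & fut <= ti$upper)
    total <- total + 250
  }
  expect_equal(inside / total, 0.95, tolerance = 0.03 / 0.95)
})

test_that("accuracy profiles judge levels against the acceptance limits", {
  mk <- function(biases, noise_sd = 0.1, seed = 8) {
    set.seed(seed)
    do.call(rbind, lapply(seq_along(biases), function(i) {
      L <- c(80, 100, 120)[i]
      data.frame(level_percent = L,
                 series_id = rep(1:3, each = 3), replicate_id = rep(1:3, 3),
                 recovered_percent = L * (1 + biases[i] / 100) +
                   stats::rnorm(9, 0, noise_sd))
    }))
  }
  # near-perfect recovery passes with narrow limits
  prof <- accuracy_profile(mk(c(0, 0, 0)))
  expect_true(prof$pass)
  expect_true(all(abs(prof$table$bias) < 1))
  # an injected +6% bias at one level fails the +/-5% rule
  prof_bad <- accuracy_profile(mk(c(0, 6, 0)))
  expect_false(prof_bad$pass)
  # noise-free perfect recovery gives degenerate (0, 0) limits
  perfect <- mk(c(0, 0, 0), noise_sd = 0)
  prof0 <- accuracy_profile(perfect)
  expect_equal(prof0$table$lower, rep(0, 3), tolerance = 1e-9)
  expect_equal(prof0$table$upper, rep(0, 3), tolerance = 1e-9)
})

test_that("profile verdicts are invariant to row order and series labels", {
  set.seed(21)
  d <- data.frame(level_percent = rep(c(80, 100, 120), each = 9),
                  series_id = rep(rep(1:3, each = 3), 3),
                  replicate_id = rep(1:3, 9),
                  recovered_percent = rep(c(80, 100, 120), each = 9) +
                    stats::rnorm(27, 0, 0.5))
  p1 <- accuracy_profile(d)
  d2 <- d[sample(nrow(d)), ]
  d2$series_id <- c(x = 1, y = 2, z = 3)[d2$series_id]  # relabel
  d2$series_id <- factor(d2$series_id)
  p2 <- accuracy_profile(d2)
  expect_equal(p1$table, p2$table, tolerance = 1e-10)
  expect_identical(p1$pass, p2$pass)
})

test_that("content summaries report mean and RSD", {
  expect_equal(content_summary(c(100, 100, 100)), c(mean = 100, rsd = 0))
  expect_equal(content_summary(c(98, 102)),
               c(mean = 100, rsd = 100 * stats::sd(c(98, 102)) / 100),
               tolerance = 1e-12)
  expect_equal(unname(content_summary(c(98, 102))[2]), 2.828427,
               tolerance = 1e-6)
  expect_error(content_summary(100), "at least 2")
  expect_error(content_summary(c(-1, 1)), "zero mean")
})

test_that("six synthetic capsule determinations stay below 5% RSD", {
  rep17 <- default_study()
  model <- rep17$models$AS
  pp <- rep17$preprocessors$AS
  form <- hgc_formulation()
  # six fresh capsules at label composition
  tab <- data.frame(level_percent = 100,
                    mass_AZ_mg = form$components[["AZ"]],
                    mass_AS_mg = form$components[["AS"]],
                    mass_placebo_mg = form$components[["cellulose"]] +
                      form$components[["silica"]],
                    total_mg = form$total_mg, role = "batch",
                    replicate_id = 1:6, varied_api = "AS")
  batch <- simulate_set(tab, form, default_library(), wavenumber_grid(),
                        noise_model(), repacks = 3, seed = 55)
  cs <- content_summary(predict(model, apply_plan(batch, pp)))
  expect_lt(cs[["rsd"]], 5)
  expect_equal(cs[["mean"]], 100, tolerance = 0.05)
})
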