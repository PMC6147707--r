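test_that("species selection enforces the occupancy threshold and tip matching", {
  set.seed(4)
  n <- 200
  plots <- make_lattice_plots(20, 10, function(x, y) stats::runif(length(x), 0, 100))
  plots$sp_in <- c(rep(1L, 25), rep(0L, n - 25))       # exactly 25 occupied
  plots$sp_out <- c(rep(1L, 24), rep(0L, n - 24))      # one short
  plots$sp_offtree <- rep(1L, n)                       # abundant, not a tip
  tips <- c("sp_in", "sp_out", "other")
  keep <- select_species(plots, min_occupied = 25, tree_tips = tips)
  expect_identical(keep, "sp_in")
  expect_error(select_species(plots, 25, tree_tips = "nobody"), "no species")
})

test_that("Poisson fits recover the MLE, AICc bookkeeping and parameter truth", {
  # intercept-only MLE is the sample mean
  f <- fit_poisson(c(0L, 1L, 2L, 3L), c(10, 20, 30, 40))
  expect_equal(f$M_intercept, 1.5)
  expect_equal(f$logLik_intercept, sum(dpois(0:3, 1.5, log = TRUE)))

  # closed-form AICc
  expect_equal(aicc(-50, 1, 100), 102 + 2 * 1 * 2 / 98, tolerance = 1e-10)

  # grid-search oracle at n = 200, identity link
  set.seed(42)
  F <- stats::runif(200, 0, 100)
  counts <- stats::rpois(200, 1 + 0.015 * F)
  fit <- fit_poisson(counts, F, "identity")
  g <- grid_fit_poisson(counts, F, "identity",
                        M_grid = seq(0.4, 2, by = 0.01),
                        C_grid = seq(-0.01, 0.04, by = 0.0005))
  expect_lt(abs(fit$M - g$M), 0.01)
  expect_lt(abs(fit$C - g$C), 0.0005)
  expect_gte(fit$logLik, g$logLik - 1e-6)

  # grid-search oracle, log link
  counts_l <- stats::rpois(200, exp(0.2 + 0.01 * F))
  fit_l <- fit_poisson(counts_l, F, "log")
  g_l <- grid_fit_poisson(counts_l, F, "log",
                          M_grid = seq(-0.5, 1, by = 0.01),
                          C_grid = seq(-0.01, 0.03, by = 0.0002))
  expect_lt(abs(fit_l$M - g_l$M), 0.01)
  expect_lt(abs(fit_l$C - g_l$C), 0.0002)

  # parameter recovery on 5000 plots within 3 expected standard errors
  set.seed(7)
  F5 <- stats::runif(5000, 0, 100)
  cnt5 <- stats::rpois(5000, 0.5 + 0.02 * F5)
  fit5 <- fit_poisson(cnt5, F5, "identity")
  se <- identity_poisson_se(0.5, 0.02, F5)
  expect_lt(abs(fit5$M - 0.5), 3 * se[1])
  expect_lt(abs(fit5$C - 0.02), 3 * se[2])

  expect_error(fit_poisson(rep(0L, 10), rep(50, 10)), "zero")
  expect_error(fit_poisson(c(0.5, 1.2), c(10, 20)), "round")
})

test_that("AICc screening separates null from strong cover effects", {
  set.seed(31)
  informative_null <- logical(100)
  informative_strong <- logical(100)
  for (r in 1:100) {
    F0 <- stats::runif(500, 0, 100)
    informative_null[r] <-
      fit_poisson(stats::rpois(500, 1.5), F0, "identity")$informative
    F1 <- stats::runif(1000, 0, 100)
    informative_strong[r] <-
      fit_poisson(stats::rpois(1000, 0.5 + 0.02 * F1), F1, "identity")$informative
  }
  expect_lt(mean(informative_null), 0.05)
  expect_gt(mean(informative_strong), 0.95)
})

test_that("occurrence probability and Omega follow the rate algebra", {
  expect_equal(suppressWarnings(occurrence_probability(manual_fit(0, 0), 50)),
               0, tolerance = 1e-8)
  expect_equal(occurrence_probability(manual_fit(log(2), 0), 50), 0.5)
  expect_equal(occurrence_probability(manual_fit(0.05, 0.02), 75),
               1 - exp(-1.55), tolerance = 1e-12)
  expect_equal(round(occurrence_probability(manual_fit(0.05, 0.02), 75), 5),
               0.78775)
  expect_warning(occurrence_probability(manual_fit(0.5, -0.02), 75), "clipped")

  # flat response: equal probabilities, Omega 0
  expect_equal(omega(manual_fit(1, 0)), 0)
  # P(5) = 0.2, P(75) = 0.1 gives ln 2
  C <- (-log(0.9) + log(0.8)) / 70
  M <- -log(0.8) - 5 * C
  expect_equal(omega(manual_fit(M, C)), log(2), tolerance = 1e-10)
  # scalar oracle
  expect_equal(omega(manual_fit(0.05, 0.02)),
               log((1 - exp(-0.15)) / (1 - exp(-1.55))), tolerance = 1e-12)
  expect_equal(omega(manual_fit(0.05, 0.02)), -1.7326, tolerance = 5e-5)
  expect_error(omega(manual_fit(1, 0), 75, 5), "F_low")
})

test_that("Omega sign opposes the cover slope for informative fits", {
  set.seed(77)
  checked <- 0
  for (link in c("identity", "log")) {
    for (r in 1:40) {
      F <- stats::runif(800, 0, 100)
      if (link == "identity") {
        M <- stats::runif(1, 1, 3); C <- stats::runif(1, -0.01, 0.01)
        lam <- pmax(M + C * F, 1e-10)
      } else {
        M <- stats::runif(1, -0.5, 0.5); C <- stats::runif(1, -0.02, 0.02)
        lam <- exp(M + C * F)
      }
      fit <- fit_poisson(stats::rpois(800, lam), F, link)
      if (fit$informative && fit$C != 0) {
        expect_equal(sign(omega(fit)), -sign(fit$C))
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 20)
})

test_that("bootstrap CIs use percentile ranks, honour determinism and shrink with n", {
  set.seed(12)
  F <- stats::runif(300, 0, 100)
  counts <- stats::rpois(300, 1 + 0.012 * F)
  oe <- bootstrap_omega(counts, F, "identity", n_boot = 199, seed = 5)
  sv <- sort(oe$boot_values)
  expect_equal(oe$ci_low, sv[floor(200 * 0.025)])
  expect_equal(oe$ci_high, sv[ceiling(200 * 0.975)])
  expect_lte(oe$ci_low, oe$ci_high)
  expect_s3_class(oe, "omega_estimate")

  # identical seed, identical interval
  oe2 <- bootstrap_omega(counts, F, "identity", n_boot = 199, seed = 5)
  expect_identical(oe$boot_values, oe2$boot_values)

  # resampling identical plots gives a zero-width interval at the point value
  const <- bootstrap_omega(rep(2L, 40), rep(30, 40), "identity",
                           n_boot = 49, seed = 1)
  expect_equal(const$ci_low, const$omega)
  expect_equal(const$ci_high, const$omega)

  # interval width decreases with sample size
  set.seed(99)
  widths <- function(n) {
    vapply(1:20, function(r) {
      Fr <- stats::runif(n, 0, 100)
      cr <- stats::rpois(n, 1 + 0.012 * Fr)
      o <- bootstrap_omega(cr, Fr, "identity", n_boot = 99, seed = 1000 + r)
      o$ci_high - o$ci_low
    }, numeric(1))
  }
  expect_lt(stats::median(widths(4000)), stats::median(widths(250)))
})

test_that("response classification follows the CI sign rule", {
  expect_equal(classify_response(-0.5, -0.1), "negative")
  expect_equal(classify_response(-0.1, 0.2), "neutral")
  expect_equal(classify_response(0.0, 0.3), "neutral")
  expect_equal(classify_response(0.1, 0.3), "positive")
  expect_equal(classify_response(-0.3, 0.0), "neutral")
})

test_that("best scale is the AICc argmin with local-first tie-breaking", {
  fits <- data.frame(species = "s1", scale = c("local", "1.6", "3.2", "6.4"),
                     AICc = c(100, 110, 120, 130), informative = TRUE)
  expect_equal(best_scale(fits)$best_scale, "local")

  tie <- data.frame(species = "s1", scale = c("3.2", "1.6"),
                    AICc = c(100, 100), informative = TRUE)
  expect_equal(best_scale(tie)$best_scale, "1.6")

  none <- data.frame(species = "s1", scale = "local", AICc = 100,
                     informative = FALSE)
  expect_true(is.na(best_scale(none)$best_scale))
})

test_that("the generating scale is recovered by cross-scale AICc comparison", {
  hits <- logical(50)
  for (r in 1:50) {
    set.seed(500 + r)
    cfg <- synthetic_config(grid_nx = 71, grid_ny = 71,
                            cover_smoothing_scale = 1, seed = 500 + r)
    pl <- simulate_cover_field(cfg)
    ms <- multiscale_cover(pl, radii = c(1.6, 3.2, 6.4))
    counts <- stats::rpois(nrow(pl), 1 + 0.02 * ms$cover_1p6)
    fits <- do.call(rbind, lapply(
      c(local = "cover_local", `1.6` = "cover_1p6",
        `3.2` = "cover_3p2", `6.4` = "cover_6p4"),
      function(col) {
        f <- fit_poisson(counts, ms[[col]], "identity")
        data.frame(species = "s", AICc = f$AICc, informative = f$informative)
      }))
    fits$scale <- c("local", "1.6", "3.2", "6.4")
    hits[r] <- identical(best_scale(fits)$best_scale, "1.6")
  }
  expect_gte(mean(hits), 0.8)
})
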