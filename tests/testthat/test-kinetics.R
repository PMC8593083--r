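test_that("standard curve recovers an exact line and rejects bad input", {
  calib <- tibble::tibble(amount = c(0, 10, 20, 40), signal = 2 * amount + 5)
  sc <- suppressWarnings(fit_standard_curve(calib))
  expect_equal(sc$slope, 2)
  expect_equal(sc$intercept, 5)
  expect_equal(convert_signal(sc, 45), 20)
  expect_error(fit_standard_curve(calib[1, ]), "at least 3")
  down <- tibble::tibble(amount = c(1, 2, 3), signal = c(9, 6, 3))
  expect_error(fit_standard_curve(down), "non-positive slope")
})

test_that("noisy calibration slope is recovered within 5%", {
  withr::local_seed(14)
  amounts <- c(5, 10, 25, 50, 100, 200)
  clean <- 3 * amounts + 40
  calib <- tibble::tibble(amount = amounts,
                          signal = clean * (1 + rnorm(6, 0, 0.02)))
  sc <- fit_standard_curve(calib)
  expect_lt(abs(sc$slope - 3) / 3, 0.05)
})

test_that("initial rate equals the OLS slope of product versus time", {
  exact <- tibble::tibble(time_min = c(2, 4, 6, 8), product = 3 * time_min)
  expect_equal(initial_rate(exact)$rate, 3)
  flat <- tibble::tibble(time_min = c(2, 4, 6, 8), product = 7)
  expect_equal(initial_rate(flat)$rate, 0)
  expect_error(initial_rate(tibble::tibble(time_min = c(2, 2),
                                           product = c(1, 2))),
               "2 distinct timepoints")
})

test_that("progress-curve slope matches the analytic initial rate when depletion is mild", {
  # closed-form MM rate as the oracle: v0 = Vmax*S0/(KM+S0)
  km <- 500; s0 <- 1000
  kcat <- 1; e <- 16     # ~8% depletion by 8 min
  v0 <- kcat * e * s0 / (km + s0)
  prod <- loopgate:::mm_progress(s0, kcat * e, km, c(2, 4, 6, 8))
  slope <- initial_rate(tibble::tibble(time_min = c(2, 4, 6, 8),
                                       product = prod))$rate
  expect_lt(abs(slope - v0) / v0, 0.05)
  # at tenfold enzyme load the curvature is severe and the OLS slope
  # underestimates v0 well beyond 5% -- the documented caveat
  prod_heavy <- loopgate:::mm_progress(s0, 10 * e * 16, km, c(2, 4, 6, 8))
  slope_heavy <- initial_rate(tibble::tibble(time_min = c(2, 4, 6, 8),
                                             product = prod_heavy))$rate
  v0_heavy <- 10 * 16 * 16 * s0 / (km + s0)
  expect_lt(slope_heavy, v0_heavy * 0.95)
})

test_that("replicate rates are averaged with their spread", {
  data <- tidyr::expand_grid(condition = "WT", substrate_nM = 100,
                             time_min = c(2, 4, 6, 8), replicate = 1:3) |>
    dplyr::mutate(product = (2 + replicate) * time_min)
  rates <- initial_rates(data)
  expect_equal(rates$rate, 4)          # mean of slopes 3, 4, 5
  expect_equal(rates$rate_sd, 1)
  expect_equal(rates$n_replicates, 3L)
  pooled <- initial_rates(data, per_replicate = FALSE)
  expect_equal(pooled$rate, 4)
})

test_that("noiseless Michaelis-Menten rates are recovered essentially exactly", {
  s <- 4000 / 2^(7:0)
  rates <- tibble::tibble(substrate_nM = s, rate = 8 * s / (400 + s))
  fit <- fit_michaelis_menten(rates, enzyme_nM = 16)
  expect_lt(abs(fit$vmax - 8) / 8, 1e-3)
  expect_lt(abs(fit$km - 400) / 400, 1e-3)
  expect_equal(fit$kcat, fit$vmax / 16)
})

test_that("saturation-only rate tables raise an extrapolation warning", {
  rates <- tibble::tibble(substrate_nM = c(500, 1000, 2000, 4000),
                          rate = rep(8, 4))
  expect_warning(fit <- fit_michaelis_menten(rates, enzyme_nM = 16),
                 "extrapolated")
  expect_true(fit$extrapolated)
})

test_that("too few substrate concentrations are rejected", {
  rates <- tibble::tibble(substrate_nM = c(100, 200, 400),
                          rate = c(1, 2, 3))
  expect_error(fit_michaelis_menten(rates, enzyme_nM = 16), "at least 4")
})

test_that("fitted fold change of a 16-fold turnover pair lands in [13, 19]", {
  truth <- tibble::tibble(condition = c("WT", "E1099K"),
                          kcat = c(0.05, 0.8), km_nM = 600,
                          enzyme_nM = c(256, 16))
  sim <- simulate_kinetics(truth = truth, seed = 99)
  sc <- suppressWarnings(fit_standard_curve(sim$calibration))
  rates <- initial_rates(sim$data, standard_curve = sc)
  fits <- fit_mm_panel(rates, setNames(truth$enzyme_nM, truth$condition))
  folds <- compare_conditions(fits, "WT")
  fold <- dplyr::filter(folds, condition == "E1099K")$kcat_fold
  expect_gt(fold, 13)
  expect_lt(fold, 19)
})

test_that("fold-change arithmetic and error propagation are exact", {
  fake_fit <- function(cond, kcat, km, kcat_se = 0, km_se = 0) {
    structure(list(condition = cond, enzyme_nM = 1, vmax = kcat,
                   vmax_se = kcat_se, km = km, km_se = km_se, kcat = kcat,
                   kcat_se = kcat_se, extrapolated = FALSE, fit = NULL,
                   data = tibble::tibble()), class = "mm_fit")
  }
  same <- list(WT = fake_fit("WT", 2, 500), M = fake_fit("M", 2, 500))
  out <- compare_conditions(same, "WT")
  expect_equal(out$kcat_fold, c(1, 1))
  expect_equal(out$efficiency_fold, c(1, 1))
  pair <- list(WT = fake_fit("WT", 1, 500), M = fake_fit("M", 16, 250))
  out2 <- compare_conditions(pair, "WT")
  m <- dplyr::filter(out2, condition == "M")
  expect_equal(m$kcat_fold, 16)
  expect_equal(m$kcat_fold_se, 0)
  expect_equal(m$km_fold, 0.5)
  # kcat/KM fold identity on point estimates
  expect_equal(m$efficiency_fold, m$kcat_fold / m$km_fold)
  expect_error(compare_conditions(pair, "REF"), "REF")
})

test_that("MM residuals are orthogonal to the fitted gradient at the optimum", {
  withr::local_seed(77)
  s <- 4000 / 2^(7:0)
  v <- 8 * s / (400 + s) * (1 + rnorm(8, 0, 0.05))
  fit <- fit_michaelis_menten(tibble::tibble(substrate_nM = s, rate = v),
                              enzyme_nM = 16)
  res <- v - fit$vmax * s / (fit$km + s)
  grad_vmax <- s / (fit$km + s)
  grad_km <- -fit$vmax * s / (fit$km + s)^2
  expect_lt(abs(sum(res * grad_vmax)), 1e-6 * sqrt(sum(res^2) *
                                                     sum(grad_vmax^2)) + 1e-10)
  expect_lt(abs(sum(res * grad_km)), 1e-6 * sqrt(sum(res^2) *
                                                   sum(grad_km^2)) + 1e-10)
})

test_that("tidy and glance expose the fit in broom conventions", {
  s <- 4000 / 2^(7:0)
  fit <- fit_michaelis_menten(
    tibble::tibble(substrate_nM = s, rate = 8 * s / (400 + s)),
    enzyme_nM = 16, condition = "WT")
  td <- tidy(fit)
  expect_equal(td$term, c("vmax", "km", "kcat"))
  expect_named(td, c("term", "estimate", "std.error"))
  gl <- glance(fit)
  expect_equal(gl$condition, "WT")
  expect_equal(gl$n, 8L)
})
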