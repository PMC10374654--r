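# Viability normalization, 4PL fitting and its S3 methods, tumor volume
# and endpoint growth comparisons.

test_that("viability is anchored to the vehicle mean", {
  tab <- data.frame(concentration = c(0, 0, 1, 2),
                    od = c(0.9, 0.7, 0.8, 0.4))
  nv <- normalize_viability(tab)
  expect_equal(nv$viability, c(112.5, 87.5, 100, 50))
  expect_equal(mean(nv$viability[nv$concentration == 0]), 100)

  expect_error(normalize_viability(data.frame(concentration = 1, od = 1)),
               "no vehicle")
  expect_error(normalize_viability(data.frame(concentration = c(0, 1),
                                              od = c(0, 1))), "zero")

  # per-group normalization when cell_line is present
  tab2 <- rbind(data.frame(cell_line = "MP", concentration = c(0, 1),
                           od = c(0.8, 0.4)),
                data.frame(cell_line = "Hep3B", concentration = c(0, 1),
                           od = c(0.4, 0.1)))
  nv2 <- normalize_viability(tab2)
  expect_equal(nv2$viability, c(100, 50, 100, 25))
})

test_that("4PL recovers noise-free parameters and flags flat data", {
  dr <- normalize_viability(simulate_dose_response(hill = 1, ic50 = 16,
                                                   seed = 1))
  fit <- fit_4pl(dr$concentration, dr$viability)
  cf <- coef(fit)
  expect_true(fit$converged)
  expect_lt(abs(cf["ic50"] - 16) / 16, 1e-6)
  expect_lt(abs(cf["hill"] - 1), 1e-6)
  expect_lt(abs(cf["top"] - 100), 1e-4)
  expect_lt(abs(cf["bottom"]), 1e-4)
  # symmetric curve: absolute and relative IC50 coincide
  expect_equal(fit$ic50_absolute, unname(cf["ic50"]), tolerance = 1e-6)
  # predict inverts the curve; vehicle predicts top
  expect_equal(predict(fit, 0), unname(cf["top"]))
  expect_equal(predict(fit, cf["ic50"]),
               unname((cf["top"] + cf["bottom"]) / 2), tolerance = 1e-6)

  flat <- fit_4pl(10^seq(-1, 2, length.out = 6), rep(100, 6))
  expect_true(flat$degenerate)
  expect_false(flat$converged)

  expect_error(fit_4pl(c(0, 1, 2, 4), rep(50, 4)), "4 distinct")
})

test_that("4PL residuals are invariant under replicate reordering", {
  dr <- normalize_viability(simulate_dose_response(noise_sd = 5, seed = 2))
  f1 <- fit_4pl(dr$concentration, dr$viability)
  set.seed(1)
  perm <- sample(nrow(dr))
  f2 <- fit_4pl(dr$concentration[perm], dr$viability[perm])
  expect_equal(f1$rss, f2$rss, tolerance = 1e-8)
  expect_equal(sort(residuals(f1)), sort(residuals(f2)), tolerance = 1e-6)
})

test_that("simulate method reproduces the fitted noise level", {
  dr <- normalize_viability(simulate_dose_response(noise_sd = 5, seed = 9))
  fit <- fit_4pl(dr$concentration, dr$viability)
  sims <- simulate(fit, nsim = 200, seed = 1)
  sd_sim <- mean(apply(sims - fitted(fit), 2, sd))
  expect_equal(sd_sim, fit$sigma, tolerance = 0.15)
})

test_that("tumor volume follows V = A * B^2 / 2 with the swap contract", {
  expect_equal(tumor_volume(10, 6), 180)
  expect_equal(tumor_volume(1, 1), 0.5)
  expect_warning(v <- tumor_volume(6, 10), "swapped")
  expect_equal(v, 180)
  expect_error(tumor_volume(0, 1), "positive")
  expect_error(tumor_volume(5, -1), "positive")

  # homogeneous of degree 3
  set.seed(10)
  A <- runif(20, 5, 15); B <- runif(20, 1, 5); s <- 2.5
  expect_equal(tumor_volume(s * A, s * B), s^3 * tumor_volume(A, B),
               tolerance = 1e-12)
})

test_that("growth endpoint test delegates to compare_scores", {
  meas <- data.frame(
    mouse_id = rep(1:10, times = 2),
    group = rep(rep(c("vehicle", "treated"), each = 5), 2),
    day = rep(c(7, 21), each = 10),
    A = c(rep(8, 10), rep(c(12, 6), each = 5)),
    B = c(rep(4, 10), rep(c(10, 3), each = 5)))
  meas$A <- meas$A + rep(seq(0, 0.9, length.out = 10), 2)
  res <- growth_endpoint_test(meas, day = 21, reference = "vehicle")
  direct <- compare_scores(
    tumor_volume(meas$A[meas$day == 21 & meas$group == "vehicle"],
                 meas$B[meas$day == 21 & meas$group == "vehicle"]),
    tumor_volume(meas$A[meas$day == 21 & meas$group == "treated"],
                 meas$B[meas$day == 21 & meas$group == "treated"]),
    method = "student")
  expect_equal(res$tests[[1]]$statistic, direct$statistic)
  expect_equal(res$tests[[1]]$p_value, direct$p_value)
  expect_lt(res$tests[[1]]$p_value, 0.001)
  expect_identical(sort(res$summary$group), c("treated", "vehicle"))

  expect_error(growth_endpoint_test(meas, day = 14), "available days: 7, 21")
})

test_that("dose-response simulator emits the expected plate layout", {
  dr <- simulate_dose_response(replicates = 3, seed = 1)
  expect_identical(nrow(dr), 27L)           # 8 concentrations + vehicle
  expect_identical(sum(dr$concentration == 0), 3L)
  expect_identical(dr, simulate_dose_response(replicates = 3, seed = 1))
  dr2 <- simulate_dose_response(replicates = 3, seed = 2, noise_sd = 5)
  expect_false(identical(dr$od, dr2$od))
})
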