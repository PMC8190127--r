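test_that("standard curves fit exactly on exact data and flag degeneracy", {
  curve <- fit_standard_curve(c(0, 10, 25, 50), 2 * c(0, 10, 25, 50) + 5)
  expect_equal(curve$slope, 2)
  expect_equal(curve$intercept, 5)
  expect_equal(curve$r_squared, 1)
  expect_error(fit_standard_curve(rep(10, 4), c(1, 2, 3, 4)), "distinct")
})

test_that("noisy standard-curve slope lands within 3 SE of truth", {
  x <- c(0, 5, 10, 25, 50, 100)
  sigma <- 3
  # closed-form OLS sampling SD of the slope at known noise sigma
  se_slope <- sigma / sqrt(sum((x - mean(x))^2))
  set.seed(99)
  for (i in 1:10) {
    y <- 2 * x + 5 + rnorm(length(x), 0, sigma)
    curve <- fit_standard_curve(x, y)
    expect_lt(abs(curve$slope - 2), 3 * se_slope)
  }
})

test_that("reading-to-concentration conversion clips and round-trips", {
  curve <- fit_standard_curve(c(0, 10, 25, 50), 2 * c(0, 10, 25, 50) + 5)
  expect_equal(as.numeric(readings_to_concentration(curve, 5)), 0)
  conc <- readings_to_concentration(curve, 2 * c(1, 7, 33) + 5)
  expect_equal(as.numeric(conc), c(1, 7, 33))
  below <- readings_to_concentration(curve, 3)
  expect_equal(as.numeric(below), 0)
  expect_true(attr(below, "below_blank"))
  signed <- readings_to_concentration(curve, 3, clip = FALSE)
  expect_equal(as.numeric(signed), -1)
})

test_that("the estimator is exact on linear-flux series for any P A V C0", {
  for (p in c(3.9e-6, 1.0e-5, 1.5e-6, 6.8e-6, 1.3e-5)) {
    est <- permeability_coefficient(linear_flux_series(p))
    expect_equal(est$p_cm_s, p, tolerance = 1e-12)
  }
  set.seed(17)
  for (i in 1:50) {
    p <- 10^runif(1, -7, -4)
    a <- runif(1, 1, 10)
    v <- runif(1, 60, 150)
    c0 <- runif(1, 10, 100)
    ti <- sample(2:6, 1)
    ser <- linear_flux_series(p, a, v, c0)
    est <- permeability_coefficient(ser, area_mm2 = a, t_index = ti)
    expect_equal(est$p_cm_s, p, tolerance = 1e-12)
  }
})

test_that("a flat receiver series gives P = 0 and bad endpoints error", {
  ser <- tracer_series(c(0, 20, 260), rep(50, 3), rep(0.4, 3), c0 = 50)
  expect_equal(permeability_coefficient(ser)$p_cm_s, 0)
  expect_error(permeability_coefficient(ser, t_index = 1), "t_index")
  ser0 <- tracer_series(c(0, 260), c(0, 0), c(0, 0), c0 = 0)
  expect_error(permeability_coefficient(ser0), "C0")
})

test_that("two-compartment simulator reaches the volume-weighted equilibrium", {
  for (vt in c(50, 100, 200)) {
    ser <- simulate_two_compartment(5e-6, v_top_ul = vt, v_bottom_ul = 100,
                                    c0 = 50, times_min = c(0, 1e7))
    ceq <- 50 * vt / (vt + 100)
    expect_equal(ser$donor_conc[2], ceq, tolerance = 1e-9)
    expect_equal(ser$receiver_conc[2], ceq, tolerance = 1e-9)
  }
  # equal volumes: both compartments end at half the load
  ser <- simulate_two_compartment(5e-6, c0 = 50, times_min = c(0, 1e7))
  expect_equal(ser$receiver_conc[2], 25, tolerance = 1e-9)
})

test_that("simulator conserves mass, is monotone, and P = 0 is inert", {
  ser0 <- simulate_two_compartment(0)
  expect_equal(ser0$receiver_conc, rep(0, 6))
  expect_equal(ser0$donor_conc, rep(50, 6))
  ser <- simulate_two_compartment(8e-6, v_top_ul = 80, v_bottom_ul = 120)
  mass <- 80 * ser$donor_conc + 120 * ser$receiver_conc
  expect_equal(max(abs(mass / mass[1] - 1)), 0, tolerance = 1e-9)
  expect_true(all(diff(ser$receiver_conc) > 0))
  ser_hi <- simulate_two_compartment(1.6e-5, v_top_ul = 80,
                                     v_bottom_ul = 120)
  expect_true(all(ser_hi$receiver_conc[-1] > ser$receiver_conc[-1]))
})

test_that("sampling events dilute both loops and track removed mass", {
  ser <- simulate_two_compartment(0, sampling_volume_ul = 10,
                                  times_min = c(0, 20, 40))
  # with P = 0 the recorded donor follows C0 * 0.9^(k-1)
  expect_equal(ser$donor_conc, 50 * 0.9^(0:2))
  expect_gt(attr(ser, "sampled_mass_ug"), 0)
  expect_error(simulate_two_compartment(1e-6, sampling_volume_ul = 200),
               "sampling volume")
})

test_that("bidirectional series match a fine-step ODE oracle and bias the
          endpoint estimator by the analytic factor", {
  p_true <- 1e-5
  ser <- simulate_two_compartment(p_true, area_mm2 = 3.7, v_top_ul = 100,
                                  v_bottom_ul = 100, c0 = 50)
  # independent numerical integration of the same two-compartment ODE
  library(deSolve)
  a_cm2 <- 0.037; vt <- 0.1; vb <- 0.1
  rhs <- function(t, y, parms) {
    flux <- p_true * a_cm2 * (y[1] - y[2])
    list(c(-flux / vt, flux / vb))
  }
  sol <- ode(c(ct = 50, cb = 0), seq(0, 260 * 60, by = 5), rhs, NULL,
             method = "lsoda", rtol = 1e-10, atol = 1e-12)
  idx <- match(ser$times_min * 60, sol[, "time"])
  expect_equal(ser$receiver_conc, unname(sol[idx, "cb"]),
               tolerance = 1e-6)
  # endpoint estimator under-reads P by (1 - exp(-kT)) / (kT)
  est <- permeability_coefficient(ser)$p_cm_s
  k <- p_true * a_cm2 * (1 / vt + 1 / vb)
  t_end <- 260 * 60
  expect_equal(est / p_true, (1 - exp(-k * t_end)) / (k * t_end),
               tolerance = 1e-9)
  expect_lt(est, p_true)
})

test_that("the estimator converges to P_true in the small-flux limit", {
  errs <- sapply(c(1e-5, 1e-6, 1e-7), function(p) {
    est <- permeability_coefficient(simulate_two_compartment(p))$p_cm_s
    abs(est / p - 1)
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("plate report summarises replicates and flags inconsistency", {
  mk <- function(dev, p, cond) {
    structure(list(p_cm_s = p, device = dev, tracer_mw_kda = 20,
                   culture_mode = cond, treatment = NA_character_),
              class = "permeability_result")
  }
  res <- c(lapply(1:2, function(i) mk(paste0("A", i),
                                      c(1e-6, 5e-6)[i], "co")),
           lapply(1:2, function(i) mk(paste0("B", i),
                                      c(1e-6, 2e-5)[i], "mono")))
  rep <- plate_permeability_report(res)
  s <- rep$summary[order(rep$summary$condition), ]
  expect_equal(nrow(s), 2)
  expect_equal(s$replicate_ratio, c(5, 20))
  expect_equal(s$consistent, c(TRUE, FALSE))
  expect_equal(rep$plate["A", 1], 1e-6)
  expect_true(is.na(rep$plate["H", 12]))
})

test_that("the table-driven pipeline recovers P exactly without noise", {
  g <- gen_tracer_readings(tracer_assay_scenario(noise_cv = 0), seed = 1)
  est <- permeability_from_readings(g$readings, g$standards)
  m <- merge(est, g$truth$devices,
             by = c("device", "condition", "tracer_mw_kda"))
  expect_equal(m$p_cm_s.x, m$p_cm_s.y, tolerance = 1e-10)
  # one summary row per condition x tracer
  rep <- plate_permeability_report(
    lapply(seq_len(nrow(est)), function(i) {
      structure(list(p_cm_s = est$p_cm_s[i], device = est$device[i],
                     tracer_mw_kda = est$tracer_mw_kda[i],
                     culture_mode = est$condition[i],
                     treatment = NA_character_),
                class = "permeability_result")
    }))
  expect_equal(nrow(rep$summary), 5)
  expect_true(all(rep$summary$n == 9))
  expect_true(all(rep$summary$consistent))
})
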