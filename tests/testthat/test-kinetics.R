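# Standard curve, recovery, initial rates, Michaelis-Menten fits, parameter
# gains and FRET efficiency.

test_that("standard curve is an OLS line with sane r-squared", {
  sc <- fit_standard_curve(1:3, 2 * (1:3) + 1)
  expect_equal(sc$slope, 2)
  expect_equal(sc$intercept, 1)
  expect_identical(sc$r_squared, 1)

  set.seed(1)
  x <- seq(1, 10, length.out = 12)
  y <- 5 * x + 2 + rnorm(12, sd = 0.5)
  sc <- fit_standard_curve(x, y)
  se_slope <- summary(sc$fit)$coefficients[2, 2]
  expect_lt(abs(sc$slope - 5), 3 * se_slope)
  expect_gt(sc$r_squared, 0.99)
  expect_equal(intensity_to_concentration(sc, sc$slope * 4 + sc$intercept), 4)

  expect_error(fit_standard_curve(1:2, 1:2), "at least 3")
  expect_error(fit_standard_curve(c(1, 1, 1), 1:3), "variance")
})

test_that("spike recovery is the measured/spiked percentage", {
  expect_identical(compute_recovery(3.75, 3.75), 100)
  expect_equal(compute_recovery(3.62, 3.75), 96.5, tolerance = 1e-3)
  expect_identical(compute_recovery(0, 3.75), 0)
  expect_error(compute_recovery(1, 0), "positive")
})

test_that("initial rate takes the longest sufficiently linear prefix", {
  t <- c(0, 10, 20, 40, 80, 160)
  ir <- initial_rate(t, 0.5 * t)
  expect_equal(ir$rate, 0.5)
  expect_identical(ir$n_points, 6L)

  # constant signal: a perfect zero-slope fit over the whole course
  ir <- initial_rate(t, rep(3, 6))
  expect_equal(ir$rate, 0)
  expect_identical(ir$n_points, 6L)

  # saturating course: the prefix rule selects the first four points
  # (r^2 = 0.9963); expected slope computed by an independent OLS oracle
  y <- 10 * (1 - exp(-t / 100))
  ir <- initial_rate(t, y)
  expect_identical(ir$n_points, 4L)
  oracle <- unname(coef(lm(y[1:4] ~ t[1:4]))[2])
  expect_equal(ir$rate, oracle)
  expect_lt(abs(ir$rate - 0.1) / 0.1, 0.2)  # within 20% of the t->0 derivative

  expect_error(initial_rate(c(0, 10), c(1, 2)), "at least 3")
  expect_error(initial_rate(c(0, 10, 5), 1:3), "increasing")
})

test_that("noiseless Michaelis-Menten data is recovered exactly by both methods", {
  S <- c(1, 3.16, 10, 31.6, 100)
  Km <- 2.83; Vmax <- 10
  V <- Vmax * S / (Km + S)
  nl <- fit_michaelis_menten(S, V, "nonlinear")
  lb <- fit_michaelis_menten(S, V, "lineweaver_burk")
  expect_equal(nl$Km, Km, tolerance = 1e-6)
  expect_equal(nl$Vmax, Vmax, tolerance = 1e-6)
  expect_equal(lb$Km, Km, tolerance = 1e-6)
  expect_equal(lb$Vmax, Vmax, tolerance = 1e-6)
  # LB linearisation identity: r^2 = 1, intercept = 1/Vmax
  expect_identical(lb$lb_r_squared, 1)
  expect_equal(1 / lb$Vmax, unname(coef(lb$fit)[1]), tolerance = 1e-12)
  # V at S = Km equals Vmax / 2
  expect_equal(Vmax * Km / (Km + Km), Vmax / 2)

  expect_error(fit_michaelis_menten(S, -V, "lineweaver_burk"), "reciprocal")
  expect_error(fit_michaelis_menten(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
})

test_that("kcat scales with the reciprocal enzyme concentration", {
  S <- c(1, 3.16, 10, 31.6, 100)
  V <- 10 * S / (2.83 + S)
  f1 <- fit_michaelis_menten(S, V, enzyme_conc = 0.5)
  f2 <- fit_michaelis_menten(S, V, enzyme_conc = 1.0)
  expect_equal(f1$kcat, 2 * f2$kcat, tolerance = 1e-9)
  expect_equal(f1$efficiency, f1$kcat / f1$Km, tolerance = 1e-12)
})

test_that("noisy Michaelis-Menten simulations recover Km across seeds", {
  S <- rep(c(1, 3.16, 10, 31.6, 100), each = 3)  # triplicate design
  Km <- 2.83; Vmax <- 10
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    V <- Vmax * S / (Km + S) * (1 + 0.05 * rnorm(length(S)))
    fit <- fit_michaelis_menten(S, V, "nonlinear")
    abs(fit$Km - Km) / Km
  }, numeric(1))
  expect_lt(mean(errs), 0.15)
})

test_that("all twelve printed parameter-gain cells are reproduced", {
  tab <- kinetic_parameters_table()
  printed <- list(
    Km = c(A = 33.64, T = 42.94, C = 42.53, G = 43.84),
    kcat = c(A = 16.78, T = 10.89, C = 3.76, G = 4.30),
    efficiency = c(A = 74.81, T = 94.51, C = 80.13, G = 85.29))
  for (par in names(printed)) {
    rows <- tab[tab$parameter == par, ]
    for (i in seq_len(nrow(rows))) {
      g <- parameter_gain(rows$ss[i], rows$tdn[i], par)
      expect_equal(round(g$gain_percent, 2), unname(printed[[par]][rows$nucleotide[i]]),
                   tolerance = 5e-3)
    }
  }
  g <- parameter_gain(4.96, 4.96, "Km")
  expect_identical(g$gain_percent, 0)
  expect_error(parameter_gain(0, 1, "Km"), "positive")
})

test_that("FRET efficiency follows E = 1 - I_DA/I_D", {
  expect_identical(fret_efficiency(1, 1), 0)
  expect_identical(fret_efficiency(0, 1), 1)
  expect_equal(fret_efficiency(0.4, 1.0), 0.6)
  expect_error(fret_efficiency(0.4, 0), "positive")
  expect_error(fret_efficiency(-1, 1), "non-negative")
})
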