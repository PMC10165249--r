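make_linear_series <- function(V = 0.0383, A = 3.74, slope = -10,
                               C0 = 20, temperature = 20, noise = 0,
                               run = "first") {
  t_min <- seq(0, 2 * 1440, by = 15)
  nh4 <- pmax(C0 + slope * t_min / 1440, 0)
  keep <- nh4 > 0
  batch_series(t_min[keep], nh4[keep] + noise * sin(seq_len(sum(keep))),
               no2 = 0.3 * (C0 - nh4[keep]), no3 = 0.7 * (C0 - nh4[keep]),
               temperature = temperature, volume = V, area = A, run = run)
}

test_that("windowed rate recovers an exact linear drawdown", {
  s <- make_linear_series()
  est <- windowed_rate(s, 10, 20)
  expect_equal(est$volumetric, 10, tolerance = 1e-10)
  expect_equal(est$areal, 10 * 0.0383 / 3.74, tolerance = 1e-10)
  expect_equal(est$areal, 0.1024, tolerance = 1e-3)
  expect_true(est$n >= 3)
  ## areal / volumetric consistency is exact
  expect_equal(est$areal * est$area, est$volumetric * est$volume)
})

test_that("windowed rate errors on an empty window and ignores outside samples", {
  s <- make_linear_series()
  expect_error(windowed_rate(s, 25, 30), "inside the")
  expect_error(windowed_rate(s, 20, 10), "c_lo < c_hi")
  ## adding samples outside the window does not change the estimate
  est_full <- windowed_rate(s, 10, 20)
  sel <- s$nh4_mgL >= 5
  s_trim <- batch_series(s$time_min[sel], s$nh4_mgL[sel], s$no2_mgL[sel],
                         s$no3_mgL[sel], temperature = 20,
                         volume = 0.0383, area = 3.74)
  expect_equal(windowed_rate(s_trim, 10, 20)$areal, est_full$areal)
})

test_that("Arrhenius fit recovers noiseless parameters to high precision", {
  Ts <- c(8, 12, 18, 24, 30)
  d <- data.frame(temperature = Ts, rate = 3 * 1.03^(Ts - 20))
  fit <- fit_arrhenius(d, T0 = 20)
  expect_equal(fit$theta, 1.03, tolerance = 1e-7)
  expect_equal(fit$R_T0, 3, tolerance = 1e-7)
  expect_equal(unname(coef(fit)), c(3, 1.03), tolerance = 1e-7)
  expect_equal(predict(fit, 26), 3 * 1.03^6, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("Arrhenius fit handles constant rates and input validation", {
  d <- data.frame(temperature = c(8, 15, 22, 30), rate = rep(2.5, 4))
  fit <- fit_arrhenius(d, T0 = 20)
  expect_equal(fit$theta, 1, tolerance = 1e-8)
  expect_equal(fit$R_T0, 2.5, tolerance = 1e-8)
  expect_error(fit_arrhenius(data.frame(temperature = c(8, 30),
                                        rate = c(1, 2))), "3 distinct")
  expect_error(fit_arrhenius(data.frame(temperature = c(8, 20, 30),
                                        rate = c(1, -2, 2))), "> 0")
})

test_that("Arrhenius fit is scale equivariant", {
  set.seed(7)
  Ts <- rep(c(8, 12, 18, 24, 30), 2)
  d <- data.frame(temperature = Ts,
                  rate = 2.5 * 1.026^(Ts - 20) * exp(rnorm(10, 0, 0.03)))
  f1 <- fit_arrhenius(d, T0 = 20)
  d2 <- transform(d, rate = 10 * rate)
  f2 <- fit_arrhenius(d2, T0 = 20)
  expect_equal(f2$theta, f1$theta, tolerance = 1e-8)
  expect_equal(f2$R_T0, 10 * f1$R_T0, tolerance = 1e-8)
})

test_that("percent-per-degree statistic matches its definition", {
  expect_equal(percent_per_degree(3, 3, 30, 8), 0)
  expect_equal(percent_per_degree(5.95, 1.82, 30, 8),
               100 * (5.95 - 1.82) / 1.82 / 22)
  expect_equal(percent_per_degree(4.69, 2.80, 30, 8),
               100 * (4.69 - 2.80) / 2.80 / 22)
  expect_error(percent_per_degree(2, 0, 30, 8), "> 0")
  expect_error(percent_per_degree(2, 1, 20, 20), "differ")
  ## identical to the scenario-module statistic (shared implementation)
  expect_identical(percent_per_degree, temperature_sensitivity)
})

test_that("run averaging means duplicates and flags singletons", {
  mk <- function(T, run, areal) {
    structure(list(temperature = T, window = c(10, 20), run = run,
                   areal = areal), class = "rate_estimate")
  }
  est <- list(mk(8, "first", 2.9), mk(8, "second", 3.1), mk(30, "first", 5.0))
  avg <- average_runs(est)
  expect_equal(avg$rate[avg$temperature == 8], 3.0)
  expect_false(avg$single_run[avg$temperature == 8])
  expect_equal(avg$rate[avg$temperature == 30], 5.0)
  expect_true(avg$single_run[avg$temperature == 30])
  expect_error(average_runs(list()), "empty")
})

test_that("nitrite accumulation is the NO2 share of oxidised N at the end", {
  s <- batch_series(c(0, 15, 30), nh4 = c(50, 40, 30),
                    no2 = c(0, 5, 10), no3 = c(0, 5, 10),
                    temperature = 8, volume = 0.1)
  expect_equal(nitrite_accumulation(s), 50)
  s0 <- batch_series(c(0, 15), nh4 = c(50, 40), no2 = c(0, 0),
                     no3 = c(0, 10), temperature = 8, volume = 0.1)
  expect_equal(nitrite_accumulation(s0), 0)
  s_bad <- batch_series(c(0, 15), nh4 = c(50, 50), no2 = c(0, 0),
                        no3 = c(0, 0), temperature = 8, volume = 0.1)
  expect_error(nitrite_accumulation(s_bad), "undefined")
})

test_that("batch series text round-trips through write/read", {
  s <- make_linear_series(temperature = 12, run = "second")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_batch_series(s, path)
  s2 <- read_batch_series(path)
  expect_equal(as.data.frame(s2), as.data.frame(s), tolerance = 1e-9)
  expect_equal(attr(s2, "temperature_C"), 12)
  expect_equal(attr(s2, "run"), "second")
  expect_equal(attr(s2, "volume_m3"), attr(s, "volume_m3"))
})
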