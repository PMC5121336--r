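alk1_schedule <- function(unit = 1) {
  data.frame(conc = c(0.19, 0.57, 1.7, 5.1, 15.3) * unit,
             start = seq(0, 800, by = 200),
             stop = seq(0, 800, by = 200) + 120)
}
ldlr_schedule <- function() {
  data.frame(conc = c(5, 14, 43, 129, 388),
             start = seq(0, 800, by = 200),
             stop = seq(0, 800, by = 200) + 120)
}

test_that("saturation fitter inverts a noiseless one-site isotherm", {
  L <- c(2, 5, 10, 25, 50, 100)
  fit <- fit_saturation(L, 67 * L / (26 + L))
  expect_equal(fit$Kd, 26, tolerance = 1e-3)
  expect_equal(fit$Bmax, 67, tolerance = 1e-3)
  # half-saturation identity of the fitted model
  expect_equal(fit$Bmax * fit$Kd / (fit$Kd + fit$Kd), fit$Bmax / 2)
  # with a linear nonspecific component
  fit_ns <- fit_saturation(L, 67 * L / (26 + L) + 0.1 * L, nonspecific = TRUE)
  expect_equal(fit_ns$Kd, 26, tolerance = 1e-2)
  expect_equal(fit_ns$NS, 0.1, tolerance = 1e-2)
})

test_that("saturation fit units follow the concentration scale", {
  L <- c(2, 5, 10, 25, 50, 100)
  B <- 67 * L / (26 + L)
  f1 <- fit_saturation(L, B)
  f2 <- fit_saturation(L * 1000, B)  # e.g. ng/ml instead of ug/ml
  expect_equal(f2$Kd / f1$Kd, 1000, tolerance = 1e-6)
  expect_equal(f2$Bmax, f1$Bmax, tolerance = 1e-6)
})

test_that("saturation fitter is robust to multiplicative noise", {
  set.seed(1)
  L <- c(2, 5, 10, 25, 50, 100)
  kds <- replicate(200, {
    B <- 67 * L / (26 + L) * (1 + rnorm(6, 0, 0.05))
    fit_saturation(L, B)$Kd
  })
  expect_lt(abs(median(kds) - 26) / 26, 0.10)
})

test_that("saturation fitter validates its inputs", {
  expect_error(fit_saturation(c(1, 2, 3), c(1, 2, 3)), ">= 4 distinct")
  expect_error(fit_saturation(c(3, 2, 1, 4), c(1, 2, 3, 4)))
})

test_that("sensorgram simulation honours the 1:1 model", {
  sched <- data.frame(conc = 10, start = 0, stop = 2000)
  # C >> Kd saturates the surface
  sg <- simulate_sensorgram(k_a = 1, k_d_rate = 0.01, R_max = 100, sched,
                            time = seq(0, 2000, 5))
  expect_equal(max(sg$response), 100 * 10 / (10 + 0.01), tolerance = 1e-6)
  expect_gt(max(sg$response), 0.998 * 100)
  # equilibrium plateau equals Rmax C / (Kd + C)
  sched2 <- data.frame(conc = 0.01, start = 0, stop = 5000)
  sg2 <- simulate_sensorgram(1, 0.01, 100, sched2, time = seq(0, 5000, 10))
  expect_equal(sg2$response[length(sg2$time)], 100 * 0.01 / (0.02),
               tolerance = 1e-3)
  # response stays within [0, Rmax]
  sg3 <- simulate_sensorgram(0.05, 0.01, 80, alk1_schedule())
  expect_true(all(sg3$response >= 0 & sg3$response <= 80 + 1e-9))
  # overlapping or decreasing single-cycle schedules are rejected
  bad <- data.frame(conc = c(2, 1), start = c(0, 50), stop = c(100, 150))
  expect_error(simulate_sensorgram(1, 0.01, 100, bad))
})

test_that("single-cycle 1:1 fit recovers the generating constants", {
  # ALK1-ectodomain schedule at its apparent affinity (200 nM = 0.2 uM)
  sg <- simulate_sensorgram(0.01 / 0.2, 0.01, 100, alk1_schedule())
  fit <- fit_1to1_kinetics(sg)
  expect_equal(fit$Kd, 0.2, tolerance = 0.01)
  # LDLR-ectodomain schedule at 7 nM
  sg2 <- simulate_sensorgram(0.01 / 7, 0.01, 100, ldlr_schedule())
  fit2 <- fit_1to1_kinetics(sg2)
  expect_equal(fit2$Kd, 7, tolerance = 0.07)
  # Kd = kd / ka by construction
  expect_equal(fit$Kd, fit$kd_rate / fit$ka)
  expect_error(fit_1to1_kinetics(
    structure(list(time = 0:100, response = rep(0, 101),
                   schedule = alk1_schedule()), class = "sensorgram")),
    "flat")
})

test_that("simulate-fit round trip recovers parameters across affinities", {
  set.seed(2)
  for (i in 1:20) {
    kd <- 10^runif(1, -2.5, -1.5)
    Kd <- 10^runif(1, -9, -5)  # 1 nM to 10 uM, molar units
    ka <- kd / Kd
    sched <- data.frame(conc = Kd * c(0.2, 0.6, 1.8, 5.4, 16.2),
                        start = seq(0, 800, 200),
                        stop = seq(0, 800, 200) + 120)
    fit <- fit_1to1_kinetics(simulate_sensorgram(ka, kd, 100, sched))
    expect_lt(abs(fit$Kd - Kd) / Kd, 0.01)
    expect_lt(abs(fit$ka - ka) / ka, 0.01)
    expect_lt(abs(fit$kd_rate - kd) / kd, 0.01)
    expect_lt(abs(fit$Rmax - 100) / 100, 0.01)
  }
})

test_that("kinetic and equilibrium routes agree on equilibrated data", {
  # long injections reach equilibrium; plateau values follow the isotherm
  Kd <- 50; kd <- 0.05; ka <- kd / Kd
  conc <- c(10, 25, 60, 150, 400)
  sched <- data.frame(conc = conc, start = seq(0, 4 * 600, 600),
                      stop = seq(0, 4 * 600, 600) + 500)
  sg <- simulate_sensorgram(ka, kd, 100, sched, time = seq(0, 3200, 0.5))
  kin <- fit_1to1_kinetics(sg)
  plateaus <- vapply(seq_len(5), function(i) {
    sg$response[which.min(abs(sg$time - (sched$stop[i] - 1)))]
  }, numeric(1))
  eq <- fit_saturation(conc, plateaus)
  expect_equal(kin$Kd, eq$Kd, tolerance = 0.02)
})

test_that("double referencing subtracts surface and blank traces", {
  tm <- 0:100
  mk <- function(y) structure(list(time = tm, response = y,
                                   schedule = data.frame(conc = 1, start = 0,
                                                         stop = 50)),
                              class = "sensorgram")
  signal <- 10 * exp(-(tm - 30)^2 / 100)
  drift <- 0.05 * tm
  corrected <- double_reference(mk(signal + drift), mk(drift), mk(rep(0, 101)))
  expect_equal(corrected$response, signal)
  # zero references are the identity
  same <- double_reference(mk(signal), NULL, NULL)
  expect_equal(same$response, signal)
  # identical traces cancel into -raw and are flagged
  path <- double_reference(mk(signal), mk(signal), mk(signal))
  expect_equal(path$response, -signal)
  expect_true(isTRUE(attr(path, "pathological")))
  bad <- mk(drift); bad$time <- bad$time + 0.5
  expect_error(double_reference(mk(signal), bad), "time base")
})

test_that("competition analysis separates shared from independent sites", {
  sched <- alk1_schedule()
  naive <- fit_1to1_kinetics(simulate_sensorgram(0.05, 0.01, 100, sched))
  # independent sites: pre-saturating the other site leaves this one alone
  pre_ind <- gen_binding("two_site",
                         params = list(ka1 = 0.05, kd1 = 0.01, Rmax1 = 100,
                                       ka2 = 1, kd2 = 1e-4, Rmax2 = 50,
                                       schedule = sched),
                         site2_occupied = 0, seed = 3)
  fit_ind <- fit_1to1_kinetics(pre_ind$data)
  out <- competition_analysis(naive, fit_ind)
  expect_equal(out$verdict, "non-competitive")
  expect_equal(out$kd_ratio, 1, tolerance = 1e-6)
  # shared site: pre-saturation removes nearly all capacity
  shared <- fit_1to1_kinetics(simulate_sensorgram(0.05, 0.01, 5, sched))
  out2 <- competition_analysis(naive, shared)
  expect_equal(out2$verdict, "competitive")
  # identical fits give ratio exactly 1
  out3 <- competition_analysis(naive, naive)
  expect_equal(out3$kd_ratio, 1)
  expect_equal(out3$amplitude_ratio, 1)
})

test_that("stability-point quantitation normalizes dissociation amplitudes", {
  sched <- data.frame(conc = 2, start = 0, stop = 300)
  ref <- simulate_sensorgram(0.05, 0.005, 100, sched, time = seq(0, 400, 1))
  expect_equal(stability_point_quantitation(ref, ref), 1.0)
  zero <- ref; zero$response <- rep(0, length(ref$time))
  expect_equal(stability_point_quantitation(zero, ref), 0.0)
  # a complex whose binding is preserved reads ~1 against the single analyte
  complex_trace <- simulate_sensorgram(0.05, 0.005, 100, sched,
                                       time = seq(0, 400, 1))
  expect_equal(stability_point_quantitation(complex_trace, ref), 1,
               tolerance = 0.05)
  short <- ref; short$time <- short$time[1:250]; short$response <- short$response[1:250]
  expect_error(stability_point_quantitation(short, ref), "beyond")
})
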