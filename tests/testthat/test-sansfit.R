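# Composite SANS model: component limits, form-factor degeneracies,
# smearing, simulation and bounded fitting.

test_that("the Beaucage term has the Guinier and power-law limits", {
  G <- 2.5; Rg <- 3; d <- 2.4
  # Q -> 0 plateau equals G
  expect_equal(beaucage_intensity(1e-5, G, Rg, d), G, tolerance = 1e-6)
  # high-Q log-log slope recovers -d within 1 %
  Q <- exp(seq(log(20 / Rg), log(60 / Rg), length.out = 50))
  slope <- coef(lm(log(beaucage_intensity(Q, G, Rg, d)) ~ log(Q)))[2]
  expect_equal(unname(slope), -d, tolerance = 0.01)
  # Guinier regression on the low-Q branch returns Rg within 2 %
  Qg <- seq(0.05 / Rg, 0.9 / Rg, length.out = 40)
  fitg <- lm(log(beaucage_intensity(Qg, G, Rg, d)) ~ I(Qg^2))
  expect_equal(sqrt(-3 * unname(coef(fitg)[2])), Rg, tolerance = 0.02)
})

test_that("the ellipsoid form factor degenerates to the sphere", {
  Q <- c(0.05, 0.2, 0.8, 2)
  R <- 12
  sphere <- (3 * (sin(Q * R) - Q * R * cos(Q * R)) / (Q * R)^3)^2
  expect_equal(ellipsoid_form_factor(Q, R, R), sphere, tolerance = 1e-8)
  expect_equal(ellipsoid_form_factor(0, 40, 10), 1, tolerance = 1e-9)
  # Guinier expansion: Rg^2 = (a^2 + 2 b^2) / 5 within 0.5 %
  a <- 40; b <- 10
  rg2 <- (a^2 + 2 * b^2) / 5
  Qg <- seq(1e-3, 0.3 / sqrt(rg2), length.out = 30)
  slope <- coef(lm(log(ellipsoid_form_factor(Qg, a, b)) ~ I(Qg^2)))[2]
  expect_equal(unname(-3 * slope), rg2, tolerance = 0.005 * rg2)
})

test_that("the power-law term enforces the network/gel exponent range", {
  Q <- c(0.1, 1, 4)
  expect_equal(powerlaw_intensity(Q, 2, 2.5), 2 * Q^(-2.5))
  expect_silent(powerlaw_intensity(Q, 1, 5 / 3))
  expect_silent(powerlaw_intensity(Q, 1, 3))
  expect_error(powerlaw_intensity(Q, 1, 3.2), "5/3")
  expect_equal(powerlaw_intensity(Q, 0, 2), rep(0, 3))
})

test_that("the composite intensity is the sum of its components", {
  m <- composite_model(powerlaw = list(A = 1e-3, d_p = 2.5),
                       ellipsoid = list(scale = 5, rg = 30, aspect = 4),
                       oligomer = list(G = 1, rg = 2.3, d = 2),
                       monomer = list(G = 0.05, d = 2), background = 0.01)
  Q <- exp(seq(log(0.01), log(5), length.out = 40))
  comp <- component_intensities(Q, m)
  expect_equal(comp$total,
               comp$powerlaw + comp$ellipsoid + comp$oligomer +
                 comp$monomer + comp$background, tolerance = 1e-12)
  expect_equal(composite_intensity(Q, m), comp$total, tolerance = 1e-12)
  expect_true(all(comp$powerlaw >= 0 & comp$ellipsoid >= 0 &
                    comp$oligomer >= 0 & comp$monomer >= 0))
  # all amplitudes zero leaves only the background
  m0 <- composite_model(background = 0.3)
  expect_equal(composite_intensity(Q, m0), rep(0.3, 40))
  # only the oligomer term reduces to the Beaucage function
  mo <- composite_model(oligomer = list(G = 1, rg = 2.3, d = 2))
  expect_equal(composite_intensity(Q, mo),
               beaucage_intensity(Q, 1, 2.3, 2), tolerance = 1e-12)
  expect_error(composite_model(oligomer = list(G = 1, rg = 7)), "1, 5")
  expect_error(composite_model(ellipsoid = list(scale = 1, rg = 60)),
               "10, 50")
})

test_that("wavelength-spread smearing is bounded and reduces to identity", {
  Q <- exp(seq(log(0.05), log(3), length.out = 60))
  mo <- composite_model(oligomer = list(G = 1, rg = 2.3, d = 2))
  expect_equal(smear_curve(Q, mo, sans_resolution(0)), composite_intensity(Q, mo))
  expect_equal(smear_curve(Q, mo, sans_resolution(0.2, enabled = FALSE)),
               composite_intensity(Q, mo))
  # flat curves are invariant under smearing
  expect_equal(smear_curve(Q, function(q) rep(2, length(q)),
                           sans_resolution(0.2)), rep(2, 60))
  # Guinier Rg of the smeared term is biased low by < 5 % at 20 % spread
  Is <- smear_curve(Q, mo, sans_resolution(0.2))
  sm <- Q < 0.9 / 2.3
  rg_s <- sqrt(-3 * coef(lm(log(Is[sm]) ~ I(Q[sm]^2)))[2])
  expect_lt(abs(rg_s - 2.3) / 2.3, 0.05)
  expect_lt(rg_s, 2.3)
})

test_that("curve simulation is seeded with the declared noise", {
  mo <- composite_model(oligomer = list(G = 1, rg = 2.3, d = 2),
                        background = 0.01)
  Q <- exp(seq(log(0.01), log(5), length.out = 300))
  exact <- simulate_curve(mo, Q, rel_noise = 0, seed = 1)
  expect_equal(exact$I, composite_intensity(Q, mo), tolerance = 1e-12)
  a <- simulate_curve(mo, Q, rel_noise = 0.05, seed = 4)
  b <- simulate_curve(mo, Q, rel_noise = 0.05, seed = 4)
  expect_identical(a$I, b$I)
  resid <- (a$I - exact$I) / exact$I
  expect_equal(sd(resid), 0.05, tolerance = 0.15)
  expect_equal(a$sigma_I, 0.05 * exact$I, tolerance = 1e-12)
})

test_that("composite fitting round-trips the generating parameters", {
  truth <- composite_model(powerlaw = list(A = 5.5e-4, d_p = 2.5),
                           ellipsoid = list(scale = 6, rg = 30, aspect = 4),
                           oligomer = list(G = 1, rg = 2.3, d = 2),
                           monomer = list(G = 0.05, d = 2),
                           background = 0.01)
  Q <- exp(seq(log(0.01), log(5), length.out = 100))
  clean <- simulate_curve(truth, Q, rel_noise = 0, seed = 1)
  clean$sigma_I <- 0.05 * clean$I    # plausible weights for the fit
  fit0 <- fit_composite(clean)
  est <- setNames(fit0$parameters$estimate, fit0$parameters$term)
  expect_equal(est[["rg_o"]], 2.3, tolerance = 0.01)
  expect_equal(est[["G_o"]], 1, tolerance = 0.01)
  expect_equal(est[["d_p"]], 2.5, tolerance = 0.01)
  expect_equal(est[["ell_rg"]], 30, tolerance = 0.01 * 30)
  # 5 % noise: oligomer Rg within 10 % across seeds
  for (sd in c(2, 6, 9)) {
    noisy <- simulate_curve(truth, Q, rel_noise = 0.05, seed = sd)
    fit <- fit_composite(noisy)
    expect_equal(fit$model$oligomer$rg, 2.3, tolerance = 0.1 * 2.3)
  }
  expect_s3_class(autoplot(fit0), "gg")
  expect_true(all(c("redchi2", "rg_oligomer") %in% names(glance(fit0))))
})

test_that("background-only data produce no significant amplitudes", {
  mb <- composite_model(background = 0.05)
  Q <- exp(seq(log(0.01), log(5), length.out = 100))
  curve <- simulate_curve(mb, Q, rel_noise = 0.05, seed = 3)
  fit <- fit_composite(curve)
  amps <- dplyr::filter(fit$parameters,
                        .data$term %in% c("G_o", "G_m", "ell_scale"))
  ok <- is.na(amps$std.error) | amps$estimate < 2 * amps$std.error + 1e-6
  expect_true(all(ok))
})

test_that("the oligomer Rg is separable from the large-aggregate amplitude", {
  base <- oligosizer:::sans_block(2.3)
  Q <- base$Q
  rgs <- vapply(c(0.5, 1, 1.5), function(k) {
    m <- base$truth
    m$powerlaw$A <- m$powerlaw$A * k
    fit <- fit_composite(simulate_curve(m, Q, 0.05, seed = 12))
    fit$model$oligomer$rg
  }, numeric(1))
  expect_lt(max(abs(rgs - rgs[2])) / rgs[2], 0.1)
})

test_that("rg_timeseries tabulates and orders fit series", {
  base <- oligosizer:::sans_block(2.3)
  fits <- lapply(list(c(4, 0.5, 221), c(2, 120, 221), c(2.3, 1, 55)),
                 function(x) {
    m <- base$truth; m$oligomer$rg <- x[1]
    fit_composite(simulate_curve(m, base$Q, 0.05, seed = round(x[1] * 10),
                                 metadata = list(time_h = x[2],
                                                 concentration_uM = x[3])))
  })
  tb <- rg_timeseries(fits)
  expect_equal(nrow(tb), 3)
  expect_equal(tb$concentration_uM, c(55, 221, 221))
  expect_equal(tb$time_h, c(1, 0.5, 120))
  # the generated 4 -> 2 nm step over the 221 uM series is reproduced
  expect_equal(tb$rg_nm[tb$concentration_uM == 221], c(4, 2),
               tolerance = 0.1 * 4)
  one <- rg_timeseries(fits[3])
  expect_equal(nrow(one), 1)
})

test_that("scattering curves round-trip through 3-column ASCII", {
  base <- oligosizer:::sans_block(2.3)
  curve <- simulate_curve(base$truth, base$Q, 0.05, seed = 2,
                          metadata = list(time_h = 1, concentration_uM = 55))
  path <- tempfile(fileext = ".dat")
  write_sans_curve(curve, path)
  back <- read_sans_curve(path)
  expect_equal(back$Q, curve$Q, tolerance = 1e-8)
  expect_equal(back$I, curve$I, tolerance = 1e-8)
  expect_equal(attr(back, "metadata")$concentration_uM, 55)
  # Angstrom input converts on read
  lines <- readLines(path)
  lines[1] <- "# Q_unit=1/A"
  writeLines(lines, path)
  backA <- read_sans_curve(path)
  expect_equal(backA$Q, 10 * curve$Q, tolerance = 1e-7)
  unlink(path)
})
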