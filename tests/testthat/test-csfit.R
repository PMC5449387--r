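# c(s) inversion: basis construction, oracle equivalence with brute-force
# non-negative least squares, recovery of simulated mixtures, regularization
# behaviour, prior refinement, discrete species fitting and the F-statistics
# significance test.

fast_opts <- fit_options(f_ratio = 1.27, vbar = 0.73)

test_that("basis columns are the unit-loading Lamm solutions", {
  sg <- s_grid(1, 5, 2)
  pro <- tiny_protocol()
  A <- build_basis(sg, fast_opts, tiny_geometry, pro, n_radial = 150)
  j <- 2
  D <- diffusion_from_s(sg[j], fast_opts$f_ratio, fast_opts$vbar)
  direct <- as.vector(solve_lamm(sg[j], D, tiny_geometry, pro,
                                 n_radial = 150)$scans)
  expect_equal(unname(A[, j]), direct, tolerance = 1e-12)
  expect_true(all(A >= 0))
  # late-time column norms decrease with s: faster species deplete the
  # inner cell (the outer 20 % is excluded: accumulation at the base).
  # Rows are time-major within radius blocks: row = t + (r - 1) * n_t.
  n_t <- 12; n_r <- 150
  last_scan_inner <- 12 + (seq_len(0.8 * n_r) - 1) * n_t
  norms <- sqrt(colSums(A[last_scan_inner, ]^2))
  expect_true(all(diff(norms) < 0))
})

test_that("with a 3-point grid fit_cs matches brute-force NNLS", {
  scans <- tiny_single_scans(noise = 0.002, seed = 11)
  sg <- s_grid(2.0, 3.0, 0.5)    # 3 grid points
  cs <- fit_cs(scans, sg, fast_opts, lambda = 0)   # regularization off
  A <- build_basis(sg, fast_opts, scans$geometry, scans$protocol,
                   n_radial = length(scans$radii))
  brute <- pracma::lsqnonneg(A, as.vector(scans$scans))$x
  expect_equal(unname(cs$amplitudes), unname(brute), tolerance = 1e-4)
})

test_that("a one-point grid reduces to single-species least squares", {
  scans <- tiny_single_scans()
  sg <- s_grid(2.5, 2.6, 0.2)   # single point at 2.5
  cs <- fit_cs(scans, sg, fast_opts)
  A <- build_basis(sg, fast_opts, scans$geometry, scans$protocol,
                   n_radial = length(scans$radii))
  beta <- sum(A * as.vector(scans$scans)) / sum(A^2)
  expect_equal(sum(cs$amplitudes), beta, tolerance = 1e-6)
})

test_that("noiseless single-species data peak at the true s", {
  scans <- tiny_single_scans(noise = 0)
  sg <- s_grid(1.5, 3.5, 0.05)
  cs <- fit_cs(scans, sg, fast_opts)
  pk <- find_peaks(cs)
  expect_gte(nrow(pk), 1)
  main <- pk$s[which.max(pk$c)]
  expect_lt(abs(main - 2.5609), 0.05 + 1e-9)   # within one grid step
  sw <- integrate_peaks(cs, list(c(1.5, 3.5)))$sw_S
  expect_equal(sw, 2.5609, tolerance = 0.02)
})

test_that("pure noise yields a near-empty distribution", {
  pro <- tiny_protocol()
  radii <- seq(6.001, 7.199, length.out = 150)
  set.seed(99)
  noise <- matrix(rnorm(12 * 150, 0, 0.01), 12, 150)
  scans <- oligosizer:::new_scan_set(radii, pro$scan_times, noise,
                                     tiny_geometry, pro, noise_sigma = 0.01)
  cs <- fit_cs(scans, s_grid(1, 3, 0.25), fast_opts)
  expect_lt(sum(cs$amplitudes), 3 * 0.01)
  expect_error(fit_cs(oligosizer:::new_scan_set(radii, pro$scan_times,
                                                matrix(0, 12, 150),
                                                tiny_geometry, pro),
                      s_grid(1, 3, 0.5), fast_opts), "zero")
})

test_that("increasing the regularization never decreases the misfit", {
  scans <- tiny_single_scans(noise = 0.005, seed = 3)
  sg <- s_grid(1.5, 3.5, 0.1)
  A <- build_basis(sg, fast_opts, scans$geometry, scans$protocol,
                   n_radial = length(scans$radii))
  y <- as.vector(scans$scans)
  AtA <- crossprod(A); Aty <- crossprod(A, y); yty <- sum(y^2)
  LtL <- crossprod(oligosizer:::second_diff_matrix(ncol(A)))
  chis <- vapply(c(0, 1e-3, 1e-2, 1e-1, 1, 10), function(lam) {
    oligosizer:::nnls_regularized(AtA, Aty, yty, lam * sqrt(sum(diag(AtA))),
                                  LtL)$chisq
  }, numeric(1))
  expect_true(all(diff(chis) >= -1e-8))
})

test_that("tikhonov and maxent agree on peak position and area", {
  scans <- tiny_single_scans(noise = 0.005, seed = 5)
  sg <- s_grid(1.5, 3.5, 0.05)
  sw <- vapply(c("tikhonov", "maxent"), function(reg) {
    cs <- fit_cs(scans, sg, fit_options(f_ratio = 1.27, vbar = 0.73,
                                        regularization = reg))
    integrate_peaks(cs, list(c(1.5, 3.5)))$sw_S
  }, numeric(1))
  expect_equal(sw[["tikhonov"]], sw[["maxent"]], tolerance = 0.02)
  expect_equal(unname(sw), c(2.5609, 2.5609), tolerance = 0.02)
})

test_that("peak integration partitions signal and converts to s20,w", {
  scans <- tiny_single_scans(noise = 0.003, seed = 8)
  cs <- fit_cs(scans, s_grid(1.5, 3.5, 0.05), fast_opts)
  pk <- integrate_peaks(cs, list(c(1.5, 2.5), c(2.5, 3.5)))
  expect_equal(sum(pk$fraction_pct), 100, tolerance = 0.1)
  expect_error(integrate_peaks(cs, list(c(1.5, 2.6), c(2.5, 3.5))), "overlap")
  # empty window reports a zero-signal record
  empty <- integrate_peaks(cs, list(c(3.4, 3.5)))
  expect_equal(empty$signal, 0, tolerance = 1e-4)
  # at 20 degC in water the s20,w equals s
  expect_equal(pk$sw20w_S, pk$sw_S, tolerance = 1e-10)
})

test_that("prior refinement sharpens peaks without degrading the fit", {
  scans <- tiny_single_scans(noise = 0.005, seed = 13)
  sg <- s_grid(1.5, 3.5, 0.05)
  cs <- fit_cs(scans, sg, fast_opts)
  expect_identical(bayesian_refine(scans, cs, numeric(0)), cs)
  expect_error(bayesian_refine(scans, cs, 9), "grid")
  ref <- bayesian_refine(scans, cs, prior_peaks = 2.55)
  # contract: chi-square stays within the original F-bound
  expect_lte(ref$chisq, cs$chisq_bound * (1 + 1e-8))
  # peak sharpens: more mass concentrated at the mode
  expect_gt(max(ref$amplitudes), max(cs$amplitudes))
  # weight-average essentially unchanged
  expect_equal(integrate_peaks(ref, list(c(1.5, 3.5)))$sw_S,
               integrate_peaks(cs, list(c(1.5, 3.5)))$sw_S,
               tolerance = 0.02)
  # priors in empty regions leave the distribution data-dominated
  far <- bayesian_refine(scans, cs, prior_peaks = c(2.55, 1.6))
  expect_lt(sum(far$amplitudes[cs$s < 1.8]), 0.02 * sum(far$amplitudes))
})

test_that("discrete species refinement recovers a two-species mixture", {
  comp <- mixture_components(loading = c(0.6, 0.4), mass = c(4514, 27084),
                             vbar = 0.73, f_ratio = c(1.4, 1.4))
  scans <- simulate_mixture(comp, tiny_geometry, tiny_protocol(),
                            noise_sigma = 0.003, seed = 21, n_radial = 200)
  opts <- fit_options(f_ratio = 1.4, vbar = 0.73)
  # init at truth on noiseless data stays put
  clean <- simulate_mixture(comp, tiny_geometry, tiny_protocol(),
                            noise_sigma = 0, seed = 1, n_radial = 200)
  sp0 <- discrete_species_fit(clean, tibble::tibble(s = comp$s,
                                                    loading = comp$loading),
                              opts)
  expect_equal(sp0$species$s, comp$s, tolerance = 1e-3)
  expect_lt(sp0$rmsd, 1e-6)
  # noisy data, perturbed init: s recovered within 2 %
  sp <- discrete_species_fit(scans, tibble::tibble(s = comp$s * c(1.2, 0.9),
                                                   loading = c(0.5, 0.5)),
                             opts)
  expect_equal(sort(sp$species$s), sort(comp$s), tolerance = 0.02)
  # merging two resolvable species into one increases the rmsd
  sp1 <- discrete_species_fit(scans, tibble::tibble(s = 1.2, loading = 1),
                              opts)
  expect_gt(sp1$rmsd, sp$rmsd)
})

test_that("the F-test flags real trace species and ignores dummies", {
  comp <- mixture_components(loading = c(0.95, 0.05), mass = c(4514, 27084),
                             vbar = 0.73, f_ratio = c(1.4, 1.4))
  scans <- simulate_mixture(comp, tiny_geometry, tiny_protocol(),
                            noise_sigma = 0.004, seed = 31, n_radial = 200)
  opts <- fit_options(f_ratio = 1.4, vbar = 0.73)
  sp <- discrete_species_fit(scans, tibble::tibble(s = comp$s,
                                                   loading = comp$loading),
                             opts)
  sig <- species_significance(scans, sp, drop_index = 2)
  expect_true(sig$significant)
  expect_gte(sig$rmsd_reduced, sig$rmsd_full)
  expect_gt(sig$rmsd_critical, sig$rmsd_full)
  # a zero-amplitude dummy species is not significant
  spd <- sp
  spd$species <- rbind(sp$species, tibble::tibble(s = 4, loading = 0))
  sigd <- species_significance(scans, spd, drop_index = 3)
  expect_false(sigd$significant)
  expect_error(species_significance(scans, sp, drop_index = 7), "range")
})

test_that("tidiers and accessors expose the fit", {
  scans <- tiny_single_scans(noise = 0.003, seed = 2)
  cs <- fit_cs(scans, s_grid(2, 3, 0.1), fast_opts)
  tb <- tidy(cs)
  expect_named(tb, c("s", "c"))
  g <- glance(cs)
  expect_true(all(c("rmsd", "lambda", "total_signal") %in% names(g)))
  expect_s3_class(autoplot(cs), "gg")
})
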