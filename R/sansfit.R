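# Four-component small-angle scattering intensity model for aggregating
# peptide solutions: power-law large aggregates, ellipsoid-of-revolution
# midsize species, Beaucage small-oligomer term, and a fixed-Rg monomer
# background, with curve simulation, optional wavelength-spread smearing,
# bounded weighted fitting and oligomer-Rg time-series extraction.
# Q is handled in 1/nm internally; 1/Angstrom input converts by x10.

#' Beaucage (unified) scattering intensity
#'
#' `I(Q) = G exp(-Q^2 Rg^2 / 3) + B [erf(Q Rg / sqrt(6))^3 / Q]^d` with the
#' standard unified-fit prefactor
#' `B = (G d / Rg^d) [6 d^2 / ((2 + d)(2 + 2d))]^(d/2) Gamma(d/2)`, joining a
#' Guinier regime (forward amplitude `G`, radius of gyration `Rg`) to a
#' high-Q power law of exponent `d`.
#'
#' @param Q Momentum transfer, 1/nm (vector, > 0).
#' @param G Guinier forward amplitude (> 0), arbitrary units.
#' @param Rg Radius of gyration, nm (> 0).
#' @param d Power-law dimensionality, in \[1, 4\].
#' @return Intensity vector, same units as `G`.
#' @export
beaucage_intensity <- function(Q, G, Rg, d = 2) {
  stopifnot(all(Q > 0), G >= 0, Rg > 0, d >= 1, d <= 4)
  B <- (G * d / Rg^d) * (6 * d^2 / ((2 + d) * (2 + 2 * d)))^(d / 2) *
    gamma(d / 2)
  G * exp(-Q^2 * Rg^2 / 3) + B * (erf_vec(Q * Rg / sqrt(6))^3 / Q)^d
}

erf_vec <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Orientationally averaged ellipsoid-of-revolution form factor
#'
#' `P(Q) = int_0^(pi/2) [3 (sin x - x cos x)/x^3]^2 sin(theta) dtheta` with
#' `x = Q sqrt(a^2 cos^2 theta + b^2 sin^2 theta)`, evaluated by fixed
#' Gauss-Legendre quadrature (96 nodes, accurate to better than 1e-6 for the
#' axis ratios used here); `P(0) = 1`.
#'
#' @param Q Momentum transfer, 1/nm (vector, >= 0).
#' @param a Polar semi-axis, nm.
#' @param b Equatorial semi-axis, nm.
#' @return Form factor values in \[0, 1\].
#' @export
ellipsoid_form_factor <- function(Q, a, b) {
  stopifnot(a > 0, b > 0)
  gl <- pracma::gaussLegendre(96, 0, pi / 2)
  sphere_amp <- function(x) {
    # 3 (sin x - x cos x)/x^3 with stable small-x limit 1
    ifelse(x < 1e-4, 1 - x^2 / 10, 3 * (sin(x) - x * cos(x)) / x^3)
  }
  vapply(Q, function(q) {
    x <- q * sqrt(a^2 * cos(gl$x)^2 + b^2 * sin(gl$x)^2)
    sum(gl$w * sphere_amp(x)^2 * sin(gl$x))
  }, numeric(1))
}

#' Power-law intensity for large aggregates
#'
#' `I(Q) = A Q^(-d_p)` with the exponent restricted to \[5/3, 3\], the
#' mass-/surface-fractal range expected for networks and gels.
#'
#' @param Q Momentum transfer, 1/nm.
#' @param A Amplitude (>= 0).
#' @param d_p Power-law exponent in \[5/3, 3\].
#' @return Intensity vector.
#' @export
powerlaw_intensity <- function(Q, A, d_p) {
  if (d_p < 5 / 3 || d_p > 3) {
    stop("power-law exponent must lie in [5/3, 3]", call. = FALSE)
  }
  stopifnot(A >= 0)
  A * Q^(-d_p)
}

# Equatorial semi-axis from (Rg, aspect): Rg^2 = (a^2 + 2 b^2)/5, a = aspect*b
ellipsoid_axes <- function(rg, aspect) {
  b <- rg * sqrt(5 / (aspect^2 + 2))
  c(a = aspect * b, b = b)
}

#' Four-component composite scattering model
#'
#' Bundles the model of a dilute aggregating peptide solution: power-law
#' large aggregates (`Rg`-equivalent above 50 nm), ellipsoid-of-revolution
#' midsize species (`Rg` 10-50 nm, parametrized by `Rg` and a fixed aspect
#' ratio), a Beaucage small-oligomer term (`Rg` 1-5 nm), a monomer Beaucage
#' background pinned at `Rg` = 1 nm, and a flat background.
#'
#' @param powerlaw `list(A, d_p)` with `A >= 0`, `d_p` in \[5/3, 3\].
#' @param ellipsoid `list(scale, rg, aspect)`; `rg` in \[10, 50\] nm, aspect
#'   ratio defaults to 4.
#' @param oligomer `list(G, rg, d)`; `rg` in \[1, 5\] nm, dimensionality `d`
#'   defaults to 2.
#' @param monomer `list(G, d)`; `Rg` is fixed at 1 nm.
#' @param background Flat background (>= 0).
#' @return An object of class `composite_model`.
#' @export
composite_model <- function(powerlaw = list(A = 0, d_p = 2.5),
                            ellipsoid = list(scale = 0, rg = 30, aspect = 4),
                            oligomer = list(G = 0, rg = 2.5, d = 2),
                            monomer = list(G = 0, d = 2),
                            background = 0) {
  powerlaw <- utils::modifyList(list(A = 0, d_p = 2.5), powerlaw)
  ellipsoid <- utils::modifyList(list(scale = 0, rg = 30, aspect = 4), ellipsoid)
  oligomer <- utils::modifyList(list(G = 0, rg = 2.5, d = 2), oligomer)
  monomer <- utils::modifyList(list(G = 0, d = 2), monomer)
  if (powerlaw$A > 0 && (powerlaw$d_p < 5 / 3 || powerlaw$d_p > 3)) {
    stop("power-law exponent must lie in [5/3, 3]", call. = FALSE)
  }
  if (ellipsoid$scale > 0 && (ellipsoid$rg < 10 || ellipsoid$rg > 50)) {
    stop("ellipsoid Rg must lie in [10, 50] nm", call. = FALSE)
  }
  if (oligomer$G > 0 && (oligomer$rg < 1 || oligomer$rg > 5)) {
    stop("oligomer Rg must lie in [1, 5] nm", call. = FALSE)
  }
  stopifnot(powerlaw$A >= 0, ellipsoid$scale >= 0, oligomer$G >= 0,
            monomer$G >= 0, background >= 0)
  structure(list(powerlaw = powerlaw, ellipsoid = ellipsoid,
                 oligomer = oligomer, monomer = monomer,
                 background = background, monomer_rg = 1),
            class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  cat("<composite_model>\n")
  cat(sprintf("  powerlaw : A = %.4g, d_p = %.3g\n", x$powerlaw$A, x$powerlaw$d_p))
  cat(sprintf("  ellipsoid: scale = %.4g, Rg = %.3g nm, aspect = %.3g\n",
              x$ellipsoid$scale, x$ellipsoid$rg, x$ellipsoid$aspect))
  cat(sprintf("  oligomer : G = %.4g, Rg = %.3g nm, d = %.3g\n",
              x$oligomer$G, x$oligomer$rg, x$oligomer$d))
  cat(sprintf("  monomer  : G = %.4g, Rg = 1 nm (fixed), d = %.3g\n",
              x$monomer$G, x$monomer$d))
  cat(sprintf("  background: %.4g\n", x$background))
  invisible(x)
}

#' Evaluate the composite model, per component or total
#'
#' @param Q Momentum transfer, 1/nm.
#' @param model A [composite_model()].
#' @return `composite_intensity()`: total intensity vector.
#'   `component_intensities()`: a tibble with one column per component plus
#'   `total`.
#' @export
composite_intensity <- function(Q, model) {
  rowSums(as.matrix(component_intensities(Q, model)[
    , c("powerlaw", "ellipsoid", "oligomer", "monomer", "background")]))
}

#' @rdname composite_intensity
#' @export
component_intensities <- function(Q, model) {
  stopifnot(inherits(model, "composite_model"))
  ax <- ellipsoid_axes(model$ellipsoid$rg, model$ellipsoid$aspect)
  pl <- if (model$powerlaw$A > 0) {
    powerlaw_intensity(Q, model$powerlaw$A, model$powerlaw$d_p)
  } else rep(0, length(Q))
  el <- if (model$ellipsoid$scale > 0) {
    model$ellipsoid$scale * ellipsoid_form_factor(Q, ax["a"], ax["b"])
  } else rep(0, length(Q))
  ol <- if (model$oligomer$G > 0) {
    beaucage_intensity(Q, model$oligomer$G, model$oligomer$rg, model$oligomer$d)
  } else rep(0, length(Q))
  mo <- if (model$monomer$G > 0) {
    beaucage_intensity(Q, model$monomer$G, model$monomer_rg, model$monomer$d)
  } else rep(0, length(Q))
  tibble::tibble(Q = Q, powerlaw = pl, ellipsoid = el, oligomer = ol,
                 monomer = mo, background = rep(model$background, length(Q)),
                 total = pl + el + ol + mo + model$background)
}

#' Instrumental resolution description
#'
#' @param rel_spread Relative wavelength spread (FWHM) `dlambda/lambda`, in
#'   \[0, 0.5); 0.2 is typical of velocity-selector SANS instruments.
#' @param enabled Apply smearing at all.
#' @return An object of class `sans_resolution`.
#' @export
sans_resolution <- function(rel_spread = 0.2, enabled = TRUE) {
  stopifnot(rel_spread >= 0, rel_spread < 0.5)
  structure(list(rel_spread = rel_spread, enabled = enabled),
            class = "sans_resolution")
}

#' Smear a model curve with a Gaussian wavelength-spread kernel
#'
#' Convolves the model intensity in Q with a Gaussian of standard deviation
#' `sigma_Q = Q (dlambda/lambda) / sqrt(8 ln 2)` (the FWHM-to-sigma
#' conversion of the triangular selector spread), using 21-node
#' Gauss-Hermite quadrature truncated at Q > 0. Disabled resolution returns
#' the unsmeared evaluation.
#'
#' @param Q Momentum transfer, 1/nm.
#' @param model A [composite_model()], or a function `I(Q)`.
#' @param resolution A [sans_resolution()].
#' @return Smeared intensity vector.
#' @export
smear_curve <- function(Q, model, resolution = sans_resolution()) {
  fI <- if (inherits(model, "composite_model")) {
    function(q) composite_intensity(q, model)
  } else model
  if (!resolution$enabled || resolution$rel_spread == 0) return(fI(Q))
  gh <- pracma::gaussHermite(21)
  sig <- Q * resolution$rel_spread / sqrt(8 * log(2))
  vapply(seq_along(Q), function(i) {
    qq <- Q[i] + sqrt(2) * sig[i] * gh$x
    keep <- qq > 0
    sum(gh$w[keep] * fI(qq[keep])) / sum(gh$w[keep])
  }, numeric(1))
}

#' Simulate a reduced scattering curve
#'
#' Evaluates the composite model (optionally smeared) on the Q grid and
#' applies multiplicative Gaussian noise: `I_sim = I (1 + eps)`,
#' `eps ~ N(0, rel_noise)`, with `sigma_I = rel_noise * I`.
#'
#' @param model A [composite_model()].
#' @param Q Momentum transfer grid, 1/nm (ascending).
#' @param rel_noise Relative noise level (>= 0).
#' @param seed Integer seed.
#' @param resolution Optional [sans_resolution()]; default off.
#' @param metadata Named list (e.g. `time_h`, `concentration_uM`) carried as
#'   attributes.
#' @return A `scattering_curve` tibble with columns `Q`, `I`, `sigma_I`.
#' @export
simulate_curve <- function(model, Q, rel_noise = 0.05, seed = 1L,
                           resolution = NULL, metadata = list()) {
  stopifnot(all(diff(Q) > 0), all(Q > 0), rel_noise >= 0)
  I0 <- if (!is.null(resolution) && resolution$enabled) {
    smear_curve(Q, model, resolution)
  } else composite_intensity(Q, model)
  eps <- if (rel_noise > 0) with_seed(seed, rnorm(length(Q), 0, rel_noise)) else 0
  out <- tibble::tibble(Q = Q, I = I0 * (1 + eps),
                        sigma_I = pmax(rel_noise * I0, 1e-12))
  structure(out, class = c("scattering_curve", class(out)),
            metadata = metadata, seed = seed)
}

#' Read/write reduced scattering curves (3-column ASCII)
#'
#' Plain-text `Q I sigma_I` rows with `#` comment lines; a
#' `# Q_unit=1/nm` or `# Q_unit=1/A` header declares the Q unit
#' (1/Angstrom values are converted to 1/nm on read).
#'
#' @param curve A `scattering_curve` (or tibble with `Q`, `I`, `sigma_I`).
#' @param path File path.
#' @return `read_sans_curve()` returns a `scattering_curve` tibble;
#'   `write_sans_curve()` returns `path` invisibly.
#' @export
write_sans_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# Q_unit=1/nm", con)
  md <- attr(curve, "metadata")
  for (nm in names(md)) writeLines(sprintf("# %s=%.10g", nm, md[[nm]]), con)
  writeLines("# Q I sigma_I", con)
  writeLines(sprintf("%.10g %.10g %.10g", curve$Q, curve$I, curve$sigma_I), con)
  invisible(path)
}

#' @rdname write_sans_curve
#' @export
read_sans_curve <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  unit <- 1
  if (any(grepl("Q_unit=1/A", hdr, fixed = TRUE))) unit <- 10
  md <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)=([-0-9.eE+]+)$", h))[[1]]
    if (length(m) == 3 && m[2] != "Q_unit") md[[m[2]]] <- as.numeric(m[3])
  }
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            col.names = c("Q", "I", "sigma_I"))
  out <- tibble::tibble(Q = body$Q * unit, I = body$I,
                        sigma_I = body$sigma_I)
  structure(out, class = c("scattering_curve", class(out)), metadata = md)
}

# Flatten a composite model into the named parameter vector used by the
# fitter, with box bounds.
model_par_table <- function(model) {
  tibble::tibble(
    name  = c("A", "d_p", "ell_scale", "ell_rg", "G_o", "rg_o", "d_o",
              "G_m", "d_m", "background"),
    value = c(model$powerlaw$A, model$powerlaw$d_p, model$ellipsoid$scale,
              model$ellipsoid$rg, model$oligomer$G, model$oligomer$rg,
              model$oligomer$d, model$monomer$G, model$monomer$d,
              model$background),
    lower = c(0, 5 / 3, 0, 10, 0, 1, 1, 0, 1, 0),
    upper = c(Inf, 3, Inf, 50, Inf, 5, 4, Inf, 4, Inf)
  )
}

par_to_model <- function(p, aspect) {
  composite_model(
    powerlaw = list(A = p[["A"]], d_p = p[["d_p"]]),
    ellipsoid = list(scale = p[["ell_scale"]], rg = p[["ell_rg"]],
                     aspect = aspect),
    oligomer = list(G = p[["G_o"]], rg = p[["rg_o"]], d = p[["d_o"]]),
    monomer = list(G = p[["G_m"]], d = p[["d_m"]]),
    background = p[["background"]]
  )
}

#' Fit the composite model to a scattering curve
#'
#' Bounded weighted least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the four-component model. The monomer Rg is always
#' fixed at 1 nm; the component dimensionalities `d_o`, `d_m` and the
#' ellipsoid aspect ratio are fixed by default (free them by removing them
#' from `fixed`). Residuals are `(I_model - I)/sigma_I`.
#'
#' @param curve A `scattering_curve` (columns `Q`, `I`, `sigma_I`).
#' @param init A [composite_model()] with starting values; default
#'   [sans_default_init()].
#' @param fixed Character vector of parameter names to hold at their initial
#'   values, among `A`, `d_p`, `ell_scale`, `ell_rg`, `G_o`, `rg_o`, `d_o`,
#'   `G_m`, `d_m`, `background`.
#' @return An object of class `sans_fit`: fitted `model`, tibble `parameters`
#'   (estimate, std.error, fixed flag), `redchi2`, per-component curves.
#' @export
fit_composite <- function(curve, init = sans_default_init(curve),
                          fixed = c("d_o", "d_m")) {
  stopifnot(all(c("Q", "I", "sigma_I") %in% names(curve)))
  pt <- model_par_table(init)
  aspect <- init$ellipsoid$aspect
  free <- !(pt$name %in% fixed)
  if (!any(free)) stop("no free parameters", call. = FALSE)
  p_all <- setNames(pt$value, pt$name)
  w <- 1 / curve$sigma_I

  resid_fn <- function(pf) {
    p <- p_all
    p[pt$name[free]] <- pf
    m <- try(par_to_model(p, aspect), silent = TRUE)
    if (inherits(m, "try-error")) return(rep(1e6, nrow(curve)))
    (composite_intensity(curve$Q, m) - curve$I) * w
  }
  fit <- minpack.lm::nls.lm(
    par = pt$value[free], lower = pt$lower[free], upper = pt$upper[free],
    fn = resid_fn, control = minpack.lm::nls.lm.control(maxiter = 300))
  if (fit$info %in% c(0, 9)) {
    stop("composite fit did not converge (info = ", fit$info, ")",
         call. = FALSE)
  }
  p_all[pt$name[free]] <- fit$par
  model <- par_to_model(p_all, aspect)
  nu <- nrow(curve) - sum(free)
  redchi2 <- sum(fit$fvec^2) / nu
  se <- rep(NA_real_, nrow(pt))
  cov <- try(solve(fit$hessian) * 2 * redchi2, silent = TRUE)
  if (!inherits(cov, "try-error")) {
    d <- diag(cov)
    se[free] <- sqrt(pmax(d, 0))
  }
  structure(list(
    model = model,
    parameters = tibble::tibble(term = pt$name, estimate = unname(p_all),
                                std.error = se, fixed = !free),
    redchi2 = redchi2, curve = curve,
    components = component_intensities(curve$Q, model)
  ), class = "sans_fit")
}

#' Heuristic starting model for [fit_composite()]
#'
#' Seeds the power-law amplitude from the lowest-Q intensity, the oligomer
#' amplitude from the intensity near the expected shoulder, the background
#' from the highest-Q tail, and neutral mid-range radii.
#'
#' @param curve A `scattering_curve`.
#' @return A [composite_model()].
#' @export
sans_default_init <- function(curve) {
  qlo <- head(curve$Q, 3); ilo <- mean(head(curve$I, 3))
  bkg <- max(min(tail(curve$I, 5)) * 0.5, 1e-8)
  i_sh <- mean(curve$I[which.min(abs(curve$Q - 0.3))])
  composite_model(
    powerlaw = list(A = max(ilo, 1e-8) * mean(qlo)^2.5, d_p = 2.5),
    ellipsoid = list(scale = max(i_sh, 1e-8) * 5, rg = 25, aspect = 4),
    oligomer = list(G = max(i_sh - bkg, 1e-6), rg = 3, d = 2),
    monomer = list(G = max(bkg, 1e-8), d = 2),
    background = bkg
  )
}

#' @export
print.sans_fit <- function(x, ...) {
  cat(sprintf("<sans_fit> reduced chi2 = %.3f\n", x$redchi2))
  print(x$parameters, n = nrow(x$parameters))
  invisible(x)
}

#' @describeIn fit_composite Parameter table (term, estimate, std.error,
#'   fixed).
#' @param x A `sans_fit`.
#' @param ... Unused.
#' @export
tidy.sans_fit <- function(x, ...) x$parameters

#' @describeIn fit_composite One-row fit summary.
#' @export
glance.sans_fit <- function(x, ...) {
  tibble::tibble(redchi2 = x$redchi2, n = nrow(x$curve),
                 n_free = sum(!x$parameters$fixed),
                 rg_oligomer = x$model$oligomer$rg)
}

#' Plot a composite SANS fit as a log-log decomposition
#'
#' @param object A `sans_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sans_fit <- function(object, ...) {
  comp <- tidyr::pivot_longer(object$components, -"Q",
                              names_to = "component", values_to = "I")
  ggplot2::ggplot() +
    ggplot2::geom_point(data = object$curve,
                        ggplot2::aes(.data$Q, .data$I), size = 0.6,
                        alpha = 0.6) +
    ggplot2::geom_line(data = dplyr::filter(comp, .data$I > 0),
                       ggplot2::aes(.data$Q, .data$I,
                                    colour = .data$component)) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Q (1/nm)", y = "I(Q) (a.u.)")
}

#' Tabulate fitted oligomer radii of gyration over an incubation series
#'
#' @param fits A list of `sans_fit` objects whose curves carry `time_h` and
#'   `concentration_uM` metadata (see [simulate_curve()]).
#' @return A tibble sorted by (concentration, time) with columns `time_h`,
#'   `concentration_uM`, `rg_nm`, `rg_se_nm`.
#' @export
rg_timeseries <- function(fits) {
  stopifnot(length(fits) >= 1)
  tb <- purrr::map_dfr(fits, function(f) {
    md <- attr(f$curve, "metadata")
    row <- dplyr::filter(f$parameters, .data$term == "rg_o")
    tibble::tibble(
      time_h = md$time_h %||% NA_real_,
      concentration_uM = md$concentration_uM %||% NA_real_,
      rg_nm = row$estimate, rg_se_nm = row$std.error
    )
  })
  dplyr::arrange(tb, .data$concentration_uM, .data$time_h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
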