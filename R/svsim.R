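# Forward simulation of sedimentation-velocity experiments: Lamm-equation
# transport of one or more non-interacting species in a sector-shaped cell,
# plus seeded Gaussian detection noise. Serves as the synthetic-data
# generator for all c(s) analyses in the package.

#' Sector cell geometry
#'
#' @param meniscus Meniscus radius, cm (default 6.0).
#' @param base Cell base radius, cm (default 7.2, a typical maximum radius).
#' @param pathlength Optical pathlength, cm (1.2 for standard absorbance
#'   cells, 0.3 for short fluorescence cells).
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(meniscus = 6.0, base = 7.2, pathlength = 1.2) {
  stopifnot(meniscus < base)
  if (meniscus < 5.8 || base > 7.3) {
    stop("radii must lie within [5.8, 7.3] cm", call. = FALSE)
  }
  structure(list(meniscus = meniscus, base = base, pathlength = pathlength),
            class = "cell_geometry")
}

#' Rotor speed, temperature and scan schedule
#'
#' @param rpm Rotor speed in revolutions per minute (50,000 or 60,000 are the
#'   usual choices for small oligomers).
#' @param temperature Run temperature, degC.
#' @param scan_times Strictly increasing scan times in seconds since full
#'   speed. Defaults to 60 scans: 90 s spacing for absorbance detection,
#'   60 s for fluorescence.
#' @param detection `"absorbance"` or `"fluorescence"`.
#' @return An object of class `rotor_protocol`.
#' @export
rotor_protocol <- function(rpm = 50000, temperature = 20,
                           scan_times = NULL,
                           detection = c("absorbance", "fluorescence")) {
  detection <- match.arg(detection)
  if (is.null(scan_times)) {
    dt <- if (detection == "absorbance") 90 else 60
    scan_times <- seq_len(60) * dt
  }
  stopifnot(rpm > 0, all(diff(scan_times) > 0), all(scan_times >= 0))
  structure(list(rpm = rpm, temperature = temperature,
                 scan_times = scan_times, detection = detection),
            class = "rotor_protocol")
}

omega2 <- function(rpm) (2 * pi * rpm / 60)^2

#' Non-interacting mixture components
#'
#' Builds the `(s, D, loading)` component table consumed by
#' [simulate_mixture()]. Components may be given directly via `s` (Svedberg),
#' `D` (m2/s) and `loading` (signal units), or through species parameters
#' `(mass, vbar, f_ratio)` from which `s` and `D` follow via [svedberg_s()]
#' and [diffusion_from_s()].
#'
#' @param s,D,loading Vectors of sedimentation coefficients (S), diffusion
#'   coefficients (m2/s) and loading signals.
#' @param mass,vbar,f_ratio Optional species parameters; used for any entry
#'   whose `s`/`D` is `NA`.
#' @param solvent Solvent for the hydrodynamic conversion.
#' @return A tibble with columns `s`, `D`, `loading`.
#' @export
mixture_components <- function(s = NA_real_, D = NA_real_, loading,
                               mass = NA_real_, vbar = NA_real_,
                               f_ratio = NA_real_,
                               solvent = solvent_conditions(20)) {
  n <- max(lengths(list(s, D, loading, mass, vbar, f_ratio)))
  tb <- tibble::tibble(s = rep_len(s, n), D = rep_len(D, n),
                       loading = rep_len(loading, n),
                       mass = rep_len(mass, n), vbar = rep_len(vbar, n),
                       f_ratio = rep_len(f_ratio, n))
  need <- is.na(tb$s)
  if (any(need)) {
    tb$s[need] <- svedberg_s(tb$mass[need], tb$vbar[need], tb$f_ratio[need],
                             solvent)
  }
  need_d <- is.na(tb$D)
  if (any(need_d)) {
    tb$D[need_d] <- diffusion_from_s(tb$s[need_d], tb$f_ratio[need_d],
                                     tb$vbar[need_d], solvent)
  }
  stopifnot(all(tb$s > 0), all(tb$D > 0), all(tb$loading >= 0))
  tb[, c("s", "D", "loading")]
}

new_scan_set <- function(radii, times, scans, geometry, protocol,
                         noise_sigma = 0, seed = NA_integer_) {
  stopifnot(nrow(scans) == length(times), ncol(scans) == length(radii),
            all(is.finite(scans)))
  structure(list(radii = radii, times = times, scans = scans,
                 geometry = geometry, protocol = protocol,
                 noise_sigma = noise_sigma, seed = seed),
            class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf(
    "<scan_set> %d scans x %d radii; %g rpm, %g degC, %s; r = [%.2f, %.2f] cm; noise sigma = %g\n",
    length(x$times), length(x$radii), x$protocol$rpm,
    x$protocol$temperature, x$protocol$detection,
    x$geometry$meniscus, x$geometry$base, x$noise_sigma))
  invisible(x)
}

#' @export
as.data.frame.scan_set <- function(x, ...) {
  as.data.frame(tidy.scan_set(x))
}

#' Tidy a scan set into long format
#'
#' @param x A `scan_set`.
#' @param ... Unused.
#' @return A tibble with columns `scan_index`, `time_s`, `radius_cm`,
#'   `signal`.
#' @export
tidy.scan_set <- function(x, ...) {
  tibble::tibble(
    scan_index = rep(seq_along(x$times), each = length(x$radii)),
    time_s = rep(x$times, each = length(x$radii)),
    radius_cm = rep(x$radii, times = length(x$times)),
    signal = as.vector(t(x$scans))
  )
}

#' Solve the Lamm equation for one species
#'
#' Crank-Nicolson finite-volume solution of sedimentation-diffusion transport
#' in a sector-shaped cell with zero flux through meniscus and base, starting
#' from a uniform unit loading. The finite-volume scheme conserves the sector
#' mass integral exactly; the time step is Courant-limited at 0.5.
#'
#' @param s Sedimentation coefficient, Svedberg.
#' @param D Diffusion coefficient, m2/s.
#' @param geometry A [cell_geometry()].
#' @param protocol A [rotor_protocol()].
#' @param n_radial Number of radial cells (default 600).
#' @param dt_max Accuracy cap on the internal time step, s.
#' @return A noise-free `scan_set` with unit loading.
#' @export
solve_lamm <- function(s, D, geometry = cell_geometry(),
                       protocol = rotor_protocol(), n_radial = 600,
                       dt_max = 10) {
  stopifnot(s > 0, D > 0)
  w2 <- omega2(protocol$rpm)
  # SI/cgs bridge: radii in cm, times in s -> s*w2*r in cm/s with s in
  # seconds; D m2/s -> cm2/s
  scans <- cpp_solve_lamm(geometry$meniscus, geometry$base, as.integer(n_radial),
                          s * 1e-13, D * 1e4, w2, protocol$scan_times, dt_max)
  radii <- cpp_lamm_radii(geometry$meniscus, geometry$base, as.integer(n_radial))
  new_scan_set(radii, protocol$scan_times, scans, geometry, protocol)
}

#' Simulate a sedimentation-velocity experiment for a mixture
#'
#' Superimposes unit-loading Lamm solutions scaled by each component's
#' loading signal and adds i.i.d. Gaussian detection noise.
#'
#' @param components A tibble from [mixture_components()].
#' @param geometry,protocol Cell and run description.
#' @param noise_sigma Standard deviation of the Gaussian noise, signal units.
#' @param seed Integer seed; the same seed reproduces the scan set exactly.
#' @param n_radial,dt_max Solver controls, see [solve_lamm()].
#' @return A `scan_set`.
#' @export
simulate_mixture <- function(components, geometry = cell_geometry(),
                             protocol = rotor_protocol(), noise_sigma = 0,
                             seed = 1L, n_radial = 600, dt_max = 10) {
  stopifnot(nrow(components) >= 1)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  total <- 0
  for (i in seq_len(nrow(components))) {
    sol <- solve_lamm(components$s[i], components$D[i], geometry, protocol,
                      n_radial = n_radial, dt_max = dt_max)
    total <- total + components$loading[i] * sol$scans
  }
  if (noise_sigma > 0) {
    total <- total + with_seed(seed, matrix(rnorm(length(total), 0, noise_sigma),
                                            nrow = nrow(total)))
  }
  radii <- cpp_lamm_radii(geometry$meniscus, geometry$base,
                          as.integer(n_radial))
  new_scan_set(radii, protocol$scan_times, total, geometry, protocol,
               noise_sigma = noise_sigma, seed = as.integer(seed))
}

#' Faxen approximation to the boundary midpoint position
#'
#' In the diffusion-free limit the sedimentation boundary sits at
#' `r = r_m exp(s w^2 t)`; used as an analytic oracle for the solver.
#'
#' @param s Sedimentation coefficient, Svedberg.
#' @param rpm Rotor speed, rpm.
#' @param t Time since full speed, s.
#' @param meniscus Meniscus radius, cm.
#' @return Boundary radius, cm.
#' @export
faxen_boundary <- function(s, rpm, t, meniscus = 6.0) {
  stopifnot(all(s > 0), rpm > 0, all(t >= 0), meniscus > 0)
  meniscus * exp(s * 1e-13 * omega2(rpm) * t)
}

#' Sector mass integral of each scan
#'
#' `m(t) = integral c r dr`, the conserved quantity of sector transport until
#' material reaches the base.
#'
#' @param scans A `scan_set`.
#' @return Numeric vector, one value per scan.
#' @export
scan_mass <- function(scans) {
  dr <- diff(scans$radii[1:2])
  as.vector(scans$scans %*% (scans$radii * dr))
}

# --- ScanSet CSV dialect -----------------------------------------------------
# Header lines '#key=value' carrying the run metadata, then long-format rows
# scan_index,time_s,radius_cm,signal.

#' Write a scan set to the package CSV dialect
#'
#' Header lines `#key=value` (rpm, temp_C, meniscus_cm, base_cm, pathlength_cm,
#' detection, noise_sigma, seed) followed by a `scan_index,time_s,radius_cm,
#' signal` long-format table. [read_scanset()] round-trips losslessly.
#'
#' @param scans A `scan_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scanset <- function(scans, path) {
  hdr <- c(
    sprintf("#rpm=%.10g", scans$protocol$rpm),
    sprintf("#temp_C=%.10g", scans$protocol$temperature),
    sprintf("#meniscus_cm=%.10g", scans$geometry$meniscus),
    sprintf("#base_cm=%.10g", scans$geometry$base),
    sprintf("#pathlength_cm=%.10g", scans$geometry$pathlength),
    sprintf("#detection=%s", scans$protocol$detection),
    sprintf("#noise_sigma=%.10g", scans$noise_sigma),
    sprintf("#seed=%s", scans$seed)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("scan_index,time_s,radius_cm,signal", con)
  tb <- tidy.scan_set(scans)
  writeLines(sprintf("%d,%.10g,%.17g,%.17g",
                     tb$scan_index, tb$time_s, tb$radius_cm, tb$signal), con)
  invisible(path)
}

#' Read a scan set written by [write_scanset()]
#'
#' @param path File path.
#' @return A `scan_set`.
#' @export
read_scanset <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  kv <- strsplit(sub("^#", "", lines[is_hdr]), "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  body <- utils::read.csv(text = lines[!is_hdr])
  times <- sort(unique(body$time_s))
  radii <- sort(unique(body$radius_cm))
  scans <- matrix(NA_real_, length(times), length(radii))
  ti <- match(body$time_s, times)
  ri <- match(body$radius_cm, radii)
  scans[cbind(ti, ri)] <- body$signal
  geometry <- cell_geometry(as.numeric(meta[["meniscus_cm"]]),
                            as.numeric(meta[["base_cm"]]),
                            as.numeric(meta[["pathlength_cm"]]))
  protocol <- rotor_protocol(as.numeric(meta[["rpm"]]),
                             as.numeric(meta[["temp_C"]]),
                             scan_times = times,
                             detection = meta[["detection"]])
  new_scan_set(radii, times, scans, geometry, protocol,
               noise_sigma = as.numeric(meta[["noise_sigma"]]),
               seed = suppressWarnings(as.integer(meta[["seed"]])))
}

#' Plot sedimentation boundaries
#'
#' @param object A `scan_set`.
#' @param every Plot every n-th scan (default 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_set <- function(object, every = 5, ...) {
  tb <- tidy.scan_set(object)
  keep <- unique(c(seq(1, length(object$times), by = every),
                   length(object$times)))
  tb <- dplyr::filter(tb, .data$scan_index %in% keep)
  ggplot2::ggplot(tb, ggplot2::aes(.data$radius_cm, .data$signal,
                                   group = .data$scan_index,
                                   colour = .data$time_s)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "radius (cm)", y = "signal", colour = "time (s)")
}
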