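# Hydrodynamic and volumetric relations linking molar mass, partial specific
# volume, frictional ratio, sedimentation and diffusion coefficients, and
# hydrodynamic radius. User-facing units follow sedimentation practice:
# Svedberg (1 S = 1e-13 s) for s, nm for radii, g/mol for mass, cm3/g for
# vbar, cP for viscosity, g/cm3 for density. Internal arithmetic is SI.

#' Density and viscosity of pure water
#'
#' Empirical correlations for the density and dynamic viscosity of
#' air-saturated pure water at atmospheric pressure, valid between 0 and
#' 40 degrees Celsius. Density follows the Kell (1975) rational polynomial;
#' viscosity follows the Kestin-type correlation anchored at
#' 1.002 cP / 20 degrees Celsius that is standard in sedimentation analysis.
#'
#' @param temperature Temperature in degrees Celsius; vectorized. Must lie in
#'   \[0, 40\].
#' @return A tibble with columns `temperature` (degC), `density` (g/cm3) and
#'   `viscosity` (cP).
#' @examples
#' water_properties(20)
#' @export
water_properties <- function(temperature) {
  if (any(!is.finite(temperature)) || any(temperature < 0 | temperature > 40)) {
    stop("temperature must lie in [0, 40] degC", call. = FALSE)
  }
  t <- temperature
  rho <- (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 -
            46.170461e-6 * t^3 + 105.56302e-9 * t^4 -
            280.54253e-12 * t^5) / (1 + 16.879850e-3 * t) / 1000
  eta <- 1.002 * 10^((20 - t) * (1.2364 - 1.37e-3 * (20 - t) +
                                   5.7e-6 * (20 - t)^2) / (t + 96))
  tibble::tibble(temperature = t, density = rho, viscosity = eta)
}

#' Solvent conditions for sedimentation and scattering work
#'
#' Bundles temperature, density and viscosity of the medium. When density or
#' viscosity are omitted they default to pure water at `temperature` via
#' [water_properties()]; dilute buffers (e.g. 10 mM phosphate) are treated as
#' water, matching common s20,w practice when no buffer correction is stated.
#'
#' @param temperature Temperature in degrees Celsius, in \[-5, 60\].
#' @param density Solvent density in g/cm3 (default: pure water).
#' @param viscosity Solvent viscosity in cP (default: pure water).
#' @param label Free-text description.
#' @return An object of class `solvent_conditions`.
#' @examples
#' solvent_conditions(20)
#' @export
solvent_conditions <- function(temperature = 20, density = NULL,
                               viscosity = NULL, label = NULL) {
  stopifnot(length(temperature) == 1, is.finite(temperature))
  if (temperature < -5 || temperature > 60) {
    stop("temperature must lie in [-5, 60] degC", call. = FALSE)
  }
  if (is.null(density) || is.null(viscosity)) {
    w <- water_properties(temperature)
    if (is.null(density)) density <- w$density
    if (is.null(viscosity)) viscosity <- w$viscosity
    if (is.null(label)) label <- sprintf("water %gC", temperature)
  }
  if (density <= 0 || viscosity <= 0) {
    stop("density and viscosity must be positive", call. = FALSE)
  }
  structure(
    list(temperature = temperature, density = density,
         viscosity = viscosity,
         label = if (is.null(label)) sprintf("solvent %gC", temperature) else label),
    class = "solvent_conditions"
  )
}

#' @export
print.solvent_conditions <- function(x, ...) {
  cat(sprintf("<solvent_conditions> %s: %.2f degC, rho = %.5f g/cm3, eta = %.4f cP\n",
              x$label, x$temperature, x$density, x$viscosity))
  invisible(x)
}

as_solvent <- function(x) {
  if (inherits(x, "solvent_conditions")) return(x)
  if (is.numeric(x) && length(x) == 1) return(solvent_conditions(x))
  stop("expected a solvent_conditions object or a temperature", call. = FALSE)
}

# Consensus amino-acid residue partial specific volumes (cm3/g, 25 degC),
# Cohn-Edsall apparent volumes as used by sedimentation-analysis tools,
# with average residue masses (Da, residue = amino acid - H2O).
.residue_vbar <- c(A = 0.74, R = 0.70, N = 0.62, D = 0.60, C = 0.63,
                   Q = 0.67, E = 0.66, G = 0.64, H = 0.67, I = 0.90,
                   L = 0.90, K = 0.82, M = 0.75, F = 0.77, P = 0.76,
                   S = 0.63, T = 0.70, W = 0.74, Y = 0.71, V = 0.86)
.residue_mass <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                   C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
                   H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                   M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                   T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

#' Partial specific volume from an amino-acid sequence
#'
#' Mass-weighted mean of Cohn-Edsall residue partial specific volumes at
#' 25 degrees Celsius, adjusted linearly to the requested temperature with
#' the conventional slope of 4.25e-4 cm3/(g K) (see [vbar_temp_adjust()]).
#'
#' @param sequence One-letter amino-acid string(s); standard 20 residues only.
#' @param temperature Target temperature in degrees Celsius, in \[0, 40\].
#' @return Partial specific volume(s) in cm3/g.
#' @examples
#' vbar_sequence("GGGG", 25) # glycine consensus, 0.64
#' @export
vbar_sequence <- function(sequence, temperature = 25) {
  stopifnot(is.character(sequence), length(sequence) >= 1)
  vapply(sequence, function(s) {
    if (!nzchar(s)) stop("sequence must be non-empty", call. = FALSE)
    aa <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(unique(aa), names(.residue_vbar))
    if (length(bad)) {
      stop("unknown residue letter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    v25 <- sum(.residue_mass[aa] * .residue_vbar[aa]) / sum(.residue_mass[aa])
    vbar_temp_adjust(v25, 25, temperature)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Temperature adjustment of a partial specific volume
#'
#' Linear correction `vbar(t) = vbar(t_ref) + 4.25e-4 * (t - t_ref)` with the
#' slope in cm3/(g K) that reproduces the conventional protein pair
#' 0.7316 cm3/g at 20 degC -> 0.7295 cm3/g at 15 degC.
#'
#' @param vbar_ref Reference partial specific volume, cm3/g.
#' @param t_ref,t Reference and target temperatures, degC, each in \[0, 40\].
#' @return Adjusted partial specific volume, cm3/g.
#' @export
vbar_temp_adjust <- function(vbar_ref, t_ref, t) {
  if (any(c(t_ref, t) < 0) || any(c(t_ref, t) > 40)) {
    stop("temperatures must lie in [0, 40] degC", call. = FALSE)
  }
  vbar_ref + 4.25e-4 * (t - t_ref)
}

#' Anhydrous sphere (Stokes) radius
#'
#' Radius of the compact sphere with the molecule's anhydrous volume,
#' `R0 = (3 M vbar / (4 pi N_A))^(1/3)`.
#'
#' @param mass Molar mass, g/mol.
#' @param vbar Partial specific volume, cm3/g.
#' @return Radius in nm.
#' @examples
#' stokes_radius_sphere(27084, 0.73) # about 1.99 nm
#' @export
stokes_radius_sphere <- function(mass, vbar) {
  stopifnot(all(mass > 0), all(vbar > 0))
  # volume per molecule in cm3; 1 cm = 1e7 nm
  (3 * mass * vbar / (4 * pi * .const$N_A))^(1 / 3) * 1e7
}

buoyancy <- function(vbar, density) {
  b <- 1 - vbar * density
  if (any(b <= 0)) {
    stop("1 - vbar*rho <= 0: species floats in this solvent", call. = FALSE)
  }
  b
}

#' Sedimentation coefficient from mass, vbar and frictional ratio
#'
#' Svedberg/Stokes relation
#' `s = M (1 - vbar rho) / (N_A 6 pi eta (f/f0) R0)` with `R0` the anhydrous
#' sphere radius of [stokes_radius_sphere()].
#'
#' @param mass Molar mass, g/mol.
#' @param vbar Partial specific volume, cm3/g.
#' @param f_ratio Frictional ratio f/f0, >= 1.
#' @param solvent A [solvent_conditions()] object (or temperature for water).
#' @return Sedimentation coefficient in Svedberg (1 S = 1e-13 s).
#' @examples
#' svedberg_s(27084, 0.73, 1.27, solvent_conditions(20)) # 2.56 S
#' @export
svedberg_s <- function(mass, vbar, f_ratio, solvent = solvent_conditions(20)) {
  sol <- as_solvent(solvent)
  stopifnot(all(f_ratio >= 1))
  b <- buoyancy(vbar, sol$density)
  r0 <- stokes_radius_sphere(mass, vbar) * 1e-9        # m
  eta <- sol$viscosity * 1e-3                          # Pa s
  s_si <- (mass / 1000) * b / (.const$N_A * 6 * pi * eta * f_ratio * r0)
  s_si * 1e13
}

#' Hydrodynamic radius from a sedimentation coefficient
#'
#' `Rh = M (1 - vbar rho) / (N_A 6 pi eta s)`.
#'
#' @inheritParams svedberg_s
#' @param s Sedimentation coefficient, Svedberg.
#' @return Hydrodynamic radius in nm.
#' @export
rh_from_s <- function(mass, vbar, s, solvent = solvent_conditions(20)) {
  sol <- as_solvent(solvent)
  stopifnot(all(s > 0))
  b <- buoyancy(vbar, sol$density)
  eta <- sol$viscosity * 1e-3
  (mass / 1000) * b / (.const$N_A * 6 * pi * eta * s * 1e-13) * 1e9
}

#' Diffusion coefficient tied to a sedimentation coefficient
#'
#' Standard c(s)-style hydrodynamic scaling: the molar mass implied by
#' `(s, f_ratio, vbar)` is back-computed from the Svedberg/Stokes relation and
#' the translational diffusion coefficient follows from the Svedberg identity
#' `s/D = M (1 - vbar rho) / (R T)`, so every returned pair satisfies that
#' identity by construction. Equivalent to the closed form
#' `D = (kT sqrt(2) / 18 pi) (eta f/f0)^(-3/2) ((1 - vbar rho)/(s vbar))^(1/2)`.
#'
#' @param s Sedimentation coefficient, Svedberg (> 0).
#' @param f_ratio Frictional ratio, >= 1.
#' @param vbar Partial specific volume, cm3/g.
#' @param solvent A [solvent_conditions()] object.
#' @return Diffusion coefficient in m2/s.
#' @export
diffusion_from_s <- function(s, f_ratio, vbar,
                             solvent = solvent_conditions(20)) {
  sol <- as_solvent(solvent)
  stopifnot(all(s > 0), all(f_ratio > 0))
  b <- buoyancy(vbar, sol$density)
  Tk <- sol$temperature + 273.15
  kT <- .const$k_B * Tk
  eta <- sol$viscosity * 1e-3
  vbar_si <- vbar * 1e-3                               # m3/kg
  kT * sqrt(2) / (18 * pi) / (eta * f_ratio)^1.5 *
    sqrt(b / (s * 1e-13 * vbar_si))
}

#' Effective frictional ratio implied by an (s, D) pair
#'
#' Inverts the diffusion-sedimentation tie of [diffusion_from_s()] for the
#' frictional ratio. Values below 1 can occur as effective basis parameters
#' for species (such as free dye) whose supplied diffusion coefficient lies
#' off the physical f/f0 >= 1 manifold.
#'
#' @inheritParams diffusion_from_s
#' @param D Diffusion coefficient, m2/s.
#' @return Effective f/f0 (dimensionless, > 0).
#' @export
f_ratio_from_sD <- function(s, D, vbar, solvent = solvent_conditions(20)) {
  sol <- as_solvent(solvent)
  stopifnot(all(s > 0), all(D > 0))
  b <- buoyancy(vbar, sol$density)
  Tk <- sol$temperature + 273.15
  kT <- .const$k_B * Tk
  eta <- sol$viscosity * 1e-3
  vbar_si <- vbar * 1e-3
  (kT * sqrt(2) / (18 * pi) * sqrt(b / (s * 1e-13 * vbar_si)) / D)^(2 / 3) / eta
}

#' Molar mass implied by (s, f_ratio, vbar)
#'
#' Inverse of [svedberg_s()] in the mass argument; used to tie diffusion to
#' sedimentation on a c(s) grid.
#'
#' @inheritParams diffusion_from_s
#' @return Molar mass in g/mol.
#' @export
mass_from_s <- function(s, f_ratio, vbar, solvent = solvent_conditions(20)) {
  sol <- as_solvent(solvent)
  b <- buoyancy(vbar, sol$density)
  eta <- sol$viscosity * 1e-3
  # s = M^{2/3} b / (N_A 6 pi eta f (3 vbar/(4 pi N_A))^{1/3}) in SI mass kg/mol
  k <- .const$N_A * 6 * pi * eta * f_ratio *
    (3 * vbar * 1e-3 / (4 * pi * .const$N_A))^(1 / 3)
  ((s * 1e-13) * k / b)^(3 / 2) * 1000
}

#' Normalize an observed s-value to 20 degC water (s20,w)
#'
#' `s20w = s_obs (eta_obs / eta_20w) ((1 - vbar rho)_20w / (1 - vbar rho)_obs)`
#' with the same vbar in both buoyancy terms (the conventional correction;
#' adjust vbar beforehand with [vbar_temp_adjust()] if a temperature-corrected
#' value is wanted).
#'
#' @param s_obs Observed sedimentation coefficient(s), Svedberg.
#' @param vbar Partial specific volume, cm3/g.
#' @param solvent_obs Conditions of the observation.
#' @return s20,w in Svedberg.
#' @export
s20w <- function(s_obs, vbar, solvent_obs = solvent_conditions(20)) {
  sol <- as_solvent(solvent_obs)
  w20 <- water_properties(20)
  b_obs <- buoyancy(vbar, sol$density)
  b_20 <- buoyancy(vbar, w20$density)
  s_obs * (sol$viscosity / w20$viscosity) * (b_20 / b_obs)
}

#' Relative centrifugal force
#'
#' `rcf = (2 pi rpm / 60)^2 r / g` (dimensionless multiples of standard
#' gravity), with `r` supplied in cm.
#'
#' @param rpm Rotor speed, revolutions per minute.
#' @param radius Radius, cm.
#' @return Relative centrifugal force (x g).
#' @examples
#' rcf(50000, 7.2)
#' @export
rcf <- function(rpm, radius) {
  stopifnot(all(rpm > 0), all(radius > 0))
  (2 * pi * rpm / 60)^2 * (radius / 100) / .const$g0
}

#' All derived hydrodynamic quantities for a species
#'
#' One-stop record for a species defined by mass, vbar and frictional ratio:
#' anhydrous radius, sedimentation and diffusion coefficients, hydrodynamic
#' radius, and s20,w.
#'
#' @inheritParams svedberg_s
#' @return A one-row tibble with columns `mass`, `vbar`, `f_ratio`, `r0_nm`,
#'   `s_S`, `s20w_S`, `d_m2s`, `rh_nm`.
#' @examples
#' hydro_species(27084, 0.73, 1.27)
#' @export
hydro_species <- function(mass, vbar, f_ratio,
                          solvent = solvent_conditions(20)) {
  sol <- as_solvent(solvent)
  s <- svedberg_s(mass, vbar, f_ratio, sol)
  tibble::tibble(
    mass = mass, vbar = vbar, f_ratio = f_ratio,
    r0_nm = stokes_radius_sphere(mass, vbar),
    s_S = s,
    s20w_S = s20w(s, vbar, sol),
    d_m2s = diffusion_from_s(s, f_ratio, vbar, sol),
    rh_nm = rh_from_s(mass, vbar, s, sol)
  )
}
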