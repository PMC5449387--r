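# Coarse-grained oligomer conformers (one bead per residue) and their
# structural/hydrodynamic properties: radius of gyration, Kirkwood bead-model
# friction and sedimentation coefficients, voxelized union-of-spheres volume,
# Kabsch RMSD, GROMOS-style (Daura) clustering and ensemble summaries. These
# calculations stand in for rigid-body hydrodynamics post-processing of MD
# snapshot ensembles.

AB42_MONOMER_MASS <- 4514.1  # Da, average mass of the 42-residue isoform

new_conformer <- function(coords, bead_radius, bead_mass, n_monomers,
                          residues_per_monomer) {
  stopifnot(is.matrix(coords), ncol(coords) == 3,
            nrow(coords) == n_monomers * residues_per_monomer)
  structure(list(coords = coords, bead_radius = bead_radius,
                 bead_mass = bead_mass, n_monomers = n_monomers,
                 residues_per_monomer = residues_per_monomer),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %d-mer, %d beads (r = %.2f nm), M = %.0f Da, Rg = %.2f nm\n",
              x$n_monomers, nrow(x$coords), x$bead_radius,
              conformer_mass(x), radius_of_gyration(x)))
  invisible(x)
}

conformer_mass <- function(conformer) {
  nrow(conformer$coords) * conformer$bead_mass
}

coords_of <- function(x) {
  if (inherits(x, "conformer")) x$coords else as.matrix(x)
}

# Grow one collapsed self-avoiding bead chain: fixed bond length, biased
# toward the local centroid, rejecting placements closer than min_sep to any
# non-bonded bead or outside the confinement radius.
grow_chain <- function(n_beads, bond = 0.38, min_sep = 0.35, r_conf = NULL) {
  if (is.null(r_conf)) r_conf <- max(0.9, 0.42 * n_beads^(1 / 3) * 1.7)
  xyz <- matrix(0, n_beads, 3)
  for (i in 2:n_beads) {
    ok <- FALSE
    for (try in 1:400) {
      u <- rnorm(3)
      # bias inward once the walk leaves the confinement sphere
      cen <- colMeans(xyz[1:(i - 1), , drop = FALSE])
      pull <- cen - xyz[i - 1, ]
      npull <- sqrt(sum(pull^2))
      if (npull > 0) u <- u + 1.2 * pull / max(npull, 1) * (npull / r_conf)
      u <- u / sqrt(sum(u^2))
      cand <- xyz[i - 1, ] + bond * u
      if (sqrt(sum((cand - cen)^2)) > r_conf) next
      if (i > 2) {
        d2 <- rowSums((xyz[1:(i - 2), , drop = FALSE] -
                         matrix(cand, i - 2, 3, byrow = TRUE))^2)
        if (min(d2) < min_sep^2) next
      }
      xyz[i, ] <- cand
      ok <- TRUE
      break
    }
    if (!ok) {            # backtrack one bead and retry
      i <- max(i - 1, 2)
      xyz[i, ] <- xyz[i - 1, ] + bond * c(1, 0, 0)
    }
  }
  xyz
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(m)
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a synthetic compact oligomer conformer
#'
#' Builds each monomer as a collapsed self-avoiding bead chain (one bead per
#' residue, bond length 0.38 nm), packs the monomers into a globule with
#' random orientations, and, when `target_rg` is given, radially rescales the
#' assembly about its center of mass until the realized radius of gyration is
#' within 5% of the target. Scaling stops (with an error naming the feasible
#' range) if it would push any bead pair closer than a quarter of the bead
#' diameter. These conformers emulate compact MD-snapshot oligomers; they
#' carry no secondary structure or energetics.
#'
#' @param n_monomers Oligomer order (>= 1).
#' @param residues_per_monomer Beads per chain (default 42).
#' @param target_rg Optional target radius of gyration, nm. `NULL` keeps the
#'   as-packed structure (and exact 0.38 nm bonds).
#' @param bead_radius Hydrodynamic bead radius, nm (default 0.51, the
#'   residue-shell convention of rigid-body bead hydrodynamics).
#' @param monomer_mass Monomer mass, Da (default 4514.1, the 42-residue
#'   amyloid-beta isoform).
#' @param seed Integer seed; same seed, same coordinates.
#' @return A `conformer`.
#' @export
generate_oligomer <- function(n_monomers, residues_per_monomer = 42,
                              target_rg = NULL, bead_radius = 0.51,
                              monomer_mass = AB42_MONOMER_MASS, seed = 1L) {
  stopifnot(n_monomers >= 1, residues_per_monomer >= 2)
  # packing is stochastic; retry with derived seeds if a compaction target
  # is narrowly infeasible for a particular packing draw
  for (attempt in 0:7) {
    conf <- try(generate_oligomer_once(
      n_monomers, residues_per_monomer, target_rg, bead_radius,
      monomer_mass, seed + 7919L * attempt), silent = TRUE)
    if (!inherits(conf, "try-error")) return(conf)
  }
  stop(attr(conf, "condition")$message, call. = FALSE)
}

generate_oligomer_once <- function(n_monomers, residues_per_monomer,
                                   target_rg, bead_radius, monomer_mass,
                                   seed) {
  coords <- with_seed(seed, {
    chains <- lapply(seq_len(n_monomers), function(k) {
      ch <- grow_chain(residues_per_monomer)
      ch <- sweep(ch, 2, colMeans(ch))
      ch %*% random_rotation()
    })
    chain_r <- max(vapply(chains, function(ch) {
      sqrt(max(rowSums(sweep(ch, 2, colMeans(ch))^2)))
    }, numeric(1)))
    if (n_monomers == 1) {
      chains[[1]]
    } else {
      # centers on a sphere (plus center for order >= 5 packing balance)
      dirs <- matrix(rnorm(3 * n_monomers), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      rad <- chain_r * 0.95
      placed <- NULL
      for (k in seq_len(n_monomers)) {
        best <- NULL; best_d <- -Inf
        for (try in 1:60) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          cand <- sweep(chains[[k]], 2, -rad * u)   # shift by +rad*u
          d <- if (is.null(placed)) Inf else {
            min(pracma::distmat(cand, placed))
          }
          if (d > best_d) { best_d <- d; best <- cand }
          if (d > 0.36) break
        }
        placed <- rbind(placed, best)
      }
      placed
    }
  })
  coords <- sweep(coords, 2, colMeans(coords))
  conf <- new_conformer(coords, bead_radius, monomer_mass / residues_per_monomer,
                        n_monomers, residues_per_monomer)
  if (!is.null(target_rg)) {
    rg0 <- radius_of_gyration(conf)
    k <- target_rg / rg0
    min_d <- min(stats::dist(coords))
    floor_d <- 0.25 * 2 * bead_radius
    k_min <- floor_d / min_d
    if (k < k_min) {
      stop(sprintf(
        "target Rg %.2f nm infeasible for this bead count; feasible range >= %.2f nm",
        target_rg, k_min * rg0), call. = FALSE)
    }
    conf$coords <- coords * k
  }
  conf
}

#' Radius of gyration of a conformer
#'
#' Mass-weighted root-mean-square bead distance from the center of mass
#' (all beads share one mass here, so the plain rms distance).
#'
#' @param conformer A `conformer` or an n x 3 coordinate matrix (nm).
#' @return Radius of gyration, nm.
#' @export
radius_of_gyration <- function(conformer) {
  xyz <- coords_of(conformer)
  stopifnot(nrow(xyz) >= 1)
  cen <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, cen)^2)))
}

#' Kirkwood bead-model translational friction
#'
#' Orientationally preaveraged Kirkwood approximation for N equal beads of
#' radius sigma:
#' `D_t = (kT / (N 6 pi eta sigma)) (1 + (sigma/N) sum_(i != j) 1/R_ij)`,
#' `f = kT / D_t`. Exact for a single bead (Stokes) and for the touching
#' two-bead dumbbell (`f = 4/3 * 6 pi eta sigma`); accurate to a few percent
#' for compact rigid clusters, which is the regime used here. Bead overlaps
#' beyond a quarter of the bead diameter trigger a warning because the
#' approximation degrades.
#'
#' @param conformer A `conformer`.
#' @param solvent A [solvent_conditions()].
#' @return A list with `f` (kg/s) and `D_t` (m2/s).
#' @export
kirkwood_friction <- function(conformer, solvent = solvent_conditions(20)) {
  sol <- as_solvent(solvent)
  xyz <- coords_of(conformer)
  sigma <- conformer$bead_radius
  stopifnot(sigma > 0)
  n <- nrow(xyz)
  eta <- sol$viscosity * 1e-3
  kT <- .const$k_B * (sol$temperature + 273.15)
  f1 <- 6 * pi * eta * sigma * 1e-9            # single-bead Stokes friction
  if (n == 1) return(list(f = f1, D_t = kT / f1))
  dij <- stats::dist(xyz)
  if (min(dij) < 0.25 * 2 * sigma) {
    warning("bead overlap beyond the soft limit; Kirkwood approximation degrades")
  }
  inv_sum <- 2 * sum(1 / dij)                  # sum over ordered pairs
  D <- kT / (n * f1) * (1 + sigma / n * inv_sum)
  list(f = kT / D, D_t = D)
}

#' Voxelized union-of-spheres volume
#'
#' Counts voxels whose centers fall inside any bead sphere.
#'
#' @param conformer A `conformer`.
#' @param voxel Voxel edge, nm; must be at most half the bead radius.
#' @return Volume in nm3.
#' @export
grid_volume <- function(conformer, voxel = 0.1) {
  xyz <- coords_of(conformer)
  r <- conformer$bead_radius
  if (voxel > r / 2) stop("voxel must be <= bead_radius / 2", call. = FALSE)
  lo <- apply(xyz, 2, min) - r - voxel
  hi <- apply(xyz, 2, max) + r + voxel
  nx <- ceiling((hi - lo) / voxel)
  occupied <- new.env(hash = TRUE)
  m <- ceiling(r / voxel)
  off <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  off <- as.matrix(off[rowSums(off^2) <= ((r / voxel) + 1)^2, ])
  count <- 0L
  seen <- array(FALSE, dim = nx + 1)
  for (b in seq_len(nrow(xyz))) {
    ctr <- round((xyz[b, ] - lo) / voxel)
    cand <- sweep(off, 2, ctr, `+`)
    keep <- cand[, 1] >= 0 & cand[, 2] >= 0 & cand[, 3] >= 0 &
      cand[, 1] <= nx[1] & cand[, 2] <= nx[2] & cand[, 3] <= nx[3]
    cand <- cand[keep, , drop = FALSE]
    cc <- sweep(cand, 2, 0) * voxel + matrix(lo, nrow(cand), 3, byrow = TRUE)
    inside <- rowSums((cc - matrix(xyz[b, ], nrow(cand), 3, byrow = TRUE))^2) <= r^2
    cand <- cand[inside, , drop = FALSE] + 1
    idx <- cbind(cand[, 1], cand[, 2], cand[, 3])
    new <- !seen[idx]
    count <- count + sum(new)
    seen[idx] <- TRUE
  }
  count * voxel^3
}

#' Partial specific volume estimate from a grid volume
#'
#' `vbar = V N_A / M` with `V` the protein volume and `M` the molecular
#' weight (volume-over-mass convention of grid-volume tools).
#'
#' @param volume Volume, nm3.
#' @param mass Molar mass, g/mol.
#' @return vbar in cm3/g.
#' @export
vbar_estimate <- function(volume, mass) {
  stopifnot(volume > 0, mass > 0)
  volume * 1e-21 * .const$N_A / mass
}

#' Hydrodynamic summary of one conformer
#'
#' Sedimentation coefficient via the Svedberg relation with the Kirkwood
#' bead friction, `s = M (1 - vbar rho) / (N_A f)`, plus diffusion
#' coefficient, hydrodynamic radius `Rh = f / (6 pi eta)`, radius of
#' gyration, grid volume and the volume-based vbar estimate.
#'
#' @param conformer A `conformer`.
#' @param vbar Partial specific volume used for buoyancy, cm3/g.
#' @param solvent A [solvent_conditions()].
#' @param voxel Voxel edge for the volume estimate, nm (`NA` skips it).
#' @return A one-row tibble: `n_monomers`, `mass`, `s_S`, `d_m2s`, `rg_nm`,
#'   `rh_nm`, `volume_nm3`, `vbar_est`.
#' @export
conformer_s <- function(conformer, vbar = 0.73,
                        solvent = solvent_conditions(20), voxel = 0.1) {
  sol <- as_solvent(solvent)
  M <- conformer_mass(conformer)
  b <- buoyancy(vbar, sol$density)
  kf <- kirkwood_friction(conformer, sol)
  eta <- sol$viscosity * 1e-3
  s_si <- (M / 1000) * b / (.const$N_A * kf$f)
  vol <- if (is.na(voxel)) NA_real_ else grid_volume(conformer, voxel)
  tibble::tibble(
    n_monomers = conformer$n_monomers, mass = M,
    s_S = s_si * 1e13, d_m2s = kf$D_t,
    rg_nm = radius_of_gyration(conformer),
    rh_nm = kf$f / (6 * pi * eta) * 1e9,
    volume_nm3 = vol,
    vbar_est = if (is.na(vol)) NA_real_ else vbar_estimate(vol, M)
  )
}

#' Least-squares RMSD after optimal rigid superposition
#'
#' Kabsch algorithm: translations removed, optimal proper rotation from the
#' SVD of the covariance matrix.
#'
#' @param conf_a,conf_b Conformers (or coordinate matrices) with equal bead
#'   counts.
#' @return RMSD in nm.
#' @export
rmsd_superposed <- function(conf_a, conf_b) {
  A <- coords_of(conf_a); B <- coords_of(conf_b)
  if (nrow(A) != nrow(B)) stop("bead counts differ", call. = FALSE)
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(mean(rowSums((A %*% t(R) - B)^2)))
}

#' Build an ensemble of conformers of one oligomer order
#'
#' Generates `n` independent conformers at per-conformer targets
#' `target_rg * (1 + N(0, jitter))`, emulating the conformational spread of
#' an MD snapshot ensemble.
#'
#' @param n Number of conformers.
#' @param n_monomers Oligomer order.
#' @param target_rg Mean target radius of gyration, nm.
#' @param jitter Relative spread of the per-conformer target (default
#'   0.025, giving s-distribution widths of roughly +/- 0.07 S for compact
#'   penta/hexamers).
#' @param seed Integer seed.
#' @inheritParams generate_oligomer
#' @return An object of class `ensemble` (list of conformers with provenance
#'   attributes).
#' @export
generate_ensemble <- function(n, n_monomers, target_rg,
                              residues_per_monomer = 42, jitter = 0.025,
                              bead_radius = 0.51,
                              monomer_mass = AB42_MONOMER_MASS, seed = 1L) {
  stopifnot(n >= 1)
  targets <- with_seed(seed, target_rg * (1 + rnorm(n, 0, jitter)))
  confs <- lapply(seq_len(n), function(i) {
    generate_oligomer(n_monomers, residues_per_monomer,
                      target_rg = targets[i], bead_radius = bead_radius,
                      monomer_mass = monomer_mass,
                      seed = seed * 1000L + i)
  })
  structure(confs, class = "ensemble", n_monomers = n_monomers,
            target_rg = target_rg, jitter = jitter, seed = seed)
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d conformers of order %d (target Rg %.2f nm)\n",
              length(x), attr(x, "n_monomers"), attr(x, "target_rg")))
  invisible(x)
}

#' GROMOS-style (Daura) neighbor-count clustering
#'
#' Iteratively: count neighbors within the RMSD cutoff for every remaining
#' structure, declare the one with the most neighbors (ties: lowest index) a
#' cluster center, remove the cluster, repeat.
#'
#' @param ensemble An `ensemble` or list of conformers.
#' @param cutoff RMSD cutoff, nm (default 0.2).
#' @return A tibble with columns `conformer`, `cluster`, `is_center`.
#' @export
daura_cluster <- function(ensemble, cutoff = 0.2) {
  n <- length(ensemble)
  stopifnot(n >= 1)
  rmsd <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      rmsd[i, j] <- rmsd[j, i] <- rmsd_superposed(ensemble[[i]], ensemble[[j]])
    }
  }
  assigned <- rep(NA_integer_, n)
  center <- rep(FALSE, n)
  cl <- 0L
  while (anyNA(assigned)) {
    cl <- cl + 1L
    left <- which(is.na(assigned))
    counts <- vapply(left, function(i) {
      sum(rmsd[i, left] <= cutoff) - 1L
    }, integer(1))
    ctr <- left[which.max(counts)]        # which.max takes the lowest index
    members <- left[rmsd[ctr, left] <= cutoff]
    assigned[members] <- cl
    center[ctr] <- TRUE
  }
  tibble::tibble(conformer = seq_len(n), cluster = assigned,
                 is_center = center)
}

#' Hydrodynamic summary of an ensemble
#'
#' Per-conformer (or per-cluster-center) hydrodynamic results plus the
#' ensemble weight-average sedimentation coefficient (cluster centers are
#' weighted by cluster size).
#'
#' @param ensemble An `ensemble`.
#' @param vbar Partial specific volume, cm3/g.
#' @param solvent A [solvent_conditions()].
#' @param cluster Reduce to Daura cluster centers first.
#' @param cutoff Clustering cutoff, nm (used when `cluster = TRUE`).
#' @param voxel Voxel size for per-conformer volumes (`NA` skips volumes,
#'   the default, since they are slow and rarely needed in bulk).
#' @return A list with `table` (one row per evaluated conformer, including
#'   `weight`), `sw` (weight-average s, S), and `clusters` (when
#'   clustered).
#' @export
ensemble_summary <- function(ensemble, vbar = 0.73,
                             solvent = solvent_conditions(20),
                             cluster = FALSE, cutoff = 0.2, voxel = NA) {
  stopifnot(length(ensemble) >= 1)
  idx <- seq_along(ensemble)
  weights <- rep(1, length(ensemble))
  clusters <- NULL
  if (cluster) {
    clusters <- daura_cluster(ensemble, cutoff)
    idx <- clusters$conformer[clusters$is_center]
    weights <- as.vector(table(clusters$cluster)[
      as.character(clusters$cluster[clusters$is_center])])
  }
  tab <- purrr::map_dfr(seq_along(idx), function(k) {
    dplyr::mutate(
      conformer_s(ensemble[[idx[k]]], vbar, solvent, voxel = voxel),
      conformer = idx[k], weight = weights[k])
  })
  list(table = tab, sw = sum(tab$s_S * tab$weight) / sum(tab$weight),
       clusters = clusters)
}

# --- Conformer I/O -----------------------------------------------------------

#' Write / read conformers as C-alpha PDB or XYZ files
#'
#' PDB files carry one CA atom per bead and one chain per monomer
#' (coordinates converted nm -> Angstrom); XYZ files are plain
#' `n / comment / C x y z` blocks in nm. Both round-trip through the matching
#' reader. PDB I/O uses the \pkg{bio3d} reader/writer.
#'
#' @param conformer A `conformer`.
#' @param path File path.
#' @param residues_per_monomer Chain length used to split beads into
#'   monomers on read.
#' @param bead_radius,monomer_mass Metadata restored on read (not stored in
#'   the file formats).
#' @return Writers return `path` invisibly; readers return a `conformer`.
#' @export
write_conformer_pdb <- function(conformer, path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("bio3d is required for PDB output", call. = FALSE)
  }
  n <- nrow(conformer$coords)
  rpm <- conformer$residues_per_monomer
  chain <- LETTERS[rep(seq_len(conformer$n_monomers), each = rpm)]
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(conformer$coords * 10)),   # nm -> Angstrom
    type = rep("ATOM", n),
    resno = rep(seq_len(rpm), conformer$n_monomers),
    resid = rep("ALA", n), elety = rep("CA", n), chain = chain
  )
  invisible(path)
}

#' @rdname write_conformer_pdb
#' @export
read_conformer_pdb <- function(path, residues_per_monomer = 42,
                               bead_radius = 0.51,
                               monomer_mass = AB42_MONOMER_MASS) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("bio3d is required for PDB input", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path)
  ca <- pdb$atom[pdb$atom$elety == "CA", ]
  coords <- as.matrix(ca[, c("x", "y", "z")]) / 10   # Angstrom -> nm
  dimnames(coords) <- NULL
  n_mono <- nrow(coords) / residues_per_monomer
  stopifnot(n_mono == round(n_mono))
  new_conformer(coords, bead_radius, monomer_mass / residues_per_monomer,
                as.integer(n_mono), residues_per_monomer)
}

#' @rdname write_conformer_pdb
#' @export
write_conformer_xyz <- function(conformer, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(conformer$coords)), con)
  writeLines(sprintf("oligomer order=%d beads_per_monomer=%d units=nm",
                     conformer$n_monomers, conformer$residues_per_monomer), con)
  writeLines(sprintf("C %.8f %.8f %.8f", conformer$coords[, 1],
                     conformer$coords[, 2], conformer$coords[, 3]), con)
  invisible(path)
}

#' @rdname write_conformer_pdb
#' @export
read_conformer_xyz <- function(path, residues_per_monomer = 42,
                               bead_radius = 0.51,
                               monomer_mass = AB42_MONOMER_MASS) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  body <- utils::read.table(text = lines[3:(2 + n)],
                            col.names = c("el", "x", "y", "z"))
  coords <- as.matrix(body[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  n_mono <- n / residues_per_monomer
  stopifnot(n_mono == round(n_mono))
  new_conformer(coords, bead_radius, monomer_mass / residues_per_monomer,
                as.integer(n_mono), residues_per_monomer)
}
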