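# Conformer generation, structural measures, Kirkwood hydrodynamics,
# grid volumes, Kabsch RMSD and Daura clustering, each against closed-form
# or brute-force oracles.

stokes_f <- function(sigma_nm, solvent = water20) {
  6 * pi * solvent$viscosity * 1e-3 * sigma_nm * 1e-9
}

test_that("generated monomer chains have exact bonds and are reproducible", {
  cm <- generate_oligomer(1, 42, seed = 7)
  bl <- sqrt(rowSums(diff(cm$coords)^2))
  expect_equal(bl, rep(0.38, 41), tolerance = 1e-6 / 0.38)
  expect_identical(generate_oligomer(1, 42, seed = 7)$coords, cm$coords)
  # no two non-bonded beads closer than a quarter bead diameter
  expect_gt(min(dist(cm$coords)), 0.25 * 2 * cm$bead_radius)
})

test_that("compaction hits the target radius of gyration", {
  ch <- generate_oligomer(6, 42, target_rg = 2.3, seed = 11)
  expect_gte(radius_of_gyration(ch), 2.19)
  expect_lte(radius_of_gyration(ch), 2.42)
  expect_gt(min(dist(ch$coords)), 0.25 * 2 * ch$bead_radius)
  expect_error(generate_oligomer(6, 42, target_rg = 0.5, seed = 1),
               "infeasible")
})

test_that("radius of gyration matches elementary cases", {
  # two equal beads 2 nm apart
  two <- oligosizer:::new_conformer(rbind(c(0, 0, 0), c(2, 0, 0)),
                                    0.51, 100, 1, 2)
  expect_equal(radius_of_gyration(two), 1)
  # coincident beads
  same <- oligosizer:::new_conformer(matrix(0, 5, 3), 0.51, 100, 1, 5)
  expect_equal(radius_of_gyration(same), 0)
  # a uniform shell of radius R approaches Rg = R
  set.seed(1)
  u <- matrix(rnorm(3 * 4000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 5
  expect_equal(radius_of_gyration(u), 5, tolerance = 1e-3)
})

test_that("Kirkwood friction matches the Stokes, dumbbell and shell oracles", {
  single <- oligosizer:::new_conformer(matrix(0, 1, 3), 0.51, 100, 1, 1)
  kf <- kirkwood_friction(single, water20)
  expect_equal(kf$f, stokes_f(0.51), tolerance = 1e-12)
  # touching dumbbell: f = (4/3) 6 pi eta sigma exactly
  dumb <- oligosizer:::new_conformer(rbind(c(0, 0, 0), c(1.02, 0, 0)),
                                     0.51, 100, 1, 2)
  expect_equal(kirkwood_friction(dumb, water20)$f, 4 / 3 * stokes_f(0.51),
               tolerance = 1e-12)
  # dense spherical shell of radius R >> sigma approaches Stokes of R
  set.seed(2)
  u <- matrix(rnorm(3 * 400), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 10
  shell <- oligosizer:::new_conformer(u, 0.51, 10, 1, 400)
  f_shell <- suppressWarnings(kirkwood_friction(shell, water20)$f)
  expect_equal(f_shell, stokes_f(10), tolerance = 0.05)
})

test_that("Kirkwood friction is invariant under rigid motion and monotone under dilation", {
  conf <- generate_oligomer(2, 15, seed = 3)
  f0 <- kirkwood_friction(conf, water20)$f
  rot <- conf
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  rot$coords <- conf$coords %*% R + 3
  expect_equal(kirkwood_friction(rot, water20)$f, f0, tolerance = 1e-12)
  fs <- vapply(c(1, 1.5, 2.5), function(k) {
    big <- conf; big$coords <- conf$coords * k
    kirkwood_friction(big, water20)$f
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("grid volumes converge to known solids", {
  sph <- oligosizer:::new_conformer(matrix(0, 1, 3), 1.0, 100, 1, 1)
  expect_equal(grid_volume(sph, 0.1), 4 / 3 * pi, tolerance = 0.02)
  # two disjoint spheres add
  two <- oligosizer:::new_conformer(rbind(c(0, 0, 0), c(5, 0, 0)),
                                    1.0, 100, 1, 2)
  expect_equal(grid_volume(two, 0.1), 2 * grid_volume(sph, 0.1),
               tolerance = 0.01)
  # halving the voxel changes the volume by < 1 %
  conf <- generate_oligomer(1, 20, seed = 2)
  v1 <- grid_volume(conf, 0.12)
  v2 <- grid_volume(conf, 0.06)
  expect_lt(abs(v1 - v2) / v2, 0.01)
  expect_error(grid_volume(conf, 0.5), "voxel")
  # vbar estimate: volume N_A / M
  expect_equal(vbar_estimate(5.47, 4514), 0.7297, tolerance = 1e-3)
})

test_that("superposed RMSD is zero for rigid copies and exact for a stretch", {
  a <- generate_oligomer(1, 20, seed = 5)
  expect_equal(rmsd_superposed(a, a), 0, tolerance = 1e-12)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  b <- a
  b$coords <- a$coords %*% R + 7
  expect_lt(rmsd_superposed(a, b), 1e-9)
  # 3-bead stretch along the superposition axis: hand-computed value
  p <- rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0))
  q <- rbind(c(-2, 0, 0), c(0, 0, 0), c(2, 0, 0))
  expect_equal(rmsd_superposed(p, q), sqrt(2 / 3))
  expect_error(rmsd_superposed(p, q[1:2, ]), "counts")
})

test_that("Daura clustering matches the brute-force oracle", {
  ens <- generate_ensemble(12, 2, 1.3, residues_per_monomer = 10, seed = 3)
  # oracle: greedy neighbour counting over the explicit RMSD matrix
  n <- length(ens)
  rm <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    rm[i, j] <- rm[j, i] <- rmsd_superposed(ens[[i]], ens[[j]])
  }
  brute <- function(cutoff) {
    left <- 1:n; out <- rep(NA_integer_, n); cl <- 0L
    while (length(left)) {
      cl <- cl + 1L
      cnt <- vapply(left, function(i) sum(rm[i, left] <= cutoff), 0)
      ctr <- left[which.max(cnt)]
      mem <- left[rm[ctr, left] <= cutoff]
      out[mem] <- cl
      left <- setdiff(left, mem)
    }
    out
  }
  for (cutoff in c(0.2, 0.5, 0.9, 2)) {
    cl <- daura_cluster(ens, cutoff)
    expect_equal(cl$cluster, brute(cutoff))
    # centers are members of their clusters, every conformer assigned once
    expect_equal(sort(cl$conformer), 1:n)
    ctrs <- cl$cluster[cl$is_center]
    expect_equal(sort(unique(cl$cluster)), sort(ctrs))
  }
  # identical structures collapse into one cluster
  same <- structure(rep(list(ens[[1]]), 5), class = "ensemble")
  cls <- daura_cluster(same, 0.2)
  expect_equal(cls$cluster, rep(1L, 5))
  # far-apart structures are all singletons at a tiny cutoff
  cld <- daura_cluster(ens, 1e-6)
  expect_equal(length(unique(cld$cluster)), n)
})

test_that("conformer hydrodynamics are internally consistent", {
  conf <- generate_oligomer(6, 42, target_rg = 2.3, seed = 11)
  h <- conformer_s(conf, 0.73, water20, voxel = NA)
  # Svedberg relation closure with the hydrocore oracle
  expect_equal(rh_from_s(h$mass, 0.73, h$s_S, water20), h$rh_nm,
               tolerance = 1e-9)
  # calibration: compact hexamers near Rg 2.1-2.3 sediment in the 2.3-2.9 S range
  expect_gt(h$s_S, 2.3)
  expect_lt(h$s_S, 2.9)
  # linear scaling in the buoyancy factor at fixed geometry
  h2 <- conformer_s(conf, 0.8, water20, voxel = NA)
  b1 <- 1 - 0.73 * water20$density
  b2 <- 1 - 0.80 * water20$density
  expect_equal(h2$s_S / h$s_S, b2 / b1, tolerance = 1e-9)
  # typed sanity band: Rh at least sqrt(3/5) * 0.9 of Rg for compact shapes
  expect_gt(h$rh_nm, sqrt(3 / 5) * 0.9 * h$rg_nm)
})

test_that("ensemble summaries order oligomer sizes with bounded overlap", {
  sums <- lapply(c(4, 5, 6), function(ord) {
    ens <- generate_ensemble(12, ord, 2.3 * (ord / 6)^(1 / 3),
                             seed = 100 + ord)
    ensemble_summary(ens, 0.73, water20)
  })
  means <- vapply(sums, function(s) mean(s$table$s_S), 0)
  expect_true(all(diff(means) > 0))
  # adjacent distributions overlap by less than 0.3 S
  for (k in 1:2) {
    lo <- sums[[k]]$table$s_S
    hi <- sums[[k + 1]]$table$s_S
    expect_lt(max(lo) - min(hi), 0.3)
  }
  # equal weights: weight-average equals the mean
  expect_equal(sums[[1]]$sw, mean(sums[[1]]$table$s_S), tolerance = 1e-12)
  # singleton ensemble summarises to that conformer
  one <- structure(list(generate_oligomer(4, 42, target_rg = 2, seed = 2)),
                   class = "ensemble")
  s1 <- ensemble_summary(one, 0.73, water20)
  expect_equal(s1$sw, s1$table$s_S)
  # clustered summary weights centers by cluster size
  ens <- generate_ensemble(6, 2, 1.3, residues_per_monomer = 10, seed = 5)
  cs <- ensemble_summary(ens, 0.73, water20, cluster = TRUE, cutoff = 2)
  expect_equal(sum(cs$table$weight), 6)
})

test_that("conformers round-trip through PDB and XYZ", {
  skip_if_not_installed("bio3d")
  conf <- generate_oligomer(2, 10, seed = 4)
  pdb <- tempfile(fileext = ".pdb")
  xyz <- tempfile(fileext = ".xyz")
  write_conformer_pdb(conf, pdb)
  back <- read_conformer_pdb(pdb, residues_per_monomer = 10)
  expect_equal(back$coords, conf$coords, tolerance = 1e-3)  # PDB: 3 decimals in Angstrom
  expect_equal(back$n_monomers, 2)
  write_conformer_xyz(conf, xyz)
  backx <- read_conformer_xyz(xyz, residues_per_monomer = 10)
  expect_equal(backx$coords, conf$coords, tolerance = 1e-7)
  unlink(c(pdb, xyz))
})
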