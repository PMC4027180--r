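test_that("Kabsch superposition handles identity, translation and rotation", {
  set.seed(1)
  ref <- matrix(rnorm(15), ncol = 3)

  s0 <- kabsch(ref, ref)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-8)

  s1 <- kabsch(ref, sweep(ref, 2, c(5, -2, 9), "+"))
  expect_equal(s1$rmsd, 0, tolerance = 1e-10)

  rz90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  s2 <- kabsch(ref, ref %*% t(rz90))
  expect_equal(s2$rmsd, 0, tolerance = 1e-10)
  expect_equal(s2$rotation %*% rz90, diag(3), tolerance = 1e-8)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-10)

  collinear <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch(collinear + 0, collinear), "degenerate|collinear")
})

test_that("Kabsch matches the angle-optimization oracle on random sets", {
  set.seed(12)
  for (i in 1:20) {
    ref <- matrix(rnorm(15, sd = 3), ncol = 3)
    mov <- matrix(rnorm(15, sd = 3), ncol = 3)
    k <- kabsch(ref, mov)
    o <- oracle_superpose_rmsd(ref, mov)
    expect_lte(k$rmsd, o + 1e-6)          # kabsch is optimal
    expect_lt(abs(k$rmsd - o), 1e-3)      # and the oracle finds it too
  }
})

make_ensemble <- function(models) structure(list(models = models),
                                            class = "structure_ensemble")

toy_model <- function(n_res = 6, seed = 5) {
  set.seed(seed)
  data.frame(residue = rep(seq_len(n_res), each = 4),
             resname = "ALA",
             atom = rep(c("N", "CA", "C", "O"), n_res),
             x = rnorm(4 * n_res, sd = 4),
             y = rnorm(4 * n_res, sd = 4),
             z = rnorm(4 * n_res, sd = 4))
}

test_that("ensemble RMSD is zero for identical or rigidly moved models", {
  m <- toy_model()
  expect_equal(ensemble_rmsd(make_ensemble(list(m, m, m)))$rmsd_mean, 0,
               tolerance = 1e-9)

  set.seed(3)
  moved <- lapply(1:4, function(i) {
    r <- random_rotation()
    xyz <- as.matrix(m[, c("x", "y", "z")]) %*% t(r)
    m2 <- m
    m2[, c("x", "y", "z")] <- sweep(xyz, 2, rnorm(3, sd = 10), "+")
    m2
  })
  expect_equal(ensemble_rmsd(make_ensemble(moved))$rmsd_mean, 0,
               tolerance = 1e-8)
})

test_that("ensemble RMSD is invariant to per-model rigid transforms", {
  set.seed(8)
  base <- toy_model(n_res = 8, seed = 8)
  models <- lapply(1:5, function(i) {
    m <- base
    m[, c("x", "y", "z")] <- as.matrix(m[, c("x", "y", "z")]) +
      matrix(rnorm(nrow(m) * 3, sd = 0.4), ncol = 3)
    m
  })
  r0 <- ensemble_rmsd(make_ensemble(models))$rmsd_mean
  moved <- lapply(models, function(m) {
    r <- random_rotation()
    m[, c("x", "y", "z")] <- sweep(as.matrix(m[, c("x", "y", "z")]) %*% t(r),
                                   2, rnorm(3, sd = 20), "+")
    m
  })
  r1 <- ensemble_rmsd(make_ensemble(moved))$rmsd_mean
  expect_equal(r1, r0, tolerance = 1e-6)
  expect_gt(r0, 0.1)
})

test_that("residue range and atom set select the superposition subset", {
  base <- toy_model(n_res = 10, seed = 9)
  models <- lapply(1:3, function(i) {
    m <- base
    wob <- m$residue > 8   # disordered tail
    m[wob, c("x", "y", "z")] <- m[wob, c("x", "y", "z")] +
      matrix(rnorm(sum(wob) * 3, sd = 3), ncol = 3)
    m
  })
  ens <- make_ensemble(models)
  core <- ensemble_rmsd(ens, residues = 1:8)
  full <- ensemble_rmsd(ens)
  expect_lt(core$rmsd_mean, full$rmsd_mean)
  expect_equal(core$n_atoms, 8L * 4L)
})

test_that("multi-MODEL PDB files round trip through the ensemble reader", {
  m1 <- toy_model(n_res = 5, seed = 2)
  set.seed(21)
  m2 <- m1
  m2[, c("x", "y", "z")] <- m1[, c("x", "y", "z")] +
    matrix(rnorm(nrow(m1) * 3, sd = 0.3), ncol = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_models(list(m1, m2), path)
  ens <- read_ensemble(path)
  expect_length(ens$models, 2L)
  direct <- ensemble_rmsd(make_ensemble(list(m1, m2)))$rmsd_mean
  from_file <- ensemble_rmsd(ens)$rmsd_mean
  expect_equal(from_file, direct, tolerance = 1e-3)
})

test_that("backbone dihedrals reproduce constructed torsions", {
  helix <- build_backbone(6, phi = -57, psi = -47)
  for (r in 2:5) {
    d <- dihedrals(helix, r)
    expect_equal(d$phi, -57, tolerance = 0.5)
    expect_equal(d$psi, -47, tolerance = 0.5)
    expect_identical(d$region, "favored_like")
  }

  extended <- build_backbone(5, phi = 180, psi = 180)
  d2 <- dihedrals(extended, 3)
  expect_equal(abs(d2$psi), 180, tolerance = 0.5)

  expect_true(is.na(dihedrals(helix, 1)$phi))
  expect_true(is.na(dihedrals(helix, 6)$psi))
})

test_that("dihedral sign convention matches an established reference", {
  set.seed(77)
  for (i in 1:10) {
    pts <- matrix(rnorm(12, sd = 2), ncol = 3)
    model <- data.frame(residue = 1:2, resname = "ALA",
                        atom = c("C", "N"),
                        x = 0, y = 0, z = 0)  # placeholder, not used
    mine <- wingbind:::.dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    ref <- bio3d::torsion.xyz(as.numeric(t(pts)), atm.inc = 4)
    expect_equal(mine, as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("dihedrals are invariant to global rigid motion", {
  helix <- build_backbone(5, phi = -57, psi = -47)
  set.seed(31)
  r <- random_rotation()
  moved <- helix
  moved[, c("x", "y", "z")] <-
    sweep(as.matrix(helix[, c("x", "y", "z")]) %*% t(r), 2, c(3, -7, 2), "+")
  for (res in 2:4) {
    expect_equal(dihedrals(moved, res)$phi, dihedrals(helix, res)$phi,
                 tolerance = 1e-6)
    expect_equal(dihedrals(moved, res)$psi, dihedrals(helix, res)$psi,
                 tolerance = 1e-6)
  }
})
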