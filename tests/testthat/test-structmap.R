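test_that("structure reading handles PDB and mmCIF equivalently", {
  atoms <- toy_ca_atoms()
  pdb_f <- withr::local_tempfile(fileext = ".pdb")
  cif_f <- withr::local_tempfile(fileext = ".cif")
  write_toy_pdb(pdb_f, atoms)
  write_toy_cif(cif_f, atoms)

  m1 <- read_structure(pdb_f)
  expect_equal(sum(m1$atom$elety == "CA"), 3L)
  m2 <- read_structure(cif_f)
  expect_equal(unname(as.matrix(m1$atom[, c("x", "y", "z")])),
               unname(as.matrix(m2$atom[, c("x", "y", "z")])),
               tolerance = 1e-6)

  empty_f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    toy", "END"), empty_f)
  expect_error(read_structure(empty_f))
})

test_that("Kabsch superposition is exact on rigid motions, det +1 always", {
  set.seed(61)
  A <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch_superpose(A, A)
  expect_equal(fit0$rmsd, 0)

  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  B <- A %*% R + matrix(rep(c(5, -2, 3), each = 10), 10, 3)
  fit <- kabsch_superpose(A, B)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(B %*% fit$rotation + matrix(fit$translation, 10, 3,
                                           byrow = TRUE), A,
               tolerance = 1e-9)

  # rmsd is symmetric and invariant to joint rigid motion
  C <- A + matrix(rnorm(30, sd = 0.4), 10, 3)
  expect_equal(kabsch_superpose(A, C)$rmsd, kabsch_superpose(C, A)$rmsd,
               tolerance = 1e-12)
  A2 <- A %*% R; C2 <- C %*% R
  expect_equal(kabsch_superpose(A2, C2)$rmsd, kabsch_superpose(A, C)$rmsd,
               tolerance = 1e-9)

  # a reflected cloud cannot be superposed to zero (no improper transforms)
  refl <- diag(c(-1, 1, 1))
  expect_gt(kabsch_superpose(A, A %*% refl)$rmsd, 0.1)
  expect_equal(det(kabsch_superpose(A, A %*% refl)$rotation), 1,
               tolerance = 1e-9)

  expect_error(kabsch_superpose(A, A[1:5, ]), "differ in length")
})

test_that("Kabsch RMSD matches the quaternion-search oracle", {
  set.seed(62)
  for (r in 1:3) {
    A <- matrix(rnorm(30), 10, 3)
    B <- A + matrix(rnorm(30, sd = 0.5), 10, 3)
    got <- kabsch_superpose(A, B)$rmsd
    want <- oracle_kabsch_rmsd(A, B)
    expect_equal(got, want, tolerance = 1e-4)
    expect_lte(got, want + 1e-8)  # closed form can never be beaten
  }
})

test_that("NCS copy comparison reports per-domain RMSDs", {
  set.seed(63)
  n <- 12
  ca1 <- data.frame(elety = "CA", resid = "ALA", chain = "A", resno = 1:n,
                    x = cumsum(rnorm(n, 3.8, 0.2)), y = rnorm(n),
                    z = rnorm(n), b = 0)
  th <- 0.5
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz2 <- as.matrix(ca1[, c("x", "y", "z")]) %*% R
  ca2 <- ca1
  ca2$chain <- "B"
  ca2[, c("x", "y", "z")] <- xyz2
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f, rbind(ca1, ca2))
  model <- read_structure(f)
  ranges <- data.frame(domain = c("d1", "d2"), chain1 = "A",
                       start1 = c(1, 7), end1 = c(6, 12), chain2 = "B",
                       start2 = c(1, 7), end2 = c(6, 12))
  tab <- ncs_copy_rmsd(model, ranges)
  # PDB coordinates carry 3 decimals, so "identical" copies differ by ~1e-3
  expect_lt(max(tab$rmsd), 2e-3)
  expect_equal(tab$n_atoms, c(6L, 6L))

  # Gaussian perturbation of one copy: rmsd close to sigma * sqrt(3)
  sigma <- 1 / sqrt(3)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  reps <- replicate(30, {
    noisy <- ca2
    noisy[, c("x", "y", "z")] <- xyz2 + matrix(rnorm(3 * n, sd = sigma), n, 3)
    write_toy_pdb(f2, rbind(ca1, noisy))
    ncs_copy_rmsd(read_structure(f2), ranges)$rmsd
  })
  # the 6-parameter refit absorbs part of the noise (6 atoms/domain), so
  # the observed mean falls somewhat below the raw sqrt(3) * sigma scale
  expect_equal(mean(reps), sigma * sqrt(3), tolerance = 0.25)
  expect_gt(mean(reps), 0.5)
})

test_that("conservation-to-B-factor mapping touches only the B column", {
  atoms <- toy_ca_atoms()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f, atoms)
  model <- read_structure(f)
  out <- withr::local_tempfile(fileext = ".pdb")

  map_conservation_to_bfactor(model, "A", c("2" = 1.5), out)
  back <- read_structure(out)
  expect_equal(back$atom$b, c(0, 1.5, 0))
  expect_equal(unname(as.matrix(back$atom[, c("x", "y", "z")])),
               unname(as.matrix(model$atom[, c("x", "y", "z")])),
               tolerance = 1e-6)

  # empty table -> all zero
  map_conservation_to_bfactor(model, "A", stats::setNames(numeric(0),
                                                          character(0)), out)
  expect_true(all(read_structure(out)$atom$b == 0))

  expect_warning(
    map_conservation_to_bfactor(model, "A", c("99" = 1), out), "99")
})

test_that("backbone dihedrals reproduce ideal helix geometry", {
  atoms <- build_backbone(6, phi = -57, psi = -47)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f, atoms)
  model <- read_structure(f)
  tor <- backbone_dihedrals(model, "A", 1:6)
  expect_true(is.na(tor$phi[1]))   # no preceding C
  expect_true(is.na(tor$psi[6]))   # no following N
  expect_equal(tor$phi[2:6], rep(-57, 5), tolerance = 2 / 57)
  expect_equal(tor$psi[1:5], rep(-47, 5), tolerance = 2 / 47)

  # cross-check against bio3d's torsion machinery
  bt <- bio3d::torsion.pdb(model)
  expect_equal(unname(bt$phi[2:6]), tor$phi[2:6], tolerance = 1e-3)
  expect_equal(unname(bt$psi[1:5]), tor$psi[1:5], tolerance = 1e-3)
})

test_that("extended-linker arithmetic", {
  one <- linker_extension_estimate(3, 0.34, 1)
  expect_equal(one$per_linker_nm, 1.02)
  ten <- linker_extension_estimate(3, 0.34, 10)
  expect_equal(ten$total_nm, 10.2)
  expect_equal(linker_extension_estimate(0)$total_nm, 0)
})
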