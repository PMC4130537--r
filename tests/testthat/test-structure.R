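make_pair_atoms <- function(d, q1 = 1, q2 = -1, eps = 0, rmin_half = 1.7) {
  mk <- function(serial, x, q, chain, el)
    structure_model(data.frame(
      serial = serial, name = el, element = el, residue_name = "XXX",
      residue_seq = 1L, chain = chain, x = x, y = 0, z = 0,
      charge = q, epsilon = eps, rmin_half = rmin_half,
      stringsAsFactors = FALSE))
  list(a = mk(1L, 0, q1, "A", "O"), b = mk(2L, d, q2, "B", "N"))
}

test_that("PDB structure and trajectory round trips preserve coordinates", {
  tc <- generate_toy_complex(13, 7, 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tc$receptor, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), 7)
  expect_equal(somaticRS:::coords_of(back), somaticRS:::coords_of(tc$receptor),
               tolerance = 1e-3, ignore_attr = TRUE)  # PDB prints 3 decimals
  expect_equal(back$atoms$serial, tc$receptor$atoms$serial)
  expect_equal(back$atoms$residue_seq, tc$receptor$atoms$residue_seq)

  traj <- generate_toy_trajectory(tc$receptor, 4, 0.2, 13)
  tpath <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, tpath)
  tback <- read_trajectory(tpath)
  expect_equal(nrow(tback$xyz), 4)
  expect_equal(unname(tback$xyz), unname(traj$xyz), tolerance = 1e-3)
})

test_that("contact listing matches the brute-force oracle and its cutoff", {
  pair5 <- make_pair_atoms(5.0)
  expect_equal(nrow(vdw_contacts(pair5$a, pair5$b, 4.0)), 0)
  pair399 <- make_pair_atoms(3.999)
  expect_equal(nrow(vdw_contacts(pair399$a, pair399$b, 4.0)), 1)
  pair4 <- make_pair_atoms(4.0)
  expect_equal(nrow(vdw_contacts(pair4$a, pair4$b, 4.0)), 1)  # inclusive

  tc <- generate_toy_complex(50, 50, 50, list(type = "cloud", box = 15))
  got <- vdw_contacts(tc$receptor, tc$ligand, 4.0)
  dm <- oracle_pair_distances(tc$receptor$atoms, tc$ligand$atoms)
  expect_equal(nrow(got), sum(dm <= 4.0))
  expect_equal(sort(got$distance), sort(dm[dm <= 4.0]), tolerance = 1e-9)
  # monotone non-decreasing in the cutoff
  expect_gte(nrow(vdw_contacts(tc$receptor, tc$ligand, 6.0)), nrow(got))
  # hydrogens excluded by default, included on request
  h <- tc$ligand
  h$atoms$element <- "H"
  expect_error(vdw_contacts(tc$receptor, h, 4.0), "empty selection")
  expect_gt(nrow(vdw_contacts(tc$receptor, h, 4.0,
                              include_hydrogens = TRUE)), 0)
})

test_that("hydrogen bonds follow distance and angle criteria", {
  # donor N-H collinear with acceptor O at 2.9 A
  don <- structure_model(data.frame(
    serial = 1:2, name = c("N", "H"), element = c("N", "H"),
    residue_name = "GLY", residue_seq = 1L, chain = "A",
    x = c(0, 1.0), y = 0, z = 0, stringsAsFactors = FALSE))
  acc <- structure_model(data.frame(
    serial = 3L, name = "O", element = "O", residue_name = "SER",
    residue_seq = 2L, chain = "B", x = 2.9, y = 0, z = 0,
    stringsAsFactors = FALSE))
  hb <- hydrogen_bonds(don, acc)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9)
  expect_equal(hb$angle, 180, tolerance = 1e-6)
  expect_identical(attr(hb, "mode"), "angle_checked")

  # bent geometry below the angle threshold is rejected
  don_bent <- don
  don_bent$atoms$x[2] <- 0.3; don_bent$atoms$y[2] <- 0.95
  hb_bent <- hydrogen_bonds(don_bent, acc, angle_min = 150)
  expect_equal(nrow(hb_bent), 0)

  # beyond d_max: nothing
  far <- acc; far$atoms$x <- 4.2
  expect_equal(nrow(hydrogen_bonds(don, far)), 0)

  # fuzzed distance-only mode agrees with a brute-force oracle
  set.seed(8)
  nA <- 12; nB <- 9
  mkrand <- function(n, chain, offset) {
    nm <- sample(c("N", "O", "CA"), n, TRUE)
    structure_model(data.frame(
      serial = seq_len(n) + offset, name = nm, element = substr(nm, 1, 1),
      residue_name = "GLY", residue_seq = seq_len(n),
      chain = chain, x = runif(n, 0, 8), y = runif(n, 0, 8),
      z = runif(n, 0, 8), stringsAsFactors = FALSE))
  }
  A <- mkrand(nA, "A", 0); B <- mkrand(nB, "B", 100)
  hb2 <- hydrogen_bonds(A, B, d_max = 3.5)
  expect_identical(attr(hb2, "mode"), "distance_only")
  dm <- oracle_pair_distances(A$atoms, B$atoms)
  n_expected <- 0
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    if (dm[i, j] > 3.5) next
    ni <- A$atoms$name[i]; nj <- B$atoms$name[j]
    # backbone typing applied independently: N donates, O accepts
    if (ni == "N" && nj == "O") n_expected <- n_expected + 1
    if (nj == "N" && ni == "O") n_expected <- n_expected + 1
  }
  expect_equal(nrow(hb2), n_expected)
  # monotone in d_max
  expect_gte(nrow(hydrogen_bonds(A, B, d_max = 5)), nrow(hb2))
})

test_that("Coulomb term reproduces the closed form and the cutoff", {
  pr <- make_pair_atoms(3.320637)
  e <- interaction_energy(pr$a, pr$b)
  expect_equal(e$electrostatic, -100.0, tolerance = 0.01)
  expect_equal(e$total, e$vdw + e$electrostatic)

  far <- make_pair_atoms(14.5)
  efar <- interaction_energy(far$a, far$b)
  expect_equal(efar$total, 0)

  # doubling all charges quadruples the electrostatic term
  pr2 <- make_pair_atoms(3.320637, q1 = 2, q2 = -2)
  expect_equal(interaction_energy(pr2$a, pr2$b)$electrostatic,
               4 * e$electrostatic, tolerance = 1e-9)
  # dielectric scales it down
  expect_equal(interaction_energy(pr$a, pr$b, dielectric = 4)$electrostatic,
               e$electrostatic / 4, tolerance = 1e-9)
  # symmetry in the two selections
  expect_equal(interaction_energy(pr$b, pr$a)$total, e$total)
  expect_error(interaction_energy(make_pair_atoms(0.05)$a,
                                  make_pair_atoms(0.05)$b), "closer")
})

test_that("Lennard-Jones term hits its minimum at r = rmin_ij", {
  pr <- make_pair_atoms(3.4, q1 = 0, q2 = 0, eps = 0.12, rmin_half = 1.7)
  e <- interaction_energy(pr$a, pr$b)
  expect_equal(e$vdw, -0.12, tolerance = 1e-9)  # eps_ij = sqrt(.12*.12)
  expect_equal(e$electrostatic, 0)
  # displaced from the minimum the energy is higher
  prx <- make_pair_atoms(3.0, q1 = 0, q2 = 0, eps = 0.12, rmin_half = 1.7)
  expect_gt(interaction_energy(prx$a, prx$b)$vdw, -0.12)
})

test_that("missing nonbonded parameters are an explicit error", {
  tc <- generate_toy_complex(3, 4, 4)
  expect_error(interaction_energy(tc$receptor, tc$ligand), "epsilon")
  rec <- assign_nonbonded_params(tc$receptor)
  lig <- assign_nonbonded_params(tc$ligand)
  expect_silent(interaction_energy(rec, lig))
  # charges already on the model are kept by default
  expect_equal(rec$atoms$charge, tc$receptor$atoms$charge)
  bad <- tc$receptor
  bad$atoms$element <- "Xx"
  expect_error(assign_nonbonded_params(bad), "Xx")
})

test_that("per-residue energies conserve the whole-selection decomposition", {
  tc <- generate_toy_complex(17, 12, 6, list(type = "cloud", box = 8))
  rec <- assign_nonbonded_params(tc$receptor)
  lig <- assign_nonbonded_params(tc$ligand)
  whole <- interaction_energy(rec, lig)
  per <- per_residue_energy(rec, lig)
  expect_equal(sum(per$total), whole$total, tolerance = 1e-6)
  expect_equal(sum(per$vdw), whole$vdw, tolerance = 1e-6)
  expect_equal(sum(per$electrostatic), whole$electrostatic, tolerance = 1e-6)
  # single-residue selection equals the direct computation
  one <- rec; one$atoms <- rec$atoms[rec$atoms$residue_seq == 1, ]
  expect_equal(per_residue_energy(one, lig)$total,
               interaction_energy(one, lig)$total)
})

test_that("RMSD is zero under rigid motion and matches bio3d", {
  set.seed(9)
  x <- matrix(rnorm(30), 10)
  expect_equal(rmsd(x, x), 0)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  moved <- x %*% t(R) + matrix(rep(c(3, -2, 7), each = 10), 10)
  expect_lt(rmsd(x, moved, superpose = TRUE), 1e-8)
  expect_gt(rmsd(x, moved, superpose = FALSE), 1)
  # symmetry of the superposed deviation
  y <- x + matrix(rnorm(30, 0, 0.4), 10)
  expect_equal(rmsd(x, y), rmsd(y, x), tolerance = 1e-9)
  # agreement with the independent bio3d implementation
  for (i in 1:5) {
    a <- matrix(rnorm(24), 8); b <- matrix(rnorm(24), 8)
    expect_equal(rmsd(a, b),
                 as.numeric(bio3d::rmsd(as.vector(t(a)), as.vector(t(b)),
                                        fit = TRUE)),
                 tolerance = 1e-3)  # bio3d rounds to 3 decimals
  }
  expect_error(rmsd(x[1:2, ], x[1:2, ], superpose = TRUE), "3 atoms")
})

test_that("RMSF separates static and mobile atoms", {
  tc <- generate_toy_complex(19, 12, 2)
  # constant trajectory: all zeros
  t0 <- generate_toy_trajectory(tc$receptor, 10, 0, 3)
  expect_equal(unname(rmsf(t0)), rep(0, 12), tolerance = 1e-12)
  # single frame: zeros with a warning
  t1 <- generate_toy_trajectory(tc$receptor, 1, 0, 3)
  expect_warning(z <- rmsf(t1), "single")
  expect_equal(unname(z), rep(0, 12))

  # one atom oscillating +/- d along x, fitted on the static atoms
  ref <- somaticRS:::coords_of(tc$receptor)
  f1 <- ref; f2 <- ref
  f1[1, 1] <- f1[1, 1] - 0.7; f2[1, 1] <- f2[1, 1] + 0.7
  tr <- trajectory(tc$receptor, rbind(as.vector(t(f1)), as.vector(t(f2))))
  rf <- rmsf(tr, fit_selection = 2:12)
  expect_equal(unname(rf[1]), 0.7, tolerance = 1e-9)
  expect_equal(unname(rf[-1]), rep(0, 11), tolerance = 1e-9)

  # Gaussian displacement: RMSF ~ sd * sqrt(3) * (n-1)/n within 10%
  big <- generate_toy_trajectory(tc$receptor, 400, 0.3, 11)
  expected <- 0.3 * sqrt(3) * (400 - 1) / 400
  expect_equal(mean(rmsf(big)), expected, tolerance = 0.10)
})

test_that("dihedrals follow the sign convention and match bio3d", {
  # canonical quadruple with a known -90 degree torsion
  p0 <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1))
  expect_equal(dihedral_angle(p0[1, ], p0[2, ], p0[3, ], p0[4, ]), -90)
  set.seed(10)
  for (i in 1:10) {
    p <- matrix(rnorm(12, sd = 2), 4)
    ang <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    # invariant under full reversal of the quadruple
    expect_equal(dihedral_angle(p[4, ], p[3, ], p[2, ], p[1, ]), ang,
                 tolerance = 1e-9)
    # negated under mirror reflection
    m <- p; m[, 1] <- -m[, 1]
    expect_equal(dihedral_angle(m[1, ], m[2, ], m[3, ], m[4, ]), -ang,
                 tolerance = 1e-9)
    ref <- bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)
    expect_equal(ang, as.numeric(ref), tolerance = 1e-2)
  }
})

test_that("phi/psi recovery and Ramachandran coding work on built backbones", {
  phi <- c(0, -57, -120, 60, -57)
  psi <- c(-47, -47, 130, 40, 0)
  m <- build_backbone(phi, psi)
  pp <- phi_psi(m, "H")
  expect_true(is.na(pp$phi[1]))          # N-terminus: no preceding C
  expect_true(is.na(pp$psi[nrow(pp)]))   # C-terminus: no following N
  inner <- 2:4
  expect_equal(pp$phi[inner], phi[inner], tolerance = 1e-6)
  expect_equal(pp$psi[inner], psi[inner], tolerance = 1e-6)
  expect_identical(pp$code[inner], c("a", "b", "l"))
})

test_that("Ramachandran codes partition the map as documented", {
  expect_identical(ramachandran_code(-57, -47), "a")
  expect_identical(ramachandran_code(60, 40), "l")
  expect_identical(ramachandran_code(-120, 130), "b")
  expect_identical(ramachandran_code(-120, -150), "b")
  expect_identical(ramachandran_code(70, 160), "e")
  expect_identical(ramachandran_code(NA, 10), NA_character_)
})

test_that("take-off coding flags the kinked-plus-bulge candidate pattern", {
  # residues 2-4 with codes b, a, b
  m <- build_backbone(c(0, -120, -57, -120, 0), c(130, 130, -47, 130, 0))
  tk <- takeoff_code(m, "H", residues = 2:4)
  expect_identical(tk$code, "bab")
  expect_true(tk$kinked_plus_candidate)
  tk2 <- takeoff_code(m, "H", residues = 2:3)
  expect_false(tk2$kinked_plus_candidate)
})
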