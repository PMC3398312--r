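test_that("minimal PDB chains parse with completeness flags", {
  ch <- read_backbone(simple_pdb_text(3), "A")
  expect_s3_class(ch, "backbone_chain")
  expect_equal(nrow(ch), 3L)
  expect_true(all(ch$complete))
  expect_equal(ch$aa, rep("G", 3))

  # residue 2 lacking CA is kept but flagged incomplete
  ch2 <- read_backbone(simple_pdb_text(3, drop = data.frame(res = 2, atom = "CA")),
                       "A")
  expect_equal(nrow(ch2), 3L)
  expect_equal(ch2$complete, c(TRUE, FALSE, TRUE))
})

test_that("missing chains and empty structures are errors", {
  expect_error(read_backbone(simple_pdb_text(3), "B"), "chain not found")
  expect_error(read_backbone("REMARK nothing here\nEND\n", "A"))
})

test_that("altloc keeps the highest-occupancy atom and HETATM is skipped", {
  lines <- c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "ALA", "A", 1, 1.1, 0, 0, occ = 0.4, alt = "A"),
    pdb_line(3, "CA", "ALA", "A", 1, 9.9, 0, 0, occ = 0.6, alt = "B"),
    pdb_line(4, "C", "ALA", "A", 1, 2.2, 0, 0),
    pdb_line(5, "N", "HOH", "A", 2, 8, 8, 8, record = "HETATM"),
    "END")
  ch <- read_backbone(paste(lines, collapse = "\n"), "A")
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$ca_x, 9.9)
})

test_that("coordinates written to PDB re-read to PDB precision", {
  set.seed(5)
  ch <- backbone_from_dihedrals(runif(8, -179, 180), runif(8, -179, 180))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb(ch, path)
  ch2 <- read_backbone(path, "A")
  co <- c("n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z", "c_x", "c_y", "c_z")
  expect_lt(max(abs(as.matrix(ch2[, co]) - as.matrix(ch[, co]))), 1e-3)
})

test_that("the four-point torsion formula matches its analytic value", {
  # independent numeric evaluation of the atan2 dihedral for this geometry
  # gives +90 degrees under the IUPAC sign convention
  expect_equal(dihedral_angle(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1), c(1, 1, 1)),
               90)
  # trans-planar four points: 180 (not -180); cis gives 0
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)),
               180)
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               0)
})

test_that("phi/psi match bio3d torsions on a synthetic chain", {
  set.seed(7)
  n <- 12
  ch <- backbone_from_dihedrals(runif(n, -179, 180), runif(n, -179, 180))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb(ch, path)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(path, verbose = FALSE))
  dh <- compute_dihedrals(ch)
  expect_wrapped_equal(tor$phi[-1], dh$phi[-1], tol = 0.2)   # PDB 1e-3 coords
  expect_wrapped_equal(tor$psi[-n], dh$psi[-n], tol = 0.2)
})

test_that("dihedral round-trip through the backbone builder is exact", {
  set.seed(11)
  n <- 30
  phi <- runif(n, -179.99, 180); psi <- runif(n, -179.99, 180)
  dh <- compute_dihedrals(backbone_from_dihedrals(phi, psi))
  expect_wrapped_equal(dh$phi[-1], phi[-1], tol = 1e-6)
  expect_wrapped_equal(dh$psi[-n], psi[-n], tol = 1e-6)
  # helical angles reproduce exactly too
  dh2 <- compute_dihedrals(backbone_from_dihedrals(rep(-60, 6), rep(-45, 6)))
  expect_wrapped_equal(dh2$phi[-1], rep(-60, 5), tol = 1e-6)
  expect_wrapped_equal(dh2$psi[-6], rep(-45, 5), tol = 1e-6)
})

test_that("terminal and incomplete-residue dihedrals are undefined", {
  ch <- read_backbone(simple_pdb_text(4, drop = data.frame(res = 3, atom = "C")),
                      "A")
  dh <- compute_dihedrals(ch)
  expect_false(dh$phi_def[1])
  expect_false(dh$psi_def[4])
  expect_false(dh$phi_def[3])   # residue 3 incomplete
  expect_false(dh$psi_def[3])
  expect_false(dh$psi_def[2])   # psi_2 needs residue 3? no: psi_2 needs N(3)
})

test_that("sliding-window extraction respects terminal and break rules", {
  set.seed(3)
  n <- 22  # 20 interior residues flanked by one residue each side
  ch <- backbone_from_dihedrals(runif(n, -179, 180), runif(n, -179, 180))
  segs <- extract_segments(ch, L = 9)
  # interior eligible window: residues 2..21 -> 12 starts
  expect_equal(nrow(segs), 12L)
  expect_equal(segs$start, 2:13)
  # overlap: consecutive windows share L-1 residues
  expect_equal(segs$start_resnum[2] - segs$start_resnum[1], 1L)

  # a chain break removes every window spanning it
  ch_break <- ch
  ch_break[11:n, c("n_x", "ca_x", "c_x")] <-
    ch_break[11:n, c("n_x", "ca_x", "c_x")] + 50
  segs_b <- extract_segments(ch_break, L = 9)
  spans <- vapply(segs_b$start, function(s) s <= 10 && s + 8 >= 11, logical(1))
  expect_false(any(spans))
  # short chains yield an empty table, not an error
  expect_equal(nrow(extract_segments(ch[1:5, ], L = 9)), 0L)
})

test_that("residue-range notation round-trips", {
  r <- render_residue_range("1jnr", "A", 614, 628)
  expect_equal(r, "1jnrA:614-628")
  p <- parse_residue_range(r)
  expect_equal(p$structure_id, "1jnr")
  expect_equal(p$chain_id, "A")
  expect_equal(p$start, 614L)
  expect_equal(p$end, 628L)
  expect_error(render_residue_range("x", "A", 10, 9))
})

test_that("kabsch_rmsd is zero under rigid motion and symmetric", {
  set.seed(13)
  A <- matrix(rnorm(48), ncol = 3)
  expect_equal(kabsch_rmsd(A, A), 0)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  B <- A %*% R + matrix(rep(c(3, -2, 7), each = nrow(A)), ncol = 3)
  expect_lt(kabsch_rmsd(A, B), 1e-9)
  # symmetry and general invariance
  C <- A + matrix(rnorm(48, sd = 0.5), ncol = 3)
  expect_equal(kabsch_rmsd(A, C), kabsch_rmsd(C, A), tolerance = 1e-9)
  expect_equal(kabsch_rmsd(A %*% R, C), kabsch_rmsd(A, C), tolerance = 1e-9)
  expect_error(kabsch_rmsd(A, A[-1, ]), "length mismatch")
})

test_that("kabsch_rmsd agrees with the bio3d superposition oracle", {
  set.seed(17)
  A <- matrix(rnorm(60), ncol = 3)
  B <- A + matrix(rnorm(60, sd = 1.2), ncol = 3)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(B)), mobile = as.numeric(t(A))))
  oracle <- bio3d::rmsd(as.numeric(t(B)), fitted)
  expect_equal(kabsch_rmsd(A, B), oracle, tolerance = 1e-3)  # bio3d rounds
  # collinear degenerate input still returns the optimum, here 0
  line <- cbind(1:5, 0, 0)
  expect_lt(kabsch_rmsd(line, line %*% R_z(1.1)), 1e-9)
})
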