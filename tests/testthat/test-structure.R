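# Coordinate model: PDB I/O, superposition, grafting, mutation, alignment.

ala_pdb_text <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
  "ATOM      5  CB  ALA A   1       2.000  -0.770  -1.210  1.00  0.00           C",
  "END")

test_that("read_pdb parses a minimal one-residue file and rejects empty input", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(ala_pdb_text, f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atoms), 5)
  expect_equal(nrow(residue_table(s)), 1)
  expect_equal(residue_table(s)$resname, "ALA")
  expect_true(all(s$atoms$standard))

  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing", "END"), empty)
  expect_error(read_pdb(empty), "no ATOM records")
  expect_error(read_pdb(file.path(tempdir(), "no-such-file.pdb")),
               "not found")
})

test_that("altloc resolves to the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.60  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   9.000   9.000  0.40  0.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- read_pdb(f)
  expect_equal(sum(s$atoms$name == "N"), 1)
  expect_equal(s$atoms$x[s$atoms$name == "N"], 0.0)
})

test_that("write_pdb round-trips the toy dimer without coordinate drift", {
  d <- toy_dimer()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(d, f)
  s2 <- read_pdb(f)
  expect_equal(length(chains(s2)), 2)
  expect_equal(nrow(s2$atoms), nrow(d$atoms))
  expect_equal(coords(s2), round(coords(d), 3), ignore_attr = TRUE)
  # second round trip is bit-exact
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("superpose recovers rigid transforms and matches quaternion oracle", {
  set.seed(11)
  x <- matrix(rnorm(30), 10, 3)
  fit0 <- superpose(x, x)
  expect_lt(fit0$rmsd, 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)

  R <- rotation_about_axis(c(0, 0, 1), 90)
  y <- sweep(x %*% t(R), 2, c(1, 2, 3), "+")
  fit <- superpose(x, y)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  expect_equal(fit$translation, c(1, 2, 3), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # noisy 4-point sets: rmsd equals the independent quaternion-method value
  for (k in 1:5) {
    a <- matrix(rnorm(12), 4, 3)
    b <- matrix(rnorm(12), 4, 3)
    expect_equal(superpose(a, b)$rmsd, quaternion_rmsd(a, b),
                 tolerance = 1e-9)
  }
  expect_error(superpose(x[1:4, ], x[1:5, ]), "differ in length")
  expect_error(superpose(x[1:2, ], x[1:2, ]), "at least 3")
})

test_that("superpose rmsd is invariant to rigid motion of either input", {
  set.seed(4)
  a <- matrix(rnorm(24), 8, 3)
  b <- matrix(rnorm(24), 8, 3)
  base <- superpose(a, b)$rmsd
  for (k in 1:3) {
    R <- rotation_about_axis(rnorm(3), runif(1, 10, 170))
    a2 <- sweep(a %*% t(R), 2, rnorm(3, 0, 10), "+")
    expect_equal(superpose(a2, b)$rmsd, base, tolerance = 1e-9)
    expect_equal(superpose(a, sweep(b %*% t(R), 2, 1:3, "+"))$rmsd, base,
                 tolerance = 1e-9)
  }
})

make_gapped <- function(full, chain, gap) {
  keep <- !(full$atoms$chain == chain & full$atoms$resno %in% gap)
  structure3d(full$atoms[keep, , drop = FALSE])
}

test_that("graft_loop self-graft restores the original structure", {
  helix <- build_peptide(strrep("A", 16), -57, -47, chain = "A")
  gap <- 7:11
  gapped <- make_gapped(helix, "A", gap)
  res <- graft_loop(gapped, helix, "A", gap, "A", gap, n_anchor = 3)
  expect_lt(res$anchor_rmsd, 1e-9)
  expect_equal(nrow(res$structure$atoms), nrow(helix$atoms))
  expect_equal(coords(res$structure), coords(helix), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("graft_loop splices a donor loop with proper peptide continuity", {
  helix <- build_peptide(strrep("A", 16), -57, -47, chain = "A")
  gap <- 7:11
  gapped <- make_gapped(helix, "A", gap)
  donor <- rigid_move(helix, axis = c(1, 1, 0), angle = 67,
                      shift = c(10, 0, -4))
  res <- graft_loop(gapped, donor, "A", gap, "A", gap, n_anchor = 3)
  s <- res$structure
  expect_equal(residue_table(s)$resno, 1:16)
  a <- s$atoms
  for (pair in list(c(6, 7), c(11, 12))) {
    ci <- which(a$resno == pair[1] & a$name == "C")
    ni <- which(a$resno == pair[2] & a$name == "N")
    d <- sqrt(sum((c(a$x[ci], a$y[ci], a$z[ci]) -
                     c(a$x[ni], a$y[ni], a$z[ni]))^2))
    expect_gt(d, 1.2)
    expect_lt(d, 1.6)
  }
  # deleting the grafted residues restores the acceptor exactly
  back <- make_gapped(s, "A", gap)
  expect_identical(back$atoms[, c("x", "y", "z")],
                   gapped$atoms[, c("x", "y", "z")])
})

test_that("graft_loop validates lengths and anchor quality", {
  helix <- build_peptide(strrep("A", 16), -57, -47, chain = "A")
  gapped <- make_gapped(helix, "A", 7:11)
  expect_error(graft_loop(gapped, helix, "A", 7:11, "A", 7:10),
               "length")
  strand <- build_peptide(strrep("A", 16), -119, 113, chain = "A")
  expect_error(graft_loop(gapped, strand, "A", 7:11, "A", 7:11, n_anchor = 3),
               "rmsd")
})

test_that("mutate_residue truncates, preserves backbone, and is identity on X->X", {
  d <- toy_dimer()
  rt <- residue_table(d)
  leu <- rt[rt$resname == "LEU" & rt$chain == "A", ][1, ]

  m <- mutate_residue(d, leu$chain, leu$resno, "A")
  rows <- which(m$atoms$chain == leu$chain & m$atoms$resno == leu$resno)
  expect_equal(sort(m$atoms$name[rows]), sort(c("N", "CA", "C", "O", "CB")))
  expect_equal(m$atoms$resname[rows[1]], "ALA")

  same <- mutate_residue(d, leu$chain, leu$resno, "L")
  expect_identical(same$atoms, d$atoms)

  big <- mutate_residue(d, leu$chain, leu$resno, "W")
  bb <- c("N", "CA", "C", "O", "CB")
  for (nm in bb) {
    i0 <- which(d$atoms$chain == leu$chain & d$atoms$resno == leu$resno &
                  d$atoms$name == nm)
    i1 <- which(big$atoms$chain == leu$chain & big$atoms$resno == leu$resno &
                  big$atoms$name == nm)
    expect_identical(coords(d)[i0, ], coords(big)[i1, ])
  }
  expect_equal(big$atoms$resname[residue_rows(big, leu$chain, leu$resno)][1],
               "TRP")

  expect_error(mutate_residue(d, "A", 999, "W"), "not found")
  expect_error(mutate_residue(d, leu$chain, leu$resno, "X"), "not standard")
})

test_that("mutate_residue picks the least-clashing rotamer (exhaustive audit)", {
  d <- toy_dimer()
  rt <- residue_table(d)
  # a buried interface leucine mutated to bulky TRP
  leu <- rt[rt$resname == "LEU" & rt$chain == "A", ][2, ]
  cands <- sidechain_rotamers(d, leu$chain, leu$resno, "TRP")
  rows <- residue_rows(d, leu$chain, leu$resno)
  env <- coords(d)[-rows, , drop = FALSE]
  kept <- c("N", "CA", "C", "O", "CB")
  counts <- vapply(cands, function(sc) {
    scm <- as.matrix(sc[!(sc$name %in% kept), c("x", "y", "z")])
    d2 <- outer(rowSums(scm^2), rowSums(env^2), "+") - 2 * scm %*% t(env)
    sum(d2 < 4)  # 2.0 A clash cutoff, squared
  }, numeric(1))
  mut <- mutate_residue(d, leu$chain, leu$resno, "W")
  mrows <- which(mut$atoms$chain == leu$chain & mut$atoms$resno == leu$resno &
                   !(mut$atoms$name %in% kept))
  scm <- coords(mut)[mrows, , drop = FALSE]
  d2 <- outer(rowSums(scm^2), rowSums(env^2), "+") - 2 * scm %*% t(env)
  chosen <- sum(d2 < 4)
  expect_equal(chosen, min(counts))
})

test_that("align_identity computes identity/similarity and is symmetric", {
  r <- align_identity("ACDEFG", "ACDEFG")
  expect_equal(r$identity, 100)
  expect_equal(r$similarity, 100)

  r2 <- align_identity("ACDEFG", "ACDEFA")
  expect_equal(r2$identity, 100 * 5 / 6, tolerance = 1e-9)

  a <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  b <- "MKTAYIARQRQISFVKSHFSRQTEERLGLIEVQ"
  f <- align_identity(a, b)
  g <- align_identity(b, a)
  expect_equal(f$identity, g$identity)
  expect_equal(f$similarity, g$similarity)
  expect_true(f$identity <= f$similarity)
  expect_true(f$similarity <= 100)

  expect_error(align_identity("", "ACD"), "empty")
  expect_error(align_identity("ACD", "AC1D"), "invalid")
})

test_that("PAS-B-like stand-in pair reproduces the template identity arithmetic", {
  # synthetic stand-in for the mouse-vs-human PAS-B comparison: 112 aligned
  # positions, 4 substitutions of which 2 are conservative, giving
  # identity 108/112 = 96.4% and similarity 110/112 = 98.2%
  f <- system.file("extdata", "synthetic_pasb_pair.fasta", package = "dimerdx")
  seqs <- read_fasta(f)
  r <- align_identity(seqs[[1]], seqs[[2]])
  expect_equal(r$aligned_length, 112)
  expect_equal(round(r$identity, 1), 96.4)
  expect_equal(round(r$similarity, 1), 98.2)
})
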