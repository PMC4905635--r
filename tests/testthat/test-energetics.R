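# Parameter assignment, generalized Born, mechanical terms, binding free
# energy and its residue-pairwise decomposition.

test_that("per-residue charges sum to formal charges", {
  tab <- default_atom_params()
  sums <- tapply(tab$charge, tab$resname, sum)
  for (rn in names(sums)) {
    expect_equal(unname(sums[rn]), unname(dimerdx::FORMAL_CHARGE[rn]),
                 tolerance = 1e-3)
  }
})

test_that("assign_parameters covers the toy dimer and reports total charge", {
  d <- toy_dimer()
  ps <- assign_parameters(d)
  expect_true(all(is.finite(ps$atoms$charge)))
  rt <- residue_table(d, standard_only = TRUE)
  expected <- sum(dimerdx::FORMAL_CHARGE[rt$resname])
  expect_equal(sum(ps$atoms$charge), expected, tolerance = 1e-3)
  # ALA neutral, ARG +1
  ala <- build_peptide("A")
  expect_equal(sum(assign_parameters(ala)$atoms$charge), 0, tolerance = 1e-3)
  arg <- build_peptide("R")
  expect_equal(sum(assign_parameters(arg)$atoms$charge), 1, tolerance = 1e-3)
})

test_that("assign_parameters strict/lenient modes behave per contract", {
  d <- toy_dimer()
  bad <- d
  bad$atoms$name[bad$atoms$name == "CB"][1] <- "XX"
  expect_error(assign_parameters(bad), "unparameterized")
  expect_warning(ps <- assign_parameters(bad, strict = FALSE),
                 "unparameterized")
  expect_equal(ps$atoms$charge[ps$atoms$name == "XX"], 0)
})

test_that("isolated atom gets the offset-corrected intrinsic Born radius", {
  s <- ion_structure(matrix(c(0, 0, 0), 1), radius = 1.55)
  r <- born_radii(s)
  expect_equal(r, 1.55 - 0.09, tolerance = 1e-12)
})

test_that("burial increases the effective Born radius", {
  xyz <- rbind(c(0, 0, 0),
               expand.grid(x = c(-3, 3), y = c(-3, 3), z = c(-3, 3)))
  s <- ion_structure(as.matrix(xyz), charges = rep(0, 9))
  r <- born_radii(s)
  expect_gt(r[1], 1.55 - 0.09)
})

test_that("two-atom descreening matches direct numerical quadrature", {
  cfg <- energy_config()
  for (d in c(2.5, 4.0, 6.0)) {
    s <- ion_structure(rbind(c(0, 0, 0), c(d, 0, 0)), radius = 1.55)
    rho <- 1.55 - cfg$gb_offset
    sj <- 0.79 * rho
    # HCT integral: over the shell [L, U], the solid-angle fraction of the
    # scaled partner sphere times 1/s^2
    f <- function(s_) {
      cosw <- (s_^2 + d^2 - sj^2) / (2 * s_ * d)
      frac <- (1 - cosw) / 2
      frac / s_^2
    }
    L <- max(abs(d - sj), rho); U <- d + sj
    I <- stats::integrate(f, L, U, rel.tol = 1e-10)$value
    psi <- rho * I
    tanh_arg <- cfg$obc_alpha * psi - cfg$obc_beta * psi^2 +
      cfg$obc_gamma * psi^3
    expected <- 1 / (1 / rho - tanh(tanh_arg) / 1.55)
    expect_equal(born_radii(s, cfg)[1], expected, tolerance = 1e-4)
  }
  s0 <- ion_structure(rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(born_radii(s0), "overlapping")
})

test_that("Born-ion analytic limit holds to 1e-6 at zero salt", {
  cfg <- energy_config(salt = 0)
  for (q in c(1, -1, 0.5)) {
    s <- ion_structure(matrix(0, 1, 3), charges = q, radius = 1.55)
    R <- 1.55 - cfg$gb_offset
    expected <- -(332.06 / 2) * (1 - 1 / 78.5) * q^2 / R
    expect_equal(gb_polar_energy(s, cfg)$total, expected, tolerance = 1e-6)
  }
  s0 <- ion_structure(matrix(0, 1, 3), charges = 0)
  expect_equal(gb_polar_energy(s0, cfg)$total, 0)
})

test_that("two-ion GB energy matches a term-by-term Still-expression script", {
  cfg <- energy_config(salt = 0.154)
  d <- 4.2
  s <- ion_structure(rbind(c(0, 0, 0), c(d, 0, 0)), charges = c(1, -1))
  radii <- born_radii(s, cfg)
  # independent accumulation over the three terms
  kap <- 0.316 * sqrt(0.154)
  pref <- function(f) 1 - exp(-kap * f) / 78.5
  self1 <- -0.5 * 332.06 * 1^2 * pref(radii[1]) / radii[1]
  self2 <- -0.5 * 332.06 * 1^2 * pref(radii[2]) / radii[2]
  fgb <- sqrt(d^2 + radii[1] * radii[2] *
                exp(-d^2 / (4 * radii[1] * radii[2])))
  crossterm <- -332.06 * (1 * -1) * pref(fgb) / fgb
  expected <- self1 + self2 + crossterm
  got <- gb_polar_energy(s, cfg)
  expect_equal(got$total, expected, tolerance = 1e-9)
  # pair tensor holds the full cross term off-diagonal, self terms on diagonal
  expect_equal(got$pair[1, 2], crossterm, tolerance = 1e-9)
  expect_equal(got$pair[1, 1], self1, tolerance = 1e-9)
})

test_that("salt screens the net electrostatic pair interaction", {
  d <- 4.2
  s <- ion_structure(rbind(c(0, 0, 0), c(d, 0, 0)), charges = c(1, -1))
  net <- sapply(c(0, 0.154, 0.5, 1.0), function(m) {
    cfg <- energy_config(salt = m)
    radii <- born_radii(s, cfg)
    fgb <- sqrt(d^2 + radii[1] * radii[2] *
                  exp(-d^2 / (4 * radii[1] * radii[2])))
    coulomb <- 332.06 * (1 * -1) / d
    gbcross <- -332.06 * (1 * -1) * (1 - exp(-cfg$kappa * fgb) / 78.5) / fgb
    abs(coulomb + gbcross)
  })
  expect_true(all(diff(net) < 0))
})

test_that("Coulomb and LJ match closed forms", {
  xyz <- rbind(c(0, 0, 0), c(3.32, 0, 0))
  s <- ion_structure(xyz, charges = c(1, -1))
  s$atoms$lj_rmin2 <- 0; s$atoms$lj_eps <- 0
  me <- mechanical_energy(s)
  expect_equal(me$ele_total, 332.06 * (1) * (-1) / 3.32, tolerance = 1e-9)
  expect_equal(me$ele_total, -100.018, tolerance = 1e-3)

  # 12-6 minimum: at r = Rmin (= sigma * 2^(1/6)) energy is exactly -eps
  rmin2 <- 1.908; eps <- 0.086
  s2 <- ion_structure(rbind(c(0, 0, 0), c(2 * rmin2, 0, 0)),
                      charges = c(0, 0))
  s2$atoms$lj_rmin2 <- rmin2; s2$atoms$lj_eps <- eps
  me2 <- mechanical_energy(s2)
  expect_equal(me2$lj_total, -eps, tolerance = 1e-12)
})

test_that("mechanical totals equal an all-pairs brute-force sum", {
  d <- toy_dimer()
  ps <- assign_parameters(d)
  me <- mechanical_energy(ps)
  a <- ps$atoms
  key <- paste(a$chain, a$resno)
  ele <- 0; lj <- 0
  excl_pairs <- list(c("C", "N"), c("CA", "N"), c("O", "N"), c("C", "CA"),
                     c("C", "CD"))
  for (i in seq_len(nrow(a) - 1)) for (j in (i + 1):nrow(a)) {
    if (key[i] == key[j]) next
    consec <- a$chain[i] == a$chain[j] && abs(a$resno[i] - a$resno[j]) == 1
    if (consec) {
      lo <- if (a$resno[i] < a$resno[j]) i else j
      hi <- if (a$resno[i] < a$resno[j]) j else i
      if (any(vapply(excl_pairs, function(p)
        a$name[lo] == p[1] && a$name[hi] == p[2], logical(1)))) next
    }
    r <- sqrt(sum((coords(ps)[i, ] - coords(ps)[j, ])^2))
    ele <- ele + 332.06 * a$charge[i] * a$charge[j] / r
    rm <- a$lj_rmin2[i] + a$lj_rmin2[j]
    ep <- sqrt(a$lj_eps[i] * a$lj_eps[j])
    lj <- lj + ep * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  expect_equal(me$ele_total, ele, tolerance = 1e-8)
  expect_equal(me$lj_total, lj, tolerance = 1e-8)
})

test_that("separated protomers bind with ~zero free energy", {
  far <- make_decoy(toy_dimer(), angle = 0, translation = c(200, 0, 0))
  bfe <- binding_free_energy(far, ab_partition(), fast_cfg())
  expect_lt(abs(bfe$dg), 0.05)
  m <- pairwise_decomposition(far, ab_partition(), fast_cfg())
  expect_true(all(abs(m$matrix) < 1e-2))
  expect_equal(sum(m$matrix), m$delta$total, tolerance = 1e-6)
})

test_that("binding free energy is symmetric in partition order", {
  b1 <- binding_free_energy(toy_dimer(), list("A", "B"), fast_cfg())
  b2 <- binding_free_energy(toy_dimer(), list("B", "A"), fast_cfg())
  expect_equal(b1$dg, b2$dg, tolerance = 1e-9)
})

test_that("engineered dimer binds better than the decoy breaking its motifs", {
  b1 <- binding_free_energy(toy_dimer(), ab_partition(), fast_cfg())
  b2 <- binding_free_energy(toy_decoy(), ab_partition(), fast_cfg())
  expect_lt(b1$dg, b2$dg)
  expect_lt(b1$dg, 0)
})

test_that("decomposition conserves the binding free energy per channel", {
  m <- toy_matrix()
  expect_equal(sum(m$matrix), m$delta$total, tolerance = 1e-6)
  expect_equal(sum(m$channels$ele), m$delta$ele, tolerance = 1e-9)
  expect_equal(sum(m$channels$vdw), m$delta$vdw, tolerance = 1e-9)
  expect_equal(sum(m$channels$gb), m$delta$gb, tolerance = 1e-9)
  expect_equal(sum(m$channels$np), m$delta$np, tolerance = 1e-9)
  expect_lt(abs(m$conservation_gap), 1e-6)
  expect_equal(m$delta$covalent, 0)
})

test_that("mechanical intramolecular entries are bitwise zero", {
  m <- toy_matrix()
  same <- outer(m$residues$protomer, m$residues$protomer, "==")
  expect_identical(unique(m$channels$ele[same]), 0)
  expect_identical(unique(m$channels$vdw[same]), 0)
  off_intra <- same & !diag(TRUE, nrow(m$matrix))
  expect_identical(unique(m$channels$gb[off_intra]), 0)
})

test_that("strict zeroing of intramolecular GB breaks conservation measurably", {
  m <- pairwise_decomposition(toy_dimer(), ab_partition(), fast_cfg(),
                              intra_gb = "zero")
  expect_gt(abs(m$conservation_gap), 1e-6)
})

test_that("the engineered salt bridge dominates its row of the ele channel", {
  m <- toy_matrix()
  ele <- m$channels$ele
  row <- ele["A:5:", ]
  expect_equal(names(which.min(row)), "B:9:")
  expect_lt(row["B:9:"], 0)
})

test_that("per-residue contributions follow the half-split rule and conserve", {
  m <- toy_matrix()
  pr <- per_residue_contribution(m)
  expect_equal(sum(pr), m$delta$total, tolerance = 1e-6)
  expect_equal(per_residue_contribution(matrix(0, 3, 3)), rep(0, 3))
  # single nonzero pair entry -2.0 split as -1.0 each
  mm <- matrix(0, 4, 4)
  mm[2, 3] <- mm[3, 2] <- -1.0  # symmetric half-entries summing to -2.0
  pr2 <- per_residue_contribution(mm)
  expect_equal(pr2, c(0, -1, -1, 0))
})

test_that("energies are invariant under rigid motion", {
  cfg <- fast_cfg()
  b1 <- binding_free_energy(toy_dimer(), ab_partition(), cfg)
  b2 <- binding_free_energy(rigid_move(toy_dimer()), ab_partition(), cfg)
  expect_equal(b1$dg, b2$dg, tolerance = 1e-6)
  expect_equal(unlist(b1$delta), unlist(b2$delta), tolerance = 1e-6)
})

test_that("interface complementarity scores follow the charge sign rules", {
  d <- toy_dimer()
  comp <- interface_complementarity(d, ab_partition(), fast_cfg(),
                                    report = toy_report())
  # engineered Lys(A5) faces Glu(B9): both ends complementary
  expect_gt(comp$score[comp$key == "A:5:"], 0)
  expect_gt(comp$score[comp$key == "B:9:"], 0)
  # mutate the Glu to Arg: facing like charges now anticomplementary
  d2 <- mutate_residue(d, "B", 9, "R")
  rep2 <- delta_sasa(d2, ab_partition(), n_points = 240)
  comp2 <- interface_complementarity(d2, ab_partition(), fast_cfg(),
                                     report = rep2)
  expect_lt(comp2$score[comp2$key == "A:5:"], 0)
  # neutral hydrophobic residues stay inside the neutrality band
  leu <- comp[comp$key == "A:9:", ]
  if (nrow(leu)) expect_lt(abs(leu$score), 0.5)
})
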