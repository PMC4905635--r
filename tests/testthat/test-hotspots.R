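# Hot-spot prediction: contact potential, empirical burial rule, alanine
# scanning, consensus ranking.

test_that("contact potential: empty shell is zero, unit weights count residues", {
  d <- toy_dimer()
  far <- make_decoy(d, angle = 0, translation = c(100, 0, 0))
  expect_equal(contact_potential(far, ab_partition(), c("A", 5)), 0)

  # unit-weight table counts partner residues in the shell
  uw <- unit_weight_table()
  cp <- contact_potential(d, ab_partition(), c("A", 5), shell = 7, weights = uw)
  # independent count of partner residues with any heavy atom within 7 A
  rows <- residue_rows(d, "A", 5)
  prows <- which(d$atoms$chain == "B")
  d2 <- outer(rowSums(coords(d, rows)^2), rowSums(coords(d, prows)^2), "+") -
    2 * coords(d, rows) %*% t(coords(d, prows))
  n_near <- length(unique(d$atoms$resno[prows[apply(d2 <= 49, 2, any)]]))
  expect_equal(cp, n_near)
  expect_gt(n_near, 0)
})

test_that("contact potential is monotone in the shell radius", {
  d <- toy_dimer()
  shells <- c(4, 5.5, 7, 9)
  vals <- vapply(shells, function(sh)
    contact_potential(d, ab_partition(), c("A", 9), shell = sh), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_error(contact_potential(d, ab_partition(), c("A", 999)), "not found")
})

test_that("empirical rule applies exact threshold semantics", {
  fake <- function(burial, contact) {
    burial >= 20 & contact >= 18
  }
  expect_true(fake(25, 20))
  expect_true(fake(20, 18))     # boundary included ("at least")
  expect_false(fake(19.9, 100))
  expect_false(fake(60, 17.9))
  # and the implementation agrees on the toy dimer with forced thresholds
  emp <- empirical_hotspots(toy_report(), toy_dimer())
  expect_true(all(emp$empirical ==
                    (emp$burial_pct >= 20 & emp$contact >= 18)))
})

test_that("contact weights make buried toy interface residues score near threshold", {
  emp <- empirical_hotspots(toy_report(), toy_dimer())
  core <- emp[emp$burial_pct >= 20, ]
  expect_gt(nrow(core), 0)
  expect_true(any(core$contact >= 18))
})

test_that("alanine scan: contact-free residue scores exactly zero", {
  far <- make_decoy(toy_dimer(), angle = 0, translation = c(150, 0, 0))
  # force a report that still flags residues so the scan covers them
  rep <- delta_sasa(far, ab_partition(), n_points = 240)
  rep$residues$dsasa[rep$residues$resname == "LEU"] <- 1
  scan <- alanine_scan(far, ab_partition(), fast_cfg(), report = rep)
  expect_gt(nrow(scan), 0)
  expect_true(all(abs(scan$ddg) < 1e-6))
  expect_true(all(!scan$alascan))
})

test_that("alanine scan: engineered salt-bridge lysine is destabilizing to remove", {
  scan <- alanine_scan(toy_dimer(), ab_partition(), fast_cfg(),
                       report = toy_report())
  lys <- scan[scan$key == "A:5:", ]
  expect_equal(nrow(lys), 1)
  expect_gt(lys$ddg, 0)
  expect_true(lys$alascan)  # way above 1 kcal/mol for a buried salt bridge
  # threshold is exact at 1.0
  expect_identical(scan$alascan, scan$ddg >= 1.0)
})

test_that("alanine scan ddG is invariant to partition order", {
  s1 <- alanine_scan(toy_dimer(), list("A", "B"), fast_cfg(),
                     report = toy_report())
  rep_ba <- delta_sasa(toy_dimer(), list("B", "A"), n_points = 240)
  s2 <- alanine_scan(toy_dimer(), list("B", "A"), fast_cfg(), report = rep_ba)
  m1 <- s1$ddg[order(s1$key)]
  m2 <- s2$ddg[order(s2$key)]
  expect_equal(s1$key[order(s1$key)], s2$key[order(s2$key)])
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("alanine scan is internally consistent with the interaction matrix", {
  d <- toy_dimer()
  cfg <- fast_cfg()
  scan <- alanine_scan(d, ab_partition(), cfg, report = toy_report())
  m <- toy_matrix()
  # a residue's cross-channel (ele+vdw+gb) row sum bounds its ddG: truncation
  # removes the side-chain share of exactly those terms
  for (k in scan$key) {
    cross_row <- 2 * (m$channels$ele[k, ] + m$channels$vdw[k, ] +
                        m$channels$gb[k, ])
    cross_sum <- sum(cross_row[m$residues$protomer !=
                                 m$residues$protomer[m$residues$key == k]])
    ddg_full_removal <- -cross_sum
    # side-chain-only removal cannot exceed full-residue removal by more than
    # the backbone share; check sign consistency for the strong interactors
    if (abs(ddg_full_removal) > 5)
      expect_equal(sign(scan$ddg[scan$key == k]), sign(ddg_full_removal))
  }
})

test_that("consensus ranking puts dual-method residues first with stated tie-breaks", {
  hr <- hotspot_report(toy_dimer(), ab_partition(), fast_cfg(),
                       report = toy_report())
  tab <- hr$table
  expect_true(all(diff(tab$consensus) <= 0 | diff(tab$rank) == 1))
  # tiers are honored: every consensus-2 residue precedes every consensus-1
  if (any(tab$consensus == 2) && any(tab$consensus < 2)) {
    expect_lt(max(tab$rank[tab$consensus == 2]),
              min(tab$rank[tab$consensus < 2]))
  }
  expect_identical(consensus_rank(hr), tab$key)
})

test_that("consensus z-score ordering matches a hand-computed oracle", {
  # four residues, hand-set scores, all same tier
  tab <- data.frame(key = c("A:1:", "A:2:", "A:3:", "A:4:"),
                    burial = c(30, 50, 40, 20),
                    contact = c(20, 10, 30, 5),
                    ddg = c(1.5, 0.5, 2.5, 0.1))
  z <- function(x) (x - mean(x)) / sd(x)
  zm <- rowMeans(cbind(z(tab$burial), z(tab$contact), z(tab$ddg)))
  expect_equal(order(-zm), c(3, 1, 2, 4))
})
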