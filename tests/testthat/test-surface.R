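# SASA, buried surface on complexation, interface residues, typed contacts.

single_atom <- function(element = "O", xyz = c(0, 0, 0)) {
  structure3d(data.frame(chain = "A", resno = 1, icode = " ", resname = "HOH",
                         name = "O1", element = element,
                         x = xyz[1], y = xyz[2], z = xyz[3],
                         stringsAsFactors = FALSE))
}

two_atoms <- function(d, elements = c("C", "C")) {
  structure3d(data.frame(chain = "A", resno = 1:2, icode = " ",
                         resname = "UNL", name = c("C1", "C2"),
                         element = elements, x = c(0, d), y = 0, z = 0,
                         stringsAsFactors = FALSE))
}

test_that("isolated-atom SASA matches the analytic sphere area", {
  s <- single_atom("C")  # r = 1.70
  got <- sasa(s, probe = 1.4, n_points = 960)$atom
  expect_equal(got, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.005)
  expect_equal(got, 120.76, tolerance = 0.005 * 120.76)
})

test_that("non-overlapping spheres keep their isolated areas exactly", {
  d <- 2 * (1.7 + 1.4) + 0.1
  s <- two_atoms(d)
  got <- sasa(s, probe = 1.4, n_points = 480)$atom
  iso <- 4 * pi * (1.7 + 1.4)^2 * (480 / 480)
  lattice_iso <- sasa(single_atom("C"), probe = 1.4, n_points = 480)$atom
  expect_equal(got, rep(lattice_iso, 2))
  expect_equal(got[1], iso, tolerance = 0.005)
})

test_that("overlapping spheres match the analytic spherical-cap formula", {
  # equal radii r, separation d = r1 + r2 (= 2r): accessible area of each
  # expanded sphere R = r + probe loses the cap inside the partner sphere
  r <- 1.7; probe <- 1.4; d <- 2 * r
  R <- r + probe
  cos_t <- d / (2 * R)  # from d^2 + R^2 - R^2 over 2 d R
  cap <- 2 * pi * R^2 * (1 - cos_t)
  expected_each <- 4 * pi * R^2 - cap
  s <- two_atoms(d)
  got <- sasa(s, probe = probe, n_points = 1920)$atom
  expect_equal(got[1], expected_each, tolerance = 0.005 * expected_each)
  expect_equal(sum(got), 2 * expected_each,
               tolerance = 0.005 * 2 * expected_each)
})

test_that("doubling the default quadrature changes per-residue SASA by under 2 percent", {
  d <- toy_dimer()
  a <- sasa(d, n_points = 1920)$residue$sasa
  b <- sasa(d, n_points = 3840)$residue$sasa
  expect_true(all(abs(a - b) / pmax(b, 1) < 0.02))
})

test_that("sasa validates inputs", {
  s <- single_atom("X")
  expect_error(sasa(s), "no SASA radius")
  expect_error(sasa(single_atom(), probe = -1), "probe > 0")
  expect_error(sasa(single_atom(), n_points = 50), "n_points")
})

test_that("separated protomers bury no surface; toy dimer buries symmetric totals", {
  far <- make_decoy(toy_dimer(), angle = 0, translation = c(100, 0, 0))
  rep_far <- delta_sasa(far, ab_partition(), n_points = 240)
  expect_true(all(rep_far$residues$dsasa < 1e-6))
  expect_length(unlist(interface_residues(rep_far)), 0)

  rep1 <- toy_report()
  rep2 <- delta_sasa(toy_dimer(), list("B", "A"), n_points = 240)
  # partition order swaps the protomer labels but not per-residue values
  expect_equal(rep1$totals$A, rep2$totals$B, tolerance = 1e-9)
  expect_equal(rep1$totals$B, rep2$totals$A, tolerance = 1e-9)
  m1 <- rep1$residues[order(rep1$residues$key), "dsasa"]
  m2 <- rep2$residues[order(rep2$residues$key), "dsasa"]
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("per-residue complex SASA never exceeds isolated SASA", {
  res <- toy_report()$residues
  expect_true(all(res$sasa_complex <= res$sasa_isolated + 1e-6))
  expect_true(all(res$dsasa >= 0))
})

test_that("delta_sasa totals agree with a doubled-quadrature recomputation", {
  rep1 <- toy_report()
  rep2 <- delta_sasa(toy_dimer(), ab_partition(), n_points = 480)
  tot1 <- rep1$totals$A + rep1$totals$B
  tot2 <- rep2$totals$A + rep2$totals$B
  expect_equal(tot1, tot2, tolerance = 0.02 * tot2)
})

test_that("interface sets shrink monotonically with the threshold", {
  rep <- toy_report()
  s0 <- interface_residues(rep, threshold = 0)
  s1 <- interface_residues(rep, threshold = 0.1)
  s5 <- interface_residues(rep, threshold = 5)
  expect_true(all(s1$A %in% s0$A) && all(s1$B %in% s0$B))
  expect_true(all(s5$A %in% s1$A) && all(s5$B %in% s1$B))
  expect_error(delta_sasa(toy_dimer(), list("A", "A")),
               "overlap|cover")
})

test_that("contact typing follows the distance and chemistry rules", {
  ct <- enumerate_contacts(toy_dimer(), ab_partition())
  # engineered Lys5(A)-Glu9(B) salt bridge is reported as an Ele contact
  sb <- ct[ct$res_i == "A:5:" & ct$res_j == "B:9:" & ct$type == "Ele", ]
  expect_equal(nrow(sb), 1)
  expect_true(sb$salt_bridge)
  expect_lte(sb$distance, 4.0)
  # engineered Leu-Leu pairs give VdW contacts
  expect_true(any(ct$type == "VdW" &
                    ct$resname_i == "LEU" & ct$resname_j == "LEU"))
})

test_that("contact list equals an independent all-pairs scan", {
  d <- toy_dimer()
  ct <- enumerate_contacts(d, ab_partition())
  a <- d$atoms
  # brute force with the same published cutoffs
  ia <- which(a$chain == "A"); ib <- which(a$chain == "B")
  pos <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ", HIS = c("ND1", "NE2"))
  neg <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  sgn <- function(rn, nm) {
    if (nm == "OXT") return(-1)
    if (!is.null(pos[[rn]]) && nm %in% pos[[rn]]) return(1)
    if (!is.null(neg[[rn]]) && nm %in% neg[[rn]]) return(-1)
    0
  }
  found <- list()
  for (i in ia) for (j in ib) {
    dd <- sqrt(sum((coords(d)[i, ] - coords(d)[j, ])^2))
    if (dd > 4.0) next
    ri <- paste(a$chain[i], a$resno[i], "", sep = ":")
    rj <- paste(a$chain[j], a$resno[j], "", sep = ":")
    salt <- sgn(a$resname[i], a$name[i]) * sgn(a$resname[j], a$name[j]) < 0 &&
      dd <= 4.0
    hb <- a$element[i] %in% c("N", "O") && a$element[j] %in% c("N", "O") &&
      dd <= 3.5
    type <- if (salt || hb) "Ele" else if (dd <= 3.9) "VdW" else NA
    if (is.na(type)) next
    found[[paste(ri, rj, type)]] <- TRUE
  }
  expect_setequal(paste(ct$res_i, ct$res_j, ct$type), names(found))
})

test_that("contacts are invariant under a global rigid transform", {
  d <- toy_dimer()
  ct1 <- enumerate_contacts(d, ab_partition())
  ct2 <- enumerate_contacts(rigid_move(d), ab_partition())
  expect_equal(ct1[, c("res_i", "res_j", "type")],
               ct2[, c("res_i", "res_j", "type")])
  expect_equal(ct1$distance, ct2$distance, tolerance = 1e-9)
})

test_that("hand-built salt bridge and hydrophobic pair get the right types", {
  # Lys NZ 2.8 A from Glu OE1 across the interface
  lys <- build_peptide("K", chain = "A")
  glu <- build_peptide("E", chain = "B")
  nz <- coords(lys)[lys$atoms$name == "NZ", ]
  oe1 <- coords(glu)[glu$atoms$name == "OE1", ]
  glu <- set_coords(glu, sweep(coords(glu), 2, oe1 - nz - c(2.8, 0, 0)))
  pair <- structure3d(rbind(lys$atoms, glu$atoms))
  ct <- enumerate_contacts(pair, ab_partition())
  ele <- ct[ct$type == "Ele", ]
  expect_gte(nrow(ele), 1)
  expect_true(any(ele$salt_bridge))
})
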