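# Shared fixtures, built in code. The canonical toy dimer is a 14-residue
# antiparallel helix pair with one Lys/Glu salt bridge and three Leu/Leu
# hydrophobic contacts across the interface; its decoy flips protomer B so
# the engineered face points away.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixture_cache)) assign(name, force(expr), .fixture_cache)
  get(name, .fixture_cache)
}

toy_motifs <- function() {
  list(list(pos = c(5, 9), type = "salt-bridge"),
       list(pos = c(2, 12), type = "hydrophobic-contact"),
       list(pos = c(9, 5), type = "hydrophobic-contact"),
       list(pos = c(12, 2), type = "hydrophobic-contact"))
}

toy_spec <- function(...) {
  toy_dimer_spec(length = 14, scaffold = "helix-pair", motifs = toy_motifs(),
                 separation = 10, seed = 7, ...)
}

toy_dimer <- function() memo("toy_dimer", build_toy_dimer(toy_spec()))

toy_decoy <- function() memo("toy_decoy", make_decoy(
  toy_dimer(), axis = c(0, 0, 1), angle = 180, translation = c(4, 0, 0)))

# light quadrature for speed; acceptance tests use their stated settings
fast_cfg <- function(...) energy_config(n_points = 240, ...)

toy_matrix <- function() memo("toy_matrix",
  pairwise_decomposition(toy_dimer(), list("A", "B"), fast_cfg()))

toy_report <- function() memo("toy_report",
  characterize_interface(toy_dimer(), list("A", "B"), n_points = 240))

ab_partition <- function() list("A", "B")

# one-residue parameterized ions for analytic GB checks
ion_structure <- function(xyz, elements = rep("N", nrow(xyz)),
                          charges = rep(1, nrow(xyz)), radius = 1.55) {
  n <- nrow(xyz)
  atoms <- data.frame(chain = "A", resno = seq_len(n), icode = " ",
                      resname = "LYS", name = paste0("NZ", seq_len(n)),
                      element = elements, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], stringsAsFactors = FALSE)
  s <- structure3d(atoms)
  s$atoms$charge <- charges
  s$atoms$gb_radius <- radius
  s$atoms$screen <- 0.79
  s$atoms$lj_rmin2 <- 0
  s$atoms$lj_eps <- 0
  class(s) <- c("parameterized", class(s))
  s
}

# independent quaternion-method superposition oracle (Horn 1987)
quaternion_rmsd <- function(mobile, reference) {
  x <- sweep(mobile, 2, colMeans(mobile))
  y <- sweep(reference, 2, colMeans(reference))
  Sxx <- t(x) %*% y
  A <- matrix(0, 4, 4)
  A[1, 1] <- Sxx[1, 1] + Sxx[2, 2] + Sxx[3, 3]
  A[1, 2] <- A[2, 1] <- Sxx[2, 3] - Sxx[3, 2]
  A[1, 3] <- A[3, 1] <- Sxx[3, 1] - Sxx[1, 3]
  A[1, 4] <- A[4, 1] <- Sxx[1, 2] - Sxx[2, 1]
  A[2, 2] <- Sxx[1, 1] - Sxx[2, 2] - Sxx[3, 3]
  A[2, 3] <- A[3, 2] <- Sxx[1, 2] + Sxx[2, 1]
  A[2, 4] <- A[4, 2] <- Sxx[1, 3] + Sxx[3, 1]
  A[3, 3] <- -Sxx[1, 1] + Sxx[2, 2] - Sxx[3, 3]
  A[3, 4] <- A[4, 3] <- Sxx[2, 3] + Sxx[3, 2]
  A[4, 4] <- -Sxx[1, 1] - Sxx[2, 2] + Sxx[3, 3]
  lam <- max(eigen(A, symmetric = TRUE)$values)
  msd <- (sum(x^2) + sum(y^2) - 2 * lam) / nrow(x)
  sqrt(max(msd, 0))
}

rigid_move <- function(s, axis = c(1, 2, 3), angle = 33,
                       shift = c(5, -3, 2)) {
  R <- rotation_about_axis(axis, angle)
  set_coords(s, sweep(coords(s) %*% t(R), 2, shift, "+"))
}
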