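# Ideal amino-acid side-chain geometry templates (heavy atoms).
# Internal coordinates (bond lengths, valence angles, torsions) frozen from
# CCD ideal residue coordinates; torsions about chi axes are stored as
# offsets relative to the named chi angle so rotamers are generated by
# substituting chi values. Generated programmatically at development time.

.aa_geometry <- list(
  ALA = list(
    n_chi = 0L,
    atoms = data.frame(
      name = c("CB"),
      element = c("C"),
      parent = c("CA"),
      gparent = c("N"),
      ggparent = c("C"),
      bond = c(1.5294),
      angle = c(109.4645),
      torsion = c(-119.9991),
      chi = c(NA_integer_),
      stringsAsFactors = FALSE
    )
  ),
  ARG = list(
    n_chi = 4L,
    atoms = data.frame(
      name = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
      element = c("C", "C", "C", "N", "C", "N", "N"),
      parent = c("CA", "CB", "CG", "CD", "NE", "CZ", "CZ"),
      gparent = c("N", "CA", "CB", "CG", "CD", "NE", "NE"),
      ggparent = c("C", "N", "CA", "CB", "CG", "CD", "CD"),
      bond = c(1.5363, 1.5371, 1.5273, 1.4435, 1.4058, 1.3906, 1.3912),
      angle = c(111.5499, 114.5356, 112.4170, 111.0161, 123.0046, 120.9962, 119.8148),
      torsion = c(-123.5605, 0.0000, 0.0000, 0.0000, 0.0000, 179.9864, -0.0124),
      chi = c(NA_integer_, 1L, 2L, 3L, 4L, NA_integer_, NA_integer_),
      stringsAsFactors = FALSE
    )
  ),
  ASN = list(
    n_chi = 2L,
    atoms = data.frame(
      name = c("CB", "CG", "ND2", "OD1"),
      element = c("C", "C", "N", "O"),
      parent = c("CA", "CB", "CG", "CG"),
      gparent = c("N", "CA", "CB", "CB"),
      ggparent = c("C", "N", "CA", "CA"),
      bond = c(1.5309, 1.5066, 1.3476, 1.2133),
      angle = c(109.4540, 109.4843, 120.0120, 119.9743),
      torsion = c(-119.9959, 0.0000, -179.9261, 0.0000),
      chi = c(NA_integer_, 1L, 2L, 2L),
      stringsAsFactors = FALSE
    )
  ),
  ASP = list(
    n_chi = 2L,
    atoms = data.frame(
      name = c("CB", "CG", "OD1", "OD2"),
      element = c("C", "C", "O", "O"),
      parent = c("CA", "CB", "CG", "CG"),
      gparent = c("N", "CA", "CB", "CB"),
      ggparent = c("C", "N", "CA", "CA"),
      bond = c(1.5301, 1.5075, 1.2080, 1.3415),
      angle = c(109.4797, 109.4630, 119.9590, 119.9993),
      torsion = c(-120.0113, 0.0000, 0.0000, -179.9359),
      chi = c(NA_integer_, 1L, 2L, 2L),
      stringsAsFactors = FALSE
    )
  ),
  CYS = list(
    n_chi = 1L,
    atoms = data.frame(
      name = c("CB", "SG"),
      element = c("C", "S"),
      parent = c("CA", "CB"),
      gparent = c("N", "CA"),
      ggparent = c("C", "N"),
      bond = c(1.5285, 1.8141),
      angle = c(109.4957, 109.4981),
      torsion = c(-120.0138, 0.0000),
      chi = c(NA_integer_, 1L),
      stringsAsFactors = FALSE
    )
  ),
  GLN = list(
    n_chi = 3L,
    atoms = data.frame(
      name = c("CB", "CG", "CD", "NE2", "OE1"),
      element = c("C", "C", "C", "N", "O"),
      parent = c("CA", "CB", "CG", "CD", "CD"),
      gparent = c("N", "CA", "CB", "CG", "CG"),
      ggparent = c("C", "N", "CA", "CB", "CB"),
      bond = c(1.5288, 1.5284, 1.5066, 1.3471, 1.2122),
      angle = c(109.4592, 109.5344, 109.5426, 120.0933, 119.9367),
      torsion = c(-120.0663, 0.0000, 0.0000, -179.9568, 0.0000),
      chi = c(NA_integer_, 1L, 2L, 3L, 3L),
      stringsAsFactors = FALSE
    )
  ),
  GLU = list(
    n_chi = 3L,
    atoms = data.frame(
      name = c("CB", "CG", "CD", "OE1", "OE2"),
      element = c("C", "C", "C", "O", "O"),
      parent = c("CA", "CB", "CG", "CD", "CD"),
      gparent = c("N", "CA", "CB", "CG", "CG"),
      ggparent = c("C", "N", "CA", "CB", "CB"),
      bond = c(1.5302, 1.5306, 1.5076, 1.2084, 1.3425),
      angle = c(109.4824, 109.4016, 109.4303, 120.0030, 119.9977),
      torsion = c(-119.9555, 0.0000, 0.0000, 0.0000, -179.9373),
      chi = c(NA_integer_, 1L, 2L, 3L, 3L),
      stringsAsFactors = FALSE
    )
  ),
  GLY = list(
    n_chi = 0L,
    atoms = NULL
  ),
  HIS = list(
    n_chi = 2L,
    atoms = data.frame(
      name = c("CB", "CG", "CD2", "ND1", "NE2", "CE1"),
      element = c("C", "C", "C", "N", "N", "C"),
      parent = c("CA", "CB", "CG", "CG", "CD2", "ND1"),
      gparent = c("N", "CA", "CB", "CB", "CG", "CG"),
      ggparent = c("C", "N", "CA", "CA", "CB", "CB"),
      bond = c(1.5337, 1.5100, 1.3376, 1.3513, 1.3739, 1.3369),
      angle = c(111.1252, 112.9791, 129.9283, 120.3285, 105.3317, 107.8621),
      torsion = c(-122.7794, 0.0000, 179.8457, 0.0000, -179.8641, 179.9049),
      chi = c(NA_integer_, 1L, 2L, 2L, NA_integer_, NA_integer_),
      stringsAsFactors = FALSE
    )
  ),
  ILE = list(
    n_chi = 2L,
    atoms = data.frame(
      name = c("CB", "CG1", "CG2", "CD1"),
      element = c("C", "C", "C", "C"),
      parent = c("CA", "CB", "CB", "CG1"),
      gparent = c("N", "CA", "CA", "CB"),
      ggparent = c("C", "N", "N", "CA"),
      bond = c(1.5288, 1.5294, 1.5303, 1.5288),
      angle = c(109.4301, 109.5474, 109.4577, 109.5474),
      torsion = c(-120.0733, 0.0000, -119.9719, 0.0000),
      chi = c(NA_integer_, 1L, 1L, 2L),
      stringsAsFactors = FALSE
    )
  ),
  LEU = list(
    n_chi = 2L,
    atoms = data.frame(
      name = c("CB", "CG", "CD1", "CD2"),
      element = c("C", "C", "C", "C"),
      parent = c("CA", "CB", "CG", "CG"),
      gparent = c("N", "CA", "CB", "CB"),
      ggparent = c("C", "N", "CA", "CA"),
      bond = c(1.5286, 1.5303, 1.5300, 1.5285),
      angle = c(109.4163, 109.4950, 109.5000, 109.5008),
      torsion = c(-119.9728, 0.0000, 0.0000, 120.0918),
      chi = c(NA_integer_, 1L, 2L, 2L),
      stringsAsFactors = FALSE
    )
  ),
  LYS = list(
    n_chi = 4L,
    atoms = data.frame(
      name = c("CB", "CG", "CD", "CE", "NZ"),
      element = c("C", "C", "C", "C", "N"),
      parent = c("CA", "CB", "CG", "CD", "CE"),
      gparent = c("N", "CA", "CB", "CG", "CD"),
      ggparent = c("C", "N", "CA", "CB", "CG"),
      bond = c(1.5300, 1.5307, 1.5308, 1.5291, 1.4694),
      angle = c(109.4527, 109.4176, 109.4405, 109.4647, 109.5004),
      torsion = c(-119.9671, 0.0000, 0.0000, 0.0000, 0.0000),
      chi = c(NA_integer_, 1L, 2L, 3L, 4L),
      stringsAsFactors = FALSE
    )
  ),
  MET = list(
    n_chi = 3L,
    atoms = data.frame(
      name = c("CB", "CG", "SD", "CE"),
      element = c("C", "C", "S", "C"),
      parent = c("CA", "CB", "CG", "SD"),
      gparent = c("N", "CA", "CB", "CG"),
      ggparent = c("C", "N", "CA", "CB"),
      bond = c(1.5294, 1.5284, 1.8137, 1.8135),
      angle = c(109.4274, 109.5449, 109.5064, 100.0339),
      torsion = c(-120.0367, 0.0000, 0.0000, 0.0000),
      chi = c(NA_integer_, 1L, 2L, 3L),
      stringsAsFactors = FALSE
    )
  ),
  PHE = list(
    n_chi = 2L,
    atoms = data.frame(
      name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
      element = c("C", "C", "C", "C", "C", "C", "C"),
      parent = c("CA", "CB", "CG", "CG", "CD1", "CD2", "CE1"),
      gparent = c("N", "CA", "CB", "CB", "CG", "CG", "CD1"),
      ggparent = c("C", "N", "CA", "CA", "CB", "CB", "CG"),
      bond = c(1.5289, 1.5052, 1.3817, 1.3832, 1.3820, 1.3819, 1.3806),
      angle = c(109.4735, 109.5165, 120.0584, 120.0047, 120.0292, 119.9770, 120.0469),
      torsion = c(-120.0941, 0.0000, 0.0000, 179.7575, 179.9942, 179.8391, -0.0485),
      chi = c(NA_integer_, 1L, 2L, 2L, NA_integer_, NA_integer_, NA_integer_),
      stringsAsFactors = FALSE
    )
  ),
  PRO = list(
    n_chi = 0L,
    atoms = data.frame(
      name = c("CB", "CG", "CD"),
      element = c("C", "C", "C"),
      parent = c("CA", "CB", "CG"),
      gparent = c("N", "CA", "CB"),
      ggparent = c("C", "N", "CA"),
      bond = c(1.5434, 1.5426, 1.5437),
      angle = c(104.7219, 105.0594, 105.0631),
      torsion = c(-118.8407, -23.7996, 0.0255),
      chi = c(NA_integer_, NA_integer_, NA_integer_),
      stringsAsFactors = FALSE
    )
  ),
  SER = list(
    n_chi = 1L,
    atoms = data.frame(
      name = c("CB", "OG"),
      element = c("C", "O"),
      parent = c("CA", "CB"),
      gparent = c("N", "CA"),
      ggparent = c("C", "N"),
      bond = c(1.5287, 1.4283),
      angle = c(109.4711, 109.5115),
      torsion = c(-120.0204, 0.0000),
      chi = c(NA_integer_, 1L),
      stringsAsFactors = FALSE
    )
  ),
  THR = list(
    n_chi = 1L,
    atoms = data.frame(
      name = c("CB", "CG2", "OG1"),
      element = c("C", "C", "O"),
      parent = c("CA", "CB", "CB"),
      gparent = c("N", "CA", "CA"),
      ggparent = c("C", "N", "N"),
      bond = c(1.5290, 1.5301, 1.4280),
      angle = c(109.4115, 109.5255, 109.5053),
      torsion = c(-120.0002, -120.0308, 0.0000),
      chi = c(NA_integer_, 1L, 1L),
      stringsAsFactors = FALSE
    )
  ),
  TRP = list(
    n_chi = 2L,
    atoms = data.frame(
      name = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
      element = c("C", "C", "C", "C", "N", "C", "C", "C", "C", "C"),
      parent = c("CA", "CB", "CG", "CG", "CD1", "CD2", "CD2", "CE2", "CE3", "CZ2"),
      gparent = c("N", "CA", "CB", "CB", "CG", "CG", "CG", "CD2", "CD2", "CE2"),
      ggparent = c("C", "N", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CD2"),
      bond = c(1.5286, 1.5067, 1.3426, 1.4639, 1.3686, 1.4068, 1.3961, 1.3906, 1.3659, 1.3773),
      angle = c(109.5226, 109.4419, 126.4957, 126.5119, 109.9318, 106.0763, 134.0470, 119.3458, 119.7952, 119.8064),
      torsion = c(-120.0255, 0.0000, 0.0000, 179.6216, 179.9435, 179.9578, 0.7839, -179.8255, 179.6391, 0.2212),
      chi = c(NA_integer_, 1L, 2L, 2L, NA_integer_, NA_integer_, NA_integer_, NA_integer_, NA_integer_, NA_integer_),
      stringsAsFactors = FALSE
    )
  ),
  TYR = list(
    n_chi = 2L,
    atoms = data.frame(
      name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
      element = c("C", "C", "C", "C", "C", "C", "C", "O"),
      parent = c("CA", "CB", "CG", "CG", "CD1", "CD2", "CE1", "CZ"),
      gparent = c("N", "CA", "CB", "CB", "CG", "CG", "CD1", "CE1"),
      ggparent = c("C", "N", "CA", "CA", "CB", "CB", "CG", "CD1"),
      bond = c(1.5287, 1.5062, 1.3823, 1.3830, 1.3810, 1.3809, 1.3867, 1.3582),
      angle = c(109.4703, 109.4975, 119.9470, 119.9427, 120.0729, 120.0203, 119.9781, 120.1300),
      torsion = c(-120.0410, 0.0000, 0.0000, 179.6919, -179.9763, 179.7745, -0.1021, -179.9659),
      chi = c(NA_integer_, 1L, 2L, 2L, NA_integer_, NA_integer_, NA_integer_, NA_integer_),
      stringsAsFactors = FALSE
    )
  ),
  VAL = list(
    n_chi = 1L,
    atoms = data.frame(
      name = c("CB", "CG1", "CG2"),
      element = c("C", "C", "C"),
      parent = c("CA", "CB", "CB"),
      gparent = c("N", "CA", "CA"),
      ggparent = c("C", "N", "N"),
      bond = c(1.5287, 1.5299, 1.5292),
      angle = c(109.4452, 109.5086, 109.4895),
      torsion = c(-120.0037, 0.0000, 120.0257),
      chi = c(NA_integer_, 1L, 1L),
      stringsAsFactors = FALSE
    )
  )
)
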