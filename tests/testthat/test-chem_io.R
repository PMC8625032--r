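# Molecule container, SDF/PDB serialization, complex reading, and protein
# superposition.

test_that("molecule constructor enforces its invariants", {
  expect_error(molecule(character(), matrix(numeric(), 0, 3)),
               class = "templig_empty_molecule")
  expect_error(molecule("H", matrix(0, 1, 3)),
               class = "templig_empty_molecule")
  expect_error(molecule("C", matrix(c(0, 0, NA), 1, 3)),
               class = "templig_bad_molecule")
  expect_error(molecule(c("C", "C"), matrix(0, 2, 3),
                        data.frame(i = 1, j = 5, order = 1)),
               class = "templig_bad_molecule")
  m <- mk_ethanol()
  expect_equal(n_heavy(m), 3)
  expect_equal(mol_center(m), colMeans(m$xyz))
  expect_equal(mol_weight(m), 2 * 12.011 + 15.999 + 6 * 1.008,
               tolerance = 1e-6)
})

test_that("SDF round trip preserves coordinates, graph and charges", {
  m <- parse_smiles("CC(=O)[O-]", name = "acetate")
  back <- read_sdf(write_sdf(m))[[1]]
  expect_equal(back$elements, m$elements)
  expect_lt(max(abs(back$xyz - m$xyz)), 1e-3)
  expect_equal(back$bonds[order(back$bonds$i, back$bonds$j), ],
               m$bonds[order(m$bonds$i, m$bonds$j), ],
               ignore_attr = TRUE)
  expect_equal(back$charges, m$charges)
})

test_that("written SDF is readable by an independent parser", {
  m <- mk_ethanol()
  tmp <- tempfile(fileext = ".sdf")
  writeLines(write_sdf(m), tmp)
  sdfs <- ChemmineR::read.SDFset(tmp)
  ab <- ChemmineR::atomblock(sdfs[[1]])
  expect_equal(nrow(ab), 3)
  expect_lt(max(abs(ab[, 1:3] - m$xyz)), 1e-3)
  expect_equal(nrow(ChemmineR::bondblock(sdfs[[1]])), 2)
})

test_that("PDB serialization puts elements and coordinates in the right columns", {
  m <- mk_ethanol()
  txt <- strsplit(write_molecule(m, "pdb"), "\n")[[1]]
  het <- grep("^HETATM", txt, value = TRUE)
  expect_length(het, 3)
  # column oracle: x in 31-38, y 39-46, z 47-54, element 77-78
  expect_equal(as.numeric(substr(het, 31, 38)), m$xyz[, 1], tolerance = 1e-3)
  expect_equal(as.numeric(substr(het, 47, 54)), m$xyz[, 3], tolerance = 1e-3)
  expect_equal(trimws(substr(het, 77, 78)), c("C", "C", "O"))
  expect_error(write_molecule(m, "mol2"), class = "templig_bad_format")
})

test_that("read_complex separates protein and ligand and handles selectors", {
  lig <- mk_ethanol()
  pdb <- c(mk_ca_chain_pdb("ACDEFGHIKLMNPQRS"),
           mk_hetatm_lines(lig$xyz, lig$elements), "END")
  ce <- read_complex(pdb, pdb_id = "toy1")
  expect_s3_class(ce, "complex_entry")
  expect_equal(n_heavy(ce$ligand), 3)
  expect_equal(nrow(ce$protein$atoms), 16)
  expect_equal(ce$binding_site_center, mol_center(lig), tolerance = 1e-3)
  # perceived connectivity matches the known graph
  expect_equal(nrow(ce$ligand$bonds), 2)

  two <- c(mk_ca_chain_pdb("ACDEFGHIKLMNPQRS"),
           mk_hetatm_lines(lig$xyz, lig$elements, resname = "LG1", resno = 900),
           mk_hetatm_lines(lig$xyz + 20, lig$elements, resname = "LG2",
                           resno = 901, start_serial = 6000), "END")
  expect_error(read_complex(two), class = "templig_ambiguous_ligand")
  expect_equal(read_complex(two, ligand_selector = "LG2")$ligand$name, "LG2")

  water_only <- c(mk_ca_chain_pdb("ACDEFGHIKLMNPQRS"),
                  mk_hetatm_lines(matrix(c(5, 5, 5), 1), "O", resname = "HOH"),
                  "END")
  expect_error(read_complex(water_only), class = "templig_no_ligand")
})

test_that("match_proteins recovers known transforms", {
  lig <- mk_ethanol()
  pdb <- c(mk_ca_chain_pdb("ACDEFGHIKLMNPQRSTVWY"), "END")
  ref <- read_complex(c(pdb[-length(pdb)],
                        mk_hetatm_lines(lig$xyz, lig$elements), "END"))$protein
  expect_lt(max(abs(match_proteins(ref, ref)$rotation - diag(3))), 1e-6)

  worst <- 0
  for (s in 1:20) {
    set.seed(s)
    tf <- rigid_transform(templig:::rotvec_to_mat(runif(3, -pi, pi)),
                          runif(3, -10, 10))
    mob <- templig:::transform_protein(ref, tf)
    rec <- match_proteins(ref, mob)
    err <- max(abs(rec$rotation %*% tf$rotation - diag(3)))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-3)
})

test_that("unrelated random-sequence chains are unalignable", {
  set.seed(4)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  s1 <- paste(sample(aa, 30, replace = TRUE), collapse = "")
  s2 <- paste(sample(aa, 30, replace = TRUE), collapse = "")
  lig <- mk_ethanol()
  p1 <- read_complex(c(mk_ca_chain_pdb(s1),
                       mk_hetatm_lines(lig$xyz, lig$elements), "END"))$protein
  p2 <- read_complex(c(mk_ca_chain_pdb(s2),
                       mk_hetatm_lines(lig$xyz, lig$elements), "END"))$protein
  expect_error(match_proteins(p1, p2), class = "templig_unalignable")
})

test_that("transform composition is consistent over rigid copies", {
  lig <- mk_ethanol()
  pdb <- c(mk_ca_chain_pdb("ACDEFGHIKLMNPQRSTVWY"),
           mk_hetatm_lines(lig$xyz, lig$elements), "END")
  A <- read_complex(pdb)$protein
  set.seed(11)
  tAB <- rigid_transform(templig:::rotvec_to_mat(runif(3, -1, 1)), runif(3, -5, 5))
  tBC <- rigid_transform(templig:::rotvec_to_mat(runif(3, -1, 1)), runif(3, -5, 5))
  B <- templig:::transform_protein(A, tAB)
  C <- templig:::transform_protein(B, tBC)
  mAB <- match_proteins(A, B)   # maps B -> A
  mBC <- match_proteins(B, C)
  mAC <- match_proteins(A, C)
  comp <- compose_transforms(mAB, mBC)
  expect_lt(max(abs(comp$rotation - mAC$rotation)), 1e-4)
  expect_lt(max(abs(comp$translation - mAC$translation)), 1e-3)
})

test_that("rigid transforms validate and invert correctly", {
  expect_error(rigid_transform(diag(c(1, 1, -1))),
               class = "templig_bad_transform")
  set.seed(2)
  tf <- rigid_transform(templig:::rotvec_to_mat(runif(3)), runif(3))
  x <- matrix(rnorm(15), 5, 3)
  expect_equal(apply_transform(apply_transform(x, tf), invert_transform(tf)),
               x, tolerance = 1e-10)
})
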