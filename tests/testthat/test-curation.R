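# SASA burial against analytic and density-refined oracles, the ordered
# filter cascade, and per-protein grouping rules.

test_that("burial is zero without protein contact and near one in a closed cage", {
  lig <- toy_ligand(1)
  far <- protein_structure(data.frame(
    chain = "A", resno = 1:10, resname = "GLY", atom_name = "CA",
    element = "C", x = 500 + 1:10, y = 0, z = 0))
  expect_equal(burial_fraction(complex_entry(far, lig))$buried_fraction, 0)

  cage <- make_toy_pocket(lig, aperture_deg = 0)   # no opening
  b <- burial_fraction(complex_entry(cage, lig))
  expect_gt(b$buried_fraction, 0.9)
  expect_equal(b$delta_sasa, b$sasa_lig - b$sasa_lig_complex)
})

test_that("single-contact burial matches the spherical-cap formula", {
  probe <- 1.4
  r1 <- 1.70; r2 <- 1.70                # C vs C
  D <- r1 + r2                           # centers at contact distance
  lig <- mk_methane()
  prot <- protein_structure(data.frame(
    chain = "A", resno = 1, resname = "GLY", atom_name = "CA", element = "C",
    x = D, y = 0, z = 0))
  b <- burial_fraction(complex_entry(prot, lig), n_points = 1960L)
  R1 <- r1 + probe; R2 <- r2 + probe
  cos_theta <- (D^2 + R1^2 - R2^2) / (2 * D * R1)
  blocked_fraction <- (1 - cos_theta) / 2   # spherical cap area fraction
  expect_equal(b$buried_fraction, blocked_fraction, tolerance = 0.02)
})

test_that("burial agrees with a quadruple-density recomputation within 2%", {
  for (s in c(2, 14)) {
    lig <- toy_ligand(s)
    pocket <- make_toy_pocket(lig)
    entry <- complex_entry(pocket, lig)
    b1 <- burial_fraction(entry, n_points = 196L)$buried_fraction
    b4 <- burial_fraction(entry, n_points = 784L)$buried_fraction
    expect_lt(abs(b1 - b4), 0.02)
  }
})

test_that("the filter cascade discards each violation for its own reason", {
  mk_entry <- function(lig, pocket = make_toy_pocket(lig), id = "E") {
    complex_entry(pocket, lig, pdb_id = id, r_free = 0.2, uniprot_id = "P1")
  }
  good1 <- mk_entry(toy_ligand(1), id = "keep1")
  good2 <- mk_entry(toy_ligand(2), id = "keep2")
  good3 <- mk_entry(toy_ligand(3), id = "keep3")

  # covalent: ligand shifted onto a shell atom
  cov_lig <- toy_ligand(4)
  cov_pocket <- make_toy_pocket(cov_lig)
  pa <- as.matrix(cov_pocket$atoms[, c("x", "y", "z")])
  nearest <- which.min(rowSums(sweep(pa, 2, mol_center(cov_lig))^2))
  shift <- pa[nearest, ] - cov_lig$xyz[templig:::heavy_idx(cov_lig)[1], ]
  cov_lig$xyz <- sweep(cov_lig$xyz, 2, -(shift - c(1.4, 0, 0)))
  covalent <- mk_entry(cov_lig, cov_pocket, id = "cov")

  # another ligand sitting in the same pocket
  crowd <- toy_ligand(5)
  crowded <- mk_entry(crowd, id = "crowded")
  bystander <- toy_ligand(6)
  bystander$xyz <- sweep(bystander$xyz, 2,
                         mol_center(bystander) - mol_center(crowd) - c(3, 0, 0))

  # ligand touching two protein entities (snug shell within contact range)
  multi_lig <- toy_ligand(7)
  mp <- make_toy_pocket(multi_lig, gap = 0.3)
  half1 <- protein_structure(mp$atoms[seq(1, nrow(mp$atoms), 2), ])
  half2 <- protein_structure(mp$atoms[seq(2, nrow(mp$atoms), 2), ])
  multi <- complex_entry(half1, multi_lig, pdb_id = "multi", r_free = 0.2,
                         uniprot_id = "P1")

  small <- mk_entry(parse_smiles("CCCCCO"), id = "small")        # 6 heavy
  light <- mk_entry(parse_smiles("CCCCCCC"), id = "light")       # 100 Da
  heavy_mw <- parse_smiles("ICC(I)(I)CC(I)(I)CI")                # > 800 Da
  expect_gt(mol_weight(heavy_mw), 800)
  heavy <- mk_entry(heavy_mw, id = "heavy")

  exposed_lig <- toy_ligand(8)
  exposed <- mk_entry(exposed_lig,
                      make_toy_pocket(exposed_lig, aperture_deg = 130),
                      id = "exposed")
  expect_lt(burial_fraction(exposed)$buried_fraction, 0.5)

  reports <- list(
    filter_entry(good1), filter_entry(good2), filter_entry(good3),
    filter_entry(covalent),
    filter_entry(crowded, context = list(other_ligands = list(bystander))),
    filter_entry(multi, context = list(proteins = list(half1, half2))),
    filter_entry(small), filter_entry(light), filter_entry(heavy),
    filter_entry(exposed))
  verdicts <- vapply(reports, `[[`, character(1), "verdict")
  reasons <- vapply(reports, `[[`, character(1), "reason")
  expect_equal(verdicts, c(rep("keep", 3), rep("discard", 7)))
  expect_equal(reasons[4:10],
               c("covalent", "multi-ligand-pocket", "multi-protein-contact",
                 "heavy-atoms", "molecular-weight", "molecular-weight",
                 "burial"))
})

test_that("boundary semantics keep entries at the stated limits", {
  lig7 <- parse_smiles("CCCCCCCBr")   # 8 heavy; MW ~ 179
  expect_equal(filter_entry(complex_entry(make_toy_pocket(lig7), lig7,
                                          "b1", 0.2, "P1"))$verdict, "keep")
  # exactly 7 heavy atoms passes the heavy-atom rule
  lig_exact <- parse_smiles("CCCCCCBr")
  expect_equal(n_heavy(lig_exact), 7)
  rep7 <- filter_entry(complex_entry(make_toy_pocket(lig_exact), lig_exact,
                                     "b2", 0.2, "P1"))
  expect_false(rep7$reason == "heavy-atoms")
})

test_that("grouping keeps the major site and the lowest R-free duplicate", {
  lig <- toy_ligand(1)
  pocket <- make_toy_pocket(lig)
  entry_at <- function(offset, id, rf, smi = NULL) {
    l <- if (is.null(smi)) lig else parse_smiles(smi)
    l$xyz <- sweep(l$xyz, 2, -offset)
    complex_entry(pocket, l, pdb_id = id, r_free = rf, uniprot_id = "P1")
  }
  entries <- list(
    entry_at(c(0, 0, 0), "a1", 0.25),
    entry_at(c(1, 0, 0), "a2", 0.22),                    # same ligand, better
    entry_at(c(0, 1, 0), "a3", 0.30, "NCCOc1ccc(CC)cc1"),
    entry_at(c(30, 0, 0), "b1", 0.20),                   # minor distant site
    entry_at(c(30, 1, 0), "b2", 0.21, "CCOc1ccc(CCO)cc1"))
  libs <- group_and_select(entries)
  expect_named(libs, "P1")
  kept <- vapply(libs$P1, `[[`, character(1), "pdb_id")
  # major site (3 ligands) retained; duplicate resolved to lowest R-free
  expect_setequal(kept, c("a2", "a3"))
  # idempotence
  libs2 <- group_and_select(libs$P1)
  expect_equal(vapply(libs2$P1, `[[`, character(1), "pdb_id"), sort(kept))

  expect_equal(length(group_and_select(entries[1])$P1), 1L)
  no_key <- entries[[1]]; no_key$uniprot_id <- NA_character_
  expect_error(group_and_select(list(no_key)), class = "templig_ungroupable")
})
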