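# Empirical scoring terms against closed-form oracles, and local refinement
# behaviour (monotone improvement, stationarity, clash handling).

single_atom_protein <- function(element, xyz) {
  protein_structure(data.frame(chain = "A", resno = 1, resname = "GLY",
                               atom_name = "CA", element = element,
                               x = xyz[1], y = xyz[2], z = xyz[3]))
}

test_that("each distance-dependent term matches its closed form", {
  # ligand: single O (donor+acceptor, not hydrophobic); protein: single N
  lig_at <- function(r) molecule("O", matrix(c(r, 0, 0), 1, 3))
  prot <- single_atom_protein("N", c(0, 0, 0))
  radii <- c(O = 1.7, N = 1.8)
  for (r in c(2.8, 3.3, 4.1, 6.0)) {
    d <- r - radii["O"] - radii["N"]
    got <- score_pose(prot, lig_at(r))$terms
    expect_equal(unname(got["gauss1"]), unname(exp(-(d / 0.5)^2)), tolerance = 1e-12)
    expect_equal(unname(got["gauss2"]), unname(exp(-((d - 3) / 2)^2)), tolerance = 1e-12)
    expect_equal(unname(got["repulsion"]), unname(ifelse(d < 0, d^2, 0)), tolerance = 1e-12)
    expect_equal(unname(got["hydrophobic"]), 0)   # polar pair
    hb <- if (d <= -0.7) 1 else if (d < 0) d / -0.7 else 0
    expect_equal(unname(got["hbond"]), unname(hb), tolerance = 1e-12)
  }
  # hydrophobic pair: single C ligand vs single C protein
  protC <- single_atom_protein("C", c(0, 0, 0))
  for (r in c(3.8, 4.5, 5.0, 5.6)) {
    d <- r - 3.8
    got <- score_pose(protC, molecule("C", matrix(c(r, 0, 0), 1, 3)))$terms
    hyd <- if (d <= 0.5) 1 else if (d < 1.5) 1.5 - d else 0
    expect_equal(unname(got["hydrophobic"]), unname(hyd), tolerance = 1e-12)
    expect_equal(unname(got["hbond"]), 0)
  }
})

test_that("a far-away ligand scores only the torsion penalty", {
  lig <- parse_smiles("CCCO")
  lig$xyz <- lig$xyz + 100
  prot <- single_atom_protein("C", c(0, 0, 0))
  sc <- score_pose(prot, lig)
  expect_equal(unname(sc$terms[c("gauss1", "gauss2", "repulsion",
                                 "hydrophobic", "hbond")]),
               rep(0, 5))
  expect_equal(sc$total,
               unname(score_weights()["torsion"] * sc$terms["torsion"]))
})

test_that("overlap is penalized more than contact and totals are additive", {
  prot <- single_atom_protein("C", c(0, 0, 0))
  at_contact <- score_pose(prot, molecule("C", matrix(c(3.8, 0, 0), 1, 3)))
  overlapping <- score_pose(prot, molecule("C", matrix(c(1.0, 0, 0), 1, 3)))
  expect_gt(unname(overlapping$terms["repulsion"]), 0)
  expect_gt(overlapping$total, at_contact$total)
  fx <- toylib_identical()
  sc <- score_pose(fx$library$entries[[1]]$protein,
                   fx$library$entries[[1]]$ligand)
  expect_equal(sc$total, sum(sc$weights * sc$terms), tolerance = 1e-9)
})

test_that("scores are invariant under co-transformation of the complex", {
  fx <- toylib_identical()
  prot <- fx$library$entries[[1]]$protein
  lig <- fx$library$entries[[1]]$ligand
  set.seed(3)
  tf <- rigid_transform(templig:::rotvec_to_mat(runif(3, -2, 2)),
                        runif(3, -10, 10))
  s1 <- score_pose(prot, lig)$total
  s2 <- score_pose(templig:::transform_protein(prot, tf),
                   templig:::transform_molecule(lig, tf))$total
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("local refinement never worsens the score and is stationary at minima", {
  # smooth polar pair: the exact optimal separation is known by closed form
  w <- score_weights()
  obj <- function(r) {
    d <- r - 1.7 - 1.8
    w["gauss1"] * exp(-(d / 0.5)^2) + w["gauss2"] * exp(-((d - 3) / 2)^2) +
      w["hbond"] * ifelse(d <= -0.7, 1, ifelse(d < 0, d / -0.7, 0)) +
      w["repulsion"] * ifelse(d < 0, d^2, 0)
  }
  r_star <- stats::optimize(obj, c(2.8, 7))$minimum
  prot <- single_atom_protein("N", c(0, 0, 0))
  lig <- molecule("O", matrix(c(r_star, 0, 0), 1, 3))
  still <- local_refine(prot, lig)
  expect_lt(still$displacement, 0.05)
  expect_lt(abs(still$score$total - score_pose(prot, lig)$total), 1e-4)

  # a pocket pose refined at construction stays essentially in place
  fx <- toylib_identical()
  again <- local_refine(fx$library$entries[[1]]$protein,
                        fx$library$entries[[1]]$ligand)
  expect_lt(again$displacement, 0.05)

  # perturbed starts: monotone improvement in every case
  for (s in 1:5) {
    set.seed(s)
    start <- lig
    start$xyz <- start$xyz + matrix(rnorm(length(start$xyz), 0, 0.25),
                                    ncol = 3)
    start_total <- score_pose(prot, start)$total
    ref <- local_refine(prot, start)
    expect_lte(ref$score$total, start_total + 1e-6)
  }
})

test_that("a pose pushed into mild clash refines to a better score", {
  fx <- toylib_identical()
  prot <- fx$library$entries[[1]]$protein
  lig <- fx$library$entries[[1]]$ligand
  # translate 0.5 A toward the nearest wall atom to create a mild clash
  pa <- as.matrix(prot$atoms[, c("x", "y", "z")])
  nearest <- which.min(rowSums(sweep(pa, 2, mol_center(lig))^2))
  dirv <- pa[nearest, ] - mol_center(lig)
  dirv <- dirv / sqrt(sum(dirv^2))
  start <- lig
  start$xyz <- sweep(start$xyz, 2, -0.5 * dirv)
  start_total <- score_pose(prot, start)$total
  ref <- local_refine(prot, start)
  expect_lt(ref$score$total, start_total)
})

test_that("a ligand buried in a solid atom lattice is irrecoverable", {
  grid <- as.matrix(expand.grid(x = seq(-6, 6, by = 1.6),
                                y = seq(-6, 6, by = 1.6),
                                z = seq(-6, 6, by = 1.6)))
  core <- protein_structure(data.frame(
    chain = "A", resno = seq_len(nrow(grid)), resname = "GLY",
    atom_name = "CA", element = "C",
    x = grid[, 1], y = grid[, 2], z = grid[, 3]))
  lig <- mk_ethanol()
  lig$xyz <- sweep(lig$xyz, 2, colMeans(lig$xyz))  # centered in the core
  expect_error(local_refine(core, lig),
               class = "templig_irrecoverable_clash")
})
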