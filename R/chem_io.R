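# Molecular file I/O: SDF V2000 and PDB HETATM for small molecules, PDB
# parsing for protein-ligand complexes (via bio3d), and OpenBabel-backed
# SMILES parsing / canonicalization / initial 3D embedding.

# ---- SDF -------------------------------------------------------------------

#' Read molecules from an SDF (V2000) file or text
#'
#' @param input Path to an SDF file, or a character vector of SDF lines /
#'   one string containing the full text.
#' @return List of [molecule()] objects.
#' @export
read_sdf <- function(input) {
  lines <- if (length(input) == 1 && file.exists(input)) readLines(input, warn = FALSE)
  else unlist(strsplit(input, "\n", fixed = TRUE))
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "$$$$")))
  mols <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (length(rec) < 4) next
    counts <- rec[4]
    na <- as.integer(substr(counts, 1, 3))
    nb <- as.integer(substr(counts, 4, 6))
    if (is.na(na) || na < 1) next
    at <- rec[4 + seq_len(na)]
    xyz <- cbind(as.numeric(substr(at, 1, 10)),
                 as.numeric(substr(at, 11, 20)),
                 as.numeric(substr(at, 21, 30)))
    el <- sub("\\s+$", "", sub("^\\s+", "", substr(at, 32, 34)))
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
    if (nb > 0) {
      bl <- rec[4 + na + seq_len(nb)]
      bonds <- data.frame(i = as.integer(substr(bl, 1, 3)),
                          j = as.integer(substr(bl, 4, 6)),
                          order = as.numeric(substr(bl, 7, 9)))
    }
    charges <- integer(na)
    for (ln in grep("^M  CHG", rec, value = TRUE)) {
      f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
      nset <- f[1]
      for (k in seq_len(nset)) charges[f[2 * k]] <- f[2 * k + 1]
    }
    nm <- if (nzchar(trimws(rec[1]))) trimws(rec[1]) else NULL
    mols[[length(mols) + 1]] <- molecule(el, xyz, bonds, charges, name = nm)
  }
  mols
}

#' Write molecules to SDF (V2000) text
#'
#' @param mols A [molecule()] or list of molecules.
#' @param file Optional path; when given the text is also written there.
#' @return Character scalar of SDF text, invisibly when `file` is given.
#' @export
write_sdf <- function(mols, file = NULL) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  blocks <- vapply(mols, function(m) {
    n <- length(m$elements)
    hdr <- c(m$name %||% "templig", "  templig", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(m$bonds)))
    at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                  m$xyz[, 1], m$xyz[, 2], m$xyz[, 3], m$elements)
    bl <- if (nrow(m$bonds))
      sprintf("%3d%3d%3d  0  0  0  0", m$bonds$i, m$bonds$j, as.integer(m$bonds$order))
    else character()
    chg <- which(m$charges != 0)
    chgl <- if (length(chg))
      vapply(chg, function(i) sprintf("M  CHG  1 %3d %3d", i, m$charges[i]),
             character(1))
    else character()
    paste(c(hdr, at, bl, chgl, "M  END", "$$$$"), collapse = "\n")
  }, character(1))
  txt <- paste0(paste(blocks, collapse = "\n"), "\n")
  if (!is.null(file)) writeLines(txt, file, sep = "")
  if (is.null(file)) txt else invisible(txt)
}

#' Serialize a molecule to SDF or PDB text
#'
#' Round-trips through [read_sdf()] / [read_complex()] preserve heavy-atom
#' coordinates to 1e-3 Angstrom and the bond graph (SDF only; PDB records
#' carry no connectivity).
#'
#' @param mol A [molecule()].
#' @param format `"sdf"` or `"pdb"`.
#' @return Character scalar with the serialized text.
#' @export
write_molecule <- function(mol, format = c("sdf", "pdb")) {
  validate_molecule(mol)
  format <- tolower(format[1])
  if (format == "sdf") return(write_sdf(mol))
  if (format != "pdb")
    templig_abort(sprintf("unsupported format '%s'", format), "templig_bad_format")
  lines <- sprintf(
    "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_along(mol$elements),
    substr(paste0(mol$elements, seq_along(mol$elements)), 1, 4),
    "LIG", "A", 1L, mol$xyz[, 1], mol$xyz[, 2], mol$xyz[, 3], 1, 0,
    toupper(mol$elements))
  paste(c(lines, "END"), collapse = "\n")
}

# ---- RDKit bridge ----------------------------------------------------------
# SMILES interpretation, canonicalization and deterministic 3D embedding
# (distance geometry + force-field relaxation) are delegated to RDKit
# through a small Python helper; results are cached per input so repeated
# fixture construction costs one subprocess per unique molecule.

.templig_cache <- new.env(parent = emptyenv())

rdkit_script <- function() {
  p <- system.file("python", "rdkit_bridge.py", package = "templig")
  if (!nzchar(p) || !file.exists(p))
    templig_abort("rdkit_bridge.py not found in the installed package",
                  "templig_no_rdkit")
  p
}

rdkit_run <- function(args, input) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    templig_abort("python not found on PATH (RDKit required)",
                  "templig_no_rdkit")
  out <- suppressWarnings(system2(py, c(shQuote(rdkit_script()), args),
                                  stdout = TRUE, stderr = FALSE,
                                  input = input))
  status <- attr(out, "status") %||% 0L
  list(status = status, text = paste(out, collapse = "\n"))
}

# Deterministic multi-conformer embedding; returns a list of molecules
# sharing one graph (SDF records). max_confs = 1 gives the single base
# geometry.
rdkit_embed <- function(smiles, max_confs = 1L, seed = 1L) {
  key <- paste0("embed|", smiles, "|", max_confs, "|", seed)
  hit <- .templig_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- rdkit_run(c("--mode", "embed", "--max-confs", max_confs,
                     "--seed", seed), input = smiles)
  if (res$status == 2L)
    templig_abort(sprintf("cannot parse SMILES '%s'", smiles),
                  "templig_bad_smiles")
  if (res$status != 0L || !nzchar(trimws(res$text)))
    templig_abort(sprintf("3D embedding failed for SMILES '%s'", smiles),
                  "templig_embed_failure")
  mols <- read_sdf(res$text)
  if (!length(mols))
    templig_abort(sprintf("3D embedding failed for SMILES '%s'", smiles),
                  "templig_embed_failure")
  .templig_cache[[key]] <- mols
  mols
}

#' Parse a SMILES string into a 3D molecule
#'
#' The SMILES is interpreted and embedded in 3D (distance geometry with a
#' fixed random seed, force-field relaxed) via RDKit; explicit hydrogens are
#' present in the result. Identical input gives bit-identical coordinates.
#'
#' @param smiles SMILES string.
#' @param name Optional molecule name.
#' @return A [molecule()] with 3D coordinates; the source SMILES is stored.
#' @export
parse_smiles <- function(smiles, name = NULL) {
  m <- rdkit_embed(smiles, max_confs = 1L, seed = 42L)[[1]]
  m$smiles <- smiles
  m$name <- name
  m
}

#' Canonical SMILES of a molecule
#'
#' @param mol A [molecule()] (or a SMILES string).
#' @return Canonical SMILES string (RDKit canonicalization).
#' @export
canonical_smiles <- function(mol) {
  if (is.character(mol)) {
    key <- paste0("can|", mol)
    hit <- .templig_cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- rdkit_run(c("--mode", "canonical"), input = mol)
  } else if (length(mol$smiles) && nzchar(mol$smiles)) {
    return(canonical_smiles(mol$smiles))
  } else {
    key <- NULL
    res <- rdkit_run(c("--mode", "canonical-molblock"), input = write_sdf(mol))
  }
  if (res$status != 0L || !nzchar(trimws(res$text)))
    templig_abort("cannot canonicalize molecule", "templig_bad_smiles")
  out <- trimws(res$text)
  if (!is.null(key)) .templig_cache[[key]] <- out
  out
}

# ---- Proteins and complexes ------------------------------------------------

#' Protein structure container
#'
#' Atom records grouped by chain and residue, with per-chain alpha-carbon
#' coordinates and one-letter sequences derived from residue names.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resname`,
#'   `atom_name`, `element`, `x`, `y`, `z`.
#' @return Object of class `protein_structure`.
#' @export
protein_structure <- function(atoms) {
  need <- c("chain", "resno", "resname", "atom_name", "element", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("Protein structure: %d atoms, %d chain(s) [%s], %d residues\n",
              nrow(x$atoms), length(ch), paste(ch, collapse = ","),
              nrow(unique(x$atoms[, c("chain", "resno")]))))
  invisible(x)
}

protein_xyz <- function(p) as.matrix(p$atoms[, c("x", "y", "z")])

protein_chains <- function(p) unique(p$atoms$chain)

# Per-chain CA table: resno, xyz, one-letter code.
chain_ca <- function(p, chain) {
  a <- p$atoms[p$atoms$chain == chain & p$atoms$atom_name == "CA", , drop = FALSE]
  a <- a[!duplicated(a$resno), , drop = FALSE]
  a$aa <- bio3d::aa321(a$resname)
  a$aa[is.na(a$aa) | a$aa == ""] <- "X"
  a
}

transform_protein <- function(p, tf) {
  xyz <- apply_transform(protein_xyz(p), tf)
  p$atoms$x <- xyz[, 1]; p$atoms$y <- xyz[, 2]; p$atoms$z <- xyz[, 3]
  p
}

#' Residue names excluded from automatic ligand extraction
#'
#' Water, monoatomic ions and common crystallization additives; the set is
#' user-extensible because deposition practice varies.
#'
#' @return Character vector of residue names.
#' @export
default_het_exclusions <- function() {
  c("HOH", "WAT", "DOD", "NA", "K", "CL", "MG", "CA", "ZN", "MN", "FE",
    "CO", "NI", "CU", "CD", "HG", "BR", "IOD", "F",
    "SO4", "PO4", "GOL", "EDO", "ACT", "DMS", "PEG", "MPD", "TRS", "FMT",
    "NO3", "BME", "IMD", "ACY")
}

# Distance-based bond perception for ligands extracted from PDB records:
# a bond exists when the interatomic distance is below the sum of covalent
# radii plus a tolerance. All orders are set to 1 (PDB carries no orders).
perceive_bonds <- function(elements, xyz, tol = 0.45) {
  n <- length(elements)
  if (n < 2) return(data.frame(i = integer(), j = integer(), order = numeric()))
  r <- element_property(elements, "covalent", 0.76)
  d <- as.matrix(stats::dist(xyz))
  lim <- outer(r, r, "+") + tol
  hit <- which(d < lim & upper.tri(d), arr.ind = TRUE)
  hit <- hit[d[hit] > 0.4, , drop = FALSE]   # guard against duplicate atoms
  data.frame(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]),
             order = rep(1, nrow(hit)))
}

#' Complex entry: one protein with one co-bound ligand
#'
#' @param protein A [protein_structure()].
#' @param ligand A [molecule()] in the crystal pose.
#' @param pdb_id Identifier string.
#' @param r_free Crystallographic R-free, or `NA`.
#' @param uniprot_id Protein accession used for grouping, or `NA`.
#' @return Object of class `complex_entry`; `binding_site_center` is the
#'   geometric center of the ligand heavy atoms.
#' @export
complex_entry <- function(protein, ligand, pdb_id = "none", r_free = NA_real_,
                          uniprot_id = NA_character_) {
  validate_molecule(ligand)
  structure(list(protein = protein, ligand = ligand, pdb_id = pdb_id,
                 r_free = r_free, uniprot_id = uniprot_id,
                 binding_site_center = mol_center(ligand)),
            class = "complex_entry")
}

#' @export
print.complex_entry <- function(x, ...) {
  cat(sprintf("Complex %s: %d protein atoms, ligand %d heavy atoms, site (%.1f, %.1f, %.1f)\n",
              x$pdb_id, nrow(x$protein$atoms), n_heavy(x$ligand),
              x$binding_site_center[1], x$binding_site_center[2],
              x$binding_site_center[3]))
  invisible(x)
}

#' Read a protein-ligand complex from PDB text
#'
#' Separates ATOM records into a [protein_structure()] and extracts one
#' HETATM group as the ligand. With `ligand_selector = "auto"` exactly one
#' candidate group (after removing waters/ions/buffers) must be present.
#'
#' @param pdb_text PDB-format text (single string or vector of lines), or a
#'   path to a PDB file.
#' @param ligand_selector Residue name of the ligand, or `"auto"`.
#' @param exclude Residue names never considered ligands.
#' @param pdb_id Identifier stored on the entry.
#' @param r_free,uniprot_id Optional metadata.
#' @return A [complex_entry()].
#' @export
read_complex <- function(pdb_text, ligand_selector = "auto",
                         exclude = default_het_exclusions(),
                         pdb_id = "none", r_free = NA_real_,
                         uniprot_id = NA_character_) {
  path <- if (length(pdb_text) == 1 && !grepl("\n", pdb_text) &&
              file.exists(pdb_text)) {
    pdb_text
  } else {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n")), tmp)
    tmp
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(prot))
    templig_abort("no protein ATOM records", "templig_no_protein")
  protein <- protein_structure(data.frame(
    chain = prot$chain, resno = prot$resno, resname = prot$resid,
    atom_name = prot$elety,
    element = normalize_element(ifelse(is.na(prot$elesy) | prot$elesy == "",
                                       substr(prot$elety, 1, 1), prot$elesy)),
    x = prot$x, y = prot$y, z = prot$z))
  het <- at[at$type == "HETATM", , drop = FALSE]
  het <- het[!het$resid %in% exclude, , drop = FALSE]
  if (ligand_selector != "auto")
    het <- het[het$resid == ligand_selector, , drop = FALSE]
  if (!nrow(het))
    templig_abort("no candidate ligand found", "templig_no_ligand")
  grp <- paste(het$chain, het$resno, het$resid)
  groups <- unique(grp)
  if (ligand_selector == "auto" && length(groups) > 1)
    templig_abort(sprintf("multiple candidate ligands: %s",
                          paste(groups, collapse = "; ")),
                  "templig_ambiguous_ligand")
  lig <- het[grp == groups[1], , drop = FALSE]
  el <- normalize_element(ifelse(is.na(lig$elesy) | lig$elesy == "",
                                 substr(lig$elety, 1, 1), lig$elesy))
  xyz <- cbind(lig$x, lig$y, lig$z)
  ligand <- molecule(el, xyz, perceive_bonds(el, xyz),
                     name = lig$resid[1])
  complex_entry(protein, ligand, pdb_id = pdb_id, r_free = r_free,
                uniprot_id = uniprot_id)
}

# ---- Protein matching ------------------------------------------------------

blosum62 <- function() {
  hit <- .templig_cache[["BLOSUM62"]]
  if (!is.null(hit)) return(hit)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  .templig_cache[["BLOSUM62"]] <- e$BLOSUM62
  e$BLOSUM62
}

align_chain_pair <- function(ca_ref, ca_mob, gap_open = 10, gap_ext = 4) {
  sub <- blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(ca_mob$aa, collapse = "")),
    Biostrings::AAString(paste(ca_ref$aa, collapse = "")),
    substitutionMatrix = sub, gapOpening = gap_open, gapExtension = gap_ext,
    type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  subj <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  im <- ir <- 0L
  pairs <- matrix(integer(), ncol = 2)
  ident <- 0L
  for (k in seq_along(pat)) {
    if (pat[k] != "-") im <- im + 1L
    if (subj[k] != "-") ir <- ir + 1L
    if (pat[k] != "-" && subj[k] != "-") {
      pairs <- rbind(pairs, c(im, ir))
      if (pat[k] == subj[k]) ident <- ident + 1L
    }
  }
  list(score = Biostrings::score(pa), pairs = pairs,
       identity = if (nrow(pairs)) ident / nrow(pairs) else 0)
}

#' Superpose one protein onto another
#'
#' Chains are paired by global sequence alignment (BLOSUM62); the rigid
#' transform minimizing the least-squares deviation over aligned alpha
#' carbons is returned. Optional iterative pruning drops poorly fitting CA
#' pairs (beyond 2 standard deviations of the pair distances) and refits.
#'
#' @param reference,mobile [protein_structure()] objects.
#' @param min_aligned Minimum number of aligned CA pairs (default 8).
#' @param min_identity Minimum sequence identity over aligned positions.
#' @param prune Iteratively prune poorly fitting pairs (default `FALSE`).
#' @return A [rigid_transform()] mapping `mobile` into the frame of
#'   `reference`.
#' @export
match_proteins <- function(reference, mobile, min_aligned = 8,
                           min_identity = 0.2, prune = FALSE) {
  ref_ch <- protein_chains(reference)
  mob_ch <- protein_chains(mobile)
  cand <- expand.grid(ref = ref_ch, mob = mob_ch, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cand)), function(k) {
    cr <- chain_ca(reference, cand$ref[k])
    cm <- chain_ca(mobile, cand$mob[k])
    if (nrow(cr) < 2 || nrow(cm) < 2) return(NULL)
    al <- align_chain_pair(cr, cm)
    list(ref = cand$ref[k], mob = cand$mob[k], al = al, cr = cr, cm = cm)
  })
  res <- Filter(Negate(is.null), res)
  if (!length(res))
    templig_abort("no alignable chains", "templig_unalignable")
  ord <- order(vapply(res, function(r) -r$al$score, numeric(1)))
  used_ref <- used_mob <- character()
  P <- Q <- NULL
  ident_n <- ident_tot <- 0
  for (r in res[ord]) {
    if (r$ref %in% used_ref || r$mob %in% used_mob) next
    if (r$al$identity < min_identity) next
    used_ref <- c(used_ref, r$ref); used_mob <- c(used_mob, r$mob)
    pr <- r$al$pairs
    Q <- rbind(Q, as.matrix(r$cr[pr[, 2], c("x", "y", "z")]))
    P <- rbind(P, as.matrix(r$cm[pr[, 1], c("x", "y", "z")]))
    ident_n <- ident_n + r$al$identity * nrow(pr); ident_tot <- ident_tot + nrow(pr)
  }
  if (is.null(P) || nrow(P) < min_aligned)
    templig_abort("too few aligned residues to superpose", "templig_unalignable")
  tf <- kabsch(P, Q)
  if (prune) {
    repeat {
      d <- sqrt(rowSums((apply_transform(P, tf) - Q)^2))
      keep <- d <= mean(d) + 2 * sd(d)
      if (all(keep) || sum(keep) < min_aligned) break
      P <- P[keep, , drop = FALSE]; Q <- Q[keep, , drop = FALSE]
      tf <- kabsch(P, Q)
    }
  }
  tf
}
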