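#' @title Synthetic fixtures
#' @description Deterministic generators for every input the pipeline
#'   needs: toy protein-ligand complexes with planted interactions, toy
#'   target libraries, synthetic activity datasets, and decoy sets. The
#'   receptors are ideal-geometry short peptides written directly in PDB
#'   format -- geometric interaction tests need exact control, not realism.
#'   Every generator is a pure function of its arguments and seed.
#' @name synthetic-fixtures
NULL

# Residue anchors sit on the x axis at 12 Angstrom spacing; all planted
# ligand atoms stay within ~4 Angstrom of their own anchor laterally, so no
# interaction criterion (largest cutoff 6 Angstrom) can reach a neighbour.
FIXTURE_SPACING <- 12

# Local atom templates (offsets from the residue anchor). Backbone amide
# N-H points +y, carbonyl C=O points -y, side chains grow along +z toward
# the ligand.
.res_template <- function(resname) {
  bb <- list(
    N = c(0.00, 1.50, 0.00), H = c(0.00, 2.50, 0.00),
    CA = c(0.00, 0.00, 0.00), C = c(1.50, -0.50, 0.00),
    O = c(1.50, -1.73, 0.00)
  )
  sc <- switch(resname,
    GLY = list(),
    ALA = list(CB = c(0.00, -0.70, 1.40)),
    LYS = list(CB = c(0.00, -0.70, 1.40), CG = c(0.00, -0.70, 2.90),
               CD = c(0.00, -0.70, 4.30), CE = c(0.00, -0.70, 5.70),
               NZ = c(0.00, -0.70, 7.00), HZ1 = c(0.00, -0.70, 8.00)),
    ASP = list(CB = c(0.00, -0.70, 1.40), CG = c(0.00, -0.70, 2.80),
               OD1 = c(0.00, -0.70, 4.00), OD2 = c(1.15, -0.70, 2.90)),
    PHE = {
      cen <- c(0.00, -0.70, 4.30)
      ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      ring <- lapply(seq_along(ring_names), function(k) {
        th <- (k - 1) * pi / 3
        cen + 1.39 * c(cos(th), sin(th), 0)
      })
      names(ring) <- ring_names
      c(list(CB = c(0.00, -0.70, 1.60)), ring)
    },
    stop("no fixture template for residue ", resname)
  )
  c(bb, sc)
}

.fmt_pdb_atom <- function(serial, name, resname, chain, resno, xyz,
                          record = "ATOM") {
  element <- if (resname %in% METAL_RES) resname else
    substr(gsub("[0-9]", "", name), 1, 1)
  name_field <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_field, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
}

# Interaction type -> residue type carrying it.
.plant_residue <- c(
  hydrophobic = "ALA", aromatic_face = "PHE", aromatic_edge = "PHE",
  hb_protein_acceptor = "GLY", hb_protein_donor = "GLY",
  salt_bridge_protein_positive = "LYS", salt_bridge_protein_negative = "ASP",
  metal_contact = "ZN"
)

# Ligand atoms realizing one planted interaction, in the residue's local
# frame. Geometries chosen to satisfy exactly one scheme-v1 criterion.
.plant_ligand <- function(type) {
  atom <- function(element, xyz, charge = 0, aromatic = FALSE,
                   donor = FALSE, acceptor = FALSE) {
    data.frame(element = element, x = xyz[1], y = xyz[2], z = xyz[3],
               charge = charge, aromatic = aromatic, donor = donor,
               acceptor = acceptor, stringsAsFactors = FALSE)
  }
  switch(type,
    hydrophobic = list(atoms = atom("C", c(0, -0.70, 5.20)), rings = list()),
    hb_protein_donor = list(atoms = atom("O", c(0, 4.40, 0), acceptor = TRUE),
                            rings = list()),
    hb_protein_acceptor = list(
      atoms = rbind(atom("N", c(1.50, -4.63, 0), donor = TRUE),
                    atom("H", c(1.50, -3.63, 0))),
      rings = list()),
    salt_bridge_protein_positive = list(
      # carboxylate-like O- placed 3.8 A from LYS NZ: inside the 4.0 A salt
      # bridge cutoff, outside the 3.5 A H-bond cutoff
      atoms = atom("O", c(0, -0.70, 10.80), charge = -1, acceptor = TRUE),
      rings = list()),
    salt_bridge_protein_negative = list(
      # quaternary ammonium (no N-H): charge criterion only
      atoms = atom("N", c(0, -0.70, 7.80), charge = 1),
      rings = list()),
    metal_contact = list(atoms = atom("O", c(0, 0, 4.10)), rings = list()),
    aromatic_face = {
      cen <- c(0, -0.70, 4.30 + 3.80)
      atoms <- do.call(rbind, lapply(0:5, function(k) {
        th <- k * pi / 3 + pi / 6  # 30 degree phase offset
        atom("C", cen + 1.39 * c(cos(th), sin(th), 0), aromatic = TRUE)
      }))
      list(atoms = atoms, rings = list(1:6))
    },
    aromatic_edge = {
      cen <- c(0, -0.70, 4.30 + 5.00)
      tilt <- 60 * pi / 180  # ring tilted about x: interplanar angle 60
      ey <- c(0, cos(tilt), sin(tilt))
      atoms <- do.call(rbind, lapply(0:5, function(k) {
        th <- k * pi / 3
        atom("C", cen + 1.39 * (cos(th) * c(1, 0, 0) + sin(th) * ey),
             aromatic = TRUE)
      }))
      list(atoms = atoms, rings = list(1:6))
    },
    stop("unknown interaction type: ", type)
  )
}

#' Generate a toy protein-ligand complex with planted interactions
#'
#' Builds a short ideal-geometry peptide (alanine padding plus one residue
#' per planted interaction) and a ligand pose positioned so that
#' [extract_ifp()] recovers exactly the planted interaction bits under
#' scheme v1. Residues sit 12 Angstrom apart, far beyond every criterion
#' cutoff, so interactions never bleed across residues.
#'
#' @param planted data.frame with columns `residue` (1-based index into the
#'   receptor chain) and `type` (one of the scheme-v1 slot names), or NULL
#'   for a contact-free complex.
#' @param n_residues Chain length (default covers all planted residues,
#'   minimum 12; valid range 10-30).
#' @param pdb_path Where to write the receptor PDB.
#' @param id Receptor / complex identifier.
#' @return List with `receptor` (parsed), `pose` ([ligand_pose()]),
#'   `pdb_path`, and `expected` (logical residue x slot matrix of the
#'   planted bits).
#' @export
#' @examples
#' \donttest{
#' cx <- generate_complex(data.frame(residue = 7, type = "hb_protein_donor"),
#'                        pdb_path = tempfile(fileext = ".pdb"))
#' ifp <- extract_ifp(cx$receptor, cx$pose)
#' identical(unname(ifp$bits), unname(cx$expected))
#' }
generate_complex <- function(planted = NULL,
                             n_residues = NULL,
                             pdb_path = tempfile(fileext = ".pdb"),
                             id = "SYN0") {
  if (is.null(planted) || nrow(planted) == 0L) {
    planted <- data.frame(residue = integer(), type = character())
  }
  stopifnot(all(c("residue", "type") %in% names(planted)))
  planted$type <- as.character(planted$type)
  bad <- setdiff(planted$type, names(.plant_residue))
  if (length(bad)) stop("unknown interaction type(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(planted$residue)) {
    stop("at most one planted interaction per residue in fixtures")
  }
  if (is.null(n_residues)) {
    n_residues <- max(12L, if (nrow(planted)) max(planted$residue) + 1L else 0L)
  }
  if (n_residues < 10L || n_residues > 30L) {
    stop("fixture receptors span 10-30 residues")
  }
  if (nrow(planted) && max(planted$residue) > n_residues) {
    stop("planted residue index exceeds chain length")
  }

  lines <- character(0)
  serial <- 0L
  lig_atoms <- NULL
  lig_rings <- list()
  expected <- matrix(FALSE, n_residues, length(IFP_SLOTS),
                     dimnames = list(NULL, IFP_SLOTS))

  for (i in seq_len(n_residues)) {
    anchor <- c((i - 1) * FIXTURE_SPACING, 0, 0)
    hit <- planted[planted$residue == i, , drop = FALSE]
    resname <- if (nrow(hit)) unname(.plant_residue[hit$type]) else "ALA"
    if (resname == "ZN") {
      serial <- serial + 1L
      lines <- c(lines, .fmt_pdb_atom(serial, "ZN", "ZN", "A", i,
                                      anchor + c(0, 0, 2.0), record = "HETATM"))
    } else {
      tmpl <- .res_template(resname)
      for (nm in names(tmpl)) {
        serial <- serial + 1L
        lines <- c(lines, .fmt_pdb_atom(serial, nm, resname, "A", i,
                                        anchor + tmpl[[nm]]))
      }
    }
    if (nrow(hit)) {
      plant <- .plant_ligand(hit$type)
      plant$atoms$x <- plant$atoms$x + anchor[1]
      offset <- if (is.null(lig_atoms)) 0L else nrow(lig_atoms)
      lig_rings <- c(lig_rings, lapply(plant$rings, function(r) r + offset))
      lig_atoms <- if (is.null(lig_atoms)) plant$atoms else
        rbind(lig_atoms, plant$atoms)
      expected[i, hit$type] <- TRUE
    }
  }
  if (is.null(lig_atoms)) {
    # contact-free ligand: a single carbon far above the chain
    lig_atoms <- data.frame(element = "C", x = 0, y = 0, z = 50,
                            charge = 0, aromatic = FALSE, donor = FALSE,
                            acceptor = FALSE, stringsAsFactors = FALSE)
  }
  pose <- ligand_pose(lig_atoms, lig_rings)

  # clash guard: no ligand heavy atom closer than 1.5 A to any receptor atom
  writeLines(c(lines, "END"), pdb_path)
  receptor <- parse_receptor(pdb_path, id = id)
  pxyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  lh <- pose$atoms[pose$atoms$element != "H", c("x", "y", "z"), drop = FALSE]
  dmin <- min(apply(as.matrix(lh), 1, function(p) {
    min(sqrt(colSums((t(pxyz) - p)^2)))
  }))
  if (dmin < 1.5) stop("unsatisfiable planted geometry: atom clash at ",
                       round(dmin, 2), " Angstrom")

  list(receptor = receptor, pose = pose, pdb_path = pdb_path,
       expected = expected)
}

# ---------------------------------------------------------------------------
# SMILES pools with controlled pairwise similarity
# ---------------------------------------------------------------------------

# Four chemically disjoint families; within a family consecutive members are
# close homologues (high Morgan Tanimoto), across families similarity is
# low. Verified by the generator itself (constraints checked at build time).
FIXTURE_FAMILIES <- list(
  sulfonamide = c("NS(=O)(=O)c1ccc(CCCC)cc1", "NS(=O)(=O)c1ccc(CCCCC)cc1",
                  "NS(=O)(=O)c1ccc(CCCCCC)cc1", "NS(=O)(=O)c1ccc(CCCCCCC)cc1"),
  fatty_acid = c("CCCCCCCCCC(=O)O", "CCCCCCCCCCC(=O)O",
                 "CCCCCCCCCCCC(=O)O", "CCCCCCCCCCCCC(=O)O"),
  aminopyrimidine = c("Nc1ccnc(NCCCCC)n1", "Nc1ccnc(NCCCCCC)n1",
                      "Nc1ccnc(NCCCCCCC)n1", "Nc1ccnc(NCCCCCCCC)n1"),
  glycol_ether = c("OCCOCCOCCO", "OCCOCCOCCOCCO",
                   "OCCOCCOCCOCCOCCO", "COCCOCCOCCO")
)

# Interaction patterns cycled over library entries so reference IFPs differ.
.library_patterns <- list(
  data.frame(residue = c(3, 7), type = c("hydrophobic", "hb_protein_donor")),
  data.frame(residue = c(4, 8), type = c("aromatic_face", "salt_bridge_protein_positive")),
  data.frame(residue = c(3, 9), type = c("hb_protein_acceptor", "metal_contact")),
  data.frame(residue = c(5, 10), type = c("aromatic_edge", "salt_bridge_protein_negative"))
)

#' Generate a toy target library
#'
#' Builds `n_classes * n_targets_per_class` synthetic complexes, one per
#' target. Each class draws its co-crystal ligands from one chemical family
#' of close homologues, so within-class ligand similarity is high and
#' cross-class similarity low; the generator verifies that the first two
#' ligands of each class have Morgan Tanimoto >= 0.7 (the near-duplicate
#' pair) and that all cross-class pairs stay <= 0.3, and fails otherwise.
#' Activities are drawn from a seeded normal around typical -log M values.
#'
#' @param dir Output directory (receptor PDBs, ligand pose JSONs, manifest
#'   CSV are written here).
#' @param n_classes Number of target classes (1-4).
#' @param n_targets_per_class Targets per class (1-4).
#' @param algorithms Fingerprint algorithms for the library.
#' @param seed Integer seed.
#' @return A `target_library` (see [build_library()]); the manifest path is
#'   attached as attribute `manifest`.
#' @export
generate_library <- function(dir = tempfile("lib"),
                             n_classes = 2L, n_targets_per_class = 2L,
                             algorithms = fp_preset("MMD"), seed = 1L) {
  stopifnot(n_classes >= 1L, n_classes <= length(FIXTURE_FAMILIES),
            n_targets_per_class >= 1L, n_targets_per_class <= 4L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  classes <- names(FIXTURE_FAMILIES)[seq_len(n_classes)]
  set.seed(seed)

  rows <- list()
  k <- 0L
  for (ci in seq_along(classes)) {
    family <- FIXTURE_FAMILIES[[classes[ci]]]
    for (ti in seq_len(n_targets_per_class)) {
      k <- k + 1L
      pdb_id <- sprintf("SYN%d", k)
      planted <- .library_patterns[[(k - 1L) %% length(.library_patterns) + 1L]]
      cx <- generate_complex(planted,
                             pdb_path = file.path(dir, paste0(pdb_id, ".pdb")),
                             id = pdb_id)
      smiles <- family[(ti - 1L) %% length(family) + 1L]
      lig_path <- file.path(dir, paste0(pdb_id, "_ligand.json"))
      write_pose_json(cx$pose, lig_path, smiles = smiles)
      rows[[k]] <- data.frame(
        pdb_id = pdb_id,
        receptor = basename(cx$pdb_path),
        ligand = basename(lig_path),
        class = classes[ci],
        target_name = sprintf("%s target %d", classes[ci], ti),
        activity = round(stats::rnorm(1, mean = 6.5, sd = 1.2), 3),
        activity_kind = sample(c("Ki", "Kd", "IC50"), 1),
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)

  lib <- build_library(manifest_path, algorithms = algorithms)

  # similarity structure guarantees
  smi <- vapply(lib$entries, function(e) e$cocrystal_smiles, character(1))
  cls <- vapply(lib$entries, function(e) e$target_class, character(1))
  fps <- compute_fingerprints_batch(unique(smi), "morgan", ids = unique(smi))
  names(fps) <- unique(smi)
  if (n_targets_per_class >= 2L) {
    for (cl in classes) {
      pair <- unique(smi[cls == cl])[1:2]
      t_pair <- tanimoto(fps[[pair[1]]]$fingerprints$morgan,
                         fps[[pair[2]]]$fingerprints$morgan)
      if (t_pair < 0.7) stop("within-class near-duplicate pair below 0.7 (",
                             cl, ": ", round(t_pair, 3), ")")
    }
  }
  cross <- expand.grid(a = unique(smi), b = unique(smi),
                       stringsAsFactors = FALSE)
  cross <- cross[cls[match(cross$a, smi)] != cls[match(cross$b, smi)], ]
  if (nrow(cross)) {
    tmax <- max(vapply(seq_len(nrow(cross)), function(r) {
      tanimoto(fps[[cross$a[r]]]$fingerprints$morgan,
               fps[[cross$b[r]]]$fingerprints$morgan)
    }, numeric(1)))
    if (tmax > 0.3) stop("cross-class ligand similarity above 0.3 (",
                         round(tmax, 3), ")")
  }
  attr(lib, "manifest") <- manifest_path
  lib
}

# ---------------------------------------------------------------------------
# Synthetic activity data
# ---------------------------------------------------------------------------

# Deterministic enumeration of distinct valid molecules: scaffold x two
# substituents (720 raw combinations; several hundred distinct after
# canonicalization). Enough for n = 300 datasets.
.molecule_pool_smiles <- function() {
  scaffolds <- c("c1ccc(%s)cc1%s", "c1ccnc(%s)c1%s", "C1CCC(%s)CC1%s",
                 "c1csc(%s)c1%s", "c1ccc2cc(%s)ccc2c1%s")
  subs <- c("O", "N", "Cl", "F", "CC", "CCC", "C(=O)O", "C(=O)N", "OC",
            "S", "C#N", "CO")
  combos <- expand.grid(sc = scaffolds, a = subs, b = subs,
                        stringsAsFactors = FALSE)
  unique(sprintf(combos$sc, combos$a, combos$b))
}

#' Generate a synthetic activity dataset over Avalon descriptors
#'
#' Enumerates `n` distinct valid molecules from a fixed combinatorial pool,
#' computes their Avalon fingerprints, picks `k_informative` bits of
#' moderate frequency (0.2-0.8), and sets
#' `activity = intercept + sum(w_j * bit_j) + N(0, noise_sd)`. Ground-truth
#' bits and weights are recorded for recovery tests.
#'
#' @param n Number of molecules (>= 50).
#' @param k_informative Number of informative Avalon bits.
#' @param noise_sd Gaussian noise SD on the activity (-log M units).
#' @param seed Integer seed.
#' @param class_label Class label attached to the dataset.
#' @param n_bits Avalon fingerprint length.
#' @return Object of class `activity_dataset`: `features` (n x n_bits 0/1
#'   matrix), `activity`, `ids`, `class_label`, `truth` (list with
#'   `informative_bits`, `weights`, `intercept`, `noise_sd`).
#' @export
generate_activity_dataset <- function(n = 300L, k_informative = 5L,
                                      noise_sd = 0, seed = 1L,
                                      class_label = "synthetic",
                                      n_bits = 512L) {
  stopifnot(n >= 50L, k_informative >= 1L)
  smiles <- .molecule_pool_smiles()
  parsed <- chemtool_run(c("parse", "--format", "smiles",
                           "--in", shQuote(write_smiles_tmp(smiles))))
  ok <- vapply(parsed, function(r) isTRUE(r$ok), logical(1))
  canon <- vapply(parsed[ok], function(r) r$smiles, character(1))
  canon <- unique(canon)
  if (length(canon) < n) stop("fewer than n distinct valid molecules in pool")
  canon <- canon[seq_len(n)]
  feats <- avalon_matrix(canon, n_bits = n_bits)
  freq <- colMeans(feats)
  candidates <- which(freq >= 0.2 & freq <= 0.8)
  if (length(candidates) < k_informative) {
    stop("not enough moderate-frequency Avalon bits for the signal")
  }
  set.seed(seed)
  informative <- sort(sample(candidates, k_informative))
  weights <- stats::runif(k_informative, 0.8, 2.0) *
    sample(c(-1, 1), k_informative, replace = TRUE)
  intercept <- 6.0
  activity <- intercept + as.numeric(feats[, informative, drop = FALSE] %*% weights) +
    stats::rnorm(n, 0, noise_sd)
  structure(list(features = feats, activity = activity,
                 ids = sprintf("act%04d", seq_len(n)),
                 smiles = canon, class_label = class_label,
                 truth = list(informative_bits = informative,
                              weights = weights, intercept = intercept,
                              noise_sd = noise_sd)),
            class = "activity_dataset")
}

#' @export
print.activity_dataset <- function(x, ...) {
  cat(sprintf("<activity_dataset %s: %d molecules x %d bits, activity %.2f-%.2f>\n",
              x$class_label, nrow(x$features), ncol(x$features),
              min(x$activity), max(x$activity)))
  invisible(x)
}

#' Generate decoy molecules for intended targets
#'
#' Draws decoys from the fixed combinatorial pool subject to two
#' constraints: every decoy has Morgan Tanimoto < `max_sim` (default 0.4,
#' the shortlist cutoff) to every co-crystal ligand of its intended target,
#' and the molecular weights across the whole decoy set spread over at
#' least 100 Da so the set is not biased to one size regime.
#'
#' @param lib A `target_library`.
#' @param intended_targets Character vector of target names to decoy.
#' @param n_per_target Decoys per intended target.
#' @param max_sim Similarity bound against the intended target's ligands.
#' @param seed Integer seed.
#' @return data.frame with columns `decoy_id`, `smiles`, `mw`,
#'   `intended_target`.
#' @export
generate_decoys <- function(lib, intended_targets, n_per_target = 5L,
                            max_sim = 0.4, seed = 1L) {
  stopifnot(n_per_target >= 1L, length(intended_targets) >= 1L)
  pool_smi <- .molecule_pool_smiles()
  parsed <- chemtool_run(c("parse", "--format", "smiles",
                           "--in", shQuote(write_smiles_tmp(pool_smi))))
  ok <- vapply(parsed, function(r) isTRUE(r$ok), logical(1))
  pool <- data.frame(
    smiles = vapply(parsed[ok], function(r) r$smiles, character(1)),
    mw = vapply(parsed[ok], function(r) as.numeric(r$mw), numeric(1)),
    stringsAsFactors = FALSE
  )
  pool <- pool[!duplicated(pool$smiles), ]
  pool_fps <- compute_fingerprints_batch(pool$smiles, "morgan",
                                         ids = pool$smiles)
  names(pool_fps) <- pool$smiles

  lib_smi <- vapply(lib$entries, function(e) e$cocrystal_smiles, character(1))
  lib_names <- vapply(lib$entries, function(e) e$target_name, character(1))
  lib_fps <- compute_fingerprints_batch(unique(lib_smi), "morgan",
                                        ids = unique(lib_smi))
  names(lib_fps) <- unique(lib_smi)

  set.seed(seed)
  out <- list()
  for (tn in intended_targets) {
    refs <- unique(lib_smi[lib_names == tn])
    if (!length(refs)) stop("intended target not in library: ", tn)
    sims <- vapply(pool$smiles, function(s) {
      max(vapply(refs, function(r) {
        tanimoto(pool_fps[[s]]$fingerprints$morgan,
                 lib_fps[[r]]$fingerprints$morgan)
      }, numeric(1)))
    }, numeric(1))
    eligible <- pool[sims < max_sim, , drop = FALSE]
    if (nrow(eligible) < n_per_target) {
      stop("decoy pool exhausted for target ", tn)
    }
    # deterministic spread: order by MW, take evenly spaced picks
    eligible <- eligible[order(eligible$mw, eligible$smiles), , drop = FALSE]
    picks <- eligible[round(seq(1, nrow(eligible), length.out = n_per_target)), ]
    picks$intended_target <- tn
    out[[tn]] <- picks
  }
  decoys <- do.call(rbind, out)
  decoys$decoy_id <- sprintf("decoy%03d", seq_len(nrow(decoys)))
  rownames(decoys) <- NULL
  if (diff(range(decoys$mw)) < 100) {
    stop("decoy set molecular-weight spread below 100 Da")
  }
  decoys[, c("decoy_id", "smiles", "mw", "intended_target")]
}
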