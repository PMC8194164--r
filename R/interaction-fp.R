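#' @title Structural interaction fingerprints (scheme "v1")
#' @description Per-residue typed protein-ligand contacts of a 3D pose,
#'   SIFt-style: 8 bit slots per residue in the fixed order hydrophobic,
#'   aromatic-face, aromatic-edge, protein-HB-acceptor, protein-HB-donor,
#'   salt-bridge-protein-positive, salt-bridge-protein-negative,
#'   metal-contact. Comparing the query pose's fingerprint with the
#'   co-crystal reference by Tanimoto gives the binding similarity T_B.
#' @name interaction-fp
NULL

IFP_SLOTS <- c("hydrophobic", "aromatic_face", "aromatic_edge",
               "hb_protein_acceptor", "hb_protein_donor",
               "salt_bridge_protein_positive", "salt_bridge_protein_negative",
               "metal_contact")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
METAL_RES <- c("ZN", "MG", "MN", "CA", "FE", "NA", "K", "CU", "NI", "CO")
WATER_RES <- c("HOH", "WAT", "H2O", "DOD")

#' Geometric criteria of interaction-fingerprint scheme "v1"
#'
#' All distances in Angstrom, angles in degrees: hydrophobic = non-aromatic
#' ligand C/S to non-aromatic side-chain C <= 4.5; H-bond = donor-heavy to
#' acceptor <= 3.5 with D-H...A angle >= 120 when the donor hydrogen is
#' present (distance-only otherwise); salt bridge = opposite formal charges
#' <= 4.0; aromatic face = ring-centroid distance <= 4.5 and interplanar
#' angle <= 30; aromatic edge = centroid distance <= 6.0 and angle in
#' (30, 90]; metal contact = ligand O/N/S <= 2.8 from a metal ion.
#'
#' @return Named list of cutoffs with a `version` field.
#' @export
ifp_scheme <- function() {
  list(version = "v1",
       hydrophobic_max = 4.5,
       hbond_max = 3.5, hbond_min_angle = 120,
       salt_bridge_max = 4.0,
       aromatic_face_max = 4.5, aromatic_face_max_angle = 30,
       aromatic_edge_max = 6.0, aromatic_edge_max_angle = 90,
       metal_max = 2.8,
       h_attach_max = 1.3)
}

# Protein H-bond donor heavy atoms by residue (side chains; backbone N is
# handled separately, excluding proline).
PROT_DONOR_SC <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), TRP = "NE1", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), CYS = "SG"
)
# Protein H-bond acceptor heavy atoms by residue (side chains; backbone
# carbonyl O / OXT handled separately).
PROT_ACCEPTOR_SC <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)
# Charged side-chain atoms at physiological pH.
PROT_POSITIVE <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
PROT_NEGATIVE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
# Aromatic ring atom names.
PROT_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Parse a receptor structure for interaction-fingerprint extraction
#'
#' Reads a PDB file (via bio3d), indexes protein residues and metal ions in
#' file order, and drops waters and unrecognized hetero residues (e.g. a
#' bound ligand) from the residue index.
#'
#' @param path PDB file.
#' @param id Receptor identifier (defaults to the file stem).
#' @return Object of class `receptor`: atom table (`atoms`), residue index
#'   (`residues`: chain, resno, resname, in file order), and `id`.
#' @export
parse_receptor <- function(path, id = NULL) {
  if (!file.exists(path)) stop("cannot read receptor PDB: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  atoms <- data.frame(
    elety = trimws(at$elety), resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno, x = at$x, y = at$y, z = at$z,
    element = elem, type = at$type, stringsAsFactors = FALSE
  )
  keep <- (atoms$resid %in% AA3) |
    (atoms$resid %in% METAL_RES & atoms$type == "HETATM")
  atoms <- atoms[keep, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no protein residues or metal ions in ", path)
  rkey <- paste(atoms$chain, atoms$resno, atoms$resid, sep = "|")
  first <- !duplicated(rkey)
  residues <- data.frame(
    chain = atoms$chain[first], resno = atoms$resno[first],
    resname = atoms$resid[first], stringsAsFactors = FALSE
  )
  atoms$res_idx <- match(rkey, rkey[first])
  structure(list(atoms = atoms, residues = residues,
                 id = if (is.null(id)) tools::file_path_sans_ext(basename(path)) else id,
                 path = normalizePath(path)),
            class = "receptor")
}

#' @export
print.receptor <- function(x, ...) {
  cat(sprintf("<receptor %s: %d residues, %d atoms>\n", x$id,
              nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

.dist3 <- function(p, q) sqrt(sum((p - q)^2))

.angle_deg <- function(a, b, c) {
  # angle at b, degrees
  u <- a - b; v <- c - b
  cosv <- sum(u * v) / (sqrt(sum(u * u)) * sqrt(sum(v * v)))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

.ring_geometry <- function(xyz) {
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2, centroid)
  normal <- svd(centered)$v[, 3]
  list(centroid = centroid, normal = normal / sqrt(sum(normal^2)))
}

.interplanar_angle <- function(n1, n2) {
  cosv <- abs(sum(n1 * n2))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

# hydrogens attached (by distance) to a heavy atom; m = matrix of H coords
.attached_h <- function(heavy_xyz, h_xyz, max_d) {
  if (is.null(h_xyz) || nrow(h_xyz) == 0L) return(h_xyz)
  d <- sqrt(colSums((t(h_xyz) - heavy_xyz)^2))
  h_xyz[d <= max_d, , drop = FALSE]
}

# H-bond test between donor heavy atom (with candidate H positions) and
# acceptor: distance, plus D-H...A angle when any H is attached.
.hbond_ok <- function(donor_xyz, donor_h, acceptor_xyz, scheme) {
  if (.dist3(donor_xyz, acceptor_xyz) > scheme$hbond_max) return(FALSE)
  if (is.null(donor_h) || nrow(donor_h) == 0L) return(TRUE)
  for (k in seq_len(nrow(donor_h))) {
    if (.angle_deg(donor_xyz, donor_h[k, ], acceptor_xyz) >= scheme$hbond_min_angle) {
      return(TRUE)
    }
  }
  FALSE
}

#' Extract the interaction fingerprint of a protein-ligand pose
#'
#' Applies the scheme-"v1" geometric criteria (see [ifp_scheme()]) to every
#' (residue, ligand-atom) combination and returns an 8-bit-per-residue
#' fingerprint over the receptor's residue index. Deterministic for a fixed
#' pose; all-zero when the ligand is beyond every cutoff.
#'
#' @param receptor A [parse_receptor()] object.
#' @param pose A [ligand_pose()].
#' @param scheme Geometric parameter set, default [ifp_scheme()].
#' @return Object of class `interaction_fp`: `residues` (the receptor's
#'   residue index), logical matrix `bits` (residues x 8 slots), `scheme`
#'   version, `receptor_id`.
#' @export
extract_ifp <- function(receptor, pose, scheme = ifp_scheme()) {
  stopifnot(inherits(receptor, "receptor"), inherits(pose, "ligand_pose"))
  la <- pose$atoms
  ok_elem <- la$element %in% c("C", "N", "O", "S", "P", "H", "F", "CL", "BR", "I", "B")
  if (!all(ok_elem)) {
    stop("cannot type ligand atom(s): ",
         paste(unique(la$element[!ok_elem]), collapse = ", "))
  }
  lxyz <- as.matrix(la[, c("x", "y", "z")])
  l_h <- lxyz[la$element == "H", , drop = FALSE]
  lig_rings <- lapply(pose$rings, function(idx) .ring_geometry(lxyz[idx, , drop = FALSE]))

  n_res <- nrow(receptor$residues)
  bits <- matrix(FALSE, n_res, length(IFP_SLOTS),
                 dimnames = list(NULL, IFP_SLOTS))
  pa <- receptor$atoms
  pxyz <- as.matrix(pa[, c("x", "y", "z")])
  max_cut <- max(scheme$hydrophobic_max, scheme$hbond_max,
                 scheme$salt_bridge_max, scheme$aromatic_edge_max,
                 scheme$metal_max)

  # precompute protein aromatic ring atom sets per residue
  for (ri in seq_len(n_res)) {
    rows <- which(pa$res_idx == ri)
    resname <- receptor$residues$resname[ri]
    r_xyz <- pxyz[rows, , drop = FALSE]
    r_name <- pa$elety[rows]
    r_elem <- pa$element[rows]

    # cheap bounding test: skip residues far from every ligand atom
    dmin <- min(vapply(seq_len(nrow(r_xyz)), function(k) {
      min(sqrt(colSums((t(lxyz) - r_xyz[k, ])^2)))
    }, numeric(1)))
    if (dmin > max_cut + 3) next  # +3 covers ring-centroid offsets

    if (resname %in% METAL_RES) {
      lig_ons <- which(la$element %in% c("O", "N", "S"))
      for (j in lig_ons) {
        if (.dist3(r_xyz[1, ], lxyz[j, ]) <= scheme$metal_max) {
          bits[ri, "metal_contact"] <- TRUE
          break
        }
      }
      next
    }

    ring_names <- PROT_RINGS[[resname]]
    ring_atoms <- character(0)
    if (!is.null(ring_names)) ring_atoms <- unlist(ring_names)

    # hydrophobic: non-aromatic ligand C/S vs non-aromatic side-chain C
    sc_c <- which(r_elem == "C" & !(r_name %in% BACKBONE_ATOMS) &
                    !(r_name %in% ring_atoms))
    lig_cs <- which(la$element %in% c("C", "S") & !la$aromatic)
    hydro <- FALSE
    for (k in sc_c) {
      d <- sqrt(colSums((t(lxyz[lig_cs, , drop = FALSE]) - r_xyz[k, ])^2))
      if (length(d) && min(d) <= scheme$hydrophobic_max) { hydro <- TRUE; break }
    }
    if (hydro) bits[ri, "hydrophobic"] <- TRUE

    # aromatic face / edge: protein ring vs ligand ring
    if (!is.null(ring_names) && length(lig_rings)) {
      for (rn in ring_names) {
        sel <- match(rn, r_name)
        if (anyNA(sel)) next
        pg <- .ring_geometry(r_xyz[sel, , drop = FALSE])
        for (lg in lig_rings) {
          dcen <- .dist3(pg$centroid, lg$centroid)
          if (dcen > scheme$aromatic_edge_max) next
          ang <- .interplanar_angle(pg$normal, lg$normal)
          if (dcen <= scheme$aromatic_face_max && ang <= scheme$aromatic_face_max_angle) {
            bits[ri, "aromatic_face"] <- TRUE
          } else if (ang > scheme$aromatic_face_max_angle && ang <= scheme$aromatic_edge_max_angle) {
            bits[ri, "aromatic_edge"] <- TRUE
          }
        }
      }
    }

    # protein as H-bond donor -> ligand acceptor
    donor_names <- PROT_DONOR_SC[[resname]]
    donor_rows <- integer(0)
    if (!is.null(donor_names)) donor_rows <- which(r_name %in% donor_names)
    if (resname != "PRO") donor_rows <- c(donor_rows, which(r_name == "N"))
    p_h <- r_xyz[r_elem == "H", , drop = FALSE]
    lig_acc <- which(la$acceptor & la$element != "H")
    if (length(donor_rows) && length(lig_acc)) {
      for (k in donor_rows) {
        hk <- .attached_h(r_xyz[k, ], p_h, scheme$h_attach_max)
        for (j in lig_acc) {
          if (.hbond_ok(r_xyz[k, ], hk, lxyz[j, ], scheme)) {
            bits[ri, "hb_protein_donor"] <- TRUE
            break
          }
        }
        if (bits[ri, "hb_protein_donor"]) break
      }
    }

    # ligand donor -> protein acceptor
    acc_names <- PROT_ACCEPTOR_SC[[resname]]
    acc_rows <- which(r_name %in% c("O", "OXT"))
    if (!is.null(acc_names)) acc_rows <- c(acc_rows, which(r_name %in% acc_names))
    lig_don <- which(la$donor & la$element != "H")
    if (length(acc_rows) && length(lig_don)) {
      for (j in lig_don) {
        hj <- .attached_h(lxyz[j, ], l_h, scheme$h_attach_max)
        for (k in acc_rows) {
          if (.hbond_ok(lxyz[j, ], hj, r_xyz[k, ], scheme)) {
            bits[ri, "hb_protein_acceptor"] <- TRUE
            break
          }
        }
        if (bits[ri, "hb_protein_acceptor"]) break
      }
    }

    # salt bridges on formal charges
    pos_names <- PROT_POSITIVE[[resname]]
    if (!is.null(pos_names)) {
      prows <- which(r_name %in% pos_names)
      lneg <- which(la$charge < 0)
      for (k in prows) {
        d <- sqrt(colSums((t(lxyz[lneg, , drop = FALSE]) - r_xyz[k, ])^2))
        if (length(d) && min(d) <= scheme$salt_bridge_max) {
          bits[ri, "salt_bridge_protein_positive"] <- TRUE
          break
        }
      }
    }
    neg_names <- PROT_NEGATIVE[[resname]]
    nrows <- which(r_name %in% c(neg_names, if (any(r_name == "OXT")) "OXT"))
    if (length(nrows)) {
      lpos <- which(la$charge > 0)
      for (k in nrows) {
        d <- sqrt(colSums((t(lxyz[lpos, , drop = FALSE]) - r_xyz[k, ])^2))
        if (length(d) && min(d) <= scheme$salt_bridge_max) {
          bits[ri, "salt_bridge_protein_negative"] <- TRUE
          break
        }
      }
    }
  }

  structure(list(residues = receptor$residues, bits = bits,
                 scheme_version = scheme$version, receptor_id = receptor$id),
            class = "interaction_fp")
}

#' @export
print.interaction_fp <- function(x, ...) {
  cat(sprintf("<interaction_fp (%s) on %s: %d residues, %d bits on>\n",
              x$scheme_version, x$receptor_id, nrow(x$residues), sum(x$bits)))
  invisible(x)
}

#' Flatten an interaction fingerprint to a logical bit-vector
#'
#' Slot-major within residue: 8 consecutive bits per residue in the order
#' given by the scheme, residues in receptor file order.
#' @param ifp An [extract_ifp()] result.
#' @return Logical vector of length `8 * n_residues`.
#' @export
ifp_bits <- function(ifp) as.vector(t(ifp$bits))

#' Binding similarity score T_B
#'
#' Tanimoto coefficient between two interaction fingerprints built on the
#' same receptor (identical residue index). Two all-empty fingerprints give
#' 0 with a warning; fingerprints from different receptors are never
#' comparable.
#'
#' @param ifp_query,ifp_ref [extract_ifp()] results on the same receptor.
#' @return Object of class `binding_similarity`: `value` (T_B in \[0, 1\])
#'   and `shared_on_bits`.
#' @export
align_and_compare <- function(ifp_query, ifp_ref) {
  stopifnot(inherits(ifp_query, "interaction_fp"),
            inherits(ifp_ref, "interaction_fp"))
  if (!identical(ifp_query$residues, ifp_ref$residues)) {
    stop("interaction fingerprints built on different residue indices")
  }
  if (!identical(ifp_query$scheme_version, ifp_ref$scheme_version)) {
    stop("interaction fingerprint scheme version mismatch")
  }
  a <- ifp_bits(ifp_query); b <- ifp_bits(ifp_ref)
  n_a <- sum(a); n_b <- sum(b); n_ab <- sum(a & b)
  if (n_a + n_b == 0L) {
    warning("both interaction fingerprints empty; T_B defined as 0")
    value <- 0
  } else {
    value <- n_ab / (n_a + n_b - n_ab)
  }
  structure(list(value = value, shared_on_bits = as.integer(n_ab)),
            class = "binding_similarity")
}

#' @export
print.binding_similarity <- function(x, ...) {
  cat(sprintf("T_B = %.4f (%d shared bits)\n", x$value, x$shared_on_bits))
  invisible(x)
}

#' Human-readable interaction table
#'
#' One row per set bit of an interaction fingerprint.
#' @param ifp An [extract_ifp()] result.
#' @param path Optional TSV output path.
#' @return data.frame with columns `chain`, `resno`, `resname`,
#'   `interaction`.
#' @export
interaction_table <- function(ifp, path = NULL) {
  idx <- which(ifp$bits, arr.ind = TRUE)
  out <- data.frame(
    chain = ifp$residues$chain[idx[, 1]],
    resno = ifp$residues$resno[idx[, 1]],
    resname = ifp$residues$resname[idx[, 1]],
    interaction = IFP_SLOTS[idx[, 2]],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$resno, out$interaction), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
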