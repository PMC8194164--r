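#' Construct a ligand pose
#'
#' A pose is the 3D placement of a ligand: a typed atom table plus aromatic
#' ring membership. Typing (formal charge, aromaticity, H-bond donor /
#' acceptor capability) is what the interaction-fingerprint extraction
#' consumes; hydrogens are ordinary rows and are associated with their donor
#' heavy atom by distance (<= 1.3 Angstrom) when bond information is absent.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (formal, default 0), `aromatic`, `donor`,
#'   `acceptor` (logical, default FALSE).
#' @param rings list of integer vectors (1-based atom indices) giving
#'   aromatic rings.
#' @return Object of class `ligand_pose`.
#' @export
ligand_pose <- function(atoms, rings = list()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L,
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$charge)) atoms$charge <- 0L
  for (col in c("aromatic", "donor", "acceptor")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- FALSE
  }
  atoms$element <- toupper(as.character(atoms$element))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite pose coordinates")
  }
  rings <- lapply(rings, as.integer)
  if (length(rings) && any(unlist(rings) < 1L | unlist(rings) > nrow(atoms))) {
    stop("ring atom index out of range")
  }
  structure(list(atoms = atoms, rings = rings), class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  heavy <- sum(x$atoms$element != "H")
  cat(sprintf("<ligand_pose: %d atoms (%d heavy), %d aromatic ring(s)>\n",
              nrow(x$atoms), heavy, length(x$rings)))
  invisible(x)
}

#' Rigid-body transform of a pose
#' @param pose A [ligand_pose()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector.
#' @return Transformed `ligand_pose`.
#' @export
transform_pose <- function(pose, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(pose$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rotation), 2, translation, FUN = "+")
  pose$atoms$x <- xyz[, 1]; pose$atoms$y <- xyz[, 2]; pose$atoms$z <- xyz[, 3]
  pose
}

#' Translate a pose
#' @param pose A [ligand_pose()].
#' @param shift length-3 numeric vector (Angstrom).
#' @return Shifted `ligand_pose`.
#' @export
shift_pose <- function(pose, shift) {
  transform_pose(pose, diag(3), shift)
}

#' Read ligand poses (with RDKit atom typing) from an SDF file
#'
#' @param path SDF file with 3D coordinates.
#' @return List of `ligand_pose` objects; each carries attributes `id` and
#'   `smiles` (canonical, hydrogens stripped).
#' @export
poses_from_sdf <- function(path) {
  if (!file.exists(path)) stop("cannot read SDF: ", path)
  recs <- chemtool_run(c("atoms", "--format", "sdf", "--in", shQuote(path)))
  bad <- Filter(function(r) !isTRUE(r$ok), recs)
  if (length(bad)) {
    stop("SDF record ", bad[[1]]$i + 1L, " failed: ", bad[[1]]$error)
  }
  norm_rings <- function(rr) {
    if (is.null(rr) || length(rr) == 0L) return(list())
    if (is.matrix(rr)) return(lapply(seq_len(nrow(rr)), function(k) rr[k, ] + 1L))
    lapply(rr, function(v) unlist(v) + 1L)
  }
  lapply(recs, function(r) {
    at <- as.data.frame(r$atoms)
    pose <- ligand_pose(
      data.frame(element = at$element, x = at$x, y = at$y, z = at$z,
                 charge = at$charge, aromatic = at$aromatic,
                 donor = at$donor, acceptor = at$acceptor,
                 stringsAsFactors = FALSE),
      rings = norm_rings(r$rings)
    )
    attr(pose, "id") <- r$id
    attr(pose, "smiles") <- r$smiles
    pose
  })
}

#' Centroid of a pose's heavy atoms
#' @param pose A [ligand_pose()].
#' @return Numeric length-3 centroid (Angstrom).
#' @export
pose_centroid <- function(pose) {
  heavy <- pose$atoms[pose$atoms$element != "H", , drop = FALSE]
  c(mean(heavy$x), mean(heavy$y), mean(heavy$z))
}

#' Axis-aligned bounding box extents of a pose's heavy atoms
#' @param pose A [ligand_pose()].
#' @return Numeric length-3 extents (Angstrom); 0 for single-atom ligands.
#' @export
pose_extents <- function(pose) {
  heavy <- pose$atoms[pose$atoms$element != "H", , drop = FALSE]
  c(diff(range(heavy$x)), diff(range(heavy$y)), diff(range(heavy$z)))
}
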