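#' @title Reference target library
#' @description Build, validate, serialize and split the reference library
#'   of protein-ligand complexes that anchors the target search: one entry
#'   per complex with its target class and name, co-crystal ligand
#'   fingerprints, reference interaction fingerprint and binding activity
#'   in -log M.
#' @name target-library
NULL

#' Write a typed ligand pose to a JSON file
#'
#' The pose JSON format carries explicit atom typing (formal charge,
#' aromaticity, donor/acceptor flags) alongside coordinates, so synthetic
#' fixtures round-trip exactly; SDF input, by contrast, is re-typed by
#' RDKit perception on read.
#'
#' @param pose A [ligand_pose()].
#' @param path Output path.
#' @param smiles SMILES of the ligand (used for fingerprints downstream).
#' @return `path`, invisibly.
#' @export
write_pose_json <- function(pose, path, smiles) {
  payload <- list(smiles = smiles,
                  atoms = pose$atoms[, c("element", "x", "y", "z", "charge",
                                         "aromatic", "donor", "acceptor")],
                  rings = pose$rings)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a typed ligand pose from a JSON file
#' @param path File written by [write_pose_json()].
#' @return A [ligand_pose()] with attribute `smiles`.
#' @export
read_pose_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  atoms <- as.data.frame(payload$atoms, stringsAsFactors = FALSE)
  rings <- payload$rings
  if (is.matrix(rings)) {
    rings <- lapply(seq_len(nrow(rings)), function(k) rings[k, ])
  } else if (!is.list(rings)) {
    rings <- if (length(rings)) list(rings) else list()
  }
  pose <- ligand_pose(atoms, rings)
  attr(pose, "smiles") <- payload$smiles
  pose
}

.read_ligand_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    pose <- read_pose_json(path)
    list(pose = pose, smiles = attr(pose, "smiles"))
  } else if (ext %in% c("sdf", "mol")) {
    poses <- poses_from_sdf(path)
    if (length(poses) != 1L) stop("ligand file must hold exactly one molecule: ", path)
    list(pose = poses[[1]], smiles = attr(poses[[1]], "smiles"))
  } else {
    stop("unsupported ligand file format: ", path)
  }
}

#' Build a target library from a manifest
#'
#' The manifest is a CSV (or data.frame) with columns
#' `pdb_id,receptor,ligand,class,target_name,activity,activity_kind`; file
#' paths are resolved relative to the manifest location. For each row the
#' co-crystal ligand fingerprints and the reference interaction fingerprint
#' (co-crystal pose against its own receptor, scheme v1) are computed. Rows
#' whose structures fail to parse are reported with reasons in the
#' `rejected` attribute, not silently dropped.
#'
#' @param manifest CSV path or data.frame.
#' @param algorithms Fingerprint algorithms stored for every entry.
#' @param base_dir Directory for resolving relative paths (defaults to the
#'   manifest's directory).
#' @return Object of class `target_library`: `entries` (list of
#'   `target_entry`) and `metadata` (algorithms, bit lengths, IFP scheme
#'   version).
#' @export
build_library <- function(manifest, algorithms = fp_preset("MMD"),
                          base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  } else if (is.null(base_dir)) {
    base_dir <- "."
  }
  required <- c("pdb_id", "receptor", "ligand", "class", "target_name",
                "activity", "activity_kind")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols)) {
    stop("manifest missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(manifest$pdb_id)) {
    stop("duplicate pdb_id in manifest: ",
         paste(unique(manifest$pdb_id[duplicated(manifest$pdb_id)]),
               collapse = ", "))
  }
  if (any(is.na(manifest$class) | !nzchar(manifest$class))) {
    stop("manifest rows with missing class label")
  }

  resolve <- function(p) ifelse(file.exists(p), p, file.path(base_dir, p))
  entries <- list()
  rejected <- list()
  # batch all fingerprints in one RDKit call
  lig_info <- vector("list", nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    lig_info[[r]] <- tryCatch(.read_ligand_file(resolve(manifest$ligand[r])),
                              error = function(e) e)
  }
  smi_ok <- !vapply(lig_info, inherits, logical(1), "error")
  fps_by_smiles <- list()
  if (any(smi_ok)) {
    smis <- unique(vapply(lig_info[smi_ok], function(x) x$smiles, character(1)))
    fsets <- compute_fingerprints_batch(smis, algorithms, ids = smis)
    fps_by_smiles <- stats::setNames(fsets, smis)
  }

  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    res <- tryCatch({
      if (inherits(lig_info[[r]], "error")) stop(conditionMessage(lig_info[[r]]))
      receptor_path <- resolve(row$receptor)
      if (!file.exists(receptor_path)) stop("receptor file not found: ", row$receptor)
      receptor <- parse_receptor(receptor_path, id = row$pdb_id)
      pose <- lig_info[[r]]$pose
      smiles <- lig_info[[r]]$smiles
      activity <- suppressWarnings(as.numeric(row$activity))
      if (!is.na(row$activity) && nzchar(as.character(row$activity)) &&
          !is.finite(activity)) {
        stop("non-finite activity for ", row$pdb_id)
      }
      fset <- fps_by_smiles[[smiles]]
      fset$molecule_id <- row$pdb_id
      entry <- structure(list(
        pdb_id = row$pdb_id,
        target_class = row$class,
        target_name = row$target_name,
        receptor_path = normalizePath(receptor_path),
        cocrystal_smiles = smiles,
        cocrystal_pose = pose,
        cocrystal_fps = fset,
        reference_ifp = extract_ifp(receptor, pose),
        activity = activity,
        activity_kind = row$activity_kind
      ), class = "target_entry")
      entry
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        pdb_id = row$pdb_id, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      entries[[length(entries) + 1L]] <- res
    }
  }
  if (length(rejected)) {
    warning(length(rejected), " manifest row(s) rejected during library build")
  }
  if (!length(entries)) stop("no valid entries: library is empty")
  lib <- structure(list(
    entries = entries,
    metadata = list(
      algorithms = as.character(algorithms),
      fp_lengths = as.list(fp_lengths()[algorithms]),
      ifp_scheme = ifp_scheme()$version,
      n_entries = length(entries)
    )
  ), class = "target_library")
  attr(lib, "rejected") <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(pdb_id = character(), reason = character())
  validate_library(lib)
  lib
}

#' @export
print.target_library <- function(x, ...) {
  cls <- table(vapply(x$entries, function(e) e$target_class, character(1)))
  cat(sprintf("<target_library: %d entries, %d class(es): %s>\n",
              length(x$entries), length(cls),
              paste(sprintf("%s (%d)", names(cls), cls), collapse = ", ")))
  invisible(x)
}

#' Validate a target library against its metadata
#'
#' Rejects duplicate PDB ids and any entry whose fingerprint algorithms or
#' bit lengths disagree with the library metadata.
#' @param lib A `target_library`.
#' @return `lib`, invisibly.
#' @export
validate_library <- function(lib) {
  ids <- vapply(lib$entries, function(e) e$pdb_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate pdb_id in library")
  for (e in lib$entries) {
    algs <- names(e$cocrystal_fps$fingerprints)
    if (!setequal(algs, lib$metadata$algorithms)) {
      stop("entry ", e$pdb_id, " fingerprint algorithms disagree with metadata")
    }
    for (a in algs) {
      if (!identical(e$cocrystal_fps$fingerprints[[a]]$nbits,
                     as.integer(lib$metadata$fp_lengths[[a]]))) {
        stop("entry ", e$pdb_id, " fingerprint length for ", a,
             " disagrees with metadata")
      }
    }
  }
  invisible(lib)
}

#' Serialize a target library to a directory
#'
#' Layout: `library.json` (entries and metadata), `fingerprints.json`
#' (sparse on-bit sidecar), per-entry receptor PDB and ligand pose JSON
#' copies. Everything is plain text, human-inspectable and diff-able;
#' serialization is deterministic, so rebuilding from the same inputs gives
#' byte-identical files.
#'
#' @param lib A `target_library`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  struct_dir <- file.path(dir, "structures")
  dir.create(struct_dir, showWarnings = FALSE)
  entries <- lapply(lib$entries, function(e) {
    rec_dest <- file.path(struct_dir, paste0(e$pdb_id, ".pdb"))
    file.copy(e$receptor_path, rec_dest, overwrite = TRUE)
    lig_dest <- file.path(struct_dir, paste0(e$pdb_id, "_ligand.json"))
    write_pose_json(e$cocrystal_pose, lig_dest, smiles = e$cocrystal_smiles)
    list(pdb_id = e$pdb_id, target_class = e$target_class,
         target_name = e$target_name,
         receptor = file.path("structures", basename(rec_dest)),
         ligand = file.path("structures", basename(lig_dest)),
         smiles = e$cocrystal_smiles,
         activity = e$activity, activity_kind = e$activity_kind,
         reference_ifp = list(
           residues = e$reference_ifp$residues,
           on_bits = which(ifp_bits(e$reference_ifp)) - 1L,
           scheme_version = e$reference_ifp$scheme_version))
  })
  jsonlite::write_json(list(metadata = lib$metadata, entries = entries),
                       file.path(dir, "library.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  write_fingerprints(lapply(lib$entries, function(e) e$cocrystal_fps),
                     file.path(dir, "fingerprints.json"))
  invisible(dir)
}

#' Load a target library from a serialized directory
#' @param dir Directory written by [write_library()].
#' @return A `target_library`.
#' @export
read_library <- function(dir) {
  fps <- read_fingerprints(file.path(dir, "fingerprints.json"))
  raw <- jsonlite::read_json(file.path(dir, "library.json"),
                             simplifyVector = FALSE)
  entries <- lapply(raw$entries, function(p) {
    receptor_path <- file.path(dir, p$receptor)
    receptor <- parse_receptor(receptor_path, id = p$pdb_id)
    pose <- read_pose_json(file.path(dir, p$ligand))
    res <- receptor$residues
    n_slots <- length(IFP_SLOTS)
    bits <- rep(FALSE, nrow(res) * n_slots)
    bits[unlist(p$reference_ifp$on_bits) + 1L] <- TRUE
    ifp <- structure(list(
      residues = res,
      bits = matrix(bits, nrow(res), n_slots, byrow = TRUE,
                    dimnames = list(NULL, IFP_SLOTS)),
      scheme_version = p$reference_ifp$scheme_version,
      receptor_id = p$pdb_id), class = "interaction_fp")
    fset <- fps[[p$pdb_id]]
    structure(list(
      pdb_id = p$pdb_id, target_class = p$target_class,
      target_name = p$target_name,
      receptor_path = normalizePath(receptor_path),
      cocrystal_smiles = p$smiles, cocrystal_pose = pose,
      cocrystal_fps = fset, reference_ifp = ifp,
      activity = if (is.null(p$activity)) NA_real_ else as.numeric(p$activity),
      activity_kind = p$activity_kind), class = "target_entry")
  })
  meta <- raw$metadata
  meta$algorithms <- unlist(meta$algorithms)
  meta$fp_lengths <- lapply(meta$fp_lengths, as.integer)
  meta$n_entries <- as.integer(meta$n_entries)
  lib <- structure(list(entries = entries, metadata = meta),
                   class = "target_library")
  validate_library(lib)
  lib
}

#' Stratified train/validation split of a target library
#'
#' Per-class random split at the requested training fraction, with the
#' constraint that every validation entry's target name also occurs among
#' the training entries (a query can only be found if its protein is in the
#' searchable set). Target names with a single entry are forced into
#' training with a warning. Deterministic for a fixed seed.
#'
#' @param lib A `target_library`.
#' @param fraction Training fraction in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @return Object of class `data_split`: `training` and `validation`
#'   (character vectors of pdb ids), `seed`.
#' @export
split_library <- function(lib, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  ids <- vapply(lib$entries, function(e) e$pdb_id, character(1))
  cls <- vapply(lib$entries, function(e) e$target_class, character(1))
  tn <- vapply(lib$entries, function(e) e$target_name, character(1))
  set.seed(seed)
  validation <- character(0)
  forced <- FALSE
  for (cl in unique(cls)) {
    in_cl <- which(cls == cl)
    n_val <- round((1 - fraction) * length(in_cl))
    if (n_val == 0L) next
    counts <- table(tn[in_cl])
    # singletons can never go to validation
    movable <- in_cl[counts[tn[in_cl]] >= 2L]
    if (length(movable) < length(in_cl)) forced <- TRUE
    cand <- movable[sample.int(length(movable))]
    remaining <- as.list(counts)
    taken <- character(0)
    for (i in cand) {
      if (length(taken) >= n_val) break
      if (remaining[[tn[i]]] >= 2L) {
        taken <- c(taken, ids[i])
        remaining[[tn[i]]] <- remaining[[tn[i]]] - 1L
      }
    }
    validation <- c(validation, taken)
  }
  if (forced) warning("target name(s) with a single entry forced into training")
  structure(list(training = setdiff(ids, validation),
                 validation = validation, seed = as.integer(seed)),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split: %d training / %d validation (seed %d)>\n",
              length(x$training), length(x$validation), x$seed))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Structure preparation
# ---------------------------------------------------------------------------

#' Prepare a receptor structure for docking and IFP extraction
#'
#' Removes waters and residues outside the allow-list (20 canonical amino
#' acids plus common catalytic metals: ZN, MG, MN, CA, FE by default --
#' metal cofactors are essential in classes such as carbonic anhydrase),
#' then adds hydrogens via Open Babel when none are present. Output is
#' PDBQT when `format = "pdbqt"` and Open Babel is available, otherwise a
#' cleaned PDB.
#'
#' @param path Input PDB.
#' @param out Output path (extension chosen from `format` when missing).
#' @param allow Residue allow-list.
#' @param format `"pdb"` or `"pdbqt"`.
#' @param obabel Path to the Open Babel binary (empty string disables
#'   hydrogen addition and PDBQT conversion).
#' @return Output path, invisibly; attribute `removed` counts dropped atoms.
#' @export
prepare_receptor <- function(path, out = NULL,
                             allow = c(AA3, c("ZN", "MG", "MN", "CA", "FE")),
                             format = c("pdb", "pdbqt"),
                             obabel = Sys.which("obabel")) {
  format <- match.arg(format)
  if (is.null(out)) out <- tempfile(fileext = paste0(".", format))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  resid <- trimws(at$resid)
  keep <- !(resid %in% WATER_RES) & (resid %in% allow)
  n_removed <- sum(!keep)
  if (!any(keep)) stop("empty structure after cleaning: ", path)
  sel <- bio3d::atom.select(pdb, eleno = at$eleno[keep], verbose = FALSE)
  clean <- bio3d::trim.pdb(pdb, sel)
  elem <- toupper(trimws(ifelse(is.na(clean$atom$elesy) | clean$atom$elesy == "",
                                substr(trimws(clean$atom$elety), 1, 1),
                                clean$atom$elesy)))
  has_h <- any(elem == "H")
  tmp_pdb <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(clean, file = tmp_pdb)
  needs_babel <- (format == "pdbqt") || !has_h
  if (needs_babel && nzchar(obabel)) {
    args <- c("-ipdb", shQuote(tmp_pdb),
              paste0("-o", if (format == "pdbqt") "pdbqt" else "pdb"),
              "-O", shQuote(out))
    if (!has_h) args <- c(args, "-h")
    if (format == "pdbqt") args <- c(args, "-xr")  # rigid receptor
    status <- suppressWarnings(system2(obabel, args, stdout = FALSE,
                                       stderr = FALSE))
    if (!identical(status, 0L)) stop("obabel failed on ", path)
  } else {
    if (format == "pdbqt") {
      stop("PDBQT output requires Open Babel; none configured")
    }
    file.copy(tmp_pdb, out, overwrite = TRUE)
  }
  unlink(tmp_pdb)
  attr(out, "removed") <- n_removed
  invisible(out)
}

#' Prepare a ligand structure for docking
#'
#' Converts an SDF/MOL ligand (3D coordinates required) to AutoDock PDBQT
#' via Open Babel: polar hydrogens retained, nonpolar hydrogens merged,
#' rotatable bonds annotated (ROOT/BRANCH records).
#'
#' @param path Input SDF/MOL file.
#' @param out Output PDBQT path.
#' @param obabel Path to the Open Babel binary.
#' @return Output path, invisibly.
#' @export
prepare_ligand <- function(path, out = tempfile(fileext = ".pdbqt"),
                           obabel = Sys.which("obabel")) {
  if (!nzchar(obabel)) stop("ligand PDBQT preparation requires Open Babel")
  if (!file.exists(path)) stop("ligand file not found: ", path)
  status <- suppressWarnings(system2(
    obabel, c("-isdf", shQuote(path), "-opdbqt", "-O", shQuote(out), "-h"),
    stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(out)) {
    stop("obabel ligand preparation failed for ", path)
  }
  txt <- readLines(out, warn = FALSE)
  if (!any(startsWith(txt, "ATOM") | startsWith(txt, "HETATM"))) {
    stop("prepared ligand has no atoms: ", path)
  }
  invisible(out)
}
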