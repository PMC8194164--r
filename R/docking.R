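#' @title Docking engine adapter
#' @description Pluggable interface to any AutoDock Vina compatible engine
#'   (PDBQT in, multi-model PDBQT out with `REMARK VINA RESULT` energies),
#'   plus a deterministic mock engine so the whole pipeline runs and is
#'   testable without an external binary. The pose with the lowest binding
#'   free energy is always the one returned.
#' @name docking-adapter
NULL

#' Construct a docking search box
#' @param center Numeric length-3 box center (Angstrom).
#' @param size Numeric length-3 box extents (Angstrom), all > 0.
#' @return Object of class `docking_box`.
#' @export
docking_box <- function(center, size) {
  center <- as.numeric(center); size <- as.numeric(size)
  stopifnot(length(center) == 3L, length(size) == 3L,
            all(is.finite(center)), all(is.finite(size)))
  if (any(size <= 0)) stop("docking box extents must be positive")
  structure(list(center = center, size = size), class = "docking_box")
}

#' Default docking box around a co-crystal ligand
#'
#' Center = co-crystal ligand heavy-atom centroid; size = ligand bounding
#' box extents plus `2 * padding` per axis (so a single-atom ligand with the
#' default 8 Angstrom padding gets a 16 Angstrom cube).
#'
#' @param pose Co-crystal [ligand_pose()] (or a `target_entry`, from which
#'   the co-crystal pose is taken).
#' @param padding Padding per side, Angstrom (default 8, a common Vina
#'   community choice).
#' @return A [docking_box()].
#' @export
default_box <- function(pose, padding = 8) {
  if (inherits(pose, "target_entry")) pose <- pose$cocrystal_pose
  stopifnot(inherits(pose, "ligand_pose"), padding >= 0)
  docking_box(pose_centroid(pose), pose_extents(pose) + 2 * padding)
}

#' Deterministic mock docking engine
#'
#' Returns planted poses verbatim: for each receptor id either a list of
#' `(pose, energy)` candidates (the minimum-energy one is selected by
#' [dock()]) or nothing, in which case `fallback_pose(receptor_id)` is used
#' at a deterministic pseudo-energy. Makes the pipeline reproducible
#' end-to-end.
#'
#' @param poses Named list: receptor id -> list of
#'   `list(pose = <ligand_pose>, energy = <kcal/mol>)`.
#' @param fallback_pose Function of receptor id returning a `ligand_pose`,
#'   or NULL (then a missing id is an error).
#' @param fallback_energy Energy (kcal/mol) attached to fallback poses.
#' @return Object of class `c("mock_engine", "docking_engine")`.
#' @export
mock_engine <- function(poses = list(), fallback_pose = NULL,
                        fallback_energy = -7.0) {
  structure(list(poses = poses, fallback_pose = fallback_pose,
                 fallback_energy = fallback_energy),
            class = c("mock_engine", "docking_engine"))
}

#' Mock engine that returns each library entry's co-crystal pose
#'
#' The idealized redocking engine: every shortlisted target receives its
#' own co-crystal ligand pose (so a query identical to the co-crystal
#' ligand scores T_B = 1 against the reference). Pseudo-energies are a
#' deterministic function of the pdb id.
#'
#' @param lib A `target_library`.
#' @return A [mock_engine()].
#' @export
library_mock_engine <- function(lib) {
  poses <- lapply(lib$entries, function(e) e$cocrystal_pose)
  names(poses) <- vapply(lib$entries, function(e) e$pdb_id, character(1))
  mock_engine(fallback_pose = function(id) {
    if (is.null(poses[[id]])) stop("no co-crystal pose for receptor ", id)
    poses[[id]]
  }, fallback_energy = -7.0)
}

#' Vina-family external docking engine
#'
#' Speaks the AutoDock Vina command-line contract; any conformant binary
#' (vina, smina, PSOVina, ...) is substitutable.
#'
#' @param path Path to the engine binary.
#' @param exhaustiveness Search exhaustiveness (default 8).
#' @param seed Engine random seed.
#' @param timeout Seconds before the engine run is aborted.
#' @return Object of class `c("vina_engine", "docking_engine")`.
#' @export
vina_engine <- function(path, exhaustiveness = 8L, seed = 42L, timeout = 600) {
  if (!nzchar(Sys.which(path)) && !file.exists(path)) {
    stop("docking engine binary not found: ", path)
  }
  structure(list(path = path, exhaustiveness = as.integer(exhaustiveness),
                 seed = as.integer(seed), timeout = timeout),
            class = c("vina_engine", "docking_engine"))
}

#' Construct a docking result
#' @param pose A [ligand_pose()].
#' @param energy Binding free energy, kcal/mol (finite).
#' @param engine Engine label.
#' @param exhaustiveness,seed Engine settings recorded for reproducibility.
#' @return Object of class `docking_result`.
#' @export
docking_result <- function(pose, energy, engine = "mock",
                           exhaustiveness = NA_integer_, seed = NA_integer_) {
  stopifnot(inherits(pose, "ligand_pose"), is.finite(energy))
  structure(list(pose = pose, energy = as.numeric(energy),
                 engine = engine, exhaustiveness = exhaustiveness,
                 seed = seed),
            class = "docking_result")
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf("<docking_result: %.2f kcal/mol via %s>\n", x$energy, x$engine))
  invisible(x)
}

#' Dock a ligand into a receptor
#'
#' Runs the engine and returns the lowest-energy pose among its outputs
#' (ties broken by output order, i.e. the first minimum).
#'
#' @param engine A `docking_engine` (mock or Vina-family).
#' @param ligand For the mock engine: ignored (poses are planted). For a
#'   Vina-family engine: path to a prepared ligand PDBQT.
#' @param receptor A [parse_receptor()] object (mock) or a path to a
#'   prepared receptor PDBQT (Vina-family).
#' @param box A [docking_box()].
#' @param receptor_id Receptor id used for pose lookup (defaults to
#'   `receptor$id` when `receptor` is a receptor object).
#' @return A [docking_result()].
#' @export
dock <- function(engine, ligand, receptor, box, receptor_id = NULL) {
  UseMethod("dock")
}

#' @export
dock.mock_engine <- function(engine, ligand, receptor, box, receptor_id = NULL) {
  if (is.null(receptor_id)) {
    receptor_id <- if (inherits(receptor, "receptor")) receptor$id else
      as.character(receptor)
  }
  cands <- engine$poses[[receptor_id]]
  if (is.null(cands)) {
    if (is.null(engine$fallback_pose)) {
      stop("mock engine has no pose planted for receptor '", receptor_id, "'")
    }
    pose <- engine$fallback_pose(receptor_id)
    return(docking_result(pose, engine$fallback_energy, engine = "mock"))
  }
  energies <- vapply(cands, function(p) p$energy, numeric(1))
  best <- which.min(energies)
  docking_result(cands[[best]]$pose, energies[best], engine = "mock")
}

#' @export
dock.vina_engine <- function(engine, ligand, receptor, box, receptor_id = NULL) {
  stopifnot(file.exists(ligand), file.exists(receptor))
  out_pdbqt <- tempfile(fileext = ".pdbqt")
  log_file <- tempfile(fileext = ".log")
  on.exit(unlink(c(log_file)), add = TRUE)
  args <- c("--receptor", shQuote(receptor), "--ligand", shQuote(ligand),
            "--center_x", box$center[1], "--center_y", box$center[2],
            "--center_z", box$center[3],
            "--size_x", box$size[1], "--size_y", box$size[2],
            "--size_z", box$size[3],
            "--exhaustiveness", engine$exhaustiveness,
            "--seed", engine$seed,
            "--out", shQuote(out_pdbqt))
  status <- suppressWarnings(system2(engine$path, args, stdout = log_file,
                                     stderr = log_file,
                                     timeout = engine$timeout))
  if (!identical(status, 0L)) {
    msg <- tryCatch(paste(readLines(log_file, warn = FALSE), collapse = "\n"),
                    error = function(e) "")
    stop("docking engine failed (exit ", status, "): ", msg)
  }
  models <- read_pdbqt_models(out_pdbqt)
  if (length(models) == 0L) stop("docking engine produced no poses")
  energies <- vapply(models, function(m) m$energy, numeric(1))
  best <- models[[which.min(energies)]]
  res <- docking_result(best$pose, best$energy,
                        engine = basename(engine$path),
                        exhaustiveness = engine$exhaustiveness,
                        seed = engine$seed)
  # sanity: pose centroid must fall inside the search box
  cen <- pose_centroid(best$pose)
  if (any(abs(cen - box$center) > box$size)) {
    stop("docked pose centroid implausibly far outside the search box")
  }
  res
}

# AutoDock atom type -> (element, acceptor?, polar H?) used when re-typing
# PDBQT poses for interaction-fingerprint extraction. PDBQT carries partial
# (not formal) charges, so salt-bridge bits are not recoverable from
# engine output; this is a documented limitation of the real-engine path.
AD_TYPES <- list(
  C  = list(element = "C", aromatic = FALSE, acceptor = FALSE),
  A  = list(element = "C", aromatic = TRUE,  acceptor = FALSE),
  N  = list(element = "N", aromatic = FALSE, acceptor = FALSE),
  NA_ = list(element = "N", aromatic = FALSE, acceptor = TRUE),
  OA = list(element = "O", aromatic = FALSE, acceptor = TRUE),
  SA = list(element = "S", aromatic = FALSE, acceptor = TRUE),
  S  = list(element = "S", aromatic = FALSE, acceptor = FALSE),
  P  = list(element = "P", aromatic = FALSE, acceptor = FALSE),
  F  = list(element = "F", aromatic = FALSE, acceptor = FALSE),
  CL = list(element = "CL", aromatic = FALSE, acceptor = FALSE),
  BR = list(element = "BR", aromatic = FALSE, acceptor = FALSE),
  I  = list(element = "I", aromatic = FALSE, acceptor = FALSE),
  H  = list(element = "H", aromatic = FALSE, acceptor = FALSE),
  HD = list(element = "H", aromatic = FALSE, acceptor = FALSE)
)

#' Parse a multi-model Vina output PDBQT file
#'
#' Reads every `MODEL` block, its `REMARK VINA RESULT` energy, and the atom
#' records, re-typing AutoDock atom types to elements. Heavy atoms whose
#' attached hydrogen is a polar `HD` are flagged as H-bond donors.
#'
#' @param path Vina-style output PDBQT.
#' @return List of `list(energy, pose)` in file order.
#' @export
read_pdbqt_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  models <- list()
  cur_atoms <- NULL
  cur_energy <- NA_real_
  flush <- function() {
    if (is.null(cur_atoms) || nrow(cur_atoms) == 0L) return()
    don <- rep(FALSE, nrow(cur_atoms))
    hd <- which(cur_atoms$ad_type == "HD")
    for (h in hd) {
      d <- sqrt((cur_atoms$x - cur_atoms$x[h])^2 +
                (cur_atoms$y - cur_atoms$y[h])^2 +
                (cur_atoms$z - cur_atoms$z[h])^2)
      d[h] <- Inf; d[cur_atoms$element == "H"] <- Inf
      don[which.min(d)] <- TRUE
    }
    cur_atoms$donor <- don
    pose <- ligand_pose(cur_atoms[, c("element", "x", "y", "z", "charge",
                                      "aromatic", "donor", "acceptor")])
    models[[length(models) + 1L]] <<- list(energy = cur_energy, pose = pose)
  }
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (startsWith(ln, "MODEL")) {
      cur_atoms <- data.frame()
      cur_energy <- NA_real_
    } else if (startsWith(ln, "REMARK VINA RESULT:")) {
      cur_energy <- as.numeric(strsplit(trimws(sub("REMARK VINA RESULT:", "", ln)),
                                        "\\s+")[[1]][1])
    } else if (tag %in% c("ATOM  ", "HETATM")) {
      ad <- trimws(substr(ln, 78, 79))
      key <- if (ad == "NA") "NA_" else ad
      ty <- AD_TYPES[[key]]
      if (is.null(ty)) ty <- list(element = ad, aromatic = FALSE, acceptor = FALSE)
      row <- data.frame(
        element = ty$element,
        x = as.numeric(substr(ln, 31, 38)),
        y = as.numeric(substr(ln, 39, 46)),
        z = as.numeric(substr(ln, 47, 54)),
        charge = 0L, aromatic = ty$aromatic, donor = FALSE,
        acceptor = ty$acceptor, ad_type = ad, stringsAsFactors = FALSE
      )
      cur_atoms <- if (is.null(cur_atoms) || nrow(cur_atoms) == 0L) row else
        rbind(cur_atoms, row)
    } else if (startsWith(ln, "ENDMDL")) {
      flush()
      cur_atoms <- NULL
    }
  }
  if (!is.null(cur_atoms) && nrow(cur_atoms) > 0L) flush()  # single-model file
  models
}
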