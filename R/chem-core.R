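#' Fingerprint algorithms and bit lengths
#'
#' Fixed bit lengths per algorithm: Morgan radius 2 (2048), MACCS keys (166),
#' Daylight-style path fingerprint (2048), Avalon (512), hashed atom pairs
#' (2048), hashed topological torsions (2048), 2D pharmacophore folded to
#' 2048.
#' @return Named integer vector of bit lengths.
#' @export
#' @examples
#' fp_lengths()["maccs"]
fp_lengths <- function() {
  c(morgan = 2048L, maccs = 166L, daylight = 2048L, avalon = 512L,
    atompairs = 2048L, torsion = 2048L, pharmacophore2d = 2048L)
}

#' Fingerprint-set presets for the ligand similarity search
#'
#' `MM` = Morgan + MACCS (class-specific mode default); `MMD` = Morgan +
#' MACCS + Daylight (all-class mode default).
#' @param preset One of `"MM"`, `"MMD"`.
#' @return Character vector of algorithm names.
#' @export
fp_preset <- function(preset = c("MMD", "MM")) {
  preset <- match.arg(preset)
  switch(preset,
         MM = c("morgan", "maccs"),
         MMD = c("morgan", "maccs", "daylight"))
}

#' Construct a fingerprint object
#'
#' A fingerprint is stored sparsely as the sorted 0-based indices of its
#' on-bits plus the fixed vector length.
#'
#' @param algorithm Algorithm name (see [fp_lengths()]).
#' @param on_bits Integer vector of 0-based on-bit indices.
#' @param nbits Total bit-vector length.
#' @return An object of class `fingerprint` with fields `algorithm`,
#'   `nbits`, `on_bits`, `n_on`.
#' @export
fingerprint <- function(algorithm, on_bits, nbits) {
  on_bits <- sort(unique(as.integer(on_bits)))
  nbits <- as.integer(nbits)
  stopifnot(length(nbits) == 1L, nbits >= 1L)
  if (length(on_bits) && (min(on_bits) < 0L || max(on_bits) >= nbits)) {
    stop("on_bits out of range [0, nbits)")
  }
  structure(
    list(algorithm = as.character(algorithm), nbits = nbits,
         on_bits = on_bits, n_on = length(on_bits)),
    class = "fingerprint"
  )
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s: %d/%d bits on>\n", x$algorithm, x$n_on, x$nbits))
  invisible(x)
}

#' Construct a fingerprint set
#' @param molecule_id Molecule identifier.
#' @param fingerprints Named list of [fingerprint()] objects (names =
#'   algorithms; must agree with each element's `algorithm` field).
#' @return An object of class `fingerprint_set`.
#' @export
fingerprint_set <- function(molecule_id, fingerprints) {
  stopifnot(is.list(fingerprints), length(fingerprints) >= 1L)
  algs <- vapply(fingerprints, function(f) f$algorithm, character(1))
  if (is.null(names(fingerprints))) names(fingerprints) <- algs
  if (!identical(unname(algs), unname(names(fingerprints)))) {
    stop("fingerprint list names must match algorithm fields")
  }
  if (anyDuplicated(algs)) stop("at most one fingerprint per algorithm")
  structure(list(molecule_id = as.character(molecule_id),
                 fingerprints = fingerprints),
            class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf("<fingerprint_set %s: %s>\n", x$molecule_id,
              paste(names(x$fingerprints), collapse = ", ")))
  invisible(x)
}

#' Parse molecules from a SMILES or SDF file
#'
#' SMILES files hold one molecule per line (optional whitespace-separated id
#' in the second column); SDF is V2000. SMILES are canonicalized at
#' ingestion, so duplicate detection downstream is by canonical SMILES.
#' Unparsable entries are reported via warnings and returned in the
#' `rejected` attribute, never silently dropped.
#'
#' @param path Input file.
#' @param format `"smiles"` or `"sdf"`.
#' @return A data.frame (one row per valid molecule, in file order) with
#'   columns `id`, `smiles` (canonical), `source`, `n_heavy`, `mw`;
#'   attribute `rejected` is a data.frame of failed entries with reasons.
#' @export
#' @examples
#' \donttest{
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("c1ccccc1 benzene", "CCO ethanol"), f)
#' parse_molecules(f, "smiles")
#' }
parse_molecules <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read molecule file: ", path)
  recs <- chemtool_run(c("parse", "--format", format, "--in", shQuote(path)))
  if (length(recs) == 0L) stop("no molecules found in ", path)
  ok <- vapply(recs, function(r) isTRUE(r$ok), logical(1))
  rejected <- do.call(rbind, lapply(recs[!ok], function(r) {
    data.frame(index = r$i + 1L,
               id = if (is.null(r$id)) NA_character_ else r$id,
               reason = r$error, stringsAsFactors = FALSE)
  }))
  if (!is.null(rejected) && nrow(rejected)) {
    warning(nrow(rejected), " molecule(s) rejected while parsing ", path,
            " (see attr(., 'rejected'))")
  }
  good <- recs[ok]
  if (length(good) == 0L) stop("no valid molecules in ", path)
  ids <- vapply(seq_along(good), function(k) {
    r <- good[[k]]
    if (!is.null(r$id) && nzchar(r$id)) r$id else sprintf("mol%04d", r$i + 1L)
  }, character(1))
  if (anyDuplicated(ids)) stop("duplicate molecule ids in ", path, ": ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- data.frame(
    id = ids,
    smiles = vapply(good, function(r) r$smiles, character(1)),
    source = if (format == "smiles") "smiles" else "sdf",
    n_heavy = vapply(good, function(r) as.integer(r$n_heavy), integer(1)),
    mw = vapply(good, function(r) as.numeric(r$mw), numeric(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "rejected") <- if (is.null(rejected))
    data.frame(index = integer(), id = character(), reason = character())
  else rejected
  out
}

#' Compute fingerprints for a batch of molecules
#'
#' One RDKit invocation per call, whatever the batch size; identical input
#' gives bit-identical output.
#'
#' @param smiles Character vector of SMILES strings.
#' @param algorithms Algorithms to compute (subset of `names(fp_lengths())`).
#' @param ids Optional molecule ids (defaults to the SMILES themselves).
#' @return A list of [fingerprint_set()] objects, one per input molecule.
#' @export
compute_fingerprints_batch <- function(smiles,
                                       algorithms = fp_preset("MMD"),
                                       ids = NULL) {
  stopifnot(length(smiles) >= 1L, length(algorithms) >= 1L)
  algorithms <- as.character(algorithms)
  bad <- setdiff(algorithms, names(fp_lengths()))
  if (length(bad)) stop("unknown fingerprint algorithm(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(ids)) ids <- smiles
  stopifnot(length(ids) == length(smiles))
  smi_file <- write_smiles_tmp(smiles)
  on.exit(unlink(smi_file), add = TRUE)
  recs <- chemtool_run(c("fp", "--in", shQuote(smi_file),
                         "--algorithms", paste(algorithms, collapse = ",")))
  fail <- Filter(function(r) !isTRUE(r$ok), recs)
  if (length(fail)) {
    r <- fail[[1]]
    extra <- if (!is.null(r$algorithm)) paste0(" [algorithm ", r$algorithm, "]") else ""
    stop("fingerprint computation failed for molecule ", r$i + 1L, extra,
         ": ", r$error)
  }
  lapply(seq_along(recs), function(k) {
    r <- recs[[k]]
    fps <- lapply(algorithms, function(alg) {
      slot <- r$fps[[alg]]
      fingerprint(alg, on_bits = slot$on, nbits = slot$nbits)
    })
    names(fps) <- algorithms
    fingerprint_set(ids[[r$i + 1L]], fps)
  })
}

#' Compute fingerprints for one molecule
#' @param smiles A single SMILES string.
#' @inheritParams compute_fingerprints_batch
#' @param id Molecule id.
#' @return A [fingerprint_set()].
#' @export
#' @examples
#' \donttest{
#' fps <- compute_fingerprints("c1ccccc1O", c("morgan", "maccs"))
#' fps$fingerprints$morgan$n_on
#' }
compute_fingerprints <- function(smiles, algorithms = fp_preset("MMD"),
                                 id = smiles) {
  stopifnot(length(smiles) == 1L)
  compute_fingerprints_batch(smiles, algorithms, ids = id)[[1]]
}

#' Tanimoto coefficient between two fingerprints
#'
#' \deqn{T = N_{ab} / (N_a + N_b - N_{ab})}
#' where \eqn{N_a}, \eqn{N_b} count the on-bits of each fingerprint and
#' \eqn{N_{ab}} the on-bits common to both. When both fingerprints are
#' all-zero the value is defined as 0 (with a warning) rather than NaN, so
#' featureless molecules never rank as perfect matches.
#'
#' @param a,b [fingerprint()] objects with identical algorithm and length.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' a <- fingerprint("morgan", c(0, 1, 2), 2048)
#' b <- fingerprint("morgan", c(1, 2, 7), 2048)
#' tanimoto(a, b)  # 2 / (3 + 3 - 2) = 0.5
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (!identical(a$algorithm, b$algorithm)) {
    stop("fingerprint algorithm mismatch: ", a$algorithm, " vs ", b$algorithm)
  }
  if (!identical(a$nbits, b$nbits)) {
    stop("fingerprint length mismatch: ", a$nbits, " vs ", b$nbits)
  }
  n_a <- a$n_on
  n_b <- b$n_on
  if (n_a == 0L && n_b == 0L) {
    warning("Tanimoto of two all-zero fingerprints defined as 0")
    return(0)
  }
  n_ab <- length(intersect(a$on_bits, b$on_bits))
  n_ab / (n_a + n_b - n_ab)
}

#' Ligand similarity score T_L
#'
#' The ligand similarity score between a query molecule and a reference
#' co-crystallized ligand: the unweighted arithmetic mean of per-algorithm
#' Tanimoto coefficients over the requested fingerprint algorithms.
#'
#' @param query,ref [fingerprint_set()] objects; both must contain every
#'   algorithm in `algorithms` (no silent averaging over a subset).
#' @param algorithms Algorithms to average over.
#' @return An object of class `similarity_score`: list with `value` (T_L)
#'   and `components` (named per-algorithm Tanimoto values).
#' @export
ligand_similarity <- function(query, ref, algorithms = fp_preset("MMD")) {
  stopifnot(inherits(query, "fingerprint_set"), inherits(ref, "fingerprint_set"),
            length(algorithms) >= 1L)
  algorithms <- as.character(algorithms)
  miss_q <- setdiff(algorithms, names(query$fingerprints))
  miss_r <- setdiff(algorithms, names(ref$fingerprints))
  if (length(miss_q) || length(miss_r)) {
    stop("fingerprint set missing algorithm(s): ",
         paste(unique(c(miss_q, miss_r)), collapse = ", "))
  }
  components <- vapply(algorithms, function(alg) {
    tanimoto(query$fingerprints[[alg]], ref$fingerprints[[alg]])
  }, numeric(1))
  structure(list(value = mean(components), components = components),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("T_L = %.4f (%s)\n", x$value,
              paste(sprintf("%s=%.3f", names(x$components), x$components),
                    collapse = ", ")))
  invisible(x)
}

#' Serialize fingerprint sets to a JSON sidecar file
#'
#' Fingerprints for a whole library are stored in one text sidecar so the
#' similarity search never re-derives them from structures. Sparse on-bit
#' encoding keeps the file compact and diff-able.
#'
#' @param fp_sets List of [fingerprint_set()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fp_sets, path) {
  payload <- lapply(fp_sets, function(fs) {
    list(molecule_id = fs$molecule_id,
         fingerprints = lapply(fs$fingerprints, function(f) {
           list(algorithm = f$algorithm, nbits = f$nbits, on = f$on_bits)
         }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load fingerprint sets from a JSON sidecar file
#' @param path File written by [write_fingerprints()].
#' @return Named list of [fingerprint_set()] (names = molecule ids).
#' @export
read_fingerprints <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(payload, function(rec) {
    fps <- lapply(rec$fingerprints, function(f) {
      fingerprint(f$algorithm, on_bits = unlist(f$on), nbits = f$nbits)
    })
    fingerprint_set(rec$molecule_id, fps)
  })
  names(out) <- vapply(out, function(fs) fs$molecule_id, character(1))
  out
}
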