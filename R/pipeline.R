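#' @title Target prediction pipeline
#' @description The five-step workflow: (1) shortlist candidate targets by
#'   ligand fingerprint similarity to the co-crystallized ligands, (2) dock
#'   the query into each shortlisted receptor, (3) score the docked pose's
#'   interaction fingerprint against the co-crystal reference (T_B),
#'   (4) predict binding activity with the class-specific forest, and
#'   (5) consolidate and rank by the combined score `w_L * T_L + w_B * T_B`
#'   (published defaults 0.7 / 0.3).
#' @name pipeline
NULL

#' Prediction options
#'
#' @param fp_preset `"MMD"` (all-class default), `"MM"` (class-specific
#'   mode default), or `"custom"` (then `algorithms` must be given).
#' @param algorithms Explicit algorithm set for `fp_preset = "custom"`.
#' @param cutoff Shortlist threshold on T_L in \[0, 1\] (default 0.4, the
#'   empirically defined workflow value).
#' @param class_filter Optional target class label: restricts the search to
#'   one class (class-specific mode).
#' @param weights Length-2 non-negative weights `(w_L, w_B)` summing to 1;
#'   default `c(0.7, 0.3)`.
#' @param top_n_report Number of top records reported by summaries.
#' @return Object of class `prediction_options`.
#' @export
prediction_options <- function(fp_preset = c("MMD", "MM", "custom"),
                               algorithms = NULL, cutoff = 0.4,
                               class_filter = NULL,
                               weights = c(0.7, 0.3), top_n_report = 10L) {
  fp_preset <- match.arg(fp_preset)
  if (fp_preset == "custom") {
    if (is.null(algorithms)) stop("custom preset needs explicit algorithms")
  } else {
    algorithms <- fp_preset(fp_preset)
  }
  stopifnot(cutoff >= 0, cutoff <= 1, length(weights) == 2L)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1")
  }
  structure(list(fp_preset = fp_preset, algorithms = as.character(algorithms),
                 cutoff = cutoff, class_filter = class_filter,
                 weights = as.numeric(weights),
                 top_n_report = as.integer(top_n_report)),
            class = "prediction_options")
}

#' Load prediction options from a YAML config file
#'
#' Recognized keys: `fp_preset`, `algorithms`, `cutoff`, `class_filter`,
#' `weights` (list of two), `top_n_report`.
#' @param path YAML file.
#' @return A [prediction_options()] object.
#' @export
read_options_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(prediction_options, cfg[intersect(names(cfg),
    c("fp_preset", "algorithms", "cutoff", "class_filter", "weights",
      "top_n_report"))])
}

#' Shortlist candidate targets by ligand similarity
#'
#' Computes T_L between the query and every library entry's co-crystal
#' ligand over the preset algorithms and keeps entries with
#' `T_L >= cutoff`, restricted to `class_filter` when set. An empty
#' shortlist is a valid outcome.
#'
#' @param query_fps [fingerprint_set()] of the query molecule.
#' @param lib A `target_library`.
#' @param opts A [prediction_options()].
#' @return data.frame with columns `pdb_id`, `target_class`, `target_name`,
#'   `t_ligand`, ordered by `t_ligand` descending (ties by `pdb_id`).
#' @export
shortlist_targets <- function(query_fps, lib, opts = prediction_options()) {
  stopifnot(inherits(query_fps, "fingerprint_set"),
            inherits(lib, "target_library"))
  miss <- setdiff(opts$algorithms, lib$metadata$algorithms)
  if (length(miss)) {
    stop("library was not built with algorithm(s): ",
         paste(miss, collapse = ", "))
  }
  entries <- lib$entries
  if (!is.null(opts$class_filter)) {
    entries <- Filter(function(e) e$target_class == opts$class_filter, entries)
  }
  if (!length(entries)) {
    return(data.frame(pdb_id = character(), target_class = character(),
                      target_name = character(), t_ligand = numeric()))
  }
  t_l <- vapply(entries, function(e) {
    ligand_similarity(query_fps, e$cocrystal_fps, opts$algorithms)$value
  }, numeric(1))
  keep <- t_l >= opts$cutoff
  out <- data.frame(
    pdb_id = vapply(entries, function(e) e$pdb_id, character(1))[keep],
    target_class = vapply(entries, function(e) e$target_class, character(1))[keep],
    target_name = vapply(entries, function(e) e$target_name, character(1))[keep],
    t_ligand = t_l[keep], stringsAsFactors = FALSE)
  out[order(-out$t_ligand, out$pdb_id), , drop = FALSE]
}

#' Combined target score
#'
#' `w_L * T_L + w_B * T_B` with the published default weights (0.7, 0.3);
#' monotone in each argument and bounded to \[0, 1\].
#'
#' @param t_l,t_b Ligand and binding similarity scores in \[0, 1\].
#' @param weights Length-2 weights summing to 1.
#' @return Combined score in \[0, 1\].
#' @export
#' @examples
#' combined_score(0.5, 0.3)  # 0.44
combined_score <- function(t_l, t_b, weights = c(0.7, 0.3)) {
  if (any(t_l < 0 | t_l > 1, na.rm = TRUE) ||
      any(t_b < 0 | t_b > 1, na.rm = TRUE)) {
    stop("similarity scores must lie in [0, 1]")
  }
  stopifnot(length(weights) == 2L, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9)
  weights[1] * t_l + weights[2] * t_b
}

#' Predict targets for one query molecule
#'
#' Runs the full workflow against a library: shortlist, dock each candidate
#' with the configured engine, extract the pose interaction fingerprint and
#' compare it to the co-crystal reference (T_B), predict class-specific
#' activity when a model is available (otherwise NA with a warning-free
#' status note), and rank by combined score. Ties are broken by T_L
#' descending, then pdb_id ascending; ranks are contiguous from 1. A
#' docking failure marks that entry `dock_failed` and excludes it from
#' ranking without aborting the run.
#'
#' @param query Query SMILES string, or a [fingerprint_set()] already
#'   computed over the preset algorithms.
#' @param lib A `target_library`.
#' @param opts A [prediction_options()].
#' @param engine A docking engine (see [mock_engine()], [vina_engine()]).
#' @param activity_models Named list of `activity_model` objects keyed by
#'   target class (see [train_class_models()]); may be empty.
#' @param query_id Identifier used in the output.
#' @return data.frame of prediction records: `query_id`, `rank`,
#'   `target_name`, `pdb_id`, `target_class`, `t_ligand`, `t_binding`,
#'   `combined`, `docking_energy`, `predicted_activity`, `status`. Failed
#'   entries carry NA rank and a status reason.
#' @export
predict_targets <- function(query, lib, opts = prediction_options(),
                            engine = mock_engine(), activity_models = list(),
                            query_id = NULL) {
  if (inherits(query, "fingerprint_set")) {
    query_fps <- query
    if (is.null(query_id)) query_id <- query$molecule_id
  } else {
    stopifnot(is.character(query), length(query) == 1L)
    if (is.null(query_id)) query_id <- query
    query_fps <- compute_fingerprints(query, opts$algorithms, id = query_id)
  }
  short <- shortlist_targets(query_fps, lib, opts)
  cols <- c("query_id", "rank", "target_name", "pdb_id", "target_class",
            "t_ligand", "t_binding", "combined", "docking_energy",
            "predicted_activity", "status")
  if (!nrow(short)) {
    out <- data.frame(query_id = character(), rank = integer(),
                      target_name = character(), pdb_id = character(),
                      target_class = character(), t_ligand = numeric(),
                      t_binding = numeric(), combined = numeric(),
                      docking_energy = numeric(),
                      predicted_activity = numeric(), status = character())
    return(out[, cols])
  }
  entries <- stats::setNames(lib$entries,
                             vapply(lib$entries, function(e) e$pdb_id,
                                    character(1)))
  # activity is predicted once per class present in the shortlist
  act_by_class <- list()
  for (cl in unique(short$target_class)) {
    if (!is.null(activity_models[[cl]])) {
      act_by_class[[cl]] <- predict_activity(activity_models[[cl]],
                                             query_fps_smiles(query, query_fps))
    }
  }
  rows <- lapply(seq_len(nrow(short)), function(k) {
    e <- entries[[short$pdb_id[k]]]
    rec <- list(query_id = query_id, rank = NA_integer_,
                target_name = e$target_name, pdb_id = e$pdb_id,
                target_class = e$target_class,
                t_ligand = short$t_ligand[k], t_binding = NA_real_,
                combined = NA_real_, docking_energy = NA_real_,
                predicted_activity = NA_real_, status = "ok")
    docked <- tryCatch(
      dock(engine, ligand = NULL,
           receptor = parse_receptor(e$receptor_path, id = e$pdb_id),
           box = default_box(e$cocrystal_pose)),
      error = function(err) err)
    if (inherits(docked, "error")) {
      rec$status <- "dock_failed"
      return(as.data.frame(rec, stringsAsFactors = FALSE))
    }
    rec$docking_energy <- docked$energy
    receptor <- parse_receptor(e$receptor_path, id = e$pdb_id)
    ifp_q <- extract_ifp(receptor, docked$pose)
    rec$t_binding <- suppressWarnings(
      align_and_compare(ifp_q, e$reference_ifp)$value)
    rec$combined <- combined_score(rec$t_ligand, rec$t_binding, opts$weights)
    act <- act_by_class[[e$target_class]]
    rec$predicted_activity <- if (is.null(act)) NA_real_ else act
    if (is.null(act) && length(activity_models)) rec$status <- "no_class_model"
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ranked <- out[out$status != "dock_failed", , drop = FALSE]
  failed <- out[out$status == "dock_failed", , drop = FALSE]
  ord <- order(-ranked$combined, -ranked$t_ligand, ranked$pdb_id)
  ranked <- ranked[ord, , drop = FALSE]
  if (nrow(ranked)) ranked$rank <- seq_len(nrow(ranked))
  out <- rbind(ranked, failed)
  rownames(out) <- NULL
  out[, cols]
}

# SMILES used for activity featurization: prefer the raw query string,
# fall back to the fingerprint-set molecule id (set when parsed from file).
query_fps_smiles <- function(query, query_fps) {
  if (is.character(query)) query else query_fps$molecule_id
}

#' Predict targets for a batch of query molecules
#'
#' Per-query failures are isolated: an unparsable query yields an error
#' record, the remaining queries still run. With the mock engine and fixed
#' seeds the whole batch is deterministic.
#'
#' @param queries Named character vector or data.frame with columns `id`,
#'   `smiles` (as returned by [parse_molecules()]).
#' @inheritParams predict_targets
#' @return Named list of per-query prediction data.frames; failed queries
#'   hold a data.frame with a single `status = "query_failed"` row.
#' @export
predict_batch <- function(queries, lib, opts = prediction_options(),
                          engine = mock_engine(), activity_models = list()) {
  if (is.data.frame(queries)) {
    ids <- queries$id
    smiles <- queries$smiles
  } else {
    smiles <- as.character(queries)
    ids <- if (!is.null(names(queries))) names(queries) else smiles
  }
  stopifnot(length(smiles) >= 1L)
  out <- lapply(seq_along(smiles), function(k) {
    tryCatch(
      predict_targets(smiles[k], lib, opts, engine, activity_models,
                      query_id = ids[k]),
      error = function(e) {
        data.frame(query_id = ids[k], rank = NA_integer_,
                   target_name = NA_character_, pdb_id = NA_character_,
                   target_class = NA_character_, t_ligand = NA_real_,
                   t_binding = NA_real_, combined = NA_real_,
                   docking_energy = NA_real_, predicted_activity = NA_real_,
                   status = paste0("query_failed: ", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
  })
  stats::setNames(out, ids)
}

#' Write batch prediction results to a CSV file
#'
#' Columns mirror the per-record fields: query id, rank, target name, PDB
#' id, class, ligand similarity, binding similarity, combined score,
#' docking energy (kcal/mol), predicted activity (-log M), status.
#'
#' @param results List from [predict_batch()] (or a single
#'   [predict_targets()] data.frame).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  if (is.data.frame(results)) results <- list(results)
  all <- do.call(rbind, results)
  names(all)[names(all) == "t_ligand"] <- "ligand_similarity"
  names(all)[names(all) == "t_binding"] <- "binding_similarity"
  names(all)[names(all) == "combined"] <- "combined_score"
  names(all)[names(all) == "docking_energy"] <- "docking_energy_kcal_mol"
  names(all)[names(all) == "predicted_activity"] <- "predicted_activity_neglogM"
  utils::write.csv(all, path, row.names = FALSE)
  invisible(path)
}
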