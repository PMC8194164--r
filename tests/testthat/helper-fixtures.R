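# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

toy_library <- function() {
  if (is.null(.fixture_cache$lib)) {
    .fixture_cache$lib <- generate_library(
      dir = file.path(tempdir(), "toylib"),
      n_classes = 2, n_targets_per_class = 2, seed = 1)
  }
  .fixture_cache$lib
}

toy_engine <- function() library_mock_engine(toy_library())

# a fake ranked prediction data.frame from a vector of target names
fake_result <- function(target_names, query_id = "q") {
  n <- length(target_names)
  data.frame(query_id = rep(query_id, n), rank = seq_len(n),
             target_name = target_names,
             pdb_id = sprintf("P%03d", seq_len(n)),
             target_class = rep("c", n),
             t_ligand = rev(seq_len(n)) / max(n, 1),
             t_binding = rep(0, n), combined = rev(seq_len(n)) / max(n, 1),
             docking_energy = rep(-7, n),
             predicted_activity = rep(NA_real_, n),
             status = rep("ok", n), stringsAsFactors = FALSE)
}

# a synthetic fingerprint over an arbitrary algorithm label
fp_of <- function(on_bits, nbits = 256, algorithm = "fp") {
  fingerprint(algorithm, on_bits, nbits)
}

fpset_of <- function(id, on_bits, nbits = 256, algorithm = "fp") {
  fps <- list(fp_of(on_bits, nbits, algorithm))
  names(fps) <- algorithm
  fingerprint_set(id, fps)
}

# minimal in-memory library whose entries carry planted fingerprint sets;
# enough structure for shortlist_targets (no receptors needed)
similarity_library <- function(entries_df, nbits = 256) {
  entries <- lapply(seq_len(nrow(entries_df)), function(k) {
    row <- entries_df[k, ]
    structure(list(
      pdb_id = row$pdb_id, target_class = row$class,
      target_name = row$target_name,
      cocrystal_smiles = NA_character_,
      cocrystal_fps = fpset_of(row$pdb_id, row$on_bits[[1]], nbits)),
      class = "target_entry")
  })
  structure(list(entries = entries,
                 metadata = list(algorithms = "fp",
                                 fp_lengths = list(fp = nbits),
                                 ifp_scheme = "v1",
                                 n_entries = length(entries))),
            class = "target_library")
}

# a tiny handwritten ethanol SDF (V2000, heavy atoms only) with a given
# atom order permutation of (C, C, O)
ethanol_sdf <- function(path, order = c(1L, 2L, 3L)) {
  atoms <- data.frame(
    sym = c("C", "C", "O"),
    x = c(0.000, 1.520, 2.200), y = c(0.000, 0.000, 1.200),
    z = c(0.000, 0.000, 0.000))
  atoms <- atoms[order, ]
  # bond list in original numbering: 1-2, 2-3; remap to the permutation
  remap <- match(seq_len(3), order)
  bonds <- rbind(c(remap[1], remap[2]), c(remap[2], remap[3]))
  lines <- c(
    "ethanol", "  synthetic", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", 3L, 2L),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            atoms$x, atoms$y, atoms$z, atoms$sym),
    sprintf("%3d%3d%3d  0  0  0  0", bonds[, 1], bonds[, 2], c(1L, 1L)),
    "M  END", "$$$$")
  writeLines(lines, path)
  path
}

# benzene SDF (flat hexagon, aromatic ring written as alternating bonds)
benzene_sdf <- function(path) {
  th <- (0:5) * pi / 3
  lines <- c(
    "benzene", "  synthetic", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", 6L, 6L),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            1.39 * cos(th), 1.39 * sin(th), rep(0, 6), rep("C", 6)),
    sprintf("%3d%3d%3d  0  0  0  0", 1:6, c(2:6, 1L),
            rep(c(2L, 1L), 3)),
    "M  END", "$$$$")
  writeLines(lines, path)
  path
}
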