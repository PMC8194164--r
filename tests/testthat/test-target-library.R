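test_that("libraries build from manifests with count conservation", {
  lib <- toy_library()
  expect_s3_class(lib, "target_library")
  expect_length(lib$entries, 4)
  classes <- vapply(lib$entries, function(e) e$target_class, character(1))
  expect_equal(length(unique(classes)), 2)
  # every entry carries fingerprints and a non-empty reference IFP
  for (e in lib$entries) {
    expect_setequal(names(e$cocrystal_fps$fingerprints),
                    lib$metadata$algorithms)
    expect_gt(sum(e$reference_ifp$bits), 0)
    expect_true(is.finite(e$activity))
  }
})

test_that("manifest rows with broken structures are rejected, others built", {
  lib <- toy_library()
  manifest <- utils::read.csv(attr(lib, "manifest"), stringsAsFactors = FALSE)
  manifest$receptor[2] <- "no_such_file.pdb"
  expect_warning(
    lib2 <- build_library(manifest, algorithms = lib$metadata$algorithms,
                          base_dir = dirname(attr(lib, "manifest"))),
    "rejected")
  expect_length(lib2$entries, 3)
  rej <- attr(lib2, "rejected")
  expect_equal(rej$pdb_id, manifest$pdb_id[2])
  expect_match(rej$reason, "not found")

  dup <- manifest
  dup$pdb_id[2] <- dup$pdb_id[1]
  expect_error(build_library(dup, base_dir = dirname(attr(lib, "manifest"))),
               "duplicate pdb_id")
})

test_that("library serialization round-trips byte-identically", {
  lib <- toy_library()
  d1 <- file.path(tempdir(), "ser1"); d2 <- file.path(tempdir(), "ser2")
  write_library(lib, d1)
  lib2 <- read_library(d1)
  write_library(lib2, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
  # loaded entries preserve scores and structures
  expect_equal(vapply(lib2$entries, function(e) e$pdb_id, character(1)),
               vapply(lib$entries, function(e) e$pdb_id, character(1)))
  expect_identical(lib2$entries[[1]]$reference_ifp$bits,
                   lib$entries[[1]]$reference_ifp$bits)
})

test_that("library validation rejects metadata mismatches", {
  lib <- toy_library()
  broken <- lib
  broken$entries[[1]]$cocrystal_fps$fingerprints$morgan$nbits <- 1024L
  expect_error(validate_library(broken), "length")
  broken2 <- lib
  names(broken2$entries[[2]]$cocrystal_fps$fingerprints)[1] <- "torsion"
  expect_error(validate_library(broken2), "algorithms")
})

test_that("splits are stratified, constrained and deterministic", {
  # 10 entries, one class, one target name, fraction 0.8 -> 8 / 2
  entries <- lapply(1:10, function(k) {
    structure(list(pdb_id = sprintf("E%02d", k), target_class = "c1",
                   target_name = "tn1"), class = "target_entry")
  })
  lib10 <- structure(list(entries = entries, metadata = list()),
                     class = "target_library")
  sp <- split_library(lib10, 0.8, seed = 3)
  expect_length(sp$training, 8)
  expect_length(sp$validation, 2)
  expect_length(intersect(sp$training, sp$validation), 0)
  expect_setequal(c(sp$training, sp$validation), sprintf("E%02d", 1:10))
  expect_identical(sp, split_library(lib10, 0.8, seed = 3))
  expect_false(identical(sp$validation,
                         split_library(lib10, 0.8, seed = 4)$validation) &&
               identical(sp$training,
                         split_library(lib10, 0.8, seed = 4)$training))

  # a singleton target name is forced into training
  entries2 <- c(entries, list(
    structure(list(pdb_id = "S01", target_class = "c1",
                   target_name = "lonely"), class = "target_entry")))
  lib11 <- structure(list(entries = entries2, metadata = list()),
                     class = "target_library")
  expect_warning(sp2 <- split_library(lib11, 0.8, seed = 3), "forced")
  expect_true("S01" %in% sp2$training)
  # every validation target name is represented in training
  tn <- function(ids, lib) vapply(lib$entries[match(ids,
    vapply(lib$entries, function(e) e$pdb_id, character(1)))],
    function(e) e$target_name, character(1))
  expect_true(all(tn(sp2$validation, lib11) %in% tn(sp2$training, lib11)))
})

test_that("per-class training fractions stay within one entry of the request", {
  entries <- c(
    lapply(1:10, function(k) structure(list(pdb_id = sprintf("A%02d", k),
      target_class = "c1", target_name = sprintf("t%d", (k - 1) %% 2)),
      class = "target_entry")),
    lapply(1:5, function(k) structure(list(pdb_id = sprintf("B%02d", k),
      target_class = "c2", target_name = "u0"), class = "target_entry")))
  lib <- structure(list(entries = entries, metadata = list()),
                   class = "target_library")
  sp <- split_library(lib, 0.8, seed = 9)
  ids_a <- sprintf("A%02d", 1:10); ids_b <- sprintf("B%02d", 1:5)
  n_train_a <- sum(sp$training %in% ids_a)
  n_train_b <- sum(sp$training %in% ids_b)
  expect_lte(abs(n_train_a - 8), 1)
  expect_lte(abs(n_train_b - 4), 1)
})

test_that("receptor preparation removes water and foreign residues", {
  cx <- generate_complex(data.frame(residue = 5, type = "hydrophobic"))
  lines <- readLines(cx$pdb_path, warn = FALSE)
  # append waters, an ion outside the allow-list, and a nonstandard residue
  extra <- c(
    "HETATM 9001  O   HOH A 900      50.000  50.000  50.000  1.00  0.00           O",
    "HETATM 9002  O   HOH A 901      52.000  50.000  50.000  1.00  0.00           O",
    "HETATM 9003 CS    CS A 902      54.000  50.000  50.000  1.00  0.00          CS",
    "HETATM 9004  C1  UNK A 903      56.000  50.000  50.000  1.00  0.00           C")
  dirty <- tempfile(fileext = ".pdb")
  writeLines(c(lines[lines != "END"], extra, "END"), dirty)
  out <- prepare_receptor(dirty, out = tempfile(fileext = ".pdb"),
                          obabel = "")
  kept <- readLines(out, warn = FALSE)
  atoms <- kept[startsWith(kept, "ATOM") | startsWith(kept, "HETATM")]
  expect_false(any(grepl("HOH|UNK|CS ", atoms)))
  expect_equal(attr(out, "removed"), 4)
  # independent line-level count: atoms out = atoms in - removed
  n_in <- sum(startsWith(lines, "ATOM") | startsWith(lines, "HETATM")) + 4
  expect_equal(length(atoms), n_in - 4)
})

test_that("hydrogen handling in receptor preparation is idempotent", {
  cx <- generate_complex(data.frame(residue = 5, type = "hydrophobic"))
  # fixture receptors already carry amide hydrogens: count unchanged
  out <- prepare_receptor(cx$pdb_path, out = tempfile(fileext = ".pdb"),
                          obabel = "")
  count_h <- function(f) {
    ll <- readLines(f, warn = FALSE)
    at <- ll[startsWith(ll, "ATOM") | startsWith(ll, "HETATM")]
    sum(trimws(substr(at, 77, 78)) == "H")
  }
  expect_equal(count_h(out), count_h(cx$pdb_path))

  # strip hydrogens, then preparation must add some back (via Open Babel)
  ll <- readLines(cx$pdb_path, warn = FALSE)
  at <- startsWith(ll, "ATOM") | startsWith(ll, "HETATM")
  keep <- !at | trimws(substr(ll, 77, 78)) != "H"
  bare <- tempfile(fileext = ".pdb")
  writeLines(ll[keep], bare)
  out2 <- prepare_receptor(bare, out = tempfile(fileext = ".pdb"))
  expect_gt(count_h(out2), 0)
})

test_that("ligand preparation yields PDBQT with polar hydrogens and torsions", {
  eth <- ethanol_sdf(tempfile(fileext = ".sdf"))
  out <- prepare_ligand(eth)
  txt <- readLines(out, warn = FALSE)
  at <- txt[startsWith(txt, "ATOM") | startsWith(txt, "HETATM")]
  types <- trimws(substr(at, 78, 79))
  expect_true("OA" %in% types)   # hydroxyl oxygen typed as acceptor
  expect_true("HD" %in% types)   # hydroxyl hydrogen retained as polar H
  expect_false("H" %in% types)   # nonpolar hydrogens merged away

  # rigid aromatic ring: no rotatable branches
  bz <- benzene_sdf(tempfile(fileext = ".sdf"))
  out2 <- prepare_ligand(bz)
  expect_false(any(startsWith(readLines(out2, warn = FALSE), "BRANCH")))

  # determinism
  out3 <- prepare_ligand(eth)
  expect_identical(readLines(out, warn = FALSE), readLines(out3, warn = FALSE))
})
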