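test_that("complex generation is a pure function of its spec", {
  planted <- data.frame(residue = c(3, 8),
                        type = c("hydrophobic", "metal_contact"))
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  c1 <- generate_complex(planted, pdb_path = f1)
  c2 <- generate_complex(planted, pdb_path = f2)
  expect_identical(readLines(f1, warn = FALSE), readLines(f2, warn = FALSE))
  expect_identical(c1$pose$atoms, c2$pose$atoms)
  expect_identical(c1$expected, c2$expected)
})

test_that("complex generation enforces its structural contract", {
  expect_error(generate_complex(data.frame(residue = c(4, 4),
                                           type = c("hydrophobic",
                                                    "metal_contact"))),
               "one planted interaction per residue")
  expect_error(generate_complex(data.frame(residue = 3, type = "nope")),
               "unknown interaction type")
  expect_error(generate_complex(n_residues = 5), "10-30")
  expect_error(generate_complex(data.frame(residue = 25, type = "hydrophobic"),
                                n_residues = 12), "exceeds chain length")
  # receptors are valid PDB: parseable with sensible residue count
  cx <- generate_complex(data.frame(residue = 7, type = "aromatic_face"))
  expect_s3_class(cx$receptor, "receptor")
  expect_gte(nrow(cx$receptor$residues), 10)
  expect_lte(nrow(cx$receptor$residues), 30)
})

test_that("toy libraries satisfy their similarity constraints", {
  lib <- toy_library()
  smi <- vapply(lib$entries, function(e) e$cocrystal_smiles, character(1))
  cls <- vapply(lib$entries, function(e) e$target_class, character(1))
  fps <- compute_fingerprints_batch(smi, "morgan", ids = smi)
  tan <- function(i, j) tanimoto(fps[[i]]$fingerprints$morgan,
                                 fps[[j]]$fingerprints$morgan)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    expect_gte(tan(idx[1], idx[2]), 0.7)  # near-duplicate pair
  }
  for (i in seq_along(smi)) for (j in seq_along(smi)) {
    if (cls[i] != cls[j]) expect_lte(tan(i, j), 0.3)
  }
})

test_that("library generation is deterministic for a fixed seed", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  lib1 <- generate_library(d1, n_classes = 2, n_targets_per_class = 2, seed = 4)
  lib2 <- generate_library(d2, n_classes = 2, n_targets_per_class = 2, seed = 4)
  expect_identical(readLines(attr(lib1, "manifest"), warn = FALSE),
                   readLines(attr(lib2, "manifest"), warn = FALSE))
  expect_identical(lib1$entries[[1]]$cocrystal_fps,
                   lib2$entries[[1]]$cocrystal_fps)
  expect_identical(vapply(lib1$entries, function(e) e$activity, numeric(1)),
                   vapply(lib2$entries, function(e) e$activity, numeric(1)))
})

test_that("synthetic activity datasets encode the declared linear signal", {
  ds1 <- generate_activity_dataset(n = 60, k_informative = 4, noise_sd = 0,
                                   seed = 6)
  ds2 <- generate_activity_dataset(n = 60, k_informative = 4, noise_sd = 0,
                                   seed = 6)
  expect_identical(ds1$features, ds2$features)
  expect_identical(ds1$activity, ds2$activity)
  # the recorded truth reproduces the labels exactly at zero noise
  rebuilt <- ds1$truth$intercept +
    as.numeric(ds1$features[, ds1$truth$informative_bits] %*% ds1$truth$weights)
  expect_equal(rebuilt, ds1$activity)
  # informative bits have moderate frequency by construction
  freq <- colMeans(ds1$features[, ds1$truth$informative_bits, drop = FALSE])
  expect_true(all(freq >= 0.2 & freq <= 0.8))
  expect_equal(anyDuplicated(ds1$smiles), 0)
})

test_that("decoy sets respect similarity and weight-spread constraints", {
  lib <- toy_library()
  targets <- vapply(lib$entries, function(e) e$target_name, character(1))[1:2]
  d1 <- generate_decoys(lib, targets, n_per_target = 4, seed = 2)
  d2 <- generate_decoys(lib, targets, n_per_target = 4, seed = 2)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 8)
  expect_gte(diff(range(d1$mw)), 100)

  # every decoy stays below the similarity bound to its intended target
  all_names <- vapply(lib$entries, function(e) e$target_name, character(1))
  all_smis <- vapply(lib$entries, function(e) e$cocrystal_smiles, character(1))
  smi_by_name <- split(all_smis, all_names)
  dec_fps <- compute_fingerprints_batch(unique(d1$smiles), "morgan",
                                        ids = unique(d1$smiles))
  names(dec_fps) <- unique(d1$smiles)
  for (k in seq_len(nrow(d1))) {
    refs <- unique(smi_by_name[[d1$intended_target[k]]])
    ref_fps <- compute_fingerprints_batch(refs, "morgan", ids = refs)
    sims <- vapply(ref_fps, function(rf) {
      tanimoto(dec_fps[[d1$smiles[k]]]$fingerprints$morgan,
               rf$fingerprints$morgan)
    }, numeric(1))
    expect_lt(max(sims), 0.4)
  }

  # by construction the intended target cannot clear the 0.4 shortlist
  # cutoff, so it is absent from every decoy's top-1
  res <- predict_targets(d1$smiles[1], lib,
                         prediction_options("MMD", cutoff = 0.4),
                         toy_engine())
  if (nrow(res) > 0) {
    expect_false(.norm_eq(res$target_name[res$rank == 1],
                          d1$intended_target[1]))
  } else {
    succeed()
  }
})

.norm_eq <- function(a, b) tolower(trimws(a)) == tolower(trimws(b))
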