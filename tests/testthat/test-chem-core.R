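test_that("SMILES files parse in order, with invalid entries reported", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benzene", "CCO ethanol", "CC(=O)O acetic"), f)
  mols <- parse_molecules(f, "smiles")
  expect_equal(mols$id, c("benzene", "ethanol", "acetic"))
  expect_equal(mols$n_heavy[1], 6)  # benzene: six heavy atoms
  expect_equal(nrow(attr(mols, "rejected")), 0)

  f2 <- tempfile(fileext = ".smi")
  writeLines(c("CCO a", "not_a_smiles b", "CCN c"), f2)
  expect_warning(mols2 <- parse_molecules(f2, "smiles"), "rejected")
  expect_equal(nrow(mols2), 2)
  expect_equal(mols2$id, c("a", "c"))
  rej <- attr(mols2, "rejected")
  expect_equal(nrow(rej), 1)
  expect_equal(rej$id, "b")

  expect_error(parse_molecules(tempfile(), "smiles"), "cannot read")
  f3 <- tempfile(fileext = ".smi")
  writeLines("junk1 junkmol", f3)
  expect_error(suppressWarnings(parse_molecules(f3, "smiles")), "no valid")
})

test_that("fingerprint generation is deterministic with configured lengths", {
  a <- compute_fingerprints("CCO", c("morgan", "maccs", "daylight"))
  b <- compute_fingerprints("CCO", c("morgan", "maccs", "daylight"))
  expect_identical(a$fingerprints, b$fingerprints)
  methane <- compute_fingerprints("C", "morgan")
  expect_equal(methane$fingerprints$morgan$nbits, 2048)
  expect_gte(methane$fingerprints$morgan$n_on, 0)
  expect_equal(a$fingerprints$maccs$nbits, 166)
  expect_error(compute_fingerprints("CCO", "nosuchfp"), "unknown")
})

test_that("atom order in SDF input does not change canonical fingerprints", {
  f1 <- ethanol_sdf(tempfile(fileext = ".sdf"), order = c(1L, 2L, 3L))
  f2 <- ethanol_sdf(tempfile(fileext = ".sdf"), order = c(3L, 1L, 2L))
  m1 <- parse_molecules(f1, "sdf")
  m2 <- parse_molecules(f2, "sdf")
  expect_identical(m1$smiles, m2$smiles)
  fp1 <- compute_fingerprints(m1$smiles, c("morgan", "maccs"))
  fp2 <- compute_fingerprints(m2$smiles, c("morgan", "maccs"))
  expect_identical(fp1$fingerprints, fp2$fingerprints)
  # independent canonicalizer agrees the two files hold the same molecule
  obabel <- Sys.which("obabel")
  if (nzchar(obabel)) {
    can <- function(f) system2(obabel, c("-isdf", shQuote(f), "-ocan"),
                               stdout = TRUE, stderr = FALSE)[1]
    expect_identical(can(f1), can(f2))
  }
})

test_that("tanimoto reproduces hand-evaluated cases and rejects mismatches", {
  a <- fingerprint("fp", c(0, 1, 2), 64)
  expect_equal(tanimoto(a, a), 1.0)
  b <- fingerprint("fp", c(10, 11, 12), 64)
  expect_equal(tanimoto(a, b), 0.0)
  # N_a = 3, N_b = 3, N_ab = 2 -> 2 / (3 + 3 - 2) = 0.5
  c2 <- fingerprint("fp", c(1, 2, 9), 64)
  expect_equal(tanimoto(a, c2), 0.5)
  expect_error(tanimoto(a, fingerprint("other", 1, 64)), "algorithm mismatch")
  expect_error(tanimoto(a, fingerprint("fp", 1, 32)), "length mismatch")
  z <- fingerprint("fp", integer(0), 64)
  expect_warning(v <- tanimoto(z, z), "all-zero")
  expect_equal(v, 0.0)
})

test_that("tanimoto matches a brute-force oracle on 1000 random pairs", {
  set.seed(42)
  nbits <- 128
  for (i in 1:1000) {
    av <- stats::runif(nbits) < stats::runif(1, 0.02, 0.5)
    bv <- stats::runif(nbits) < stats::runif(1, 0.02, 0.5)
    a <- fingerprint("fp", which(av) - 1L, nbits)
    b <- fingerprint("fp", which(bv) - 1L, nbits)
    union <- sum(av | bv)
    oracle <- if (union == 0) 0 else sum(av & bv) / union
    got <- suppressWarnings(tanimoto(a, b))
    expect_equal(got, oracle)
    expect_equal(got, suppressWarnings(tanimoto(b, a)))  # symmetry
    expect_gte(got, 0); expect_lte(got, 1)
    if (sum(av) > 0) expect_equal(tanimoto(a, a), 1)
  }
})

test_that("ligand similarity averages per-algorithm Tanimoto components", {
  # planted bit sets realizing components 0.2, 0.4, 0.6
  mk <- function(alg, q_bits, r_bits) {
    list(q = fingerprint(alg, q_bits, 32), r = fingerprint(alg, r_bits, 32))
  }
  p1 <- mk("a1", c(0, 1, 2), c(0, 8, 9))          # 1/5  = 0.2
  p2 <- mk("a2", c(0, 1, 2), c(0, 1, 8, 9))       # 2/5  = 0.4
  p3 <- mk("a3", c(0, 1, 2, 3), c(0, 1, 2, 9))    # 3/5  = 0.6
  q <- fingerprint_set("q", list(a1 = p1$q, a2 = p2$q, a3 = p3$q))
  r <- fingerprint_set("r", list(a1 = p1$r, a2 = p2$r, a3 = p3$r))
  s <- ligand_similarity(q, r, c("a1", "a2", "a3"))
  expect_equal(unname(s$components), c(0.2, 0.4, 0.6))
  expect_equal(s$value, 0.4)
  # single algorithm: mean of one
  s1 <- ligand_similarity(q, r, "a2")
  expect_equal(s1$value, 0.4)
  # identity query
  si <- ligand_similarity(q, q, c("a1", "a2", "a3"))
  expect_equal(unname(si$components), c(1, 1, 1))
  expect_equal(si$value, 1)
  # missing algorithm is a contract error, not silent subsetting
  expect_error(ligand_similarity(q, r, c("a1", "zz")), "missing algorithm")
})

test_that("ligand similarity is monotone in each component", {
  set.seed(7)
  for (i in 1:50) {
    q_bits <- sort(sample(0:63, 8))
    r1 <- sort(sample(0:63, 8))
    q <- fingerprint_set("q", list(a = fingerprint("a", q_bits, 64),
                                   b = fingerprint("b", q_bits, 64)))
    r_lo <- fingerprint_set("r", list(a = fingerprint("a", r1, 64),
                                      b = fingerprint("b", r1, 64)))
    # raise component "b" by making it identical to the query
    r_hi <- fingerprint_set("r", list(a = fingerprint("a", r1, 64),
                                      b = fingerprint("b", q_bits, 64)))
    expect_gte(ligand_similarity(q, r_hi, c("a", "b"))$value,
               ligand_similarity(q, r_lo, c("a", "b"))$value)
  }
})

test_that("fingerprint sidecar files round-trip", {
  sets <- compute_fingerprints_batch(c("CCO", "c1ccccc1"),
                                     c("morgan", "maccs"),
                                     ids = c("m1", "m2"))
  path <- tempfile(fileext = ".json")
  write_fingerprints(sets, path)
  back <- read_fingerprints(path)
  expect_equal(names(back), c("m1", "m2"))
  expect_identical(back$m1$fingerprints, sets[[1]]$fingerprints)
  expect_identical(back$m2$fingerprints, sets[[2]]$fingerprints)
})

test_that("fingerprint presets match their published compositions", {
  expect_equal(fp_preset("MM"), c("morgan", "maccs"))
  expect_equal(fp_preset("MMD"), c("morgan", "maccs", "daylight"))
})
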