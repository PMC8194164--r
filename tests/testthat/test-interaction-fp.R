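all_ifp_types <- c("hydrophobic", "aromatic_face", "aromatic_edge",
                   "hb_protein_acceptor", "hb_protein_donor",
                   "salt_bridge_protein_positive",
                   "salt_bridge_protein_negative", "metal_contact")

test_that("every planted interaction type is recovered bit-exactly", {
  for (ty in all_ifp_types) {
    cx <- generate_complex(data.frame(residue = 7, type = ty))
    ifp <- extract_ifp(cx$receptor, cx$pose)
    expect_identical(unname(ifp$bits), unname(cx$expected),
                     label = paste("planted", ty))
    expect_equal(sum(ifp$bits), 1, label = paste("exactly one bit for", ty))
  }
})

test_that("multi-interaction complexes recover all planted bits and nothing else", {
  planted <- data.frame(
    residue = c(3, 5, 8, 10),
    type = c("hydrophobic", "hb_protein_donor", "aromatic_face",
             "metal_contact"))
  cx <- generate_complex(planted)
  ifp <- extract_ifp(cx$receptor, cx$pose)
  expect_identical(unname(ifp$bits), unname(cx$expected))
  expect_equal(sum(ifp$bits), 4)
})

test_that("a ligand far from every residue yields an all-zero fingerprint", {
  cx <- generate_complex(data.frame(residue = 6, type = "hydrophobic"))
  far <- shift_pose(cx$pose, c(0, 0, 20))
  ifp <- extract_ifp(cx$receptor, far)
  expect_equal(sum(ifp$bits), 0)
})

test_that("extraction is deterministic and invariant to rigid motion", {
  cx <- generate_complex(data.frame(residue = c(4, 9),
                                    type = c("hb_protein_donor",
                                             "salt_bridge_protein_positive")))
  i1 <- extract_ifp(cx$receptor, cx$pose)
  i2 <- extract_ifp(cx$receptor, cx$pose)
  expect_identical(i1$bits, i2$bits)

  # rotate receptor and pose jointly: bits must not change
  th <- 0.61
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  shift <- c(5.5, -3.2, 7.1)
  rec2 <- cx$receptor
  xyz <- as.matrix(rec2$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rot), 2, shift, FUN = "+")
  rec2$atoms$x <- xyz[, 1]; rec2$atoms$y <- xyz[, 2]; rec2$atoms$z <- xyz[, 3]
  pose2 <- transform_pose(cx$pose, rot, shift)
  i3 <- extract_ifp(rec2, pose2)
  expect_identical(i1$bits, i3$bits)
})

test_that("binding similarity follows the Tanimoto arithmetic", {
  planted <- data.frame(
    residue = c(3, 5, 8, 10),
    type = c("hydrophobic", "hb_protein_donor", "aromatic_face",
             "metal_contact"))
  cx <- generate_complex(planted)
  ref <- extract_ifp(cx$receptor, cx$pose)
  # co-crystal against itself: T_B = 1
  expect_equal(align_and_compare(ref, ref)$value, 1)

  # keep the first two planted fragments (1 atom each), push the rest away:
  # query reproduces exactly half of the reference's 4 bits, adds none
  # -> 2 / (4 + 2 - 2) = 0.5
  half <- cx$pose
  keep <- 1:2
  half$atoms[-keep, c("z")] <- half$atoms[-keep, "z"] + 40
  q <- extract_ifp(cx$receptor, half)
  expect_equal(sum(q$bits), 2)
  cmp <- align_and_compare(q, ref)
  expect_equal(cmp$value, 0.5)
  expect_equal(cmp$shared_on_bits, 2L)

  # both empty: 0 with a warning
  far <- shift_pose(cx$pose, c(0, 0, 50))
  e1 <- extract_ifp(cx$receptor, far)
  expect_warning(v <- align_and_compare(e1, e1)$value, "empty")
  expect_equal(v, 0)

  # different receptors are never comparable
  other <- generate_complex(data.frame(residue = 3, type = "hydrophobic"),
                            n_residues = 14)
  expect_error(align_and_compare(ref, extract_ifp(other$receptor, other$pose)),
               "different residue")
})

test_that("adding query-only bits never increases T_B (brute force, 1 residue)", {
  res <- data.frame(chain = "A", resno = 1L, resname = "ALA",
                    stringsAsFactors = FALSE)
  mk <- function(bits8) {
    structure(list(residues = res,
                   bits = matrix(bits8, 1, 8,
                                 dimnames = list(NULL, targetfish:::IFP_SLOTS)),
                   scheme_version = "v1", receptor_id = "x"),
              class = "interaction_fp")
  }
  jacc <- function(a, b) {
    u <- sum(a | b); if (u == 0) 0 else sum(a & b) / u
  }
  set.seed(11)
  for (i in 1:200) {
    qa <- stats::runif(8) < 0.4
    rb <- stats::runif(8) < 0.4
    got <- suppressWarnings(align_and_compare(mk(qa), mk(rb))$value)
    expect_equal(got, jacc(qa, rb))
    # flip on one query bit absent from the reference
    off <- which(!qa & !rb)
    if (length(off)) {
      qa2 <- qa; qa2[off[1]] <- TRUE
      got2 <- suppressWarnings(align_and_compare(mk(qa2), mk(rb))$value)
      expect_lte(got2, got + 1e-12)
    }
  }
})

test_that("interaction tables list each set bit with residue context", {
  cx <- generate_complex(data.frame(residue = c(4, 9),
                                    type = c("aromatic_edge", "metal_contact")))
  ifp <- extract_ifp(cx$receptor, cx$pose)
  tab <- interaction_table(ifp)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$interaction, c("aromatic_edge", "metal_contact"))
  expect_setequal(tab$resno, c(4, 9))
  out <- tempfile(fileext = ".tsv")
  interaction_table(ifp, out)
  expect_true(file.exists(out))
  expect_equal(nrow(utils::read.delim(out)), 2)
})
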