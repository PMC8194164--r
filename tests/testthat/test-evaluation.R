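test_that("top-N success rates follow rank thresholds", {
  res <- list(q1 = fake_result(c("true A", paste("f", 1:11)), "q1"))
  truth <- list(q1 = "True A")  # case-insensitive matching
  expect_equal(success_rate(res, truth, 1), 1)
  expect_equal(success_rate(res, truth, 5), 1)
  expect_equal(success_rate(res, truth, 10), 1)

  # true targets at ranks 3 and 12 over two queries
  res2 <- list(
    q1 = fake_result(c("f1", "f2", "tA", paste("g", 1:9)), "q1"),
    q2 = fake_result(c(paste("h", 1:11), "tB"), "q2"))
  truth2 <- list(q1 = "tA", q2 = "tB")
  expect_equal(success_rate(res2, truth2, 1), 0)
  expect_equal(success_rate(res2, truth2, 5), 0.5)
  expect_equal(success_rate(res2, truth2, 10), 0.5)

  # queries without truth are excluded with a warning
  expect_warning(v <- success_rate(res2, truth2[1], 5), "without ground truth")
  expect_equal(v, 1)
})

test_that("precision/recall/F1 at N reproduce hand-worked cases", {
  # 2 true targets, 1 matched within top 10 of exactly 10 records
  res <- list(q = fake_result(c("tA", paste("f", 1:9)), "q"))
  truth <- list(q = c("tA", "tB"))
  prf <- prf_at_n(res, truth, 10)
  expect_equal(prf$recall, 0.5)
  expect_equal(prf$precision, 0.1)
  expect_equal(prf$f1, 2 * 0.1 * 0.5 / (0.1 + 0.5))

  # perfect retrieval: |truth| = n, all in top n
  res2 <- list(q = fake_result(c("tA", "tB", "tC"), "q"))
  prf2 <- prf_at_n(res2, list(q = c("tA", "tB", "tC")), 3)
  expect_equal(prf2$precision, 1)
  expect_equal(prf2$recall, 1)
  expect_equal(prf2$f1, 1)

  # total miss
  prf3 <- prf_at_n(res2, list(q = "zz"), 3)
  expect_equal(c(prf3$precision, prf3$recall, prf3$f1), c(0, 0, 0))

  # zero returned records: flagged (0, 0, 0)
  empty <- fake_result(character(0), "q")
  prf4 <- prf_at_n(list(q = empty), list(q = "tA"), 10)
  expect_true(prf4$per_query$flagged)
  expect_equal(prf4$f1, 0)

  # duplicate PDB entries of one target name count once toward TP
  res5 <- list(q = fake_result(c("tA", "tA", "f1"), "q"))
  prf5 <- prf_at_n(res5, list(q = c("tA", "tB")), 3)
  expect_equal(prf5$per_query$tp, 1)
})

test_that("precision/recall/F1 agree with a brute-force oracle", {
  oracle <- function(ranked, truth, n) {
    truth <- unique(tolower(truth))
    top <- unique(tolower(ranked[seq_len(min(n, length(ranked)))]))
    tp <- 0
    for (t in truth) for (p in top) if (identical(t, p)) tp <- tp + 1
    denom <- min(n, length(ranked))
    if (denom == 0) return(c(0, 0, 0))
    prec <- tp / denom
    rec <- tp / length(truth)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec, rec, f1)
  }
  set.seed(13)
  pool <- sprintf("name%02d", 1:15)
  for (i in 1:200) {
    len <- sample(0:12, 1)
    ranked <- sample(pool, len)
    truth <- sample(pool, sample(1:3, 1))
    n <- sample(c(1, 5, 10), 1)
    got <- prf_at_n(list(q = fake_result(ranked, "q")),
                    list(q = truth), n)
    expect_equal(c(got$precision, got$recall, got$f1),
                 oracle(ranked, truth, n))
  }
})

test_that("success rates never decrease with N", {
  set.seed(21)
  pool <- sprintf("n%02d", 1:20)
  res <- lapply(1:15, function(k) fake_result(sample(pool, 12), paste0("q", k)))
  names(res) <- paste0("q", 1:15)
  truth <- stats::setNames(lapply(1:15, function(k) sample(pool, 2)),
                           paste0("q", 1:15))
  s <- vapply(c(1, 3, 5, 8, 10, 12), function(n) success_rate(res, truth, n),
              numeric(1))
  expect_true(all(diff(s) >= 0))
})

test_that("evaluation reports aggregate ranks, success and PRF", {
  res <- list(
    q1 = fake_result(c("tA", "f1", "f2"), "q1"),
    q2 = fake_result(c("f1", "f2", "tB", "f3"), "q2"))
  truth <- list(q1 = "tA", q2 = "tB")
  rep <- evaluation_report(res, truth)
  expect_equal(unname(rep$first_true_rank), c(1L, 3L))
  expect_equal(unname(rep$success), c(0.5, 1, 1))
  expect_s3_class(rep$per_query, "data.frame")
})

test_that("decoy evaluation counts cumulative top-N recoveries", {
  # 50 decoys, intended target in top 10 for 3 of them -> fail 94%
  mk_decoys <- function(tname, ranks, n = 50) {
    out <- list()
    for (k in seq_len(n)) {
      names_k <- paste("f", 1:12)
      if (k <= length(ranks)) names_k[ranks[k]] <- tname
      out[[sprintf("%s_d%02d", tname, k)]] <- fake_result(names_k)
    }
    out
  }
  res <- mk_decoys("CA target", c(1, 7, 9))
  intended <- stats::setNames(rep("CA target", 50), names(res))
  rep <- decoy_evaluate(res, intended)
  expect_equal(rep$top1, 1)
  expect_equal(rep$top10, 3)
  expect_equal(rep$top10_pct, 6)
  expect_equal(rep$fail_pct, 94)
  expect_equal(rep$fail, 47)
  # counts are cumulative in N
  expect_true(rep$top1 <= rep$top5 && rep$top5 <= rep$top10)

  # total rejection
  res0 <- mk_decoys("X", integer(0), n = 10)
  rep0 <- decoy_evaluate(res0, stats::setNames(rep("X", 10), names(res0)))
  expect_equal(rep0$fail_pct, 100)
})

test_that("pooled percentage aggregation reproduces table arithmetic", {
  counts <- data.frame(n = c(19, 19, 18, 16, 5),
                       top10 = c(19, 18, 13, 16, 0))
  agg <- aggregate_table(counts)
  expect_equal(unname(agg$totals["n"]), 77)
  expect_equal(unname(agg$totals["top10"]), 66)
  expect_equal(unname(agg$percent["top10"]), 86)

  # count conservation and validation
  expect_equal(sum(counts$top10), unname(agg$totals["top10"]))
  expect_error(aggregate_table(data.frame(n = 5, top10 = 7)), "inconsistent")
  zero <- aggregate_table(data.frame(n = c(10, 10), top10 = c(0, 0)))
  expect_equal(unname(zero$percent["top10"]), 0)
})
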