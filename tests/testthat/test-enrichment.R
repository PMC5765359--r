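test_that("exact Poisson test matches its worked examples and edge cases", {
  expect_equal(exact_poisson_test(0, 0, 100, 100), 1)
  # symmetric mode: every outcome is at most as likely as the observed one
  expect_equal(exact_poisson_test(5, 5, 100, 100), 1)
  # 5 vs 0 with equal libraries: outcomes 0 and 5 of Binomial(5, 1/2)
  expect_equal(exact_poisson_test(5, 0, 100, 100), 2 / 32)
  # vectorized
  expect_equal(exact_poisson_test(c(0, 5, 5), c(0, 5, 0), 100, 100),
               c(1, 1, 0.0625))
  expect_error(exact_poisson_test(1, 1, 0, 100), "library")
  expect_error(exact_poisson_test(-1, 1, 100, 100), "counts")
})

test_that("exact test agrees with enumeration, is symmetric and scale-free", {
  ratios <- list(c(100, 200), c(150, 150), c(200, 100))
  for (ns in ratios) {
    for (t in c(1, 3, 7, 12)) {
      for (y1 in 0:t) {
        p_pkg <- exact_poisson_test(y1, t - y1, ns[1], ns[2])
        expect_equal(p_pkg, oracle_exact_p(y1, t - y1, ns[1], ns[2]),
                     tolerance = 1e-13)
        # label symmetry
        expect_equal(p_pkg, exact_poisson_test(t - y1, y1, ns[2], ns[1]),
                     tolerance = 1e-13)
        # scaling both libraries leaves p unchanged
        expect_equal(p_pkg, exact_poisson_test(y1, t - y1, 7 * ns[1],
                                               7 * ns[2]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("exact test agrees with the edgeR Poisson exact test", {
  skip_if_not_installed("edgeR")
  set.seed(5)
  y1 <- sample(0:40, 25, TRUE); y2 <- sample(0:40, 25, TRUE)
  p_pkg <- exact_poisson_test(y1, y2, 1e5, 2e5)
  p_edger <- edgeR::binomTest(y1, y2, 1e5, 2e5)
  # on exact probability ties edgeR's sorted-cumsum excludes outcomes
  # order-dependently while the minimum-likelihood rule includes all tied
  # outcomes; compare only the tie-free cases
  tie_free <- vapply(seq_along(y1), function(i) {
    t <- y1[i] + y2[i]
    if (t == 0) return(TRUE)
    d <- dbinom(0:t, t, 1 / 3)
    dobs <- d[y1[i] + 1]
    sum(abs(d - dobs) < 1e-6 * dobs) == 1
  }, logical(1))
  expect_gt(sum(tie_free), 15)
  expect_equal(p_pkg[tie_free], p_edger[tie_free], tolerance = 1e-9)
  # tied cases can only make the minimum-likelihood p larger
  expect_true(all(p_pkg >= p_edger - 1e-9))
})

test_that("doubled-tail alternative is a valid two-sided p-value", {
  p_min <- exact_poisson_test(9, 1, 100, 100)
  p_dbl <- exact_poisson_test(9, 1, 100, 100, method = "doubled")
  expect_gte(p_dbl, p_min - 1e-12)
  expect_true(all(exact_poisson_test(0:6, 6:0, 100, 300,
                                     method = "doubled") <= 1))
  expect_equal(exact_poisson_test(0, 0, 10, 10, method = "doubled"), 1)
})

test_that("log2 enrichment follows the prior-count formula", {
  expect_equal(log2_enrichment(10, 10, 1e6, 1e6), 0)
  expect_equal(log2_enrichment(7, 0, 1e6, 1e6, prior = 1), 3)
  # n_ip = 2 n_mock: log2((16/2n) / (4/n)) = 1
  expect_equal(log2_enrichment(15, 3, 2e6, 1e6, prior = 1), 1)
  # scaling both libraries by c leaves the value unchanged
  expect_equal(log2_enrichment(15, 3, 2e6 * 3, 1e6 * 3, prior = 1), 1)
  # finite even at zero counts
  expect_true(is.finite(log2_enrichment(0, 0, 1e6, 5e5)))
  expect_error(log2_enrichment(1, 1, 1e6, 1e6, prior = 0), "prior")
})

test_that("BH adjustment matches the step-up definition and its properties", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.1)), c(0.015, 0.06, 0.1))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.2, 1.2)), "\\[0, 1\\]")

  set.seed(31)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-15))
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("replicate-pair enrichment reproduces direct per-pair computation", {
  set.seed(12)
  n_feat <- 20
  mock_mat <- matrix(rpois(n_feat * 3, 50), n_feat, 3)
  ip_mat <- matrix(rpois(n_feat * 3, 50), n_feat, 3)
  ip_mat[7, ] <- rpois(3, 400)             # spiked 8x feature
  lib_ip <- colSums(ip_mat) + 1000
  lib_mock <- colSums(mock_mat) + 800
  ip <- mk_counts(ip_mat, lib_ip)
  mock <- mk_counts(mock_mat, lib_mock)
  res <- enrich_pairs(ip, mock, prior = 1)

  pairs <- attr(res, "pairs")
  expect_identical(dim(pairs), c(2L, 3L))
  for (k in 1:3) {
    i <- pairs[1, k]; j <- pairs[2, k]
    yi <- ip_mat[, i] + ip_mat[, j]; ni <- lib_ip[i] + lib_ip[j]
    ym <- mock_mat[, i] + mock_mat[, j]; nm <- lib_mock[i] + lib_mock[j]
    expect_equal(res[[paste0("log2_pair", k)]],
                 log2_enrichment(yi, ym, ni, nm, 1))
    expect_equal(res[[paste0("p_pair", k)]],
                 exact_poisson_test(yi, ym, ni, nm))
    expect_equal(res[[paste0("fdr_pair", k)]],
                 bh_adjust(res[[paste0("p_pair", k)]]))
    expect_true(all(res[[paste0("fdr_pair", k)]] >=
                      res[[paste0("p_pair", k)]] - 1e-15))
  }
  # the spiked feature attains the maximum combined enrichment
  expect_identical(which.max(res$combined_log2), 7L)
  expect_true(res$is_target[7])
  # combined value averages only FDR-passing pairs
  pass <- res[7, paste0("fdr_pair", 1:3)] < 0.01
  expect_equal(res$combined_log2[7],
               mean(unlist(res[7, paste0("log2_pair", 1:3)])[unlist(pass)]))
})

test_that("pair combination handles identity, zeros and mismatches", {
  # identical pooled normalized counts in every pair -> combined 0
  mat <- matrix(30, 4, 3, dimnames = list(paste0("f", 1:4), NULL))
  ip <- mk_counts(mat, c(1e4, 1e4, 1e4))
  mock <- mk_counts(mat, c(1e4, 1e4, 1e4))
  res <- enrich_pairs(ip, mock)
  expect_equal(res$combined_log2, rep(0, 4))
  # identical replicates -> all per-pair p equal
  expect_equal(res$p_pair1, res$p_pair2)
  expect_equal(res$p_pair2, res$p_pair3)

  # all-zero features report log2 = 0 and p = 1 even with unequal libraries
  z <- matrix(0, 2, 3, dimnames = list(c("a", "b"), NULL))
  rz <- enrich_pairs(mk_counts(z, c(1e4, 2e4, 3e4)),
                     mk_counts(z, c(5e3, 5e3, 5e3)))
  expect_equal(rz$combined_log2, c(0, 0))
  expect_equal(rz$p_pair1, c(1, 1))

  # mismatched feature lists error
  bad <- mk_counts(matrix(1, 3, 3, dimnames = list(c("x", "y", "z"), NULL)),
                   rep(1e4, 3))
  expect_error(enrich_pairs(ip, bad), "feature list")
  # fewer than two replicates error
  expect_error(enrich_pairs(mk_counts(mat[, 1, drop = FALSE], 1e4), mock),
               "replicates")
})

test_that("crossed pairing tests single replicates against each other", {
  set.seed(9)
  ip_mat <- matrix(rpois(9, 80), 3, 3)
  mock_mat <- matrix(rpois(9, 40), 3, 3)
  ip <- mk_counts(ip_mat, c(1e4, 1.2e4, 9e3))
  mock <- mk_counts(mock_mat, c(8e3, 1.1e4, 1e4))
  res <- enrich_pairs(ip, mock, pairing = "crossed")
  pairs <- attr(res, "pairs")
  k <- 1; i <- pairs[1, k]; j <- pairs[2, k]
  expect_equal(res$log2_pair1,
               log2_enrichment(ip_mat[, i], mock_mat[, j],
                               1e4, c(8e3, 1.1e4, 1e4)[j], 1))
})

test_that("target calling applies the two-of-three consensus rule", {
  expect_identical(call_targets(data.frame(feature_id = character(0),
                                           log2_pair1 = numeric(0),
                                           fdr_pair1 = numeric(0))),
                   character(0))
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    log2_pair1 = c(2, 2, 2, 0.5),
                    log2_pair2 = c(2, 2, 0.5, 2),
                    log2_pair3 = c(2, 0.5, 0.5, 2),
                    fdr_pair1 = c(0.001, 0.001, 0.001, 0.5),
                    fdr_pair2 = c(0.001, 0.001, 0.001, 0.001),
                    fdr_pair3 = c(0.001, 0.5, 0.001, 0.001),
                    stringsAsFactors = FALSE)
  # a: 3 pairs pass; b: 2 (pair3 fails FDR); c: 1 (log2 too low); d: 2
  expect_identical(call_targets(res), c("a", "b", "d"))
  expect_identical(call_targets(res, min_reps = 3), "a")
  expect_identical(call_targets(res, log2_cutoff = 1.5, fdr_cutoff = 0.01,
                                min_reps = 2), c("a", "b", "d"))
})

test_that("region tallies count features above the fold cutoff", {
  res <- data.frame(feature_id = paste0("g", 1:6, ":", rep(c("utr5", "utr3"), 3)),
                    kind = rep(c("utr5", "utr3"), 3),
                    combined_log2 = c(0.5, 2.5, 1.0, 2.1, 2.2, 1.9),
                    stringsAsFactors = FALSE)
  tal <- region_enrichment_tally(res, fold_cutoff = 4)   # log2 > 2
  expect_equal(tal, c(utr5 = 1L, utr3 = 2L))
  expect_equal(region_enrichment_tally(res, fold_cutoff = 2),
               c(utr5 = 1L, utr3 = 3L))                  # log2 > 1
  none <- region_enrichment_tally(
    data.frame(kind = "utr3", combined_log2 = 0.1), 4)
  expect_equal(unname(none), 0L)
})

test_that("RPKM uses the 0.5 pseudocount and replicate averaging", {
  expect_equal(compute_rpkm(1000, 1000, 1e6), 1000.5)
  expect_equal(compute_rpkm(0, 2000, 1e6), 0.5 / 2)
  m <- matrix(c(100, 100), 1, 2)
  expect_equal(unname(compute_rpkm(m, 1000, c(1e6, 1e6))),
               compute_rpkm(100, 1000, 1e6))
  # different replicates: mean of per-replicate RPKM
  m2 <- matrix(c(100, 300), 1, 2)
  expect_equal(unname(compute_rpkm(m2, 1000, c(1e6, 2e6))),
               mean(c(compute_rpkm(100, 1000, 1e6),
                      compute_rpkm(300, 1000, 2e6))))
  expect_error(compute_rpkm(1, 0, 1e6), "gene_length")
  expect_error(compute_rpkm(1, 100, 0), "library_size")
})
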