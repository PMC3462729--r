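test_that("array-pair sampling is exhaustive for small P, seeded otherwise", {
  ps <- sample_array_pairs(3, n_pairs = 100, seed = 1)
  expect_true(ps$exhaustive)
  expect_equal(ps$pairs, cbind(k = c(1L, 1L, 2L), l = c(2L, 3L, 3L)),
               ignore_attr = TRUE)

  a <- sample_array_pairs(50, n_pairs = 100, seed = 42)
  b <- sample_array_pairs(50, n_pairs = 100, seed = 42)
  expect_false(a$exhaustive)
  expect_identical(a$pairs, b$pairs)
  expect_equal(nrow(a$pairs), 100L)
  expect_true(all(a$pairs[, 1L] < a$pairs[, 2L]))
  expect_false(any(duplicated(a$pairs)))
  expect_error(sample_array_pairs(1), "n_arrays")
})

test_that("pair inclusion is uniform across seeds within binomial error", {
  P <- 50L
  total <- P * (P - 1L) / 2L
  n_draws <- 4000L
  counts <- matrix(0L, P, P)
  for (s in seq_len(n_draws)) {
    pr <- sample_array_pairs(P, n_pairs = 100, seed = s)$pairs
    counts[pr] <- counts[pr] + 1L
  }
  freq <- counts[upper.tri(counts)]
  p <- 100 / total
  se <- sqrt(p * (1 - p) / n_draws)
  # ~1225 pair frequencies; allow a 5-sigma band
  expect_true(all(abs(freq / n_draws - p) < 5 * se))
})

test_that("differential spread vanishes for parallel profiles", {
  m <- rbind(g1 = c(1, 3, 2), g2 = c(1, 3, 2))
  colnames(m) <- paste0("a", 1:3)
  em <- expression_matrix(m, "t")
  ps <- sample_array_pairs(3, seed = 1)
  expect_equal(unname(diff_spread(c("g1", "g2"), em, ps)), c(0, 0))

  # constant offset between genes: d_i identical across genes, SD still 0
  m2 <- rbind(A = c(1, 3), B = c(5, 7))
  colnames(m2) <- c("a1", "a2")
  em2 <- expression_matrix(m2, "t")
  ps2 <- sample_array_pairs(2, seed = 1)
  expect_equal(unname(diff_spread(c("A", "B"), em2, ps2)), c(0, 0))
  # while the absolute spread is positive (sd of (1,5) = sd of (3,7) = sqrt(8))
  expect_equal(unname(abs_spread(c("A", "B"), em2)),
               rep(sqrt(8), 2), tolerance = 1e-12)
})

test_that("diff and abs spreads match explicit-loop oracles", {
  em <- random_em(4, 6, seed = 21)
  ps <- sample_array_pairs(6, n_pairs = 100, seed = 1)
  expect_true(ps$exhaustive)
  expect_equal(nrow(ps$pairs), 15L)
  expect_equal(unname(diff_spread(genes(em), em, ps)),
               bf_diff_spread(genes(em), em, ps$pairs), tolerance = 1e-10)

  em2 <- random_em(5, 8, seed = 22)
  expect_equal(unname(abs_spread(genes(em2), em2)),
               bf_abs_spread(genes(em2), em2), tolerance = 1e-10)
})

test_that("correlation summaries follow hand-computed Pearson values", {
  m <- rbind(A = c(0, 1, 2), B = c(0, 2, 4), C = c(2, 1, 0))
  colnames(m) <- paste0("a", 1:3)
  em <- expression_matrix(m, "t")
  # r_AB = 1, r_AC = -1, r_BC = -1
  got <- corr_summary(c("A", "B", "C"), em)
  expect_equal(unname(got), c(-1 / 3, -1), tolerance = 1e-12)

  # affine dependence: B = 2A + 1
  m2 <- rbind(A = c(0, 1, 2), B = c(1, 3, 5))
  colnames(m2) <- paste0("a", 1:3)
  em2 <- expression_matrix(m2, "t")
  expect_equal(unname(corr_summary(c("A", "B"), em2)), c(1, 1))
})

test_that("zero-variance genes are excluded pairwise from correlations", {
  m <- rbind(A = c(0, 1, 2), B = c(0, 2, 4), flat = c(3, 3, 3))
  colnames(m) <- paste0("a", 1:3)
  em <- expression_matrix(m, "t")
  got <- corr_summary(c("A", "B", "flat"), em)
  expect_equal(unname(got), c(1, 1))  # only the A-B pair survives

  allflat <- rbind(f1 = c(1, 1, 1), f2 = c(2, 2, 2))
  colnames(allflat) <- paste0("a", 1:3)
  emf <- expression_matrix(allflat, "t")
  expect_true(all(is.na(corr_summary(c("f1", "f2"), emf))))
  # but spread metrics remain defined (zero diff spread, constant offset)
  ps <- sample_array_pairs(3, seed = 1)
  expect_equal(unname(diff_spread(c("f1", "f2"), emf, ps)), c(0, 0))
  # and PCA has zero trace -> undefined pc1
  expect_true(is.na(pc1_fraction(c("f1", "f2"), emf)))
})

test_that("large sets are reduced to the same seeded 50-gene subsample", {
  em <- random_em(60, 12, seed = 30)
  got <- corr_summary(genes(em), em, max_genes = 50, seed = 99)
  pick <- withr::with_seed(99L, sample.int(60, 50))
  want <- bf_corr_summary(genes(em)[pick], em)
  expect_equal(unname(got), want, tolerance = 1e-10)
})

test_that("pc1 equals the leading eigenvalue share of the covariance", {
  m <- rbind(A = c(0, 1, 2), B = c(0, 2, 4))
  colnames(m) <- paste0("a", 1:3)
  em <- expression_matrix(m, "t")
  # cov = [[1,2],[2,4]], eigenvalues (5, 0)
  expect_equal(unname(pc1_fraction(c("A", "B"), em)), 1.0, tolerance = 1e-12)

  profile <- withr::with_seed(8L, stats::rnorm(20))
  ident <- matrix(rep(profile, each = 4), 4, 20,
                  dimnames = list(paste0("g", 1:4), paste0("a", 1:20)))
  emi <- expression_matrix(ident, "t")
  expect_equal(unname(pc1_fraction(genes(emi), emi)), 1.0, tolerance = 1e-12)

  em2 <- random_em(6, 20, seed = 31)
  expect_equal(unname(pc1_fraction(genes(em2), em2)),
               bf_pc1(genes(em2), em2), tolerance = 1e-10)

  # wide case exercises the Gram-matrix route (n > P)
  em3 <- random_em(30, 10, seed = 32)
  expect_equal(unname(pc1_fraction(genes(em3), em3)),
               bf_pc1(genes(em3), em3), tolerance = 1e-10)
})

test_that("metric ranges and invariances hold on random fixtures", {
  for (seed in 1:20) {
    n <- sample(2:8, 1)
    P <- sample(3:20, 1)
    em <- random_em(n, P, seed = seed + 500)
    ps <- sample_array_pairs(P, n_pairs = 10^6, seed = 1)  # exhaustive
    ds <- diff_spread(genes(em), em, ps)
    as_ <- abs_spread(genes(em), em)
    cs <- corr_summary(genes(em), em)
    p1 <- pc1_fraction(genes(em), em)
    expect_true(all(ds >= 0) && all(as_ >= 0))
    expect_true(all(cs >= -1 & cs <= 1))
    expect_true(p1 >= 1 / n - 1e-12 && p1 <= 1 + 1e-12)

    # array relabeling leaves exhaustive diff spread unchanged
    perm <- sample(P)
    emp <- expression_matrix(em$values[, perm], "t")
    expect_equal(unname(diff_spread(genes(em), emp, ps)), unname(ds),
                 tolerance = 1e-12)

    # adding a constant to one gene's profile: corr and pc1 unchanged
    shifted <- em$values
    shifted[1, ] <- shifted[1, ] + 5
    ems <- expression_matrix(shifted, "t")
    expect_equal(unname(corr_summary(genes(ems), ems)), unname(cs),
                 tolerance = 1e-10)
    expect_equal(unname(pc1_fraction(genes(ems), ems)), unname(p1),
                 tolerance = 1e-10)

    # adding a constant to one array's column: spreads unchanged
    colshift <- em$values
    colshift[, 1] <- colshift[, 1] + 3
    emc <- expression_matrix(colshift, "t")
    expect_equal(unname(diff_spread(genes(emc), emc, ps)), unname(ds),
                 tolerance = 1e-10)
    expect_equal(unname(abs_spread(genes(emc), emc)), unname(as_),
                 tolerance = 1e-10)
  }
})

test_that("sampled diff spread is an unbiased estimate of the exhaustive value", {
  em <- random_em(6, 25, seed = 77)
  exhaustive <- diff_spread(genes(em), em,
                            sample_array_pairs(25, n_pairs = 10^6,
                                               seed = 1))[["s_mean_diff"]]
  est <- vapply(1:60, function(s)
    diff_spread(genes(em), em,
                sample_array_pairs(25, n_pairs = 100,
                                   seed = s))[["s_mean_diff"]],
    numeric(1L))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - exhaustive), 4 * se)
})

test_that("an unrelated noise gene dilutes corr_mean and pc1 in expectation", {
  deltas <- vapply(1:30, function(seed) {
    withr::local_seed(seed + 900)
    P <- 15L
    f <- stats::rnorm(P)
    tight <- t(vapply(1:4, function(i) f + stats::rnorm(P, sd = 0.1),
                      numeric(P)))
    noise <- matrix(stats::rnorm(P), 1, P)
    m <- rbind(tight, noise)
    dimnames(m) <- list(paste0("g", 1:5), paste0("a", seq_len(P)))
    em <- expression_matrix(m, "t")
    base_c <- corr_summary(paste0("g", 1:4), em)[["corr_mean"]]
    base_p <- pc1_fraction(paste0("g", 1:4), em)[["pc1"]]
    with_c <- corr_summary(paste0("g", 1:5), em)[["corr_mean"]]
    with_p <- pc1_fraction(paste0("g", 1:5), em)[["pc1"]]
    c(base_c - with_c, base_p - with_p)
  }, numeric(2L))
  expect_gt(mean(deltas[1, ]), 0)
  expect_gt(mean(deltas[2, ]), 0)
  expect_gt(mean(deltas[1, ] > 0), 0.9)
})

test_that("batch evaluation composes the single-set operations", {
  em <- random_em(60, 10, seed = 55)
  coll <- random_collection(20, genes(em), seed = 56, source = "SRC_A")
  rec <- evaluate_collections(coll, em, n_pairs = 30, seed = 123)
  expect_equal(nrow(rec), 20L)
  pairs <- sample_array_pairs(10, n_pairs = 30,
                              seed = stable_seed_for_test(123, "array_pairs"))
  for (i in seq_len(nrow(rec))) {
    g <- coll$sets[[rec$set_id[i]]]
    expect_equal(rec$s_mean_diff[i],
                 diff_spread(g, em, pairs)[["s_mean_diff"]], tolerance = 1e-12)
    expect_equal(rec$s_mean_exp[i],
                 abs_spread(g, em)[["s_mean_exp"]], tolerance = 1e-12)
    expect_equal(rec$pc1[i], pc1_fraction(g, em)[["pc1"]], tolerance = 1e-12)
  }
  # determinism: identical table on a repeated run
  rec2 <- evaluate_collections(coll, em, n_pairs = 30, seed = 123)
  expect_identical(rec, rec2)

  # a single 2-gene set populates every metric field
  mini <- gene_set_collection(list(s = genes(em)[1:2]), source = "MINI")
  one <- evaluate_collections(mini, em, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_true(all(!is.na(one[, consistency_metrics()])))

  # adding a collection does not change existing sets' results
  coll2 <- random_collection(5, genes(em), seed = 57, source = "SRC_B")
  rec3 <- evaluate_collections(list(coll, coll2), em, n_pairs = 30, seed = 123)
  expect_identical(rec3[rec3$source == "SRC_A", ], rec)
})
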