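test_that("rank dissimilarity is blind to monotone transforms and attains
           its bounds", {
  set.seed(51)
  Y <- matrix(rnorm(5 * 10), 5, 10)
  Y[2, ] <- exp(2 * Y[1, ]) - 3          # increasing transform of row 1
  Y[3, ] <- -Y[1, ]                      # rank reversal (no ties)
  d <- rank_dissimilarity(Y)$d
  expect_equal(d[1, 2], 0, tolerance = 1e-14)
  expect_equal(d[1, 3], 2, tolerance = 1e-14)
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 2))
  expect_equal(d, t(d))
})

test_that("dissimilarities match the brute-force tie-aware Spearman", {
  set.seed(52)
  Y <- matrix(sample(1:6, 50, replace = TRUE), 5, 10)  # many ties
  Y[1, 1] <- 7   # avoid constant rows
  d <- rank_dissimilarity(Y)$d
  expect_equal(unname(d), brute_spearman_dissimilarity(Y),
               tolerance = 1e-12)
  Yc <- Y; Yc[4, ] <- 3
  expect_error(rank_dissimilarity(Yc), "constant")
})

test_that("equidistant points embed as an equilateral triangle with zero
           stress", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  emb <- mds_sstress(d, k = 2, n_restarts = 4, seed = 1)
  expect_lt(emb$stress, 1e-6)
  dd <- as.matrix(dist(emb$coords))
  expect_equal(dd[upper.tri(dd)], rep(1, 3), tolerance = 1e-4)
})

test_that("a planted 2-D configuration is recovered to its distances", {
  set.seed(53)
  X <- matrix(rnorm(8 * 2), 8, 2)
  d <- as.matrix(dist(X))
  emb <- mds_sstress(d, k = 2, n_restarts = 4, seed = 2)
  expect_lt(emb$stress, 1e-6)
  expect_equal(as.matrix(dist(emb$coords))[upper.tri(d)],
               d[upper.tri(d)], tolerance = 1e-4)
})

test_that("stress is monotone in restarts and recomputable from coords", {
  set.seed(54)
  d <- as.matrix(dist(matrix(rnorm(9 * 4), 9, 4)))  # not 2-D embeddable
  e1 <- mds_sstress(d, k = 2, n_restarts = 1, seed = 7)
  e10 <- mds_sstress(d, k = 2, n_restarts = 10, seed = 7)
  expect_lte(e10$stress, e1$stress + 1e-12)
  expect_equal(sstress_of(e10, d), e10$stress, tolerance = 1e-10)
  expect_warning(z <- mds_sstress(matrix(0, 4, 4), k = 2), "zero")
  expect_equal(z$stress, 0)
  expect_true(all(z$coords == 0))
})

test_that("the CV-SVM is perfect on separable data and invariant to
           duplication", {
  set.seed(55)
  X <- rbind(cbind(rnorm(10, -10), rnorm(10)),
             cbind(rnorm(10, 10), rnorm(10)))
  lab <- rep(c("a", "b"), each = 10)
  r <- cv_svm_classify(X, lab, seed = 3)
  expect_equal(r$accuracy, 1)
  r2 <- cv_svm_classify(rbind(X, X), c(lab, lab), seed = 3)
  expect_equal(r2$accuracy, 1)
})

test_that("permutation p follows the add-one rule and its bounds", {
  set.seed(56)
  X <- rbind(cbind(rnorm(8, -10), rnorm(8)),
             cbind(rnorm(8, 10), rnorm(8)))
  lab <- rep(c("a", "b"), each = 8)
  expect_warning(r <- permutation_test(X, lab, n_perm = 60, seed = 4),
                 "coarse")
  expect_equal(r$accuracy, 1)
  expect_equal(r$p, (1 + sum(r$null_losses <= r$loss)) / 61)
  expect_gt(r$p, 0)
  expect_lte(r$p, 1)
  # no shuffle should reach zero loss on well-separated clouds
  expect_equal(r$p, 1 / 61, tolerance = 1e-12)
})

test_that("chance-level labels give chance-level accuracy", {
  set.seed(57)
  accs <- vapply(1:40, function(i) {
    X <- matrix(rnorm(20 * 2), 20, 2)
    lab <- rep(c("a", "b"), each = 10)
    cv_svm_classify(X, lab, seed = i)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 1.96 * sqrt(0.25 / (40 * 20)) + 0.05)
})

test_that("classify_pair is deterministic and end-to-end affinity-blind", {
  co <- pair_cohort(n = 8, R = 30, seed = 58)
  res1 <- suppressWarnings(
    classify_pair(co$binding["PK"], "svPPA", "nfvPPA",
                  n_perm = 60, seed = 5))
  fns <- lapply(seq_len(16), function(i) function(x) exp(i / 5 * x) + i)
  tr <- list(PK = transform_subject_rows(co$binding$PK, fns))
  res2 <- suppressWarnings(
    classify_pair(tr, "svPPA", "nfvPPA", n_perm = 60, seed = 5))
  expect_identical(res1$PK$dissimilarity$d, res2$PK$dissimilarity$d)
  expect_identical(res1$PK$embedding$coords, res2$PK$embedding$coords)
  expect_identical(res1$PK$accuracy, res2$PK$accuracy)
  expect_identical(res1$PK$p, res2$PK$p)

  res3 <- suppressWarnings(
    classify_pair(co$binding["PK"], "svPPA", "nfvPPA", n_perm = 60,
                  seed = 5))
  expect_identical(res1$PK$accuracy, res3$PK$accuracy)
  expect_identical(res1$PK$null_losses, res3$PK$null_losses)
})

test_that("multimodal fusion concatenates standardized embeddings in 4-D", {
  co <- pair_cohort(n = 7, R = 30, seed = 59)
  res <- suppressWarnings(
    classify_pair(co$binding, "svPPA", "nfvPPA", multimodal = TRUE,
                  n_perm = 60, seed = 6))
  expect_named(res, c("PK", "AV", "multimodal"))
  expect_equal(ncol(res$multimodal$coords), 4)
  expect_equal(sqrt(mean(res$multimodal$coords[, 1:2]^2)), 1,
               tolerance = 1e-8)
})

test_that("age and sex labels of structureless data classify at chance", {
  ps_sex <- ps_age <- numeric(9)
  for (i in 1:9) {
    co <- null_cohort(n = 10, R = 40, seed = 60 + i)
    dm <- rank_dissimilarity(co$binding$PK)
    emb <- mds_sstress(dm, n_restarts = 4, seed = 7 + i)
    sex_lab <- factor(co$subjects$sex)
    age_lab <- factor(co$subjects$age > median(co$subjects$age),
                      labels = c("young", "old"))
    ps_sex[i] <- suppressWarnings(
      permutation_test(emb, sex_lab, n_perm = 99, seed = 8 + i))$p
    ps_age[i] <- suppressWarnings(
      permutation_test(emb, age_lab, n_perm = 99, seed = 900 + i))$p
  }
  expect_gt(median(ps_sex), 0.1)
  expect_gt(median(ps_age), 0.1)
})
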