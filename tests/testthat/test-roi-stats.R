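make_bm <- function(v, groups, seed_regions = NULL) {
  R <- ncol(v)
  reg <- default_region_table(R)
  sub <- data.frame(subject_id = sprintf("s%02d", seq_len(nrow(v))),
                    group = groups, age = 60 + seq_len(nrow(v)),
                    sex = rep(c("F", "M"), length.out = nrow(v)))
  binding_matrix(v, reg, sub)
}

test_that("partial-volume correction divides by the grey+white fraction", {
  reg <- default_region_table(3)
  sub <- data.frame(subject_id = "s1", group = "control", age = 60,
                    sex = "F")
  m <- binding_matrix(matrix(c(0.5, 0.3, 0.2), 1, 3), reg, sub)
  gm <- covariate_matrix(matrix(0.3, 1, 3), reg, sub, "gm_fraction")
  wm <- covariate_matrix(matrix(0.2, 1, 3), reg, sub, "wm_fraction")
  out <- partial_volume_correct(m, gm, wm)
  expect_equal(unname(out$values[1, 1]), 1.0)

  gm1 <- covariate_matrix(matrix(0.6, 1, 3), reg, sub, "gm_fraction")
  wm1 <- covariate_matrix(matrix(0.4, 1, 3), reg, sub, "wm_fraction")
  expect_equal(partial_volume_correct(m, gm1, wm1)$values, m$values)

  wm_bad <- covariate_matrix(matrix(0.9, 1, 3), reg, sub, "wm_fraction")
  expect_error(partial_volume_correct(m, gm, wm_bad), "outside")
})

test_that("correction inverts the generator's CSF contamination exactly", {
  co <- generate_cohort(synthetic_config(
    n_per_group = c(control = 6, svPPA = 6), R = 25, seed = 5))
  truth <- co$binding$PK
  tf <- co$covariates$gm$values + co$covariates$wm$values
  observed <- truth
  observed$values <- truth$values * tf
  fixed <- partial_volume_correct(observed, co$covariates$gm,
                                  co$covariates$wm)
  expect_equal(fixed$values, truth$values, tolerance = 1e-12)
})

test_that("gg_epsilon attains its analytic limits", {
  k <- 5
  cs <- matrix(0.3, k, k); diag(cs) <- 1        # compound symmetry
  expect_equal(gg_epsilon(cs), 1)
  u <- seq_len(k) - mean(seq_len(k))            # rank-1 centred covariance
  expect_equal(gg_epsilon(outer(u, u)), 1 / (k - 1))
  expect_error(gg_epsilon(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("gg_epsilon matches Box's explicit-sum formula and is
           translation-invariant", {
  set.seed(31)
  for (i in 1:25) {
    V <- random_spd(4)
    eps <- gg_epsilon(V)
    box <- max(1 / 3, min(1, brute_gg_box(V)))
    expect_equal(eps, box, tolerance = 1e-10)
    expect_equal(gg_epsilon(V + 0.7), eps, tolerance = 1e-10)
    expect_gte(eps, 1 / 3)
    expect_lte(eps, 1)
  }
})

test_that("rm_anova agrees with the multivariate-model oracle (car)", {
  set.seed(12)
  Y <- matrix(rnorm(18 * 5), 18, 5)
  g <- factor(rep(c("a", "b", "c"), each = 6))
  mine <- rm_anova(Y, g)

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  mlm <- lm(Y ~ g)
  idata <- data.frame(region = factor(seq_len(5)))
  a <- car::Anova(mlm, idata = idata, idesign = ~region, type = 3)
  s <- suppressWarnings(summary(a, multivariate = FALSE))
  uni <- s$univariate.tests
  getF <- function(nm) uni[nm, "F value"]
  expect_equal(mine$F[mine$effect == "diagnosis"], getF("g"),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(mine$F[mine$effect == "region"], getF("region"),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(mine$F[mine$effect == "region:diagnosis"],
               getF("g:region"), tolerance = 1e-8, ignore_attr = TRUE)
  eps_car <- s$pval.adjustments["region", "GG eps"]
  expect_equal(mine$epsilon[mine$effect == "region"], eps_car,
               tolerance = 1e-8, ignore_attr = TRUE)
  p_car <- s$pval.adjustments["g:region", "Pr(>F[GG])"]
  expect_equal(mine$p[mine$effect == "region:diagnosis"], p_car,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("two identical groups give a diagnosis F of zero", {
  set.seed(3)
  v <- matrix(rnorm(8 * 6), 8, 6)
  Y <- rbind(v, v)
  g <- rep(c("a", "b"), each = 8)
  an <- rm_anova(Y, g)
  expect_lt(an$F[an$effect == "diagnosis"], 1e-20)
  expect_lt(an$F[an$effect == "region:diagnosis"], 1e-20)
})

test_that("degenerate designs are rejected", {
  Y <- matrix(rnorm(12), 4, 3)
  expect_error(rm_anova(Y, c("a", "a", "a", "b")), "at least 2 subjects")
  expect_error(rm_anova(Y, rep("a", 4)), "at least 2 groups")
})

test_that("planted group mode yields a significant interaction", {
  hits <- 0
  for (i in 1:20) {
    co <- generate_cohort(synthetic_config(
      n_per_group = c(control = 10, svPPA = 10), R = 30,
      seed = 600 + i))
    an <- rm_anova(co$binding$PK)
    hits <- hits + (an$p[an$effect == "region:diagnosis"] < 0.001)
  }
  expect_gte(hits, 19)
})

test_that("post hoc adjustments obey BH / Bonferroni structure", {
  set.seed(8)
  v <- rbind(matrix(rnorm(4 * 4), 4, 4),
             matrix(rnorm(4 * 4, mean = 2), 4, 4))
  m <- make_bm(v, rep(c("control", "svPPA"), each = 4))
  tab <- posthoc_region_tests(m, "svPPA", "control")
  expect_true(all(tab$p_fdr >= tab$p_raw - 1e-15))
  expect_true(all(tab$p_bonf >= tab$p_fdr - 1e-15))
  expect_equal(tab$p_fdr, brute_bh(tab$p_raw), tolerance = 1e-12)
})

test_that("BH step-up equals the brute-force definition", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(p.adjust(rep(1, 5), "BH"), rep(1, 5))
  set.seed(21)
  for (i in 1:30) {
    p <- runif(sample(1:10, 1))
    expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("Welch reduces to Student under equal variances and sizes", {
  set.seed(13)
  a <- rnorm(8)
  b <- a + 0.9          # identical sample variance, shifted mean
  v <- rbind(matrix(rep(a, 3), 8, 3), matrix(rep(b, 3), 8, 3))
  m <- make_bm(v, rep(c("control", "svPPA"), each = 8))
  welch <- posthoc_region_tests(m, "svPPA", "control")
  student <- posthoc_region_tests(m, "svPPA", "control", var_equal = TRUE)
  expect_equal(welch$t, student$t, tolerance = 1e-12)
  expect_equal(welch$df, student$df, tolerance = 1e-12)
})

test_that("zero-variance regions are flagged untested", {
  v <- cbind(rep(1, 6), rnorm(6), rnorm(6))
  m <- make_bm(v, rep(c("control", "svPPA"), each = 3))
  tab <- posthoc_region_tests(m, "svPPA", "control")
  expect_false(tab$tested[1])
  expect_true(all(tab$tested[2:3]))
  expect_true(is.na(tab$t[1]))
})
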