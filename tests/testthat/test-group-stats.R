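test_that("observed F and t statistics match linear-model fits", {
  set.seed(7)
  n <- 18
  g <- rep(c("HC", "MSA", "PD"), each = 6)
  age <- runif(n, 45, 80)
  y <- rnorm(n) + 0.02 * age
  r <- permutation_ancova(y, g, covariates = age, n_perm = 200, seed = 1,
                          exact = "never")
  fit <- anova(lm(y ~ age + factor(g)))
  expect_equal(r$observed, fit["factor(g)", "F value"], tolerance = 1e-10)
  expect_equal(r$df, c(2, n - 4))
  ph <- posthoc_pairwise(y, g, covariates = age, n_perm = 200, seed = 1,
                         exact = "never")
  cf <- summary(lm(y ~ factor(g) + age))$coefficients
  expect_equal(ph$t[ph$contrast == "HC>MSA"], -cf["factor(g)MSA", "t value"],
               tolerance = 1e-10)
  V <- vcov(lm(y ~ factor(g) + age))[2:3, 2:3]
  expect_equal(ph$t[ph$contrast == "MSA>PD"],
               (cf["factor(g)MSA", "Estimate"] - cf["factor(g)PD", "Estimate"]) /
                 sqrt(V[1, 1] + V[2, 2] - 2 * V[1, 2]),
               tolerance = 1e-8)
})

test_that("degenerate outcomes give F = 0 and p = 1", {
  y <- rep(2.5, 12)
  g <- rep(c("A", "B", "C"), each = 4)
  r <- permutation_ancova(y, g, n_perm = 99, seed = 1, exact = "never")
  expect_equal(r$observed, 0)
  expect_equal(r$p, 1)
})

test_that("exhaustive omnibus p equals the full-relabeling lm oracle", {
  set.seed(13)
  g <- rep(c("A", "B", "C"), times = c(3, 3, 2))
  y <- rnorm(8)
  r <- permutation_ancova(y, g, n_perm = 10000, exact = "auto")
  expect_true(r$exhaustive)
  expect_equal(r$n_perm, 560)   # 8!/(3!3!2!)
  Fstat <- function(lab) anova(lm(y ~ factor(lab)))[1, 4]
  Fobs <- Fstat(g)
  pos1 <- combn(8, 3)
  hits <- 0; tot <- 0
  for (j1 in seq_len(ncol(pos1))) {
    rest <- setdiff(1:8, pos1[, j1])
    pos2 <- combn(rest, 3)
    for (j2 in seq_len(ncol(pos2))) {
      lab <- character(8)
      lab[pos1[, j1]] <- "A"; lab[pos2[, j2]] <- "B"; lab[lab == ""] <- "C"
      tot <- tot + 1
      if (Fstat(lab) >= Fobs - 1e-8) hits <- hits + 1
    }
  }
  expect_equal(r$p, hits / tot, tolerance = 1e-12)
})

test_that("two-group exhaustive t contrast equals enumeration", {
  set.seed(14)
  g <- rep(c("A", "B"), each = 4)
  y <- rnorm(8) + ifelse(g == "A", 0.8, 0)
  ph <- posthoc_pairwise(y, g, n_perm = 10000, exact = "auto")
  expect_true(all(ph$exhaustive))
  expect_equal(ph$n_perm[1], 70)    # choose(8, 4)
  tstat <- function(lab) unname(t.test(y[lab == "A"], y[lab == "B"],
                                       var.equal = TRUE)$statistic)
  tobs <- tstat(g)
  sets <- combn(8, 4)
  tall <- apply(sets, 2, function(s) {
    lab <- rep("B", 8); lab[s] <- "A"; tstat(lab)
  })
  expect_equal(ph$p[ph$contrast == "A>B"], mean(tall >= tobs - 1e-8),
               tolerance = 1e-12)
  expect_equal(ph$p[ph$contrast == "A<B"], mean(-tall >= -tobs - 1e-8),
               tolerance = 1e-12)
})

test_that("post hoc one-tailed p-values swap under sign flip and FWER is Bonferroni", {
  set.seed(15)
  g <- rep(c("A", "B", "C"), each = 5)
  y <- rnorm(15)
  p1 <- posthoc_pairwise(y, g, n_perm = 500, seed = 3, exact = "never")
  p2 <- posthoc_pairwise(-y, g, n_perm = 500, seed = 3, exact = "never")
  expect_equal(p1$p[p1$contrast == "A>B"], p2$p[p2$contrast == "A<B"],
               tolerance = 1e-12)
  expect_equal(p1$p[p1$contrast == "B>C"], p2$p[p2$contrast == "B<C"],
               tolerance = 1e-12)
  expect_equal(p1$p_fwer, pmin(1, p1$p * 6))
  # monotone, order-preserving adjustment
  expect_true(all(diff(p1$p_fwer[order(p1$p)]) >= -1e-12))
  expect_true(all(p1$p_fwer >= p1$p))
})

test_that("planted group effects are detected and FL keeps covariates nuisance", {
  set.seed(16)
  g <- rep(c("HC", "MSA", "PD"), each = 15)
  age <- sample(45:80, 45, replace = TRUE)
  y <- 0.25 - 0.075 * (g == "MSA") + rnorm(45, 0, 0.05)
  omni <- permutation_ancova(y, g, covariates = age, n_perm = 2000,
                             seed = 2)
  expect_lt(omni$p, 0.01)
  ph <- posthoc_pairwise(y, g, covariates = age, n_perm = 2000, seed = 2)
  expect_lt(ph$p_fwer[ph$contrast == "HC>MSA"], 0.05)
  expect_gt(ph$p[ph$contrast == "HC<MSA"], 0.5)
})

test_that("spearman matches the closed form and behaves under reversal", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8)
  y <- c(2, 0.5, 5, 1, 12, 2.2, 6, 9)
  sp <- spearman_corr(x, y)
  d <- rank(x) - rank(y)
  n <- 8
  expect_equal(sp$rho, 1 - 6 * sum(d^2) / (n * (n^2 - 1)),
               tolerance = 1e-12)
  expect_equal(spearman_corr(x, -y)$rho, -sp$rho, tolerance = 1e-12)
  expect_equal(spearman_corr(x, 2 * x + 1)$rho, 1)
  expect_identical(spearman_corr(x, rep(1, 8))$flag, "constant")
  # exact p agrees with closed-form enumeration over all 6! permutations
  set.seed(17)
  x6 <- rnorm(6); y6 <- rnorm(6)
  sp6 <- spearman_corr(x6, y6)
  P <- lcnm:::perm_matrix(6)
  ry <- rank(y6)
  rho_all <- apply(P, 1, function(p) {
    dd <- rank(x6) - ry[p]
    1 - 6 * sum(dd^2) / (6 * 35)
  })
  expect_equal(sp6$p, mean(abs(rho_all) >= abs(sp6$rho) - 1e-12),
               tolerance = 1e-12)
  # large n falls back to the t approximation, close to cor.test
  set.seed(18)
  xl <- rnorm(40); yl <- xl + rnorm(40)
  spl <- spearman_corr(xl, yl)
  ct <- cor.test(xl, yl, method = "spearman", exact = FALSE)
  expect_equal(spl$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(spl$method, "t approximation")
})

test_that("Brown-Forsythe Levene test matches car and flags heteroscedasticity", {
  skip_if_not_installed("car")
  set.seed(19)
  g <- rep(c("A", "B", "C"), each = 12)
  y <- rnorm(36) * ifelse(g == "B", 3, 1)
  lv <- levene_test(y, g)
  ref <- car::leveneTest(y ~ factor(g), center = median)
  expect_equal(lv$W, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(lv$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
  expect_lt(lv$p, 0.05)
  # identical groups give W = 0
  y0 <- rep(rnorm(12), 3)
  expect_equal(levene_test(y0, g)$W, 0)
})

test_that("descriptive tests reproduce hand-computed statistics", {
  # sex-by-group table with counts 7/11, 6/5, 11/7
  sex <- c(rep(c("M", "F"), c(7, 11)), rep(c("M", "F"), c(6, 5)),
           rep(c("M", "F"), c(11, 7)))
  grp <- rep(c("HC", "MSA", "PD"), c(18, 11, 18))
  cov <- data.frame(group = grp, sex = sex,
                    age = seq_len(47), moca_raw = NA_integer_)
  res <- descriptive_tests(cov)
  tab <- table(sex, grp)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2_hand <- sum((tab - expected)^2 / expected)
  expect_equal(res$sex_chisq$statistic, chi2_hand, tolerance = 1e-10)
  expect_equal(chi2_hand, 1.848, tolerance = 0.001)
  # identical distributions: H ~ 0, chi-square exactly 0 for balanced 2x2
  cov2 <- data.frame(group = rep(c("A", "B"), each = 10),
                     sex = rep(c("M", "F"), 10),
                     age = rep(1:10, 2))
  res2 <- descriptive_tests(cov2)
  expect_equal(res2$sex_chisq$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$age_kruskal$H, 0, tolerance = 1e-10)
  expect_error(descriptive_tests(data.frame(group = "A")), "lacks columns")
  # Mann-Whitney U for a two-group score
  cov3 <- data.frame(group = rep(c("MSA", "PD"), each = 8),
                     sex = rep("M", 16), age = 1:16,
                     moca_raw = c(21:28, 24:31))
  res3 <- descriptive_tests(cov3)
  wt <- suppressWarnings(wilcox.test(moca_raw ~ group, data = cov3))
  expect_equal(res3$score_tests$moca_raw$U, unname(wt$statistic))
})

test_that("MoCA education adjustment adds one point below 13 years, capped", {
  expect_equal(adjust_moca(24, 12), 25L)
  expect_equal(adjust_moca(24, 16), 24L)
  expect_equal(adjust_moca(30, 10), 30L)
  expect_equal(adjust_moca(c(10, 29, 30), c(8, 12, 20)), c(11L, 30L, 30L))
  expect_error(adjust_moca(31, 10), "\\[0, 30\\]")
})
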