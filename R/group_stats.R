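# Scalar-level inference: permutation "ANCOVA-type" omnibus (Freedman-Lane
# residual permutation with a nuisance covariate), FWER-controlled
# one-tailed post hoc contrasts, Spearman correlations, Brown-Forsythe
# Levene test, descriptive tests and the MoCA education adjustment.

# ---- permutation plumbing -------------------------------------------------

# all n! permutations as an (n! x n) index matrix, by vectorized insertion
perm_matrix <- function(n) {
  if (n > 10L) stop("full permutation enumeration limited to n <= 10",
                    call. = FALSE)
  P <- matrix(1L, 1L, 1L)
  for (k in 2L:n) {
    m <- nrow(P)
    blocks <- lapply(seq_len(k), function(pos) {
      if (pos == 1L) cbind(k, P)
      else if (pos == k) cbind(P, k)
      else cbind(P[, seq_len(pos - 1L), drop = FALSE], k,
                 P[, pos:(k - 1L), drop = FALSE])
    })
    P <- do.call(rbind, blocks)
  }
  P
}

# number of distinct relabelings of a grouping vector
n_relabelings <- function(counts) {
  exp(lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)))
}

# all distinct group relabelings, returned as permutation index columns
# sigma such that y[sigma] regrouped by the *original* labels reproduces
# each relabeling exactly once (the statistic is invariant to within-group
# order)
relabel_perms <- function(group) {
  g <- as.integer(group)
  counts <- tabulate(g)
  n <- length(g)
  assign_rec <- function(pos, lab) {
    if (lab == length(counts))
      return(matrix(pos, ncol = 1L))
    ch <- combn(pos, counts[lab])
    do.call(cbind, lapply(seq_len(ncol(ch)), function(j) {
      rest <- assign_rec(setdiff(pos, ch[, j]), lab + 1L)
      rbind(matrix(ch[, j], nrow = counts[lab], ncol = ncol(rest)), rest)
    }))
  }
  # columns: positions receiving label 1 first, then label 2, ...
  asg <- assign_rec(seq_len(n), 1L)
  sigma <- matrix(0L, n, ncol(asg))
  row_of <- order(g)          # original positions sorted by label
  sigma[row_of, ] <- asg
  sigma
}

# Freedman-Lane statistics over a set of permutations.
# perms: n x m index matrix.  Returns F (length m) and, if contrasts are
# given (list of coefficient-space vectors), a contrasts x m t matrix.
fl_stats <- function(y, X_full, X_red, perms, contrasts = NULL) {
  n <- length(y)
  qf <- qr(X_full); qr_ <- qr(X_red)
  if (qf$rank < ncol(X_full))
    stop("design matrix is singular", call. = FALSE)
  fitted_red <- qr.fitted(qr_, y)
  e <- y - fitted_red
  Ystar <- fitted_red + matrix(e[perms], n)
  RSS_full <- colSums(qr.resid(qf, Ystar)^2)
  RSS_red <- colSums(qr.resid(qr_, Ystar)^2)
  q <- qf$rank - qr_$rank
  df <- n - qf$rank
  Fv <- ((RSS_red - RSS_full) / q) / (RSS_full / df)
  # no residual variation around the reduced model: nothing to test
  degenerate <- RSS_red <= 1e-12 * (colSums(Ystar^2) + 1e-300)
  Fv[degenerate | !is.finite(Fv)] <- 0
  out <- list(F = Fv, df1 = q, df2 = df)
  if (!is.null(contrasts)) {
    B <- qr.coef(qf, Ystar)
    XtXinv <- chol2inv(qr.R(qf))
    sigma2 <- RSS_full / df
    tmat <- matrix(NA_real_, length(contrasts), ncol(Ystar))
    for (i in seq_along(contrasts)) {
      cv <- contrasts[[i]]
      num <- drop(crossprod(cv, B))
      se <- sqrt(sigma2 * drop(crossprod(cv, XtXinv %*% cv)))
      ti <- num / se
      ti[!is.finite(ti)] <- 0
      tmat[i, ] <- ti
    }
    out$t <- tmat
  }
  out
}

build_designs <- function(group, covariates, n) {
  g <- droplevels(as.factor(group))
  if (any(table(g) < 2L))
    stop("every group needs at least 2 members", call. = FALSE)
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1L)
    X <- model.matrix(~g)
  } else {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    Z <- cbind(1, cv)
    X <- cbind(model.matrix(~g), cv)
  }
  list(g = g, X_full = X, X_red = Z, has_cov = !is.null(covariates))
}

choose_perms <- function(g, has_cov, n_perm, seed, exact) {
  n <- length(g)
  counts <- table(g)
  n_distinct <- if (has_cov) factorial(n) else n_relabelings(counts)
  exhaustive <- switch(exact,
    always = TRUE,
    never = FALSE,
    auto = n_distinct <= n_perm)
  if (exhaustive && n_distinct > 2e6)
    stop("exhaustive enumeration infeasible for this design", call. = FALSE)
  if (exhaustive) {
    perms <- if (has_cov) t(perm_matrix(n)) else relabel_perms(g)
  } else {
    if (!is.null(seed)) set.seed(seed)
    perms <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  }
  list(perms = perms, exhaustive = exhaustive)
}

perm_pvalue <- function(stat_perm, stat_obs, exhaustive) {
  tol <- 1e-8 * max(1, abs(stat_obs))
  if (exhaustive) mean(stat_perm >= stat_obs - tol)
  else (1 + sum(stat_perm >= stat_obs - tol)) / (1 + length(stat_perm))
}

# ---- user-facing tests ----------------------------------------------------

#' Permutation ANCOVA-type omnibus group test
#'
#' Tests the group factor adjusting for covariates using the observed
#' partial F statistic and a Freedman-Lane permutation null: residuals of
#' the reduced (covariate-only) model are permuted, the reduced fit is
#' re-added, and F recomputed.  The p-value uses the add-one estimator
#' `(1 + b) / (1 + n_perm)`, so it is never zero.  When the number of
#' distinct relabelings (no covariates) or raw permutations (with
#' covariates, n <= 10) does not exceed `n_perm`, exhaustive enumeration
#' is used automatically and the p-value is the exact fraction.
#'
#' @param y per-subject outcome (e.g. a sub-regional NM contrast).
#' @param group group labels (>= 2 members per group).
#' @param covariates optional vector or data.frame of nuisance
#'   covariates (e.g. age).
#' @param n_perm number of Monte-Carlo permutations (default 10000).
#' @param seed RNG seed for the permutation draw.
#' @param exact `"auto"` (default), `"never"` or `"always"`.
#' @return object of class `perm_result`.
#' @export
permutation_ancova <- function(y, group, covariates = NULL,
                               n_perm = 10000L, seed = NULL,
                               exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  n <- length(y)
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  des <- build_designs(group, covariates, n)
  pp <- choose_perms(des$g, des$has_cov, n_perm, seed, exact)
  obs <- fl_stats(y, des$X_full, des$X_red, matrix(seq_len(n), n, 1L))
  st <- fl_stats(y, des$X_full, des$X_red, pp$perms)
  p <- perm_pvalue(st$F, obs$F, pp$exhaustive)
  structure(list(statistic_name = "F", observed = obs$F, p = p,
                 n_perm = ncol(pp$perms), exhaustive = pp$exhaustive,
                 seed = seed, tail = "upper", df = c(obs$df1, obs$df2),
                 contrast = "group omnibus (ANCOVA-type)"),
            class = "perm_result")
}

#' One-tailed pairwise post hoc contrasts with FWER correction
#'
#' All ordered pairwise group contrasts (six for three groups: HC>MSA,
#' HC<MSA, HC>PD, HC<PD, MSA>PD, MSA<PD), each a one-tailed t contrast in
#' the full group + covariate model with a shared Freedman-Lane
#' permutation null.  Family-wise error is controlled by Bonferroni:
#' `p_fwer = min(1, p * n_tests)`, equivalent to testing each contrast at
#' `alpha / n_tests`.
#'
#' @inheritParams permutation_ancova
#' @param n_tests number of tests used for the FWER correction; defaults
#'   to the number of contrasts performed.
#' @return data.frame of class `lc_posthoc`: contrast label, observed t,
#'   one-tailed permutation p, FWER-adjusted p, permutation count and
#'   mode.
#' @export
posthoc_pairwise <- function(y, group, covariates = NULL,
                             n_perm = 10000L, seed = NULL,
                             exact = c("auto", "never", "always"),
                             n_tests = NULL) {
  exact <- match.arg(exact)
  n <- length(y)
  des <- build_designs(group, covariates, n)
  lev <- levels(des$g)
  p_coef <- ncol(des$X_full)
  coef_vec <- function(l) {
    v <- numeric(p_coef)
    nm <- paste0("g", l)
    hit <- match(nm, colnames(des$X_full))
    if (!is.na(hit)) v[hit] <- 1
    v
  }
  pairs <- combn(lev, 2L)
  contrasts <- list(); labels <- character(0)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    contrasts[[length(contrasts) + 1L]] <- coef_vec(a) - coef_vec(b)
    labels <- c(labels, paste0(a, ">", b))
    contrasts[[length(contrasts) + 1L]] <- coef_vec(b) - coef_vec(a)
    labels <- c(labels, paste0(a, "<", b))
  }
  if (is.null(n_tests)) n_tests <- length(contrasts)
  pp <- choose_perms(des$g, des$has_cov, n_perm, seed, exact)
  obs <- fl_stats(y, des$X_full, des$X_red, matrix(seq_len(n), n, 1L),
                  contrasts)
  st <- fl_stats(y, des$X_full, des$X_red, pp$perms, contrasts)
  pvals <- vapply(seq_along(contrasts), function(i)
    perm_pvalue(st$t[i, ], obs$t[i, 1], pp$exhaustive), numeric(1))
  out <- data.frame(contrast = labels,
                    t = obs$t[, 1],
                    df = obs$df2,
                    p = pvals,
                    p_fwer = pmin(1, pvals * n_tests),
                    n_perm = ncol(pp$perms),
                    exhaustive = pp$exhaustive,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "n_tests") <- n_tests
  class(out) <- c("lc_posthoc", "data.frame")
  out
}

#' Spearman rank correlation with exact or t-approximate p-value
#'
#' Rho is the Pearson correlation of mid-ranks (tie-aware).  For
#' `n <= exact_n_max` the p-value is computed by full enumeration of all
#' n! rank permutations; otherwise by the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y numeric vectors (n >= 3, finite).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact_n_max largest n for exact enumeration (default 9;
#'   enumeration is supported up to n = 10).
#' @return list with `rho`, `p`, `n`, `method` and `alternative`;
#'   constant input gives `rho = NA` with flag `"constant"`.
#' @export
spearman_corr <- function(x, y,
                          alternative = c("two.sided", "greater", "less"),
                          exact_n_max = 9L) {
  alternative <- match.arg(alternative)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "none",
                alternative = alternative, flag = "constant"))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_n_max) {
    P <- perm_matrix(n)
    ryc <- ry - mean(ry); rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    R <- matrix(ryc[t(P)], n)          # n x n! matrix of permuted ranks
    rho_perm <- drop(crossprod(rxc, R)) / denom
    tol <- 1e-12
    p <- switch(alternative,
      two.sided = mean(abs(rho_perm) >= abs(rho) - tol),
      greater = mean(rho_perm >= rho - tol),
      less = mean(rho_perm <= rho + tol))
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- switch(alternative,
      two.sided = 2 * pt(abs(tt), n - 2, lower.tail = FALSE),
      greater = pt(tt, n - 2, lower.tail = FALSE),
      less = pt(tt, n - 2))
    p <- min(1, p)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method, alternative = alternative)
}

#' Brown-Forsythe (median-centered) Levene test
#'
#' Homogeneity-of-variance test: one-way F on absolute deviations from
#' the group medians.
#'
#' @param y numeric outcome.
#' @param group group labels (>= 2 groups, each >= 2 members).
#' @return list with `W` (the F-type statistic), `df` and `p`.
#' @export
levene_test <- function(y, group) {
  g <- droplevels(as.factor(group))
  k <- nlevels(g)
  if (k < 2L || any(table(g) < 2L))
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  med <- tapply(y, g, median)
  z <- abs(y - med[g])
  n <- length(y)
  zbar <- mean(z)
  zg <- tapply(z, g, mean)
  ng <- tabulate(g)
  ss_between <- sum(ng * (zg - zbar)^2)
  ss_within <- sum((z - zg[g])^2)
  if (ss_between <= 0) return(list(W = 0, df = c(k - 1L, n - k), p = 1))
  W <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(W = W, df = c(k - 1L, n - k),
       p = pf(W, k - 1, n - k, lower.tail = FALSE))
}

#' Descriptive group comparisons for a covariate table
#'
#' Kruskal-Wallis for age across groups, chi-square (no continuity
#' correction) for sex, Mann-Whitney U for scores observed in exactly two
#' groups, and per-group median/IQR summaries.
#'
#' @param covariates data.frame with at least `group`, `age`, `sex`.
#' @param score_cols numeric columns to compare between pairs of groups
#'   (columns absent from the table are skipped).
#' @return list of class `lc_descriptives` with `age_kruskal`
#'   (statistic H, df, p), `sex_chisq` (statistic, df, p, table),
#'   `score_tests` and `summaries`.
#' @export
descriptive_tests <- function(covariates,
                              score_cols = c("moca_adj", "moca_raw")) {
  needed <- c("group", "age", "sex")
  missing_cols <- setdiff(needed, names(covariates))
  if (length(missing_cols))
    stop("covariate table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  g <- droplevels(as.factor(covariates$group))
  kw <- kruskal.test(covariates$age, g)
  sex_tab <- table(covariates$sex, g)
  chi <- suppressWarnings(chisq.test(sex_tab, correct = FALSE))
  score_tests <- list()
  for (sc in intersect(score_cols, names(covariates))) {
    v <- covariates[[sc]]
    have <- tapply(v, g, function(z) any(!is.na(z)))
    gl <- names(have)[have]
    if (length(gl) == 2L) {
      sel <- g %in% gl & !is.na(v)
      wt <- suppressWarnings(
        wilcox.test(v[sel] ~ droplevels(g[sel])))
      score_tests[[sc]] <- list(groups = gl, U = unname(wt$statistic),
                                p = wt$p.value)
    }
  }
  iqr_summary <- function(v) {
    vapply(levels(g), function(l) {
      z <- v[g == l & !is.na(v)]
      if (!length(z)) return(c(median = NA_real_, IQR = NA_real_))
      c(median = median(z), IQR = unname(diff(quantile(z, c(0.25, 0.75)))))
    }, numeric(2))
  }
  num_cols <- names(covariates)[vapply(covariates, is.numeric, logical(1))]
  summaries <- lapply(setNames(num_cols, num_cols),
                      function(cn) iqr_summary(covariates[[cn]]))
  structure(list(
    age_kruskal = list(H = unname(kw$statistic), df = unname(kw$parameter),
                       p = kw$p.value),
    sex_chisq = list(statistic = unname(chi$statistic),
                     df = unname(chi$parameter), p = chi$p.value,
                     table = sex_tab),
    score_tests = score_tests,
    summaries = summaries), class = "lc_descriptives")
}

#' Education-adjusted MoCA score
#'
#' Adds one point for participants with 12 or fewer years of education,
#' capped at the scale maximum of 30.
#'
#' @param raw integer raw MoCA (0-30).
#' @param education_years integer years of education.
#' @return adjusted integer score (vectorized).
#' @export
adjust_moca <- function(raw, education_years) {
  if (any(!is.na(raw) & (raw < 0 | raw > 30)))
    stop("raw MoCA scores must lie in [0, 30]", call. = FALSE)
  out <- as.integer(raw) + as.integer(!is.na(education_years) &
                                      education_years <= 12)
  pmin(30L, out)
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.4f, permutation p = %.4g (%s, %d permutations)\n",
              x$contrast, x$statistic_name, x$observed, x$p,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$n_perm))
  invisible(x)
}

#' @export
print.lc_posthoc <- function(x, ...) {
  nt <- attr(x, "n_tests")
  cat(sprintf("One-tailed post hoc contrasts (FWER by Bonferroni x %s):\n",
              if (is.null(nt)) "n_tests" else nt))
  print.data.frame(x, digits = 4)
  invisible(x)
}
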