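# Group inference: demographics tests (chi-square / Kruskal-Wallis / one-way
# ANOVA), cognition z-scoring, region-wise permutation ANCOVA with post-hoc
# contrasts, and partial correlations. The permutation scheme is
# Freedman-Lane: residuals of the covariate-only model are permuted, so the
# null respects the covariates.

#' Z-score cognition across the whole cohort
#'
#' Each test's raw scores are standardized against the mean and SD over all
#' subjects; tests flagged as timed (e.g. trail-making, scored in seconds
#' where larger is worse) are then sign-flipped so that a higher z always
#' means better performance.
#'
#' @param raw data.frame of raw test scores (one column per test).
#' @param timed character vector naming the time-scored columns.
#' @param domains optional named character vector mapping test column to
#'   cognitive-domain name for the output columns.
#' @return data.frame of z-scores (columns renamed to domains if supplied).
#' @export
zscore_cognition <- function(raw, timed = character(),
                             domains = NULL) {
  raw <- as.data.frame(raw)
  if (nrow(raw) < 2)
    stop_nc("need at least 2 subjects", "nc_validation_error")
  z <- lapply(names(raw), function(ts) {
    x <- raw[[ts]]
    s <- sd(x)
    if (!is.finite(s) || s == 0)
      stop_nc(sprintf("zero variance in test '%s'", ts), "nc_validation_error")
    zz <- (x - mean(x)) / s
    if (ts %in% timed) -zz else zz
  })
  out <- as.data.frame(z, col.names = names(raw))
  if (!is.null(domains)) names(out) <- unname(domains[names(raw)])
  out
}

#' Pearson chi-square test on a contingency table
#'
#' Groups x categories counts; Pearson statistic without continuity
#' correction, df = (R-1)(C-1), p from the chi-square survival function.
#' (For df = 2 the identity p = exp(-X2/2) holds and is used as an internal
#' cross-check in the test suite.)
#'
#' @param counts matrix of nonnegative integer counts.
#' @return list with `chisq`, `df`, `p`.
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(dim(counts) < 2))
    stop_nc("table must be at least 2x2", "nc_validation_error")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop_nc("empty row or column", "nc_validation_error")
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(chisq = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' One-way ANOVA (raw data or summary statistics)
#'
#' `oneway_anova` runs the textbook between/within decomposition on raw
#' values; `oneway_anova_summary` reproduces it exactly from per-group sizes,
#' means, and SDs (useful when only published summaries are available).
#'
#' @param values numeric vector.
#' @param groups group labels (coerced to factor).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop_nc("need >= 2 groups with >= 2 observations each",
            "nc_validation_error")
  a <- anova(lm(values ~ groups))
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2], p = a$`Pr(>F)`[1])
}

#' @rdname oneway_anova
#' @param ns,means,sds per-group sample sizes, means, and standard deviations.
#' @export
oneway_anova_summary <- function(ns, means, sds) {
  k <- length(ns)
  if (k < 2 || any(ns < 2))
    stop_nc("need >= 2 groups with n >= 2", "nc_validation_error")
  N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  Fv <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fv, df1 = k - 1, df2 = N - k,
       p = pf(Fv, k - 1, N - k, lower.tail = FALSE))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with the chi-square approximation (df = k - 1).
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(unique(values)) < 2)
    stop_nc("all values identical", "nc_validation_error")
  ht <- kruskal.test(values, factor(groups))
  list(H = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# ---- permutation ANCOVA ----------------------------------------------------

# design matrices for group factor + centered covariates
ancova_designs <- function(group, covariates) {
  group <- factor(group)
  n <- length(group)
  C <- if (is.null(covariates)) NULL else {
    C <- as.matrix(covariates)
    scale(C, center = TRUE, scale = FALSE)   # centering stabilizes conditioning
  }
  X_red <- cbind(intercept = rep(1, n), C)
  G <- stats::model.matrix(~group)[, -1, drop = FALSE]
  X_full <- cbind(X_red, G)
  qf <- qr(X_full)
  if (qf$rank < ncol(X_full))
    stop_nc("rank-deficient ANCOVA design", "nc_rank_error")
  list(qr_red = qr(X_red), qr_full = qf, q = ncol(G),
       p_full = ncol(X_full), n = n, group = group)
}

# partial F of the group factor over covariates, vectorized over columns of Y
partial_F <- function(Y, dz) {
  Y <- as.matrix(Y)
  rss_red <- colSums(qr.resid(dz$qr_red, Y)^2)
  rss_full <- colSums(qr.resid(dz$qr_full, Y)^2)
  ((rss_red - rss_full) / dz$q) / (rss_full / (dz$n - dz$p_full))
}

perm_matrix <- function(n, n_perm, seed) {
  with_seed(seed, vapply(seq_len(n_perm), function(i) sample.int(n),
                         integer(n)))
}

#' Permutation ANCOVA for a group factor with covariates
#'
#' Tests the group factor with a partial F over the covariates. The null
#' distribution is built by Freedman-Lane permutation: residuals of the
#' reduced (covariate-only) model are permuted and added back to its fitted
#' values, and the partial F is recomputed for each permuted outcome. The
#' p-value uses the add-one convention, `p = (1 + #[F* >= F_obs]) /
#' (1 + n_perm)`, so it is never zero. When the omnibus test passes `alpha`,
#' pairwise post-hoc contrasts are run with the same machinery on each pair
#' of groups. With no covariates and `scheme = "labels"` the observed F
#' equals the plain one-way ANOVA F.
#'
#' @param values numeric outcome vector (e.g. one region's measure).
#' @param group group labels.
#' @param covariates data.frame/matrix of covariates or `NULL`.
#' @param n_perm number of permutations (default 1000).
#' @param alpha omnibus threshold gating the post-hoc contrasts.
#' @param seed integer seed controlling the permutations.
#' @param scheme `"freedman-lane"` (default) or `"labels"` (permute the
#'   outcome directly, ignoring covariates under the null).
#' @return Object of class `ancova_perm`: list with `F_obs`, `p_perm`,
#'   `df = c(df1, df2)`, `posthoc` (data.frame of pairwise t, permutation p,
#'   and direction, or `NULL`), `n_perm`, `seed`.
#' @export
ancova_permutation <- function(values, group, covariates = NULL,
                               n_perm = 1000, alpha = 0.01, seed = 1,
                               scheme = c("freedman-lane", "labels")) {
  scheme <- match.arg(scheme)
  if (n_perm < 100)
    warning("fewer than 100 permutations gives a coarse p-value")
  dz <- ancova_designs(group, covariates)
  y <- as.numeric(values)
  F_obs <- partial_F(y, dz)
  P <- perm_matrix(dz$n, n_perm, seed)
  Ystar <- if (scheme == "freedman-lane") {
    mu <- y - qr.resid(dz$qr_red, y)
    e <- qr.resid(dz$qr_red, y)
    mu + matrix(e[P], dz$n)
  } else matrix(y[P], dz$n)
  F_null <- partial_F(Ystar, dz)
  p_perm <- (1 + sum(F_null >= F_obs)) / (1 + n_perm)
  posthoc <- NULL
  if (p_perm < alpha) {
    lv <- levels(dz$group)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    posthoc <- do.call(rbind, lapply(seq_along(pairs), function(k) {
      pr <- pairs[[k]]
      i <- dz$group %in% pr
      cov_i <- if (is.null(covariates)) NULL
               else as.matrix(covariates)[i, , drop = FALSE]
      dz2 <- ancova_designs(droplevels(dz$group[i]), cov_i)
      y2 <- y[i]
      F2 <- partial_F(y2, dz2)
      # sign: adjusted mean of the second level minus the first
      beta <- qr.coef(dz2$qr_full, y2)
      t_obs <- sign(beta[length(beta)]) * sqrt(F2)
      P2 <- perm_matrix(dz2$n, n_perm, sub_seed(seed, k, 7L))
      Y2 <- if (scheme == "freedman-lane") {
        mu2 <- y2 - qr.resid(dz2$qr_red, y2)
        mu2 + matrix(qr.resid(dz2$qr_red, y2)[P2], dz2$n)
      } else matrix(y2[P2], dz2$n)
      F2n <- partial_F(Y2, dz2)
      data.frame(pair = paste(pr, collapse = "-"), t = t_obs,
                 p_perm = (1 + sum(F2n >= F2)) / (1 + n_perm),
                 direction = if (t_obs < 0) paste(pr[2], "<", pr[1])
                             else paste(pr[2], ">", pr[1]),
                 stringsAsFactors = FALSE)
    }))
    rownames(posthoc) <- NULL
  }
  structure(list(F_obs = F_obs, p_perm = p_perm,
                 df = c(dz$q, dz$n - dz$p_full), posthoc = posthoc,
                 n_perm = n_perm, alpha = alpha, seed = seed,
                 scheme = scheme),
            class = "ancova_perm")
}

#' @export
print.ancova_perm <- function(x, ...) {
  cat(sprintf("Permutation ANCOVA (%s, %d permutations)\n", x$scheme, x$n_perm))
  cat(sprintf("  F(%d, %d) = %.3f, permutation p = %.4g\n",
              x$df[1], x$df[2], x$F_obs, x$p_perm))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc contrasts:\n")
    for (i in seq_len(nrow(x$posthoc)))
      cat(sprintf("    %-18s t = %6.2f  p = %.4g\n", x$posthoc$pair[i],
                  x$posthoc$t[i], x$posthoc$p_perm[i]))
  }
  invisible(x)
}

#' Region-wise permutation ANCOVA
#'
#' Runs [ancova_permutation()] on every column of a subjects x regions
#' measure matrix. Exactly one result per region is returned; no region is
#' silently dropped (a degenerate region yields an `NA` row). No
#' multiple-comparison correction is applied by default; set `fdr = TRUE`
#' to add Benjamini-Hochberg adjusted p-values.
#'
#' @param measures subjects x regions numeric matrix (column names = region
#'   ids).
#' @param group,covariates,n_perm,alpha,seed,scheme passed to
#'   [ancova_permutation()].
#' @param fdr append a BH-adjusted p column?
#' @return data.frame with one row per region: `region`, `F_obs`, `p_perm`,
#'   `significant`, and optionally `p_fdr`; the per-region `ancova_perm`
#'   objects are attached as attribute `fits`.
#' @export
region_stats <- function(measures, group, covariates = NULL, n_perm = 1000,
                         alpha = 0.01, seed = 1, fdr = FALSE,
                         scheme = "freedman-lane") {
  measures <- as.matrix(measures)
  K <- ncol(measures)
  ids <- colnames(measures)
  if (is.null(ids)) ids <- as.character(seq_len(K))
  fits <- lapply(seq_len(K), function(j) {
    y <- measures[, j]
    if (any(is.na(y)) || sd(y) == 0) return(NULL)
    ancova_permutation(y, group, covariates, n_perm, alpha,
                       seed = sub_seed(seed, j, 11L), scheme = scheme)
  })
  df <- data.frame(
    region = ids,
    F_obs = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$F_obs,
                   numeric(1)),
    p_perm = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$p_perm,
                    numeric(1)),
    stringsAsFactors = FALSE)
  df$significant <- !is.na(df$p_perm) & df$p_perm < alpha
  if (fdr) df$p_fdr <- stats::p.adjust(df$p_perm, "BH")
  attr(df, "fits") <- fits
  df
}

#' Partial correlation
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on the covariates;
#' p from a t distribution with `n - 2 - k` degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of covariates or `NULL` (plain
#'   correlation).
#' @return list with `r`, `df`, `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 3)
    stop_nc("too few observations for the covariate count",
            "nc_validation_error")
  if (k > 0) {
    X <- cbind(1, as.matrix(covariates))
    qx <- qr(X)
    if (qx$rank < ncol(X))
      stop_nc("rank-deficient covariate matrix", "nc_rank_error")
    x <- qr.resid(qx, x); y <- qr.resid(qx, y)
  }
  r <- cor(x, y)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * pt(-abs(tval), df))
}

#' Table-1-style demographics comparison
#'
#' Compares each listed variable across groups with the appropriate test:
#' chi-square for binary/categorical variables, one-way ANOVA or
#' Kruskal-Wallis (selectable per variable) for continuous ones.
#'
#' @param subjects cohort data.frame (needs a `group` column).
#' @param continuous named character vector: variable -> `"anova"` or
#'   `"kruskal"`.
#' @param categorical character vector of categorical/binary column names.
#' @return data.frame with `variable`, `test`, `statistic`, `p`.
#' @export
demographics_table <- function(subjects,
                               continuous = c(age = "kruskal",
                                              education_years = "kruskal"),
                               categorical = c("sex", "hypertension",
                                               "diabetes", "smoking",
                                               "drinking")) {
  g <- factor(subjects$group, wmh_groups())
  rows <- list()
  for (v in names(continuous)) {
    x <- subjects[[v]]
    res <- if (continuous[[v]] == "anova") {
      a <- oneway_anova(x, g); list(test = "anova", stat = a$F, p = a$p)
    } else {
      kk <- kruskal_wallis(x, g); list(test = "kruskal-wallis", stat = kk$H,
                                       p = kk$p)
    }
    rows[[v]] <- data.frame(variable = v, test = res$test,
                            statistic = res$stat, p = res$p)
  }
  for (v in categorical) {
    tab <- table(g, factor(subjects[[v]]))
    ct <- chi_square_test(as.matrix(tab))
    rows[[v]] <- data.frame(variable = v, test = "chi-square",
                            statistic = ct$chisq, p = ct$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
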