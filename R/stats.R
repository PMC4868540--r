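# Group-level statistics: rank-sum panels with Bonferroni correction,
# pairwise-correlation screen, PCA variance profile, canonical variate
# analysis and the label-shuffle permutation test.

#' Rank-sum test panel with Bonferroni correction
#'
#' Two-sided Wilcoxon rank-sum test per parameter between two groups on
#' pairwise-complete data, flagged at the Bonferroni-corrected level
#' alpha/m, where m is the number of parameters tested (0.05/17 = 0.003
#' for the full panel).
#'
#' @param groupA,groupB numeric matrices (flies x parameters) with
#'   matching column names; NA entries are dropped per parameter.
#' @param alpha family-wise level (default 0.05).
#' @param minPerGroup minimum defined values per group for a parameter to
#'   be tested.
#' @return data.frame (parameter, statistic, p, significant) with
#'   attributes \code{cutoff} and \code{m}.
#' @export
ranksumPanel <- function(groupA, groupB, alpha = 0.05, minPerGroup = 3L) {
  stopifnot(is.matrix(groupA), is.matrix(groupB),
            identical(colnames(groupA), colnames(groupB)))
  m <- ncol(groupA)
  cutoff <- alpha / m
  res <- data.frame(parameter = colnames(groupA),
                    statistic = NA_real_, p = NA_real_,
                    significant = NA)
  for (j in seq_len(m)) {
    a <- groupA[, j]; b <- groupB[, j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < minPerGroup || length(b) < minPerGroup) next
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
    p <- wt$p.value
    # fully tied data carry no evidence against the null; the normal
    # approximation degenerates (0/0), so report p = 1 explicitly
    if (is.nan(p)) p <- 1
    res$statistic[j] <- unname(wt$statistic)
    res$p[j] <- p
    res$significant[j] <- is.finite(p) && p < cutoff
  }
  attr(res, "cutoff") <- cutoff
  attr(res, "m") <- m
  res
}

#' Pairwise correlation screen
#'
#' Pearson correlation for every unordered pair of parameters
#' (m(m-1)/2 pairs; 136 for 17 parameters) on pairwise-complete rows,
#' with a two-sided p-value per pair and a count of significant pairs.
#' The significance criterion defaults to unadjusted alpha = 0.05 and can
#' be switched to Bonferroni across pairs.
#'
#' @param M numeric matrix (flies x parameters).
#' @param alpha significance level.
#' @param adjust "none" (default) or "bonferroni".
#' @param minComplete minimum pairwise-complete rows to test a pair.
#' @return data.frame (param1, param2, r, p, significant) with attributes
#'   \code{nPairs} and \code{nSignificant}.
#' @export
pairwiseCorrelations <- function(M, alpha = 0.05,
                                 adjust = c("none", "bonferroni"),
                                 minComplete = 5L) {
  adjust <- match.arg(adjust)
  stopifnot(is.matrix(M))
  m <- ncol(M)
  pairs <- utils::combn(m, 2L)
  nPairs <- ncol(pairs)
  cutoff <- if (adjust == "bonferroni") alpha / nPairs else alpha
  nm <- colnames(M)
  if (is.null(nm)) nm <- paste0("p", seq_len(m))
  res <- data.frame(param1 = nm[pairs[1L, ]], param2 = nm[pairs[2L, ]],
                    r = NA_real_, p = NA_real_, significant = NA)
  for (k in seq_len(nPairs)) {
    xi <- M[, pairs[1L, k]]; yi <- M[, pairs[2L, k]]
    ok <- !is.na(xi) & !is.na(yi)
    if (sum(ok) < minComplete) next
    if (stats::sd(xi[ok]) == 0 || stats::sd(yi[ok]) == 0) next
    ct <- stats::cor.test(xi[ok], yi[ok], method = "pearson")
    res$r[k] <- unname(ct$estimate)
    res$p[k] <- ct$p.value
    res$significant[k] <- ct$p.value < cutoff
  }
  attr(res, "nPairs") <- nPairs
  attr(res, "nSignificant") <- sum(res$significant, na.rm = TRUE)
  res
}

#' PCA variance profile
#'
#' Principal component analysis of the complete-case rows, standardized
#' by default (the 17 parameters mix ratios and normalized changes on
#' different scales). Returns the fraction of variance per component.
#'
#' @param M numeric matrix (flies x parameters).
#' @param standardize z-score columns before the decomposition.
#' @return List with \code{fractions} (non-increasing, summing to 1),
#'   \code{loadings} and \code{sdev}.
#' @export
pcaVariance <- function(M, standardize = TRUE) {
  stopifnot(is.matrix(M))
  cc <- stats::complete.cases(M)
  if (sum(cc) < 2L) stop("need at least 2 complete rows", call. = FALSE)
  X <- M[cc, , drop = FALSE]
  keep <- apply(X, 2L, stats::sd) > 0
  pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE,
                      scale. = standardize)
  v <- pc$sdev^2
  list(fractions = v / sum(v), loadings = pc$rotation, sdev = pc$sdev)
}

# pooled within-group and between-group covariance matrices
.scatterMatrices <- function(X, groups) {
  lev <- levels(groups)
  G <- length(lev)
  n <- nrow(X)
  p <- ncol(X)
  grand <- colMeans(X)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (g in lev) {
    Xg <- X[groups == g, , drop = FALSE]
    mg <- colMeans(Xg)
    W <- W + crossprod(sweep(Xg, 2L, mg))
    dm <- mg - grand
    B <- B + nrow(Xg) * tcrossprod(dm)
  }
  list(W = W / (n - G), B = B / (G - 1L))
}

# CV1 axis and median group distance via the symmetric generalized
# eigenproblem; lean path shared by cva() and permutationTest()
.cvaCore <- function(X, groups, ridge = 0, quiet = FALSE) {
  sm <- .scatterMatrices(X, groups)
  W <- sm$W
  if (ridge > 0) W <- W + ridge * diag(ncol(X))
  C <- tryCatch(chol(W), error = function(e) NULL)
  tries <- 0L
  while (is.null(C) && tries < 6L) {
    ridge <- max(ridge, 1e-10) * 100
    if (!quiet)
      warning("within-group covariance singular; adding ridge ", ridge)
    C <- tryCatch(chol(sm$W + ridge * diag(ncol(X))),
                  error = function(e) NULL)
    tries <- tries + 1L
  }
  if (is.null(C))
    stop("within-group covariance could not be inverted", call. = FALSE)
  inner <- forwardsolve(t(C), sm$B)
  K <- forwardsolve(t(C), t(inner))
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE)
  axes <- backsolve(C, ev$vectors)
  list(values = ev$values, axes = axes, ridge = ridge)
}

# median distance between group medians of projections on CV1
.medianGroupDistance <- function(proj, groups) {
  med <- tapply(proj, groups, stats::median)
  d <- stats::dist(med)
  stats::median(as.numeric(d))
}

#' Canonical variate analysis
#'
#' Linear projection maximizing between-group relative to within-group
#' variance: W is the pooled within-group covariance, B the group-size
#' weighted covariance of group means about the grand mean, and the
#' canonical axes are the leading eigenvectors of W^-1 B (computed
#' through the equivalent symmetric generalized eigenproblem, so the
#' eigenvalues are real by construction). The number of canonical
#' dimensions is one less than the number of groups; for two groups all
#' group separation lies on a single axis.
#'
#' @param M numeric matrix (flies x parameters); rows with NA are
#'   dropped (complete-case).
#' @param groups group label per row (coerced to factor).
#' @param ridge ridge added to W (default 0; a minimal ridge is applied
#'   automatically, with a warning, if W is singular).
#' @return A \linkS4class{CVAResult} with per-fly projections on CV1 and
#'   the observed distance between group medians.
#' @export
cva <- function(M, groups, ridge = 0) {
  stopifnot(is.matrix(M))
  groups <- factor(groups)
  if (length(groups) != nrow(M))
    stop("one group label per row required", call. = FALSE)
  cc <- stats::complete.cases(M)
  X <- M[cc, , drop = FALSE]
  g <- droplevels(groups[cc])
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L))
    stop("every group needs at least 2 complete rows", call. = FALSE)
  core <- .cvaCore(X, g, ridge)
  nDim <- nlevels(g) - 1L
  axes <- core$axes[, seq_len(nDim), drop = FALSE]
  rownames(axes) <- colnames(M)
  proj <- as.numeric(X %*% axes[, 1L])
  res <- new("CVAResult",
             eigenvalues = core$values[seq_len(nDim)],
             axes = axes, projections = proj, groups = g,
             distance = .medianGroupDistance(proj, g),
             permutationP = NA_real_, permutationPPlusOne = NA_real_,
             nPerm = 0L, seed = NA_integer_)
  attr(res, "ridge") <- core$ridge
  res
}

#' Label-shuffle permutation test for CVA group separation
#'
#' Shuffles the group labels, recomputes the canonical variate analysis
#' and the median distance between group medians on CV1 for each
#' shuffle, and reports the fraction of shuffled datasets whose distance
#' strictly exceeds the observed one (ties count as non-exceeding). The
#' (k+1)/(n+1) convention is reported as a secondary field. The original
#' analysis used 50,000 shuffles.
#'
#' @param M numeric matrix (flies x parameters).
#' @param groups group label per row.
#' @param nPerm number of label shuffles (>= 100).
#' @param seed mandatory RNG seed.
#' @param ridge ridge passed to the CVA.
#' @return A \linkS4class{CVAResult} with the permutation fields set and
#'   the null distribution in attribute \code{nullDistribution}.
#' @export
permutationTest <- function(M, groups, nPerm = 50000L, seed, ridge = 0) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  nPerm <- as.integer(nPerm)
  if (nPerm < 100L) stop("nPerm must be >= 100", call. = FALSE)
  res <- cva(M, groups, ridge)
  cc <- stats::complete.cases(M)
  X <- M[cc, , drop = FALSE]
  g <- droplevels(factor(groups)[cc])
  obs <- res@distance
  # reuse the (possibly auto-ridged) regularization of the observed fit
  effRidge <- max(ridge, attr(res, "ridge"))
  set.seed(as.integer(seed))
  nullDist <- vapply(seq_len(nPerm), function(i) {
    gp <- sample(g)
    core <- .cvaCore(X, gp, effRidge, quiet = TRUE)
    proj <- as.numeric(X %*% core$axes[, 1L])
    .medianGroupDistance(proj, gp)
  }, numeric(1))
  k <- sum(nullDist > obs)
  res@permutationP <- k / nPerm
  res@permutationPPlusOne <- (k + 1) / (nPerm + 1)
  res@nPerm <- nPerm
  res@seed <- as.integer(seed)
  attr(res, "nullDistribution") <- nullDist
  res
}
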