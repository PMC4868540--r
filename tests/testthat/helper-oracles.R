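# Independent brute-force references used to validate the package's
# implementations. These deliberately use naive, explicit formulations.

# explicit per-frame two-threshold state machine with backfilled start
schmidtOracle <- function(speed, lo, hi) {
  n <- length(speed)
  st <- rep(NA_character_, n)
  cur <- NA_character_
  for (i in seq_len(n)) {
    s <- speed[i]
    if (!is.na(s) && s < lo) cur <- "stop"
    else if (!is.na(s) && s > hi) cur <- "run"
    st[i] <- cur
  }
  # backfill leading undecided frames from the first decisive state
  if (anyNA(st)) {
    firstKnown <- which(!is.na(st))
    if (!length(firstKnown)) return(NULL)   # undeterminable
    st[seq_len(firstKnown[1] - 1L)] <- st[firstKnown[1]]
  }
  st
}

# naive generalized eigenproblem W^-1 B via plain eigen() on the
# (generally non-symmetric) product
cvaOracle <- function(X, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  n <- nrow(X); p <- ncol(X); G <- length(lev)
  grand <- colMeans(X)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (g in lev) {
    Xg <- X[groups == g, , drop = FALSE]
    mg <- colMeans(Xg)
    for (i in seq_len(nrow(Xg)))
      W <- W + tcrossprod(Xg[i, ] - mg)
    B <- B + nrow(Xg) * tcrossprod(mg - grand)
  }
  W <- W / (n - G); B <- B / (G - 1)
  ev <- eigen(solve(W) %*% B)
  ord <- order(Re(ev$values), decreasing = TRUE)
  a1 <- Re(ev$vectors[, ord[1]])
  proj <- as.numeric(X %*% a1)
  med <- tapply(proj, groups, median)
  list(axis = a1, projections = proj,
       separation = abs(diff(range(med))) /
         stats::sd(proj - ave(proj, groups)))
}

# exhaustive-enumeration two-sided rank-sum p-value (no ties assumed)
ranksumEnumOracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  ranks <- rank(pooled)
  wObs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  wAll <- apply(idx, 2, function(ii) {
    sum(rank(pooled)[ii]) - n1 * (n1 + 1) / 2
  })
  lower <- mean(wAll <= wObs)
  upper <- mean(wAll >= wObs)
  min(1, 2 * min(lower, upper))
}
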