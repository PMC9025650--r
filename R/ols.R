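# Fast per-feature ordinary least squares.
#
# QR decomposition with the same algebra as summary.lm: coefficients via
# qr.coef, unscaled covariance via chol2inv of the R factor (pivot-aware),
# classical homoskedastic t-based p-values, and adjusted R^2 computed as
# 1 - (1 - R^2)(n - 1)/(n - p - 1). Rank-deficient designs return NA for the
# aliased coefficients so callers can flag degenerate features instead of
# crashing.
fast_ols <- function(X, y) {
  n <- length(y)
  qx <- qr(X)
  r <- qx$rank
  cf <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  rss <- sum(res^2)
  df <- n - r
  se <- rep(NA_real_, ncol(X))
  if (df > 0) {
    R <- qr.R(qx)[seq_len(r), seq_len(r), drop = FALSE]
    cov_unscaled <- chol2inv(R)
    se[qx$pivot[seq_len(r)]] <- sqrt(diag(cov_unscaled) * rss / df)
  }
  tval <- cf / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- if (tss > 0 && df > 0) 1 - (1 - r2) * (n - 1) / df else NA_real_
  names(cf) <- names(se) <- names(tval) <- names(pval) <- colnames(X)
  list(coef = cf, se = se, t = tval, p = pval,
       r2 = r2, adj_r2 = adj_r2, n = n, df = df, rank = r, rss = rss)
}
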