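# Shared fixtures and independent oracles for the test suite.

# Directly construct a harmonized set from effect vectors (bypasses the
# harmonization path so estimator tests are independent of it).
make_hset <- function(beta_exp, beta_out, se_out, se_exp = 0.01,
                      ids = sprintf("rs%03d", seq_along(beta_exp)),
                      eaf = 0.3) {
  k <- length(beta_exp)
  structure(
    data.frame(snp_id = ids, chrom = "1", pos = seq_len(k),
               beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
               eaf_exp = rep_len(eaf, k),
               beta_out = beta_out, se_out = rep_len(se_out, k),
               eaf_out = rep_len(eaf, k),
               palindromic = FALSE, action_taken = "kept",
               stringsAsFactors = FALSE),
    exposure_name = "exp", outcome_name = "out",
    class = c("harmonized_set", "data.frame"))
}

# A harmonized set whose per-SNP Wald ratios and ratio SEs are exactly the
# given values (beta_exp = 1 throughout).
hset_from_ratios <- function(ratios, ratio_ses, se_exp = 1e-6) {
  make_hset(beta_exp = rep(1, length(ratios)), beta_out = ratios,
            se_out = ratio_ses, se_exp = se_exp)
}

# Weighted-least-squares oracle by explicit normal equations.
oracle_wls <- function(x, y, w, intercept = TRUE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  XtWX <- t(X) %*% (w * X)
  coef <- drop(solve(XtWX, t(X) %*% (w * y)))
  resid <- y - drop(X %*% coef)
  df <- length(y) - ncol(X)
  sigma2 <- sum(w * resid^2) / df
  list(coef = coef, cov_unscaled = solve(XtWX), sigma = sqrt(sigma2),
       resid = resid)
}

# Brute-force weighted-median oracle: interpolate the weighted empirical
# quantile function at 0.5 using cumulative-weight midpoints, scanning
# adjacent pairs explicitly.
oracle_weighted_median <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(theta[1])
  n <- length(theta)
  if (0.5 >= p[n]) return(theta[n])
  for (i in seq_len(n - 1)) {
    if (p[i] <= 0.5 && 0.5 <= p[i + 1]) {
      return(theta[i] + (theta[i + 1] - theta[i]) *
               (0.5 - p[i]) / (p[i + 1] - p[i]))
    }
  }
  stop("unreachable")
}

# Brute-force Benjamini-Hochberg step-up oracle.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Brute-force greedy clumping oracle over an explicit r2 lookup function.
oracle_clump <- function(df, r2_fun, r2_threshold, window_kb) {
  df <- df[order(df$pvalue, df$snp_id), ]
  picked <- character(0)
  while (nrow(df) > 0) {
    idx <- df[1, ]
    picked <- c(picked, idx$snp_id)
    df <- df[-1, , drop = FALSE]
    if (nrow(df) == 0) break
    drop <- vapply(seq_len(nrow(df)), function(i) {
      df$chrom[i] == idx$chrom &&
        abs(df$pos[i] - idx$pos) <= window_kb * 1000 &&
        r2_fun(idx$snp_id, df$snp_id[i]) >= r2_threshold
    }, logical(1))
    df <- df[!drop, , drop = FALSE]
  }
  picked
}

# Small in-memory GWAS table used by the IO tests.
io_fixture <- function() {
  data.frame(
    snp = c("rs1", "rs2", "rs3"), chr = c("1", "2", "3"),
    pos = c(1000L, 2000L, 3000L),
    ea = c("a", "C", "g"), oa = c("G", "t", "A"),
    eaf = c(0.25, 0.5, 0.75),
    beta = c(0.1, -0.2, 0.05), se = c(0.01, 0.02, 0.03),
    p = c(1e-9, 1e-7, 0.5), n = c(10000, 10000, 10000),
    stringsAsFactors = FALSE)
}
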