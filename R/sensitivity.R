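# Heterogeneity, pleiotropy and robustness diagnostics: Cochran's Q,
# Egger intercept, leave-one-out, funnel data, MR-PRESSO.

#' Cochran's Q heterogeneity test
#'
#' Quantifies heterogeneity of the per-SNP Wald ratios about the
#' fixed-effect IVW estimate: `Q = sum(w_j * (theta_j - beta_ivw)^2)` with
#' inverse-variance weights, referred to a chi-square distribution on
#' k - 1 degrees of freedom. A p-value above 0.05 supports the
#' fixed-effects IVW model; below it, the random-effects model.
#'
#' @param hset A `harmonized_set` with at least 2 kept SNPs.
#' @return List with `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(hset) {
  r <- .ratios(hset)
  k <- length(r$theta)
  if (k < 2L) stop("Cochran's Q needs at least 2 instruments, got ", k)
  w <- 1 / r$se^2
  beta <- sum(w * r$theta) / sum(w)
  q <- sum(w * (r$theta - beta)^2)
  list(q = q, df = k - 1L,
       pvalue = stats::pchisq(q, k - 1, lower.tail = FALSE))
}

.sign_conclusion <- function(ci_low_beta, ci_high_beta) {
  if (ci_low_beta > 0) 1L else if (ci_high_beta < 0) -1L else 0L
}

#' Leave-one-out analysis
#'
#' Re-estimates the causal effect k times, each time excluding one
#' instrument, to check that no single SNP drives the overall result. Rows
#' are flagged when the exclusion changes the qualitative conclusion: the
#' confidence interval of the reduced set no longer supports the sign
#' conclusion (positive / negative / null) of the full-set estimate.
#'
#' @param hset A `harmonized_set` with at least 3 kept SNPs.
#' @param estimator `"ivw"` (default, the usual choice), `"egger"`, or
#'   `"weighted_median"`.
#' @param ... Passed to the estimator (e.g. `seed` for the weighted
#'   median).
#' @return Data frame with one row per excluded SNP: `excluded_snp`,
#'   `beta`, `se`, `pvalue`, `or`, `ci_low`, `ci_high`,
#'   `conclusion_changed`. The full-set estimate is attached as attribute
#'   `full_estimate`.
#' @export
leave_one_out <- function(hset, estimator = c("ivw", "egger",
                                              "weighted_median"), ...) {
  estimator <- match.arg(estimator)
  fun <- switch(estimator, ivw = mr_ivw, egger = mr_egger,
                weighted_median = mr_weighted_median)
  h <- harmonized_kept(hset)
  k <- nrow(h)
  if (k < 3L) stop("leave-one-out needs at least 3 instruments, got ", k)
  full <- fun(hset, ...)
  full_sign <- .sign_conclusion(full$beta - .z975 * full$se,
                                full$beta + .z975 * full$se)
  rows <- lapply(seq_len(k), function(i) {
    e <- fun(h[-i, , drop = FALSE], ...)
    loo_sign <- .sign_conclusion(e$beta - .z975 * e$se,
                                 e$beta + .z975 * e$se)
    data.frame(excluded_snp = h$snp_id[i], beta = e$beta, se = e$se,
               pvalue = e$pvalue, or = e$or, ci_low = e$ci_low,
               ci_high = e$ci_high,
               conclusion_changed = loo_sign != full_sign,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "full_estimate") <- full
  out
}

#' Funnel-plot data and asymmetry summary
#'
#' Per-SNP Wald ratios with their precisions (1/se), the coordinates of
#' the conventional funnel plot used to inspect directional pleiotropy /
#' small-study-type bias. Symmetry about the IVW estimate is summarised by
#' the inverse-variance-weighted skewness of the ratios; values near 0
#' indicate an approximately symmetric funnel.
#'
#' @param hset A `harmonized_set` with at least 1 kept SNP.
#' @return Data frame with `snp_id`, `ratio`, `precision`; attribute
#'   `asymmetry` holds the weighted skewness (NA with fewer than 3 SNPs).
#' @export
funnel_data <- function(hset) {
  r <- .ratios(hset)
  out <- data.frame(snp_id = r$snp_id, ratio = r$theta,
                    precision = 1 / r$se, stringsAsFactors = FALSE)
  if (length(r$theta) >= 3) {
    w <- 1 / r$se^2
    w <- w / sum(w)
    mu <- sum(w * r$theta)
    sdv <- sqrt(sum(w * (r$theta - mu)^2))
    attr(out, "asymmetry") <- if (sdv > 0)
      sum(w * (r$theta - mu)^3) / sdv^3 else 0
  } else {
    attr(out, "asymmetry") <- NA_real_
  }
  out
}

#' MR-PRESSO: global pleiotropy test and outlier detection
#'
#' Residual-sum-of-squares test for horizontal pleiotropy. The observed
#' RSS is built from leave-one-out predictions: for each SNP j the IVW
#' estimate computed without SNP j predicts the SNP-outcome effect as
#' `beta_loo_j * beta_exp_j`; the squared deviation of the observed effect,
#' standardized by the outcome variance, is SNP j's contribution. The null
#' distribution comes from `n_sim` parametric simulations of the outcome
#' effects under the no-pleiotropy model (normal around the leave-one-out
#' predictions with the observed outcome standard errors), with the
#' leave-one-out machinery re-applied to each simulated data set. The
#' global p-value is the Monte-Carlo tail probability
#' `(1 + #(RSS_sim >= RSS_obs)) / (n_sim + 1)`. Each SNP's observed
#' contribution is likewise compared with its simulated distribution and
#' Bonferroni-adjusted over the k instruments; SNPs below
#' `outlier_significance` are reported as outliers, and IVW estimates
#' before and after their removal are returned. When outliers exist a
#' distortion p-value compares the observed estimate shift against the
#' shift obtained by removing random SNP subsets of the same size.
#'
#' @param hset A `harmonized_set` with at least 4 kept SNPs.
#' @param n_sim Number of null simulations (>= 100); default 1000.
#' @param seed Optional integer seed.
#' @param outlier_significance Threshold applied to the
#'   Bonferroni-adjusted per-SNP p-values; default 0.05.
#' @return A `presso_result` list: `global_rss`, `global_pvalue`,
#'   `outlier_pvalues` (named, Bonferroni-adjusted), `outliers`,
#'   `distortion_pvalue` (NA when no outliers), `estimate_before`,
#'   `estimate_after` (NULL when no outliers or too few SNPs remain).
#' @export
mr_presso <- function(hset, n_sim = 1000, seed = NULL,
                      outlier_significance = 0.05) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  r <- .ratios(hset)
  h <- r$h
  k <- nrow(h)
  if (k < 4L) {
    stop("MR-PRESSO not applicable with fewer than 4 instruments (got ",
         k, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  w <- 1 / r$se^2                    # ratio weights
  sw <- sum(w); swt <- sum(w * r$theta)
  beta_loo <- (swt - w * r$theta) / (sw - w)   # IVW without SNP j, per j
  pred <- beta_loo * h$beta_exp
  d_obs <- (h$beta_out - pred)^2 / h$se_out^2
  rss_obs <- sum(d_obs)

  # simulate outcome effects under no pleiotropy and recompute the
  # leave-one-out residuals on each simulated data set (vectorized over sims)
  bo_sim <- matrix(stats::rnorm(k * n_sim, mean = pred, sd = h$se_out),
                   nrow = k)
  th_sim <- bo_sim / h$beta_exp
  swt_sim <- colSums(w * th_sim)                        # n_sim
  beta_loo_sim <- (matrix(swt_sim, k, n_sim, byrow = TRUE) - w * th_sim) /
    (sw - w)
  d_sim <- (bo_sim - beta_loo_sim * h$beta_exp)^2 / h$se_out^2
  rss_sim <- colSums(d_sim)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  p_snp <- (1 + rowSums(d_sim >= d_obs)) / (n_sim + 1)
  p_adj <- pmin(1, k * p_snp)
  names(p_adj) <- h$snp_id
  outliers <- h$snp_id[p_adj < outlier_significance]

  est_before <- mr_ivw(hset)
  est_after <- NULL
  distortion_p <- NA_real_
  if (length(outliers)) {
    keep <- !(h$snp_id %in% outliers)
    if (sum(keep) >= 2L) {
      est_after <- mr_ivw(h[keep, , drop = FALSE])
      # distortion: observed shift vs shifts from removing random subsets
      n_out <- length(outliers)
      d_observed <- est_before$beta - est_after$beta
      ivw_wo <- function(idx) {
        wk <- w[-idx]; tk <- r$theta[-idx]
        sum(wk * tk) / sum(wk)
      }
      d_null <- vapply(seq_len(n_sim), function(b) {
        est_before$beta - ivw_wo(sample.int(k, n_out))
      }, numeric(1))
      distortion_p <- (1 + sum(abs(d_null) >= abs(d_observed))) / (n_sim + 1)
    }
  }
  structure(list(global_rss = rss_obs, global_pvalue = global_p,
                 outlier_pvalues = p_adj, outliers = outliers,
                 distortion_pvalue = distortion_p,
                 estimate_before = est_before, estimate_after = est_after,
                 n_sim = n_sim),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO global test: RSS = %.3f, p = %.4g (%d simulations)\n",
              x$global_rss, x$global_pvalue, x$n_sim))
  if (length(x$outliers)) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    cat(sprintf("  distortion p = %.4g\n", x$distortion_pvalue))
  } else {
    cat("  no significant outliers\n")
  }
  invisible(x)
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, leave-one-out, funnel
#' data and MR-PRESSO. Diagnostics whose instrument-count minimum is not
#' met are recorded as `NULL` with the reason in `$not_applicable`.
#'
#' @param hset A `harmonized_set`.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed Seed for MR-PRESSO.
#' @param loo_estimator Estimator for the leave-one-out series.
#' @return A `sensitivity_report` list with elements `q_stat`, `q_df`,
#'   `q_pvalue`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pvalue`, `loo`, `funnel`, `presso`,
#'   `not_applicable`.
#' @export
sensitivity_report <- function(hset, n_sim = 1000, seed = NULL,
                               loo_estimator = "ivw") {
  na_reasons <- character(0)
  try_part <- function(expr, label) {
    tryCatch(expr, error = function(e) {
      na_reasons[[label]] <<- conditionMessage(e)
      NULL
    })
  }
  q <- try_part(cochran_q(hset), "cochran_q")
  eg <- try_part(mr_egger(hset), "egger")
  loo <- try_part(leave_one_out(hset, estimator = loo_estimator), "loo")
  fun <- try_part(funnel_data(hset), "funnel")
  pr <- try_part(mr_presso(hset, n_sim = n_sim, seed = seed), "presso")
  structure(list(
    q_stat = q$q %||% NA_real_, q_df = q$df %||% NA_integer_,
    q_pvalue = q$pvalue %||% NA_real_,
    egger_intercept = if (is.null(eg)) NA_real_ else eg$intercept,
    egger_intercept_se = if (is.null(eg)) NA_real_ else eg$intercept_se,
    egger_intercept_pvalue = if (is.null(eg)) NA_real_ else eg$intercept_pvalue,
    loo = loo, funnel = fun, presso = pr,
    not_applicable = na_reasons
  ), class = "sensitivity_report")
}
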