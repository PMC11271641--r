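# Causal-effect estimators for harmonized two-sample summary data:
# Wald ratio, IVW (fixed / multiplicative random effects), MR-Egger,
# weighted median.

.z975 <- 1.959964

.mr_estimate <- function(method, beta, se, pvalue, n_snps, ...) {
  or <- to_odds_ratio(beta, se)
  structure(
    c(list(method = method, beta = beta, se = se, pvalue = pvalue,
           or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
           n_snps = n_snps), list(...)),
    class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method, x$n_snps))
  cat(sprintf("  beta = %.4f (se %.4f), p = %.3g\n", x$beta, x$se, x$pvalue))
  cat(sprintf("  OR = %.2f (95%% CI %.2f-%.2f)\n", x$or, x$ci_low, x$ci_high))
  if (!is.null(x$intercept)) {
    cat(sprintf("  Egger intercept = %.4f (se %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_pvalue))
  }
  if (!is.null(x$q_stat)) {
    cat(sprintf("  Cochran's Q = %.3f on %d df, p = %.3g\n",
                x$q_stat, x$q_df, x$q_pvalue))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
             pvalue = x$pvalue,
             intercept = x$intercept %||% NA_real_,
             intercept_se = x$intercept_se %||% NA_real_,
             intercept_pvalue = x$intercept_pvalue %||% NA_real_,
             stringsAsFactors = FALSE)
}

#' Wald ratio and its first-order standard error
#'
#' The per-SNP causal estimate: SNP-outcome effect divided by SNP-exposure
#' effect, with the first-order (delta-method) standard error
#' `se_out / |beta_exp|`.
#'
#' @param beta_exp SNP-exposure effect(s); must be nonzero.
#' @param beta_out SNP-outcome effect(s).
#' @param se_out Standard error(s) of `beta_out`; positive.
#' @return List with vectors `ratio` and `se_ratio`.
#' @export
wald_ratio <- function(beta_exp, beta_out, se_out) {
  if (any(beta_exp == 0)) stop("Wald ratio undefined: beta_exp = 0")
  stopifnot(all(se_out > 0))
  list(ratio = beta_out / beta_exp, se_ratio = se_out / abs(beta_exp))
}

.ratios <- function(hset) {
  h <- harmonized_kept(hset)
  if (nrow(h) == 0L) stop("no kept instruments in harmonized set")
  if (all(h$beta_exp == 0)) stop("no valid Wald ratios: all beta_exp are zero")
  if (any(h$beta_exp == 0)) {
    warning(sum(h$beta_exp == 0), " instrument(s) with beta_exp = 0 dropped")
    h <- h[h$beta_exp != 0, , drop = FALSE]
  }
  w <- wald_ratio(h$beta_exp, h$beta_out, h$se_out)
  list(snp_id = h$snp_id, theta = w$ratio, se = w$se_ratio, h = h)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-SNP Wald ratios by inverse-variance weighting, the standard
#' primary estimator for summary-data MR. With weights `w_j = 1/se_ratio_j^2`
#' the estimate is `sum(w*theta)/sum(w)`; the fixed-effect standard error is
#' `1/sqrt(sum(w))`. Under the multiplicative random-effects model the
#' standard error is inflated by `max(1, sqrt(Q/(k-1)))`, where Q is
#' Cochran's heterogeneity statistic. `model = "auto"` follows the usual
#' decision rule: fixed effects when the Q-test p-value exceeds 0.05,
#' random effects otherwise. A single instrument degenerates to the Wald
#' ratio (method `"wald"`).
#'
#' @param hset A `harmonized_set` (only kept rows are used).
#' @param model `"auto"` (default), `"fixed"`, or `"random"`.
#' @return An `mr_estimate` with fields `beta`, `se`, `pvalue`, `or`,
#'   `ci_low`, `ci_high`, `n_snps`, plus `q_stat`, `q_df`, `q_pvalue`,
#'   `overdispersion_scale` and the `model_used`.
#' @export
mr_ivw <- function(hset, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  r <- .ratios(hset)
  k <- length(r$theta)
  if (k == 1L) {
    z <- r$theta / r$se
    return(.mr_estimate("wald", r$theta, r$se, 2 * stats::pnorm(-abs(z)), 1L))
  }
  w <- 1 / r$se^2
  beta <- sum(w * r$theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (r$theta - beta)^2)
  q_df <- k - 1L
  q_p <- stats::pchisq(q, q_df, lower.tail = FALSE)
  scale <- max(1, sqrt(q / q_df))
  model_used <- switch(model,
                       fixed = "fixed",
                       random = "random",
                       auto = if (q_p > 0.05) "fixed" else "random")
  se <- if (model_used == "random") se_fixed * scale else se_fixed
  z <- beta / se
  .mr_estimate(paste0("ivw_", model_used), beta, se, 2 * stats::pnorm(-abs(z)),
               k, q_stat = q, q_df = q_df, q_pvalue = q_p,
               overdispersion_scale = scale, model_used = model_used)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the SNP-outcome effects on the
#' SNP-exposure effects with an intercept, using inverse outcome-variance
#' weights. SNPs are first oriented so every exposure effect is
#' non-negative, which gives the intercept its meaning as the average
#' directional (horizontal) pleiotropic effect; the slope is the causal
#' estimate, consistent under the InSIDE assumption even when instruments
#' are pleiotropic. Standard errors use multiplicative overdispersion with
#' the residual scale floored at 1; p-values come from the t distribution
#' with k - 2 degrees of freedom, confidence intervals use the normal
#' 97.5th percentile.
#'
#' @param hset A `harmonized_set` with at least 3 kept SNPs.
#' @return An `mr_estimate` with `intercept`, `intercept_se`,
#'   `intercept_pvalue` and `overdispersion_scale` populated.
#' @export
mr_egger <- function(hset) {
  r <- .ratios(hset)
  k <- nrow(r$h)
  if (k < 3L) stop("MR-Egger needs at least 3 instruments, got ", k)
  flip <- sign(r$h$beta_exp)
  bx <- r$h$beta_exp * flip
  by <- r$h$beta_out * flip
  w <- 1 / r$h$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))
  scale <- max(1, sm$sigma)
  se <- sqrt(diag(sm$cov.unscaled)) * scale
  tval <- cf / se
  pv <- 2 * stats::pt(-abs(tval), df = k - 2)
  .mr_estimate("egger", unname(cf[2]), unname(se[2]), unname(pv[2]), k,
               intercept = unname(cf[1]), intercept_se = unname(se[1]),
               intercept_pvalue = unname(pv[1]),
               overdispersion_scale = scale)
}

# Weighted median of ratio estimates theta with weights w: the value of the
# weighted empirical quantile function at probability 0.5, linearly
# interpolated between cumulative-weight midpoints.
.weighted_median <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w)
  p <- s - w / 2
  if (0.5 <= p[1]) return(theta[1])
  if (0.5 >= p[length(p)]) return(theta[length(theta)])
  stats::approx(p, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The median of the inverse-variance-weighted empirical distribution of
#' the per-SNP Wald ratios. The estimator is consistent as long as at
#' least half of the weight comes from valid instruments, making it robust
#' to up to 50% invalid instruments. The standard error is obtained by
#' parametric bootstrap: `n_boot` resamples of the exposure and outcome
#' effects from normal distributions centred at their observed values with
#' their reported standard errors.
#'
#' @param hset A `harmonized_set` with at least 3 kept SNPs.
#' @param n_boot Number of bootstrap resamples (>= 100); default 1000.
#' @param seed Optional integer seed making the bootstrap reproducible.
#' @return An `mr_estimate` (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed = NULL) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  r <- .ratios(hset)
  k <- nrow(r$h)
  if (k < 3L) stop("weighted median needs at least 3 instruments, got ", k)
  w <- 1 / r$se^2
  beta <- .weighted_median(r$theta, w)
  if (!is.null(seed)) set.seed(seed)
  h <- r$h
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(k, h$beta_exp, h$se_exp)
    by <- stats::rnorm(k, h$beta_out, h$se_out)
    ok <- bx != 0
    th <- by[ok] / bx[ok]
    wb <- (abs(bx[ok]) / h$se_out[ok])^2
    .weighted_median(th, wb)
  }, numeric(1))
  se <- stats::sd(boots)
  z <- beta / se
  .mr_estimate("weighted_median", beta, se, 2 * stats::pnorm(-abs(z)), k)
}

#' Convert a log odds-ratio estimate to the OR scale
#'
#' @param beta Log odds ratio(s).
#' @param se Standard error(s), non-negative.
#' @return List with `or = exp(beta)` and the 95% Wald interval
#'   `exp(beta -/+ 1.959964 * se)`.
#' @export
to_odds_ratio <- function(beta, se) {
  stopifnot(all(se >= 0))
  list(or = exp(beta), ci_low = exp(beta - .z975 * se),
       ci_high = exp(beta + .z975 * se))
}

#' Run the standard trio of MR estimators on one harmonized set
#'
#' IVW (auto fixed/random), MR-Egger and the weighted median, as commonly
#' reported together. Methods whose instrument-count minimum is not met are
#' recorded as not estimable rather than erroring.
#'
#' @param hset A `harmonized_set`.
#' @param n_boot Bootstrap resamples for the weighted median.
#' @param seed Seed for the weighted-median bootstrap.
#' @return Named list of `mr_estimate` objects (entries may be `NULL` with
#'   a `not_estimable` attribute describing why).
#' @export
mr_all_methods <- function(hset, n_boot = 1000, seed = NULL) {
  run <- function(f) tryCatch(f, error = function(e) {
    structure(list(), not_estimable = conditionMessage(e))
  })
  list(ivw = run(mr_ivw(hset)),
       egger = run(mr_egger(hset)),
       weighted_median = run(mr_weighted_median(hset, n_boot, seed)))
}

#' Assemble an estimates table in publication shape
#'
#' @param estimates Named list as returned by [mr_all_methods()].
#' @param exposure,outcome Trait labels.
#' @param digits Rounding applied to OR and CI columns in the `or_text`
#'   rendering (2, matching common reporting style).
#' @return Data frame with one row per estimable method: exposure, outcome,
#'   method, n_snps, beta, se, or, ci_low, ci_high, pvalue, or_text.
#' @export
estimates_table <- function(estimates, exposure, outcome, digits = 2) {
  rows <- lapply(names(estimates), function(m) {
    e <- estimates[[m]]
    if (!inherits(e, "mr_estimate")) return(NULL)
    cbind(data.frame(exposure = exposure, outcome = outcome,
                     stringsAsFactors = FALSE),
          as.data.frame(e))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$or_text <- sprintf(paste0("%.", digits, "f (%.", digits, "f-%.",
                                digits, "f)"),
                         out$or, out$ci_low, out$ci_high)
  rownames(out) <- NULL
  out
}
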