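# Synthetic two-sample GWAS summary statistics with known ground truth.

#' Simulation configuration for two-sample summary data
#'
#' Defines the generative model for a pair of synthetic GWAS summary
#' tables with a known causal effect. Per SNP j: an effect-allele
#' frequency is drawn uniformly from `eaf_range`; a true SNP-exposure
#' effect `gamma_j` from Normal(`instrument_beta_mean`,
#' `instrument_beta_sd`); the exposure standard error follows the
#' allele-frequency-scaled large-sample form
#' `1/sqrt(2*eaf*(1-eaf)*n_exposure)`; the observed exposure effect is
#' normal around `gamma_j`. The outcome effect is normal around
#' `causal_beta * gamma_j + alpha_j` with the analogous standard error
#' under `n_outcome`, where the pleiotropic effect `alpha_j` is 0 for
#' valid instruments and, for the invalid fraction `prop_invalid`, drawn
#' Normal(0, sd) (`pleiotropy = "balanced"`) or Normal(mean, sd)
#' (`"directional"`).
#'
#' Case/control cohorts are emulated through the effective sample size
#' `n_eff = 4 / (1/n_cases + 1/n_controls)` (see [effective_n()]); the
#' defaults correspond to a small psychiatric exposure GWAS (2,248 cases /
#' 7,992 controls) against a biobank cancer outcome (636 cases / 455,640
#' controls) with 13 instruments, a realistic lower bound on instrument
#' count and power for this kind of analysis.
#'
#' @param n_snps Number of instruments; default 13.
#' @param causal_beta True causal effect (log odds ratio); default 0.
#' @param instrument_beta_mean,instrument_beta_sd Distribution of true
#'   SNP-exposure effects; defaults 0.15 and 0.05.
#' @param eaf_range Uniform bounds for allele frequencies; default
#'   c(0.1, 0.9).
#' @param n_exposure,n_outcome (Effective) sample sizes; defaults
#'   `effective_n(2248, 7992)` and `effective_n(636, 455640)`.
#' @param pleiotropy `"none"` (default), `"balanced"`, `"directional"`.
#' @param pleiotropy_mean Mean pleiotropic effect (directional only);
#'   default 0.
#' @param pleiotropy_sd SD of pleiotropic effects; default 0.
#' @param prop_invalid Fraction of instruments receiving a pleiotropic
#'   effect, in [0, 1); default 0.3 when pleiotropy is requested, else 0.
#' @param seed Integer seed; all randomness in
#'   [simulate_two_sample()] flows from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_snps = 13, causal_beta = 0,
                              instrument_beta_mean = 0.15,
                              instrument_beta_sd = 0.05,
                              eaf_range = c(0.1, 0.9),
                              n_exposure = effective_n(2248, 7992),
                              n_outcome = effective_n(636, 455640),
                              pleiotropy = c("none", "balanced",
                                             "directional"),
                              pleiotropy_mean = 0, pleiotropy_sd = 0,
                              prop_invalid = NULL, seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  if (is.null(prop_invalid)) {
    prop_invalid <- if (pleiotropy == "none") 0 else 0.3
  }
  stopifnot(n_snps >= 1, instrument_beta_sd >= 0, pleiotropy_sd >= 0,
            prop_invalid >= 0, prop_invalid < 1,
            length(eaf_range) == 2, eaf_range[1] > 0.05 - 1e-12,
            eaf_range[2] < 0.95 + 1e-12, eaf_range[1] < eaf_range[2],
            n_exposure > 2, n_outcome > 2)
  structure(list(n_snps = as.integer(n_snps), causal_beta = causal_beta,
                 instrument_beta_mean = instrument_beta_mean,
                 instrument_beta_sd = instrument_beta_sd,
                 eaf_range = eaf_range, n_exposure = n_exposure,
                 n_outcome = n_outcome, pleiotropy = pleiotropy,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 prop_invalid = prop_invalid, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Effective sample size of a case/control GWAS
#'
#' `n_eff = 4 / (1/n_cases + 1/n_controls)`, the sample size of a
#' balanced study with equivalent precision; used to emulate case/control
#' cohorts in the continuous-trait standard-error approximation.
#'
#' @param n_cases,n_controls Positive counts.
#' @return Effective sample size.
#' @export
effective_n <- function(n_cases, n_controls) {
  stopifnot(n_cases > 0, n_controls > 0)
  4 / (1 / n_cases + 1 / n_controls)
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Generates exposure and outcome summary-statistics tables from a
#' [simulation_config()], fully reproducible from its seed. Alleles are
#' assigned non-palindromic (A/G) so that harmonization keeps every SNP;
#' SNPs are placed on alternating chromosomes at widely spaced positions
#' so they are trivially independent for clumping purposes.
#'
#' @param config A `simulation_config`.
#' @return List with `exposure` and `outcome` (`summary_stats` data
#'   frames) and `truth` (list with per-SNP `gamma`, `alpha`, `eaf`,
#'   `invalid` ids, and the generative parameters).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  k <- config$n_snps
  snp_id <- sprintf("rs%07d", seq_len(k))
  chrom <- as.character(((seq_len(k) - 1L) %% 22L) + 1L)
  pos <- 1000000L + 20000000L * (((seq_len(k) - 1L) %/% 22L) + 1L) +
    seq_len(k)
  eaf <- stats::runif(k, config$eaf_range[1], config$eaf_range[2])
  gamma <- stats::rnorm(k, config$instrument_beta_mean,
                        config$instrument_beta_sd)

  se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_exposure)
  beta_exp <- stats::rnorm(k, gamma, se_exp)

  n_invalid <- round(config$prop_invalid * k)
  invalid <- if (n_invalid > 0) sort(sample.int(k, n_invalid)) else integer(0)
  alpha <- numeric(k)
  if (config$pleiotropy != "none" && n_invalid > 0) {
    mu <- if (config$pleiotropy == "directional") config$pleiotropy_mean else 0
    alpha[invalid] <- stats::rnorm(n_invalid, mu, config$pleiotropy_sd)
  }

  se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_outcome)
  beta_out <- stats::rnorm(k, config$causal_beta * gamma + alpha, se_out)

  pv <- function(b, s) 2 * stats::pnorm(-abs(b / s))
  exposure <- summary_stats(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G", eaf = eaf,
    beta = beta_exp, se = se_exp, pvalue = pmax(pv(beta_exp, se_exp), 1e-300),
    n = config$n_exposure, trait_name = "synthetic_exposure")
  outcome <- summary_stats(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G", eaf = eaf,
    beta = beta_out, se = se_out, pvalue = pmax(pv(beta_out, se_out), 1e-300),
    n = config$n_outcome, trait_name = "synthetic_outcome")
  list(exposure = exposure, outcome = outcome,
       truth = list(snp_id = snp_id, gamma = gamma, alpha = alpha, eaf = eaf,
                    invalid = snp_id[invalid],
                    causal_beta = config$causal_beta, config = config))
}

#' Shift the outcome effects of selected SNPs
#'
#' Adds `shift` to `beta_out` of the named kept SNPs of a harmonized set,
#' leaving everything else untouched; used to create known outliers for
#' exercising outlier-detection diagnostics.
#'
#' @param hset A `harmonized_set`.
#' @param snp_ids Character vector of kept SNP ids (may be empty).
#' @param shift Additive shift on the outcome-effect scale.
#' @return The modified `harmonized_set`.
#' @export
inject_outliers <- function(hset, snp_ids, shift) {
  if (length(snp_ids) == 0L) return(hset)
  kept_ids <- harmonized_kept(hset)$snp_id
  unknown <- setdiff(snp_ids, kept_ids)
  if (length(unknown)) {
    stop("unknown or non-kept snp_id(s): ", paste(unknown, collapse = ", "))
  }
  idx <- hset$snp_id %in% snp_ids
  hset$beta_out[idx] <- hset$beta_out[idx] + shift
  hset
}
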