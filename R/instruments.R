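# Instrument selection: significance filtering, LD clumping, strength (F),
# confounder exclusion lists.

#' Filter summary statistics at a significance threshold
#'
#' Keeps exactly the records with `pvalue` strictly below `p_threshold`
#' (genome-wide significance is conventionally 5e-8; a relaxed 5e-6 is used
#' for traits with few genome-wide-significant hits), preserving input
#' order. A warning is raised when nothing survives; an empty set is a
#' legitimate result meaning "no instruments".
#'
#' @param records A `summary_stats` data frame.
#' @param p_threshold Significance threshold in (0, 1); comparison is
#'   strict (`pvalue < p_threshold`).
#' @return The filtered `summary_stats` data frame.
#' @export
filter_significant <- function(records, p_threshold = 5e-8) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  keep <- records$pvalue < p_threshold
  if (!any(keep)) {
    warning("no records pass p < ", format(p_threshold),
            "; no instruments available")
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  .restat(out, records)
}

.restat <- function(out, template) {
  attr(out, "trait_name") <- attr(template, "trait_name")
  class(out) <- class(template)
  out
}

#' Read a pairwise LD table
#'
#' @param path TSV/CSV with columns `snp_a`, `snp_b`, `r2`.
#' @return Data frame with those columns.
#' @export
read_ld_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  ld <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("snp_a", "snp_b", "r2")
  if (!all(need %in% names(ld))) {
    stop("LD table must have columns snp_a, snp_b, r2")
  }
  ld
}

#' Greedy LD clumping
#'
#' Selects approximately independent index SNPs by the standard greedy
#' procedure: records are ranked by ascending p-value (ties broken by
#' lexicographic `snp_id`); the most significant remaining SNP becomes an
#' index SNP, and every other remaining SNP on the same chromosome within
#' `window_kb` kilobases whose squared correlation with the index is at
#' least `r2_threshold` is removed. Repeats until exhausted. The result is
#' deterministic and independent of input row order.
#'
#' Linkage is an injected dependency: a pairwise table of r-squared values
#' (columns `snp_a`, `snp_b`, `r2`). Pairs within the window that are
#' absent from the table are an error by default; with `strict = FALSE`
#' they are assumed independent (r-squared 0) with a warning.
#'
#' @param records A `summary_stats` data frame carrying `chrom` and `pos`.
#' @param ld Pairwise r-squared data frame, a path readable by
#'   [read_ld_table()], or `NULL` (empty table; requires `strict = FALSE`
#'   unless no two SNPs share a window).
#' @param r2_threshold Independence threshold in (0, 1]; default 0.001.
#' @param window_kb Clumping window in kilobases; default 10000.
#' @param strict Error on LD pairs missing from the table (default) rather
#'   than assuming r-squared 0.
#' @return The clumped `summary_stats` data frame, index SNPs in selection
#'   order (ascending p).
#' @export
ld_clump <- function(records, ld = NULL, r2_threshold = 0.001,
                     window_kb = 10000, strict = TRUE) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1, window_kb > 0)
  if (nrow(records) <= 1L) return(records)
  if (is.character(ld)) ld <- read_ld_table(ld)
  if (is.null(ld)) ld <- data.frame(snp_a = character(), snp_b = character(),
                                    r2 = numeric())
  if (any(is.na(records$chrom)) || any(is.na(records$pos))) {
    stop("ld_clump requires chrom and pos on every record")
  }
  ld_key <- c(paste(ld$snp_a, ld$snp_b, sep = "\r"),
              paste(ld$snp_b, ld$snp_a, sep = "\r"))
  ld_val <- c(ld$r2, ld$r2)

  ord <- order(records$pvalue, records$snp_id)
  rec <- records[ord, , drop = FALSE]
  remaining <- rep(TRUE, nrow(rec))
  picked <- integer(0)
  warned <- FALSE
  for (i in seq_len(nrow(rec))) {
    if (!remaining[i]) next
    picked <- c(picked, i)
    remaining[i] <- FALSE
    cand <- which(remaining &
                    rec$chrom == rec$chrom[i] &
                    abs(rec$pos - rec$pos[i]) <= window_kb * 1000)
    if (!length(cand)) next
    key <- paste(rec$snp_id[i], rec$snp_id[cand], sep = "\r")
    r2 <- ld_val[match(key, ld_key)]
    if (anyNA(r2)) {
      if (strict) {
        miss <- rec$snp_id[cand[is.na(r2)]][1]
        stop("LD table lacks r2 for pair within window: ",
             rec$snp_id[i], " / ", miss,
             " (use strict = FALSE to assume r2 = 0)")
      }
      if (!warned) {
        warning("LD pairs missing from table assumed independent (r2 = 0)")
        warned <- TRUE
      }
      r2[is.na(r2)] <- 0
    }
    remaining[cand[r2 >= r2_threshold]] <- FALSE
  }
  out <- rec[picked, , drop = FALSE]
  rownames(out) <- NULL
  .restat(out, records)
}

#' Per-SNP instrument strength: variance explained and F-statistic
#'
#' For each record computes the variance in the exposure explained by the
#' variant, R2 = 2 * EAF * (1 - EAF) * beta^2, and the F-statistic
#' F = R2 * (n - k - 1) / (k * (1 - R2)). Instruments with F at or below 10
#' are flagged weak (the conventional threshold is strict: F > 10 means
#' strong). Records without an allele frequency cannot be scored; they are
#' flagged `scorable = FALSE` rather than raising an error.
#'
#' @param records A `summary_stats` data frame.
#' @param n Sample size used when a record has no `n` of its own (e.g. the
#'   trait-level total). Must exceed `k + 1`.
#' @param k Number of instruments the F refers to; 1 for per-SNP F
#'   (default).
#' @return Data frame with columns `snp_id`, `r2`, `f`, `weak`, `scorable`.
#' @export
instrument_strength <- function(records, n = NULL, k = 1) {
  n_eff <- ifelse(!is.na(records$n), records$n,
                  if (is.null(n)) NA_real_ else n)
  if (anyNA(n_eff)) stop("sample size unavailable for some records; supply n")
  stopifnot(all(n_eff > k + 1), k >= 1)
  scorable <- !is.na(records$eaf) & records$eaf > 0 & records$eaf < 1
  r2 <- ifelse(scorable,
               2 * records$eaf * (1 - records$eaf) * records$beta^2,
               NA_real_)
  f <- r2 * (n_eff - k - 1) / (k * (1 - r2))
  data.frame(snp_id = records$snp_id, r2 = r2, f = f,
             weak = ifelse(scorable, f <= 10, NA),
             scorable = scorable, stringsAsFactors = FALSE)
}

#' Joint instrument strength over a set of SNPs
#'
#' Sums per-SNP variance explained and computes the joint F with k equal to
#' the number of scorable instruments.
#'
#' @inheritParams instrument_strength
#' @return List with `r2` (summed), `f`, `k`, and `n` used.
#' @export
joint_instrument_strength <- function(records, n = NULL) {
  per <- instrument_strength(records, n = n, k = 1)
  k <- sum(per$scorable)
  if (k == 0L) stop("no scorable instruments (allele frequencies missing)")
  n_eff <- ifelse(!is.na(records$n), records$n,
                  if (is.null(n)) NA_real_ else n)
  n_use <- min(n_eff, na.rm = TRUE)
  r2 <- sum(per$r2, na.rm = TRUE)
  list(r2 = r2, f = r2 * (n_use - k - 1) / (k * (1 - r2)), k = k, n = n_use)
}

#' Remove instruments on an exclusion list
#'
#' Drops records whose `snp_id` appears in the exclusion list (e.g. SNPs
#' associated with confounders per a PhenoScanner-style lookup), reporting
#' each removal with its reason. Exclusion ids not present in the records
#' trigger a warning and are otherwise ignored.
#'
#' @param records A `summary_stats` data frame.
#' @param exclusions Data frame with columns `snp_id` and `reason`, a path
#'   to a TSV with those columns, or `NULL`/empty for a no-op.
#' @return The filtered `summary_stats` data frame.
#' @export
apply_exclusion_list <- function(records, exclusions = NULL) {
  if (is.character(exclusions)) {
    exclusions <- utils::read.table(exclusions, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
  }
  if (is.null(exclusions) || nrow(exclusions) == 0L) return(records)
  if (!"reason" %in% names(exclusions)) exclusions$reason <- "unspecified"
  hit <- records$snp_id %in% exclusions$snp_id
  if (any(hit)) {
    dropped <- exclusions[match(records$snp_id[hit], exclusions$snp_id), ]
    message("excluded ", sum(hit), " instrument(s): ",
            paste(sprintf("%s (%s)", dropped$snp_id, dropped$reason),
                  collapse = "; "))
  }
  orphan <- setdiff(exclusions$snp_id, records$snp_id)
  if (length(orphan)) {
    warning("exclusion id(s) not present among instruments: ",
            paste(orphan, collapse = ", "))
  }
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  .restat(out, records)
}
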