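# Reading, validation and allele harmonization of GWAS summary statistics.

#' Canonical column names for GWAS summary-statistics tables
#'
#' The default mapping from canonical field names to column headers expected
#' in input files. Users override individual entries through the
#' `column_map` argument of [read_summary_stats()].
#'
#' @return Named character vector: canonical field -> default column header.
#' @export
canonical_columns <- function() {
  c(
    snp_id = "snp", chrom = "chr", pos = "pos",
    effect_allele = "ea", other_allele = "oa", eaf = "eaf",
    beta = "beta", se = "se", pvalue = "p",
    n = "n", n_cases = "n_cases", n_controls = "n_controls"
  )
}

.required_fields <- c("snp_id", "effect_allele", "other_allele",
                      "beta", "se", "pvalue")

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited summary-statistics table (delimiter
#' auto-detected from the header line), maps its columns onto the canonical
#' fields, upper-cases alleles, and validates every row against the field
#' invariants (single-base distinct alleles, `se > 0`, p-value in (0, 1],
#' allele frequency in [0, 1] when present). Rows failing validation are
#' counted and reported via a message, never silently dropped. When a SNP
#' identifier occurs more than once, the row with the lowest p-value is kept
#' and the duplicates are counted.
#'
#' @param path Path to a delimited text file with one header row.
#' @param column_map Named list/character vector overriding entries of
#'   [canonical_columns()], e.g. `list(snp_id = "rsid", pvalue = "P_VAL")`.
#' @param trait_name Name of the trait the statistics describe.
#' @return A `summary_stats` data frame with canonical columns `snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`, `n_cases`, `n_controls` (missing ones filled with `NA`),
#'   and attributes `trait_name`, `n_rejected`, `n_duplicates`.
#' @export
read_summary_stats <- function(path, column_map = list(), trait_name = "trait") {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  map <- canonical_columns()
  if (length(column_map)) {
    cm <- unlist(column_map)
    bad <- setdiff(names(cm), names(map))
    if (length(bad)) stop("unknown canonical field(s) in column_map: ",
                          paste(bad, collapse = ", "))
    map[names(cm)] <- cm
  }
  missing_req <- .required_fields[!map[.required_fields] %in% names(raw)]
  if (length(missing_req)) {
    stop("required column(s) missing from ", path, ": ",
         paste(sprintf("%s (mapped to '%s')", missing_req, map[missing_req]),
               collapse = ", "))
  }

  get_col <- function(field, as = identity) {
    col <- map[[field]]
    if (col %in% names(raw)) as(raw[[col]]) else rep(NA, nrow(raw))
  }
  out <- data.frame(
    snp_id        = as.character(get_col("snp_id")),
    chrom         = as.character(get_col("chrom")),
    pos           = suppressWarnings(as.integer(get_col("pos"))),
    effect_allele = toupper(as.character(get_col("effect_allele"))),
    other_allele  = toupper(as.character(get_col("other_allele"))),
    eaf           = suppressWarnings(as.numeric(get_col("eaf"))),
    beta          = suppressWarnings(as.numeric(get_col("beta"))),
    se            = suppressWarnings(as.numeric(get_col("se"))),
    pvalue        = suppressWarnings(as.numeric(get_col("pvalue"))),
    n             = suppressWarnings(as.numeric(get_col("n"))),
    n_cases       = suppressWarnings(as.numeric(get_col("n_cases"))),
    n_controls    = suppressWarnings(as.numeric(get_col("n_controls"))),
    stringsAsFactors = FALSE
  )

  bases <- c("A", "C", "G", "T")
  valid <- !is.na(out$snp_id) & nzchar(out$snp_id) &
    out$effect_allele %in% bases & out$other_allele %in% bases &
    out$effect_allele != out$other_allele &
    is.finite(out$beta) &
    is.finite(out$se) & out$se > 0 &
    is.finite(out$pvalue) & out$pvalue > 0 & out$pvalue <= 1 &
    (is.na(out$eaf) | (out$eaf >= 0 & out$eaf <= 1))
  n_rejected <- sum(!valid)
  if (n_rejected > 0) {
    message(n_rejected, " row(s) of ", path,
            " failed validation and were rejected")
  }
  out <- out[valid, , drop = FALSE]
  if (nrow(out) == 0L) stop("no parseable rows in ", path)

  # duplicate snp_id: keep the lowest-p row, count the rest
  out <- out[order(out$pvalue, out$snp_id), , drop = FALSE]
  dup <- duplicated(out$snp_id)
  n_duplicates <- sum(dup)
  if (n_duplicates > 0) {
    message(n_duplicates, " duplicate SNP id(s) in ", path,
            "; lowest-p rows kept")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out,
            trait_name = trait_name,
            n_rejected = n_rejected,
            n_duplicates = n_duplicates,
            class = c("summary_stats", "data.frame"))
}

#' Construct a summary-statistics table from vectors
#'
#' Convenience constructor used by the simulator and in tests; applies the
#' same invariants as [read_summary_stats()].
#'
#' @param snp_id,effect_allele,other_allele,beta,se,pvalue Required fields.
#' @param chrom,pos,eaf,n,n_cases,n_controls Optional fields.
#' @param trait_name Trait label stored as an attribute.
#' @return A `summary_stats` data frame.
#' @export
summary_stats <- function(snp_id, effect_allele, other_allele, beta, se,
                          pvalue, chrom = NA_character_, pos = NA_integer_,
                          eaf = NA_real_, n = NA_real_, n_cases = NA_real_,
                          n_controls = NA_real_, trait_name = "trait") {
  out <- data.frame(
    snp_id = as.character(snp_id), chrom = as.character(chrom),
    pos = as.integer(pos),
    effect_allele = toupper(effect_allele),
    other_allele = toupper(other_allele),
    eaf = as.numeric(eaf), beta = as.numeric(beta), se = as.numeric(se),
    pvalue = as.numeric(pvalue), n = as.numeric(n),
    n_cases = as.numeric(n_cases), n_controls = as.numeric(n_controls),
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$effect_allele != out$other_allele),
            all(out$se > 0), all(out$pvalue > 0 & out$pvalue <= 1),
            all(is.na(out$eaf) | (out$eaf >= 0 & out$eaf <= 1)))
  structure(out, trait_name = trait_name, n_rejected = 0L, n_duplicates = 0L,
            class = c("summary_stats", "data.frame"))
}

#' Write summary statistics to a tab-delimited file
#'
#' Writes the canonical columns under the default headers of
#' [canonical_columns()], so the file round-trips through
#' [read_summary_stats()].
#'
#' @param records A `summary_stats` data frame.
#' @param path Output path.
#' @param sep Field delimiter, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path, sep = "\t") {
  out <- as.data.frame(records)[, names(canonical_columns())]
  names(out) <- unname(canonical_columns())
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches SNPs present in both traits by identifier and expresses the
#' outcome association relative to the exposure's effect allele. Outcome
#' records whose alleles are swapped relative to the exposure have their
#' effect sign flipped and allele frequency complemented; allele pairs that
#' match only after strand complementing are aligned the same way.
#' Palindromic variants (A/T or C/G) cannot be resolved by allele labels:
#' they are aligned by allele-frequency concordance when both frequencies
#' are available and informative, and dropped as ambiguous when either
#' trait's minor-allele frequency lies within `palindrome_eaf_window` of
#' 0.5 (or when either frequency is missing). Every exposure SNP appears in
#' the result exactly once with an `action_taken` label.
#'
#' @param exposure,outcome `summary_stats` data frames (see
#'   [read_summary_stats()]).
#' @param palindrome_eaf_window Half-width of the ambiguity window around
#'   EAF 0.5 for palindromic SNPs; must lie in [0, 0.5). Default 0.08, i.e.
#'   palindromes with EAF in (0.42, 0.58) are dropped.
#' @param drop_palindromic_ambiguous Drop ambiguous palindromes (default
#'   `TRUE`). When `FALSE`, palindromic SNPs are aligned purely by allele
#'   labels, which assumes both studies report the same strand.
#' @return A `harmonized_set` data frame with one row per exposure SNP:
#'   `snp_id`, `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`, `se_out`,
#'   `eaf_out`, `palindromic`, `action_taken` (one of `kept`,
#'   `sign_flipped`, `dropped_palindromic`, `dropped_missing`,
#'   `dropped_incompatible`), plus `chrom`/`pos` carried from the exposure.
#'   Attributes `exposure_name` and `outcome_name` carry the trait labels.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08,
                      drop_palindromic_ambiguous = TRUE) {
  stopifnot(nrow(exposure) > 0, nrow(outcome) > 0,
            palindrome_eaf_window >= 0, palindrome_eaf_window < 0.5)
  oidx <- match(exposure$snp_id, outcome$snp_id)

  k <- nrow(exposure)
  action <- character(k)
  beta_out <- se_out <- eaf_out <- rep(NA_real_, k)
  palin <- .is_palindromic(exposure$effect_allele, exposure$other_allele)

  for (i in seq_len(k)) {
    j <- oidx[i]
    if (is.na(j)) { action[i] <- "dropped_missing"; next }
    ea_e <- exposure$effect_allele[i]; oa_e <- exposure$other_allele[i]
    ea_o <- outcome$effect_allele[j];  oa_o <- outcome$other_allele[j]
    b <- outcome$beta[j]; s <- outcome$se[j]; f <- outcome$eaf[j]

    if (palin[i]) {
      if (!.is_palindromic(ea_o, oa_o) ||
          !all(c(ea_o, oa_o) %in% c(ea_e, oa_e, .complement[[ea_e]],
                                    .complement[[oa_e]]))) {
        action[i] <- "dropped_incompatible"; next
      }
      # align labels first (for a palindrome the strand-complemented pair is
      # the label-swapped pair, so label alignment is sufficient here)
      if (ea_o == oa_e && oa_o == ea_e) { b <- -b; f <- 1 - f }
      if (drop_palindromic_ambiguous) {
        fe <- exposure$eaf[i]
        if (is.na(fe) || is.na(f)) { action[i] <- "dropped_palindromic"; next }
        if (min(fe, 1 - fe) > 0.5 - palindrome_eaf_window ||
            min(f, 1 - f) > 0.5 - palindrome_eaf_window) {
          action[i] <- "dropped_palindromic"; next
        }
        # frequency-discordant: the two studies report opposite strands
        if ((fe - 0.5) * (f - 0.5) < 0) { b <- -b; f <- 1 - f }
      }
    } else {
      if (ea_o == ea_e && oa_o == oa_e) {
        # aligned as-is
      } else if (ea_o == oa_e && oa_o == ea_e) {
        b <- -b; f <- 1 - f
      } else {
        ea_c <- .complement[[ea_o]]; oa_c <- .complement[[oa_o]]
        if (ea_c == ea_e && oa_c == oa_e) {
          # opposite strand, same orientation
        } else if (ea_c == oa_e && oa_c == ea_e) {
          b <- -b; f <- 1 - f
        } else {
          action[i] <- "dropped_incompatible"; next
        }
      }
    }
    beta_out[i] <- b; se_out[i] <- s; eaf_out[i] <- f
    action[i] <- if (isTRUE(all.equal(b, outcome$beta[j]))) "kept" else "sign_flipped"
  }

  res <- data.frame(
    snp_id = exposure$snp_id,
    chrom = exposure$chrom, pos = exposure$pos,
    beta_exp = exposure$beta, se_exp = exposure$se, eaf_exp = exposure$eaf,
    beta_out = beta_out, se_out = se_out, eaf_out = eaf_out,
    palindromic = palin, action_taken = action,
    stringsAsFactors = FALSE
  )
  if (!any(action %in% c("kept", "sign_flipped"))) {
    stop("no overlapping instruments between '",
         attr(exposure, "trait_name") %||% "exposure", "' and '",
         attr(outcome, "trait_name") %||% "outcome", "'")
  }
  rownames(res) <- NULL
  structure(res,
            exposure_name = attr(exposure, "trait_name") %||% "exposure",
            outcome_name = attr(outcome, "trait_name") %||% "outcome",
            class = c("harmonized_set", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kept records of a harmonized set
#'
#' @param hset A `harmonized_set`.
#' @return The rows with `action_taken` of `kept` or `sign_flipped`,
#'   attributes preserved.
#' @export
harmonized_kept <- function(hset) {
  out <- hset[hset$action_taken %in% c("kept", "sign_flipped"), , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$exposure_name <- attr(hset, "exposure_name")
  attributes(out)$outcome_name <- attr(hset, "outcome_name")
  class(out) <- class(hset)
  out
}

#' Write a harmonized set as TSV
#'
#' @param hset A `harmonized_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(hset, path) {
  utils::write.table(as.data.frame(hset), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
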