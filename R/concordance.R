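# Truth-vs-query genotype concordance and non-reference concordance (NRC).
#
# Mismatches are keyed on the TRUTH sample's genotype class: e_ra counts
# truth-heterozygous sites where the query disagrees, whatever the query
# class is. NRC deliberately omits hom-ref matches (m_rr) so that the score
# is not inflated by the abundant trivially-concordant hom-ref sites.

#' Build a concordance table from counts
#'
#' Low-level constructor for the per-class match/mismatch table; normally
#' produced by [genotype_concordance()], but exposed so NRC can be evaluated
#' on externally tabulated counts.
#'
#' @param e_rr,e_ra,e_aa Mismatch counts at truth hom-ref / het / hom-alt
#'   sites.
#' @param m_rr,m_ra,m_aa Match counts at truth hom-ref / het / hom-alt
#'   sites.
#' @param transition_matrix Optional 4x4 truth-class by query-class count
#'   matrix over `HOM_REF`, `HET`, `HOM_ALT`, `MISSING`.
#' @param excluded Named or unnamed count(s) of sites excluded from the
#'   match/mismatch tallies.
#' @param n_compared Number of sites entering the e/m counts; derived from
#'   the counts when omitted.
#' @return An object of class `concordance_table`.
#' @export
concordance_table <- function(e_rr = 0, e_ra = 0, e_aa = 0,
                              m_rr = 0, m_ra = 0, m_aa = 0,
                              transition_matrix = NULL, excluded = 0,
                              n_compared = NULL) {
  counts <- c(e_rr = e_rr, e_ra = e_ra, e_aa = e_aa,
              m_rr = m_rr, m_ra = m_ra, m_aa = m_aa)
  if (any(counts < 0)) stop("concordance counts must be nonnegative")
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(
      0, 4L, 4L, dimnames = list(truth = GT_CLASSES[1:4],
                                 query = GT_CLASSES[1:4]))
  }
  structure(list(
    e_rr = e_rr, e_ra = e_ra, e_aa = e_aa,
    m_rr = m_rr, m_ra = m_ra, m_aa = m_aa,
    transition_matrix = transition_matrix,
    excluded = excluded,
    n_compared = if (is.null(n_compared)) sum(counts) else n_compared
  ), class = "concordance_table")
}

#' Per-class genotype concordance between a truth and a query VCF
#'
#' Compares one sample's genotypes between two VCFs over the sites present
#' in both (matched exactly on chromosome, position, REF and ALT), optionally
#' restricted to the sites of a third VCF. Each compared site is classified
#' by the truth genotype: `e_rr`/`e_ra`/`e_aa` count mismatches at truth
#' hom-ref/het/hom-alt sites and `m_rr`/`m_ra`/`m_aa` the matches. The full
#' 4x4 truth-by-query transition matrix (including `MISSING`) is always
#' tabulated.
#'
#' Sites where either call is `OTHER`, or whose REF/ALT disagree between the
#' files, are excluded and counted. By default sites where either sample is
#' `MISSING` are also excluded from the e/m counts (they still appear in the
#' transition matrix); with `missing_as_mismatch = TRUE` a missing query call
#' at a truth-called site counts as a mismatch of the truth class.
#'
#' @param truth,query Paths to the truth and query VCFs, or `vcf` objects.
#' @param sample Sample ID present in both files.
#' @param sites Optional path to (or `vcf` object of) a site-restriction
#'   VCF; only positions present there are compared.
#' @param missing_as_mismatch Count query-missing calls as mismatches
#'   instead of excluding them.
#' @return A [concordance_table()] with the six e/m counts, the transition
#'   matrix, and a named `excluded` breakdown.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(config = cohort_config(n_sites = 300, seed = 2))
#' truth <- file.path(tempdir(), "truth.vcf")
#' query <- file.path(tempdir(), "query.vcf")
#' write_cohort_vcf(cohort, truth)
#' inject_errors(truth, "focal", error_spec(p_rarr = 0.1), query, seed = 3)
#' tab <- genotype_concordance(truth, query, "focal")
#' tab
#' nrc(tab)
#' }
#' @export
genotype_concordance <- function(truth, query, sample, sites = NULL,
                                 missing_as_mismatch = FALSE) {
  tv <- if (inherits(truth, "vcf")) truth else read_vcf(truth)
  qv <- if (inherits(query, "vcf")) query else read_vcf(query)
  locate_sample(tv, sample)
  locate_sample(qv, sample)

  t_key <- paste(tv$fixed[, "CHROM"], tv$fixed[, "POS"], sep = ":")
  q_key <- paste(qv$fixed[, "CHROM"], qv$fixed[, "POS"], sep = ":")
  if (anyDuplicated(t_key) || anyDuplicated(q_key))
    stop("duplicate (chrom, pos) records are not supported; first offender: ",
         c(t_key[duplicated(t_key)], q_key[duplicated(q_key)])[1L])

  qi <- match(t_key, q_key)
  keep <- !is.na(qi)
  if (!is.null(sites)) {
    sv <- if (inherits(sites, "vcf")) sites else read_vcf(sites)
    s_key <- paste(sv$fixed[, "CHROM"], sv$fixed[, "POS"], sep = ":")
    keep <- keep & t_key %in% s_key
  }
  ti <- which(keep)
  qi <- qi[keep]

  allele_ok <- tv$fixed[ti, "REF"] == qv$fixed[qi, "REF"] &
    tv$fixed[ti, "ALT"] == qv$fixed[qi, "ALT"]
  n_allele_mismatch <- sum(!allele_ok)
  ti <- ti[allele_ok]
  qi <- qi[allele_ok]

  tk <- .classify_int(gt_strings(tv, sample))[ti]
  qk <- .classify_int(gt_strings(qv, sample))[qi]

  other <- tk == .OTHER | qk == .OTHER
  n_other <- sum(other)
  tk <- tk[!other]
  qk <- qk[!other]

  tm <- matrix(tabulate(tk + 4L * (qk - 1L), nbins = 16L), 4L, 4L,
               dimnames = list(truth = GT_CLASSES[1:4],
                               query = GT_CLASSES[1:4]))

  if (missing_as_mismatch) {
    scored <- tk <= 3L & qk <= 3L | (tk <= 3L & qk == .MISSING)
    n_missing_excl <- sum(!scored)          # truth-missing sites only
  } else {
    scored <- tk <= 3L & qk <= 3L
    n_missing_excl <- sum(!scored)
  }
  ts <- tk[scored]
  qs <- qk[scored]
  mism <- ts != qs
  e <- tabulate(ts[mism], nbins = 3L)
  m <- tabulate(ts[!mism], nbins = 3L)

  concordance_table(
    e_rr = e[1L], e_ra = e[2L], e_aa = e[3L],
    m_rr = m[1L], m_ra = m[2L], m_aa = m[3L],
    transition_matrix = tm,
    excluded = c(other_class = n_other,
                 allele_mismatch = n_allele_mismatch,
                 missing = n_missing_excl),
    n_compared = length(ts)
  )
}

#' Non-reference concordance
#'
#' Computes `NRC = 1 - (e_rr + e_ra + e_aa) / (e_rr + e_ra + e_aa + m_ra +
#' m_aa)`. The hom-ref match count `m_rr` is deliberately omitted: in typical
#' cohorts most sites are concordant hom-ref calls, and including them would
#' mask genotyping error at the informative (non-reference) genotypes.
#'
#' @param table A [concordance_table()].
#' @return NRC in \[0, 1\]; 1 exactly when there are no mismatches.
#'   Errors when `e_rr + e_ra + e_aa + m_ra + m_aa` is zero (no
#'   non-reference information to score).
#' @examples
#' nrc(concordance_table(e_ra = 1, m_ra = 9))  # 0.9
#' @export
nrc <- function(table) {
  stopifnot(inherits(table, "concordance_table"))
  err <- table$e_rr + table$e_ra + table$e_aa
  denom <- err + table$m_ra + table$m_aa
  if (denom <= 0)
    stop("NRC is undefined: no mismatches and no non-reference matches")
  1 - err / denom
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Genotype concordance (", x$n_compared, " sites scored)\n", sep = "")
  cat(sprintf("  truth class   mismatch  match\n"))
  cat(sprintf("  HOM_REF  %12d %6d\n", x$e_rr, x$m_rr))
  cat(sprintf("  HET      %12d %6d\n", x$e_ra, x$m_ra))
  cat(sprintf("  HOM_ALT  %12d %6d\n", x$e_aa, x$m_aa))
  if (any(x$excluded > 0))
    cat("  excluded: ",
        paste(sprintf("%s=%d", names(x$excluded), x$excluded),
              collapse = "  "), "\n", sep = "")
  cat("  transition matrix (truth rows x query columns):\n")
  print(x$transition_matrix)
  nrc_val <- tryCatch(nrc(x), error = function(e) NA_real_)
  if (!is.na(nrc_val)) cat(sprintf("  NRC = %.6f\n", nrc_val))
  else cat("  NRC undefined (no non-reference information)\n")
  invisible(x)
}

## Tab-separated serialisation used by the CLI.
.concordance_tsv <- function(x) {
  tm <- x$transition_matrix
  cells <- as.vector(t(tm))
  names(cells) <- paste0("n_", rep(rownames(tm), each = 4L), "_",
                         rep(colnames(tm), times = 4L))
  nrc_val <- tryCatch(nrc(x), error = function(e) NA_real_)
  c(paste(c("e_rr", "e_ra", "e_aa", "m_rr", "m_ra", "m_aa"),
          c(x$e_rr, x$e_ra, x$e_aa, x$m_rr, x$m_ra, x$m_aa), sep = "\t"),
    paste(names(cells), cells, sep = "\t"),
    paste(paste0("excluded_", names(x$excluded)), x$excluded, sep = "\t"),
    paste("nrc", format(nrc_val, digits = 10), sep = "\t"))
}
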