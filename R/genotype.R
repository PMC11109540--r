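# Genotype class machinery shared by every module.
#
# Internal coding: 1 = HOM_REF, 2 = HET, 3 = HOM_ALT, 4 = MISSING, 5 = OTHER.
# Only the first three classes are eligible for error injection; MISSING is a
# sink (no "resurrection" modes) and OTHER (half-calls, allele index > 1,
# ploidy != 2) always passes through untouched.

GT_CLASSES <- c("HOM_REF", "HET", "HOM_ALT", "MISSING", "OTHER")

.HOM_REF <- 1L
.HET     <- 2L
.HOM_ALT <- 3L
.MISSING <- 4L
.OTHER   <- 5L

# Canonical unphased GT string emitted for rewritten genotypes.
.CANONICAL_GT <- c("0/0", "0/1", "1/1", "./.")

# Exhaustive lookup for the diploid biallelic states (both phasings).
.GT_LOOKUP <- c(
  "0/0" = 1L, "0|0" = 1L,
  "0/1" = 2L, "1/0" = 2L, "0|1" = 2L, "1|0" = 2L,
  "1/1" = 3L, "1|1" = 3L,
  "./." = 4L, ".|." = 4L
)

## Integer classification of GT strings; vectorised hot path.
.classify_int <- function(gt) {
  k <- unname(.GT_LOOKUP[gt])
  k[is.na(k)] <- .OTHER
  k
}

.as_class_int <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    k <- match(x, GT_CLASSES)
    if (anyNA(k)) {
      # fall back to interpreting the input as GT strings
      k <- .classify_int(x)
    }
    return(k)
  }
  if (is.numeric(x)) {
    k <- as.integer(x)
    if (any(k < 1L | k > 5L, na.rm = TRUE))
      stop("genotype class codes must be in 1..5")
    return(k)
  }
  stop("cannot interpret input as genotype classes")
}

.class_factor <- function(k) factor(GT_CLASSES[k], levels = GT_CLASSES)

#' Classify diploid genotype strings
#'
#' Maps VCF GT strings onto the five genotype classes used throughout the
#' package. `0/0` (either phasing) is `HOM_REF`; `0/1` and `1/0` are both
#' `HET`; `1/1` is `HOM_ALT`; `./.` is `MISSING`. Anything else -- half-calls
#' such as `./1`, allele indices above 1, haploid or polyploid calls -- is
#' `OTHER` and is never touched by the error model.
#'
#' @param gt Character vector of GT strings (the first colon-separated
#'   subfield of a VCF sample field).
#' @return A factor with levels `HOM_REF`, `HET`, `HOM_ALT`, `MISSING`,
#'   `OTHER`, one element per input string.
#' @examples
#' classify_gt(c("0/1", "1|0", "1/1", "./.", "./1", "0/2"))
#' @export
classify_gt <- function(gt) {
  stopifnot(is.character(gt))
  .class_factor(.classify_int(gt))
}

#' Parse diploid genotype strings into allele calls
#'
#' Decomposes GT strings into allele indices, phase flag and genotype class.
#' Non-diploid strings yield `NA` alleles and class `OTHER`.
#'
#' @param gt Character vector of GT strings.
#' @return A data frame with columns `allele_a`, `allele_b` (integer allele
#'   index, `NA` for a missing allele), `phased` (logical; `NA` when the
#'   string is not a two-allele call) and `klass` (factor as in
#'   [classify_gt()]).
#' @examples
#' parse_gt(c("1|0", "./.", "0/2", "1"))
#' @export
parse_gt <- function(gt) {
  stopifnot(is.character(gt))
  m <- regmatches(gt, regexec("^(\\.|[0-9]+)([/|])(\\.|[0-9]+)$", gt))
  ok <- lengths(m) == 4L
  a <- b <- rep(NA_integer_, length(gt))
  phased <- rep(NA, length(gt))
  if (any(ok)) {
    pieces <- matrix(unlist(m[ok]), nrow = 4L)
    a[ok] <- suppressWarnings(as.integer(pieces[2L, ]))
    b[ok] <- suppressWarnings(as.integer(pieces[4L, ]))
    phased[ok] <- pieces[3L, ] == "|"
  }
  data.frame(
    allele_a = a, allele_b = b, phased = phased,
    klass = classify_gt(gt)
  )
}
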