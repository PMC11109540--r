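# The nine-mode error/missingness model.
#
# A mode name encodes source -> target genotype class: the first two letters
# are the source (ra = het, rr = hom-ref, aa = hom-alt), the last two the
# target (rr = hom-ref, ra = het, aa = hom-alt, mm = missing). Each source
# class has exactly three modes; together with the stay-unchanged outcome
# they form one categorical distribution per class.

#' Names of the nine error/missingness modes
#'
#' Exported constant listing the mode names in canonical order; see
#' [error_spec()] for the naming scheme.
#'
#' @format A character vector of length 9.
#' @export
ERROR_MODES <- c(
  "rarr", "raaa", "ramm",   # HET     -> HOM_REF / HOM_ALT / MISSING
  "rrra", "rraa", "rrmm",   # HOM_REF -> HET / HOM_ALT / MISSING
  "aara", "aarr", "aamm"    # HOM_ALT -> HET / HOM_REF / MISSING
)

# Mode index layout per source class (rows: HOM_REF, HET, HOM_ALT).
# .CLASS_MODE_IDX[cls, j] = index into ERROR_MODES of that class's j-th mode;
# .CLASS_TARGET[cls, j]   = target class code of that mode.
.CLASS_MODE_IDX <- rbind(
  HOM_REF = c(4L, 5L, 6L),
  HET     = c(1L, 2L, 3L),
  HOM_ALT = c(7L, 8L, 9L)
)
.CLASS_TARGET <- rbind(
  HOM_REF = c(.HET, .HOM_ALT, .MISSING),
  HET     = c(.HOM_REF, .HOM_ALT, .MISSING),
  HOM_ALT = c(.HET, .HOM_REF, .MISSING)
)

#' Specify per-mode genotype error probabilities
#'
#' Builds and validates the nine-probability error/missingness specification.
#' Mode names encode the transition: the first two letters give the source
#' genotype (`ra` = heterozygous, `rr` = homozygous reference, `aa` =
#' homozygous alternate) and the last two the erroneous result (`rr`, `ra`,
#' `aa`, or `mm` = missing). For example `p_rarr` is the probability that a
#' heterozygous call drops out to homozygous reference, and `p_aamm` the
#' probability that a homozygous-alternate call becomes missing.
#'
#' Unspecified probabilities default to 0. Each probability must lie in
#' \[0, 1\] and the three probabilities sharing a source class must sum to at
#' most 1; the remainder is the probability that the genotype is left
#' unchanged.
#'
#' @param p_rarr,p_raaa,p_ramm Probabilities applied to heterozygous calls
#'   (to hom-ref, hom-alt, missing).
#' @param p_rrra,p_rraa,p_rrmm Probabilities applied to homozygous-reference
#'   calls (to het, hom-alt, missing).
#' @param p_aara,p_aarr,p_aamm Probabilities applied to homozygous-alternate
#'   calls (to het, hom-ref, missing).
#' @return A named numeric vector of length 9 with class `error_spec`.
#' @examples
#' error_spec(p_rarr = 0.05, p_raaa = 0.01)
#' @seealso [transition_for()], [inject_errors()]
#' @export
error_spec <- function(p_rarr = 0, p_raaa = 0, p_ramm = 0,
                       p_rrra = 0, p_rraa = 0, p_rrmm = 0,
                       p_aara = 0, p_aarr = 0, p_aamm = 0) {
  p <- c(rarr = p_rarr, raaa = p_raaa, ramm = p_ramm,
         rrra = p_rrra, rraa = p_rraa, rrmm = p_rrmm,
         aara = p_aara, aarr = p_aarr, aamm = p_aamm)
  validate_error_spec(structure(as.numeric(p), names = names(p),
                                class = "error_spec"))
}

#' Validate an error specification
#'
#' Checks that every probability lies in \[0, 1\] and that the probabilities
#' sharing a source genotype class sum to at most 1. Called by
#' [error_spec()]; exposed so that specs built programmatically can be
#' re-checked.
#'
#' @param spec An `error_spec`, or a named numeric vector using the nine mode
#'   names (missing modes default to 0).
#' @return The validated `error_spec` (invisibly unchanged).
#' @export
validate_error_spec <- function(spec) {
  if (!inherits(spec, "error_spec")) {
    if (!is.numeric(spec) || is.null(names(spec)))
      stop("'spec' must be an error_spec or a named numeric vector")
    bad <- setdiff(names(spec), ERROR_MODES)
    if (length(bad))
      stop("unknown error mode(s): ", paste(bad, collapse = ", "))
    full <- structure(numeric(9L), names = ERROR_MODES)
    full[names(spec)] <- spec
    spec <- structure(full, class = "error_spec")
  }
  p <- unclass(spec)
  bad <- which(!is.finite(p) | p < 0 | p > 1)
  if (length(bad))
    stop("probability --p_", names(p)[bad[1L]], "=", p[bad[1L]],
         " is outside [0, 1]")
  for (cls in rownames(.CLASS_MODE_IDX)) {
    idx <- .CLASS_MODE_IDX[cls, ]
    s <- sum(p[idx])
    if (s > 1 + 1e-12)
      stop(cls, " mode probabilities (",
           paste0("p_", names(p)[idx], collapse = " + "),
           ") sum to ", format(s), " > 1")
  }
  spec
}

#' Transition distribution for one genotype class
#'
#' Expands an error specification into the categorical distribution governing
#' one source genotype class: the three erroneous outcomes plus the
#' stay-unchanged outcome, whose probability is the complement of the mode
#' probabilities. Genotypes observed as `MISSING` or `OTHER` have no
#' transitions: they pass through the injector unchanged.
#'
#' @param spec A validated [error_spec()].
#' @param klass `"HOM_REF"`, `"HET"` or `"HOM_ALT"`.
#' @return A data frame with columns `target` (genotype class), `mode` (mode
#'   name, `NA` for the stay outcome) and `prob`; probabilities sum to 1.
#' @examples
#' transition_for(error_spec(p_rarr = 0.05, p_raaa = 0.01), "HET")
#' @export
transition_for <- function(spec, klass) {
  spec <- validate_error_spec(spec)
  if (!is.character(klass) || length(klass) != 1L ||
      !klass %in% rownames(.CLASS_MODE_IDX))
    stop("no transitions are defined for class '", paste(klass, collapse = ","),
         "'; only HOM_REF, HET and HOM_ALT genotypes are eligible")
  idx <- .CLASS_MODE_IDX[klass, ]
  p <- unclass(spec)[idx]
  data.frame(
    target = GT_CLASSES[c(.CLASS_TARGET[klass, ], match(klass, GT_CLASSES))],
    mode = c(ERROR_MODES[idx], NA_character_),
    prob = c(p, 1 - sum(p)),
    row.names = NULL
  )
}

#' @export
print.error_spec <- function(x, ...) {
  cat("Genotype error specification (probability per mode)\n")
  p <- unclass(x)
  for (cls in c("HET", "HOM_REF", "HOM_ALT")) {
    idx <- .CLASS_MODE_IDX[cls, ]
    cat(sprintf("  %-7s -> %s   (stay %.4g)\n", cls,
                paste(sprintf("%s=%.4g", names(p)[idx], p[idx]),
                      collapse = " "),
                1 - sum(p[idx])))
  }
  invisible(x)
}

## Vectorised single-draw mutation of genotype class codes.
##
## One uniform draw is consumed per eligible genotype, in input order, so a
## fixed RNG state fully determines the output. Returns the new class codes
## and, per element, the realized mode index into ERROR_MODES (0 = unchanged,
## including ineligible MISSING/OTHER input).
.mutate_classes <- function(k, spec) {
  p <- unclass(spec)
  mode <- integer(length(k))
  new <- k
  elig <- which(k <= 3L)
  if (length(elig)) {
    u <- stats::runif(length(elig))
    kc <- k[elig]
    p1 <- p[.CLASS_MODE_IDX[kc, 1L]]
    p2 <- p[.CLASS_MODE_IDX[kc, 2L]]
    p3 <- p[.CLASS_MODE_IDX[kc, 3L]]
    sel <- integer(length(elig))                 # 0 = stay
    sel[u < p1 + p2 + p3] <- 3L
    sel[u < p1 + p2] <- 2L
    sel[u < p1] <- 1L
    hit <- sel > 0L
    if (any(hit)) {
      ij <- cbind(kc[hit], sel[hit])
      new[elig[hit]] <- .CLASS_TARGET[ij]
      mode[elig[hit]] <- .CLASS_MODE_IDX[ij]
    }
  }
  list(klass = new, mode = mode)
}

#' Stochastically corrupt a single genotype call
#'
#' Applies the error model to one GT string with a single categorical draw
#' from the source class's transition distribution. `MISSING` and `OTHER`
#' calls are returned unchanged without consuming a draw. When the stay
#' outcome is drawn the input string is returned bit-identically (phase
#' separator included); a realized error is written as the canonical unphased
#' representative of the target class (`0/0`, `0/1`, `1/1` or `./.`).
#'
#' Uses R's global random number stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param gt A single GT string, e.g. `"0/1"`.
#' @param spec A validated [error_spec()].
#' @return A list with `gt` (the possibly rewritten string) and `mode` (the
#'   realized mode name, or `NA` if unchanged).
#' @examples
#' set.seed(1)
#' mutate_call("0/1", error_spec(p_rarr = 1))
#' @export
mutate_call <- function(gt, spec) {
  stopifnot(is.character(gt), length(gt) == 1L)
  spec <- validate_error_spec(spec)
  res <- .mutate_classes(.classify_int(gt), spec)
  list(
    gt = if (res$mode > 0L) .CANONICAL_GT[res$klass] else gt,
    mode = if (res$mode > 0L) ERROR_MODES[res$mode] else NA_character_
  )
}
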