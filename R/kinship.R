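# KING-robust pairwise kinship and the genotyping-error degradation sweep.
#
# The estimator is the between-family KING-robust kinship coefficient,
# computed from per-site genotype-class counts only:
#
#   phi = (n_het_het - 2 * n_opp_hom) / (2 * min(h_i, h_j))
#         + 1/2 - (h_i + h_j) / (4 * min(h_i, h_j))
#
# where h_i, h_j are the two samples' heterozygous-site counts over the
# jointly called sites, n_het_het the sites where both are heterozygous and
# n_opp_hom the opposite-homozygote sites. For a duplicated sample this
# reduces algebraically to exactly 0.5; degree-d relatives have expectation
# 2^-(d+1).

#' Shared genotype-class counts for a sample pair
#'
#' Tallies the per-site quantities consumed by the KING-robust estimator.
#' Sites where either sample is `MISSING` or `OTHER` are excluded from every
#' count.
#'
#' @param gi,gj Equal-length genotype-class vectors for the two samples:
#'   factors from [genotype_classes()], class labels, integer codes, or raw
#'   GT strings.
#' @return A `pair_counts` list: `n_het_het`, `n_opp_hom`, `n_het_i`,
#'   `n_het_j`, `n_compared`.
#' @export
pair_counts <- function(gi, gj) {
  ki <- .as_class_int(gi)
  kj <- .as_class_int(gj)
  if (length(ki) != length(kj))
    stop("genotype vectors differ in length (", length(ki), " vs ",
         length(kj), ")")
  ok <- ki <= 3L & kj <= 3L
  ki <- ki[ok]
  kj <- kj[ok]
  structure(list(
    n_het_het = sum(ki == .HET & kj == .HET),
    n_opp_hom = sum((ki == .HOM_REF & kj == .HOM_ALT) |
                    (ki == .HOM_ALT & kj == .HOM_REF)),
    n_het_i = sum(ki == .HET),
    n_het_j = sum(kj == .HET),
    n_compared = length(ki)
  ), class = "pair_counts")
}

#' KING-robust kinship coefficient
#'
#' @param counts A [pair_counts()] object.
#' @return The kinship estimate; negative values are expected for unrelated
#'   pairs. Errors when either sample has no heterozygous calls over the
#'   compared sites (the estimator is undefined).
#' @examples
#' # a duplicated sample is exactly 0.5
#' g <- c(1, 2, 2, 3, 2)
#' king_robust_phi(pair_counts(g, g))
#' @export
king_robust_phi <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  hmin <- min(counts$n_het_i, counts$n_het_j)
  if (hmin == 0L)
    stop("KING-robust kinship is undefined: a sample has no heterozygous ",
         "calls over the compared sites")
  (counts$n_het_het - 2 * counts$n_opp_hom) / (2 * hmin) +
    0.5 - (counts$n_het_i + counts$n_het_j) / (4 * hmin)
}

#' Relationship degree from a kinship coefficient
#'
#' The standard KING inference ranges: bin boundaries at `2^-(d + 3/2)`,
#' i.e. 0.3536 / 0.1768 / 0.0884 / 0.0442, the geometric midpoints between
#' the expected kinships `2^-(d+1)` of adjacent degrees.
#'
#' @param phi Numeric vector of kinship coefficients.
#' @return Character vector: `"0"` (duplicate/monozygotic), `"1"`, `"2"`,
#'   `"3"`, or `"UNRELATED"`.
#' @examples
#' classify_degree(c(0.5, 0.25, 0.125, 0.0625, 0))
#' @export
classify_degree <- function(phi) {
  cut_points <- 2^-c(1.5, 2.5, 3.5, 4.5)
  out <- rep("UNRELATED", length(phi))
  out[phi > cut_points[4L]] <- "3"
  out[phi > cut_points[3L]] <- "2"
  out[phi > cut_points[2L]] <- "1"
  out[phi > cut_points[1L]] <- "0"
  out
}

#' Kinship of every pair involving a focal sample
#'
#' @param classes Genotype-class matrix (sites x samples) or a `vcf`
#'   object / `hap_cohort`.
#' @param focal Focal sample ID.
#' @return A data frame with one row per other sample: `sample`, `phi`,
#'   `degree` (`NA` phi when the estimator is undefined for that pair).
#' @export
kinship_pairs <- function(classes, focal) {
  classes <- .class_matrix(classes)
  others <- setdiff(colnames(classes), focal)
  if (!focal %in% colnames(classes))
    stop("focal sample '", focal, "' not found")
  phi <- vapply(others, function(s) {
    tryCatch(king_robust_phi(pair_counts(classes[, focal], classes[, s])),
             error = function(e) NA_real_)
  }, numeric(1))
  data.frame(sample = others, phi = phi,
             degree = ifelse(is.na(phi), NA_character_, classify_degree(phi)),
             row.names = NULL)
}

## Coerce the accepted cohort representations to a class-code matrix.
.class_matrix <- function(x) {
  if (inherits(x, "hap_cohort")) return(cohort_classes(x))
  if (inherits(x, "vcf")) {
    g <- gt_strings(x)
    k <- .classify_int(g)
    dim(k) <- dim(g)
    colnames(k) <- x$samples
    return(k)
  }
  if (is.matrix(x)) {
    k <- .as_class_int(x)
    dim(k) <- dim(x)
    colnames(k) <- colnames(x)
    return(k)
  }
  stop("cannot interpret input as a genotype-class matrix")
}

#' Error-rate sweep of kinship degree-classification accuracy
#'
#' Reproduces the kinship-degradation experiment: for each error mode and
#' each rate on the grid, inject that single mode (all other modes held at
#' 0) into the focal sample of a clean cohort, re-estimate KING-robust
#' kinship for every pair involving the focal sample, classify relationship
#' degrees, and score accuracy against the pedigree truth. Every injection
#' starts from the clean cohort, never from a previously corrupted one. A
#' pair whose kinship is undefined after injection (focal left with no
#' heterozygous calls) is scored as misclassified.
#'
#' The guessing floor -- the accuracy of always predicting the most common
#' truth degree among the scored pairs -- is reported alongside as the
#' baseline any informative classifier must beat.
#'
#' @param cohort Path to the cohort VCF, a `vcf` object, or a `hap_cohort`.
#' @param focal Focal sample ID (the error-injected individual).
#' @param ped A [pedigree()] supplying truth degrees; only its members
#'   present in the cohort are scored.
#' @param modes Error modes to sweep (default all nine).
#' @param rate_grid Error rates; default 0 to 0.2 in steps of 0.01.
#' @param seed Optional integer seed for the single RNG stream driving all
#'   injections.
#' @return A data frame of class `king_sweep` with columns `mode`, `rate`,
#'   `accuracy`, `guessing_floor`; plot with [plot.king_sweep()].
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(config = cohort_config(n_sites = 5000, seed = 1))
#' sw <- run_sweep(cohort, "focal", build_benchmark_pedigree(),
#'                 modes = c("rraa", "rarr"), rate_grid = c(0, 0.1, 0.2),
#'                 seed = 1)
#' sw
#' }
#' @export
run_sweep <- function(cohort, focal, ped, modes = ERROR_MODES,
                      rate_grid = seq(0, 0.2, by = 0.01), seed = NULL) {
  if (is.character(cohort)) cohort <- read_vcf(cohort)
  classes <- .class_matrix(cohort)
  stopifnot(inherits(ped, "pedigree"))
  modes <- match.arg(modes, ERROR_MODES, several.ok = TRUE)
  if (any(rate_grid < 0 | rate_grid > 1)) stop("rates must lie in [0, 1]")
  if (!focal %in% colnames(classes))
    stop("focal sample '", focal, "' not found in cohort")
  deg <- pedigree_degrees(ped)
  if (!focal %in% rownames(deg))
    stop("focal sample '", focal, "' not found in pedigree")
  others <- intersect(setdiff(colnames(classes), focal), rownames(deg))
  if (!length(others)) stop("no pedigree members to score against")
  truth <- deg[focal, others]
  floor_acc <- max(table(truth)) / length(truth)

  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(rate = rate_grid, mode = modes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  acc <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    spec_args <- stats::setNames(list(grid$rate[r]),
                                 paste0("p_", grid$mode[r]))
    spec <- do.call(error_spec, spec_args)
    focal_k <- .mutate_classes(classes[, focal], spec)$klass
    pred <- vapply(others, function(s) {
      tryCatch(
        classify_degree(king_robust_phi(pair_counts(focal_k, classes[, s]))),
        error = function(e) NA_character_)
    }, character(1))
    acc[r] <- mean(!is.na(pred) & pred == truth)
  }
  structure(
    data.frame(mode = grid$mode, rate = grid$rate, accuracy = acc,
               guessing_floor = floor_acc),
    class = c("king_sweep", "data.frame"),
    focal = focal, n_pairs = length(truth),
    n_sites = nrow(classes)
  )
}

#' Plot a kinship degradation sweep
#'
#' One line per error mode: degree-classification accuracy against the
#' injected error rate, with the guessing floor drawn as a solid black line
#' at the bottom.
#'
#' @param x A `king_sweep` from [run_sweep()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.king_sweep <- function(x, ...) {
  modes <- unique(x$mode)
  rates <- sort(unique(x$rate))
  acc <- sapply(modes, function(m) {
    xi <- x[x$mode == m, ]
    xi$accuracy[match(rates, xi$rate)]
  })
  graphics::matplot(rates, acc, type = "l", lty = 1, lwd = 2,
                    col = seq_along(modes),
                    xlab = "error rate", ylab = "degree classification accuracy",
                    ylim = c(0, 1), ...)
  graphics::abline(h = x$guessing_floor[1L], col = "black", lwd = 2)
  graphics::legend("bottomleft", legend = c(modes, "guessing"),
                   col = c(seq_along(modes), "black"), lty = 1, lwd = 2,
                   cex = 0.8, bg = "white")
  invisible(x)
}

#' @export
print.king_sweep <- function(x, ...) {
  cat("Kinship degradation sweep: focal '", attr(x, "focal"), "', ",
      attr(x, "n_pairs"), " pairs, ", attr(x, "n_sites"), " sites\n",
      sep = "")
  print.data.frame(x)
  invisible(x)
}
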