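# Synthetic cohort generation: Hardy-Weinberg founders plus pedigree
# gene-dropping. Emulates the statistical structure of an array-masked
# pedigree cohort at desk scale: unlinked biallelic SNPs, founder genotypes
# drawn under HWE at a per-site allele frequency, offspring alleles
# transmitted by Mendelian segregation independently across sites. There is
# no recombination map and no LD -- the pairwise genotype-class counts that
# kinship estimation consumes do not depend on linkage.

#' Configuration for a synthetic SNP cohort
#'
#' @param n_sites Number of biallelic SNP sites.
#' @param maf_range Lower and upper bound of the per-site alternate allele
#'   frequency, drawn uniformly; the default (0.05, 0.5) avoids
#'   near-monomorphic sites.
#' @param seed Optional integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_sites = 50000L, maf_range = c(0.05, 0.5),
                          seed = NULL) {
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 1L) stop("n_sites must be >= 1")
  if (length(maf_range) != 2L || maf_range[1L] <= 0 ||
      maf_range[1L] > maf_range[2L] || maf_range[2L] > 0.5)
    stop("maf_range must satisfy 0 < low <= high <= 0.5")
  structure(list(n_sites = n_sites, maf_range = as.numeric(maf_range),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cohort_config")
}

## Internal haplotype container: h1/h2 are n_sites x n_individuals 0/1
## integer matrices (allele per haplotype), sites is the shared metadata.
.hap_cohort <- function(h1, h2, sites) {
  structure(list(h1 = h1, h2 = h2, sites = sites, ids = colnames(h1)),
            class = "hap_cohort")
}

#' Simulate unrelated founders under Hardy-Weinberg equilibrium
#'
#' Draws a per-site alternate allele frequency uniformly within
#' `config$maf_range`, then samples each founder's two haploid alleles
#' independently as Bernoulli(f) -- so alternate allele counts are
#' Binomial(2, f), the HWE genotype law. Sites are independent (unlinked).
#'
#' @param config A [cohort_config()].
#' @param n_founders Number of founder individuals (0 allowed).
#' @param ids Optional founder IDs; defaults to `F1..Fn`.
#' @return A `hap_cohort`: haplotype matrices `h1`, `h2` (sites x
#'   individuals) and a `sites` data frame (`chrom`, `pos`, `ref`, `alt`,
#'   `af`).
#' @export
simulate_founders <- function(config, n_founders,
                              ids = sprintf("F%d", seq_len(n_founders))) {
  stopifnot(inherits(config, "cohort_config"))
  n_founders <- as.integer(n_founders)
  if (is.na(n_founders) || n_founders < 0L) stop("n_founders must be >= 0")
  if (length(ids) != n_founders) stop("length(ids) must equal n_founders")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_sites
  af <- stats::runif(n, config$maf_range[1L], config$maf_range[2L])
  h1 <- matrix(stats::rbinom(n * n_founders, 1L, af), nrow = n,
               ncol = n_founders, dimnames = list(NULL, ids))
  h2 <- matrix(stats::rbinom(n * n_founders, 1L, af), nrow = n,
               ncol = n_founders, dimnames = list(NULL, ids))
  sites <- data.frame(chrom = "1", pos = seq_len(n), ref = "A", alt = "C",
                      af = af)
  .hap_cohort(h1, h2, sites)
}

#' Define a pedigree
#'
#' @param id Character vector of individual IDs.
#' @param father,mother Parent IDs aligned with `id`; `NA` for founders.
#'   Each individual has either both parents (in the pedigree) or neither.
#' @return A `pedigree`: a data frame of the members topologically ordered
#'   so parents precede offspring.
#' @export
pedigree <- function(id, father = NA_character_, mother = NA_character_) {
  id <- as.character(id)
  father <- rep_len(as.character(father), length(id))
  mother <- rep_len(as.character(mother), length(id))
  if (anyDuplicated(id)) stop("pedigree IDs must be unique")
  founder <- is.na(father) & is.na(mother)
  if (any(is.na(father) != is.na(mother)))
    stop("each individual needs both parents or neither: ",
         id[is.na(father) != is.na(mother)][1L])
  missing_parent <- setdiff(c(father[!founder], mother[!founder]), id)
  if (length(missing_parent))
    stop("parent(s) not in pedigree: ", paste(missing_parent, collapse = ", "))

  # Kahn topological sort; detects parent cycles.
  ped <- data.frame(id = id, father = father, mother = mother,
                    stringsAsFactors = FALSE)
  ordered <- character()
  placed <- founder
  names(placed) <- id
  while (any(!placed)) {
    ready <- !placed & (is.na(father) | placed[father]) &
      (is.na(mother) | placed[mother])
    if (!any(ready)) stop("pedigree parent references contain a cycle")
    ordered <- c(ordered, id[ready])
    placed[ready] <- TRUE
  }
  ped <- ped[match(c(id[founder], ordered), ped$id), , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(is.na(x$father))
  cat("Pedigree: ", nrow(x), " members (", founders, " founders)\n", sep = "")
  print.data.frame(x)
  invisible(x)
}

#' Kinship coefficients implied by a pedigree
#'
#' Standard recursive pedigree kinship: founders are mutually unrelated and
#' non-inbred; for an individual `i` with parents `(f, m)` and any `j` that
#' is not a descendant of `i`, `phi(i, j) = (phi(f, j) + phi(m, j)) / 2`, and
#' `phi(i, i) = (1 + phi(f, m)) / 2`.
#'
#' @param ped A [pedigree()].
#' @return A symmetric matrix of kinship coefficients; the self-kinship of a
#'   non-inbred individual is 0.5.
#' @export
pedigree_kinship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      K[i, i] <- 0.5
    } else {
      K[i, i] <- 0.5 * (1 + K[fa[i], mo[i]])
      if (i > 1L) {
        j <- seq_len(i - 1L)
        K[i, j] <- K[j, i] <- 0.5 * (K[fa[i], j] + K[mo[i], j])
      }
    }
  }
  K
}

#' True relationship degrees implied by a pedigree
#'
#' Converts pedigree kinship into relationship-degree labels: kinship
#' `2^-(d+1)` corresponds to degree `d` (0.5 self/duplicate, 0.25 first
#' degree, 0.125 second, 0.0625 third). Pairs with zero kinship, or related
#' more remotely than the third degree, are labelled `UNRELATED`.
#'
#' @param ped A [pedigree()].
#' @return A character matrix of labels in `{"0","1","2","3","UNRELATED"}`.
#' @export
pedigree_degrees <- function(ped) {
  K <- pedigree_kinship(ped)
  d <- round(-log2(2 * K))
  lab <- matrix("UNRELATED", nrow(K), ncol(K), dimnames = dimnames(K))
  lab[K > 0 & d <= 3] <- as.character(d[K > 0 & d <= 3])
  lab
}

#' Drop founder genotypes through a pedigree
#'
#' Mendelian gene-dropping: for every non-founder, each site's paternal
#' allele is drawn uniformly from the father's two alleles and the maternal
#' allele from the mother's, independently across sites (no linkage).
#' Individuals are filled in pedigree order, parents before offspring.
#'
#' @param ped A [pedigree()].
#' @param founders A `hap_cohort` from [simulate_founders()] whose columns
#'   cover every founder of `ped`.
#' @param seed Optional integer seed.
#' @return A `hap_cohort` over all pedigree members, columns in pedigree
#'   order.
#' @export
gene_drop <- function(ped, founders, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(founders, "hap_cohort"))
  founder_ids <- ped$id[is.na(ped$father)]
  absent <- setdiff(founder_ids, colnames(founders$h1))
  if (length(absent))
    stop("founder genotypes missing for: ", paste(absent, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(founders$h1)
  h1 <- h2 <- matrix(0L, n, nrow(ped), dimnames = list(NULL, ped$id))
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$father[i])) {
      h1[, i] <- founders$h1[, ped$id[i]]
      h2[, i] <- founders$h2[, ped$id[i]]
    } else {
      pat <- h1[, ped$father[i]]
      swap <- stats::runif(n) < 0.5
      pat[swap] <- h2[swap, ped$father[i]]
      mat <- h1[, ped$mother[i]]
      swap <- stats::runif(n) < 0.5
      mat[swap] <- h2[swap, ped$mother[i]]
      h1[, i] <- pat
      h2[, i] <- mat
    }
  }
  .hap_cohort(h1, h2, founders$sites)
}

#' Benchmark pedigree with relatives of degree 1-3
#'
#' A fixed 18-member, three-generation pedigree built around a focal
#' individual: parents and a full sibling (1st degree), paternal
#' grandparents, a paternal uncle and a paternal half-sibling (2nd degree),
#' two first cousins (3rd degree), and unrelated/married-in founders. Truth
#' degrees follow from [pedigree_degrees()].
#'
#' @return A [pedigree()]; the focal individual is `"focal"`.
#' @export
build_benchmark_pedigree <- function() {
  pedigree(
    id = c("gf", "gm", "mo", "au", "hm",           # founders
           paste0("u", 1:6),                       # unrelated founders
           "fa", "unc",                            # generation 2
           "focal", "sib", "half", "cuz1", "cuz2"),# generation 3
    father = c(rep(NA, 11),
               "gf", "gf",
               "fa", "fa", "fa", "unc", "unc"),
    mother = c(rep(NA, 11),
               "gm", "gm",
               "mo", "mo", "hm", "au", "au")
  )
}

#' Simulate a full cohort for a pedigree
#'
#' Convenience wrapper: simulates HWE founders for the pedigree's founders
#' (seeded by the config), then gene-drops through the pedigree on the same
#' RNG stream.
#'
#' @param ped A [pedigree()]; defaults to [build_benchmark_pedigree()].
#' @param config A [cohort_config()].
#' @return A `hap_cohort` over all pedigree members.
#' @export
simulate_cohort <- function(ped = build_benchmark_pedigree(),
                            config = cohort_config()) {
  founder_ids <- ped$id[is.na(ped$father)]
  founders <- simulate_founders(config, length(founder_ids), ids = founder_ids)
  gene_drop(ped, founders)
}

#' Genotype class codes of a simulated cohort
#'
#' @param cohort A `hap_cohort`.
#' @return An integer matrix (sites x individuals) of genotype class codes:
#'   1 = `HOM_REF`, 2 = `HET`, 3 = `HOM_ALT`.
#' @export
cohort_classes <- function(cohort) {
  stopifnot(inherits(cohort, "hap_cohort"))
  cohort$h1 + cohort$h2 + 1L
}

#' Write a simulated cohort as a VCF
#'
#' Emits a minimal GT-only VCF (unphased genotypes) that round-trips through
#' [read_vcf()] with identical genotype classes.
#'
#' @param cohort A `hap_cohort`.
#' @param path Destination (`.gz` for bgzipped output).
#' @param af_info Emit the simulated allele frequency as `INFO/AF`.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path, af_info = TRUE) {
  stopifnot(inherits(cohort, "hap_cohort"))
  s <- cohort$sites
  info <- if (af_info) sprintf("AF=%.6g", s$af) else rep(".", nrow(s))
  gt_cols <- lapply(seq_along(cohort$ids), function(j)
    paste0(cohort$h1[, j], "/", cohort$h2[, j]))
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=snperr-synthetic-cohort",
    "##contig=<ID=1>",
    if (af_info)
      '##INFO=<ID=AF,Number=A,Type=Float,Description="Simulated alternate allele frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", cohort$ids), collapse = "\t")
  body <- do.call(paste, c(
    list(s$chrom, s$pos, ".", s$ref, s$alt, ".", ".", info, "GT"),
    gt_cols, list(sep = "\t")))
  .write_vcf_lines(c(meta, header, if (length(body)) body), path)
  invisible(path)
}
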