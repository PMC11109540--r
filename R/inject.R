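# Core simulator: stream a VCF and stochastically rewrite the genotypes of
# one designated sample according to the error specification.
#
# The file is processed in chunks of lines through a single pass; memory use
# is bounded by the chunk size, not the file size, which is what makes
# whole-chromosome inputs practical. One uniform draw is consumed per
# eligible genotype in file order, so (input, spec, seed) fully determines
# the output.

#' Inject genotyping error into one sample of a VCF
#'
#' Streams `input` record by record and, for the designated sample only,
#' applies the nine-mode error model: each `HOM_REF`/`HET`/`HOM_ALT`
#' genotype triggers a single categorical draw over its class's erroneous
#' outcomes and the stay-unchanged complement (see [transition_for()]).
#' Realized errors are written as the canonical unphased genotype (`0/0`,
#' `0/1`, `1/1`, `./.`); everything else -- unchanged genotypes, all other
#' FORMAT subfields of the target sample, every other sample and every fixed
#' field -- is copied through byte-for-byte. `MISSING` and `OTHER` (half
#' calls, allele index > 1, non-diploid) genotypes always pass through.
#'
#' INFO annotations such as AC/AF are deliberately not recomputed after
#' mutation; the output's INFO fields are identical to the input's.
#'
#' @param input Path to the input VCF (plain or bgzipped).
#' @param sample Sample ID to corrupt, as spelled in the VCF header.
#' @param spec An [error_spec()]; the default all-zero spec makes the run an
#'   identity copy.
#' @param output Destination path (`.gz` for bgzipped output), or `NULL` to
#'   stream the VCF to standard output. On any error no partial output file
#'   is left behind.
#' @param seed Optional integer seed for the single RNG stream; identical
#'   `(input, spec, seed)` yield identical output files.
#' @param chunk_size Number of records held in memory at a time.
#' @return An `injection_report`: counts of sites scanned, eligible
#'   genotypes per source class, realized changes per mode, skipped
#'   `MISSING`/`OTHER` genotypes, and the seed used.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(config = cohort_config(n_sites = 200, seed = 7))
#' vcf <- file.path(tempdir(), "cohort.vcf")
#' write_cohort_vcf(cohort, vcf)
#' rep <- inject_errors(vcf, "focal", error_spec(p_rarr = 0.05, p_raaa = 0.01),
#'                      output = file.path(tempdir(), "cohort.err.vcf"),
#'                      seed = 1)
#' rep
#' }
#' @seealso [genotype_concordance()] to measure the injected error,
#'   [error_spec()] for the model.
#' @export
inject_errors <- function(input, sample, spec = error_spec(), output = NULL,
                          seed = NULL, chunk_size = 20000L) {
  spec <- validate_error_spec(spec)
  if (!is.character(input) || length(input) != 1L || !file.exists(input))
    stop("cannot read VCF: '", input, "' does not exist")
  con <- .vcf_connection(input)
  on.exit(close(con), add = TRUE)

  header <- character()
  pending <- character()
  repeat {
    l <- readLines(con, 1L)
    if (length(l) == 0L) break
    if (startsWith(l, "#")) header <- c(header, l) else { pending <- l; break }
  }
  if (length(header) == 0L || !startsWith(header[length(header)], "#CHROM"))
    stop("malformed VCF '", input, "': no #CHROM header line")
  cols <- strsplit(header[length(header)], "\t", fixed = TRUE)[[1L]]
  n_cols <- length(cols)
  if (n_cols < 10L)
    stop("'", input, "' carries no sample genotype columns")
  col_i <- 9L + locate_sample(cols[-seq_len(9L)], sample)

  to_stdout <- is.null(output)
  if (to_stdout) {
    out_con <- stdout()
    tmp <- NULL
  } else {
    tmp <- tempfile(fileext = ".vcf")
    out_con <- file(tmp, "wt")
    done <- FALSE
    on.exit({
      if (!done) {
        try(close(out_con), silent = TRUE)
        unlink(tmp)
      }
    }, add = TRUE)
  }
  writeLines(header, out_con)

  if (!is.null(seed)) set.seed(seed)

  sites <- 0L
  eligible <- c(HOM_REF = 0L, HET = 0L, HOM_ALT = 0L)
  changes <- structure(integer(9L), names = ERROR_MODES)
  passthrough <- 0L

  first <- TRUE
  repeat {
    fresh <- readLines(con, chunk_size)
    chunk <- if (first) c(pending, fresh) else fresh
    first <- FALSE
    if (length(chunk) == 0L) break
    m <- .parse_body_chunk(chunk, n_cols, offset = length(header) + sites)
    fld <- m[col_i, ]
    gt <- sub(":.*", "", fld)
    k <- .classify_int(gt)
    res <- .mutate_classes(k, spec)
    hit <- which(res$mode > 0L)
    if (length(hit)) {
      rest <- substring(fld[hit], nchar(gt[hit]) + 1L)
      m[col_i, hit] <- paste0(.CANONICAL_GT[res$klass[hit]], rest)
    }
    sites <- sites + length(chunk)
    tab <- tabulate(k, nbins = 5L)
    eligible <- eligible + tab[1:3]
    passthrough <- passthrough + tab[4L] + tab[5L]
    changes <- changes + tabulate(res$mode, nbins = 9L)
    writeLines(do.call(paste, c(asplit(m, 1L), list(sep = "\t"))), out_con)
    if (length(fresh) < chunk_size) break
  }

  if (!to_stdout) {
    close(out_con)
    if (grepl("\\.gz$", output)) {
      Rsamtools::bgzip(tmp, dest = output, overwrite = TRUE)
      unlink(tmp)
    } else {
      if (!suppressWarnings(file.rename(tmp, output))) {
        ok <- file.copy(tmp, output, overwrite = TRUE)
        unlink(tmp)
        if (!ok) stop("cannot write output VCF to '", output, "'")
      }
    }
    done <- TRUE
  }

  structure(list(
    input = input,
    output = if (to_stdout) NA_character_ else output,
    sample = sample,
    spec = spec,
    sites_scanned = sites,
    eligible_by_class = eligible,
    changes_by_mode = changes,
    passthrough_other = passthrough,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  ), class = "injection_report")
}

#' @export
print.injection_report <- function(x, ...) {
  cat("Genotype error injection: sample '", x$sample, "'\n", sep = "")
  cat("  sites scanned:      ", x$sites_scanned, "\n", sep = "")
  cat("  eligible genotypes: ",
      paste(sprintf("%s=%d", names(x$eligible_by_class), x$eligible_by_class),
            collapse = "  "), "\n", sep = "")
  cat("  passthrough (MISSING/OTHER): ", x$passthrough_other, "\n", sep = "")
  ch <- x$changes_by_mode[x$changes_by_mode > 0L]
  if (length(ch)) {
    cat("  realized changes:\n")
    for (i in seq_along(ch))
      cat(sprintf("    %s: %d\n", names(ch)[i], ch[i]))
  } else {
    cat("  realized changes: none\n")
  }
  if (!is.na(x$seed)) cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

## Tab-separated report serialisation used by the CLI.
.report_tsv <- function(report) {
  c(paste("sites_scanned", report$sites_scanned, sep = "\t"),
    paste(paste0("eligible_", names(report$eligible_by_class)),
          report$eligible_by_class, sep = "\t"),
    paste(paste0("changed_", names(report$changes_by_mode)),
          report$changes_by_mode, sep = "\t"),
    paste("passthrough_other", report$passthrough_other, sep = "\t"),
    paste("seed", report$seed, sep = "\t"))
}
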