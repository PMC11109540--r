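# In-memory and line-level VCF handling.
#
# The package only ever rewrites the GT subfield of one sample; everything
# else (ID, QUAL, FILTER, INFO, other FORMAT subfields, other samples) is an
# opaque payload that must round-trip byte-for-byte. Records are therefore
# kept as character matrices of raw fields, not decoded into typed columns.
# Coordinates are VCF-native 1-based throughout.
#
# Large files never go through read_vcf(): the injector streams (see
# inject.R) using the same chunk parser, .parse_body_chunk().

.VCF_FIXED <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")

.vcf_connection <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

## Split body lines into a fields-by-records matrix, validating field counts.
## `offset` = number of lines preceding the chunk (for error messages).
.parse_body_chunk <- function(lines, n_cols, offset = 0L) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != n_cols)) {
    bad <- which(nf != n_cols)[1L]
    stop("malformed VCF record at line ", offset + bad, ": expected ",
         n_cols, " tab-separated fields, found ", nf[bad])
  }
  matrix(unlist(parts, use.names = FALSE), nrow = n_cols)
}

#' Read a multi-sample VCF into memory
#'
#' Parses a plain or bgzipped VCF 4.x file into a lightweight container that
#' preserves every field verbatim, so that [write_vcf()] reproduces the input
#' exactly when nothing is mutated. Suited to the cohort sizes used for
#' concordance and kinship work; error injection on large files streams
#' through [inject_errors()] instead and never materialises the file.
#'
#' @param path Path to a VCF file (`.vcf` or `.vcf.gz`).
#' @return An object of class `vcf`: a list with `meta` (the `##` header
#'   lines), `samples` (sample names from the `#CHROM` line), `fixed`
#'   (character matrix of the 8 fixed columns, one row per record), `format`
#'   (FORMAT strings, or `NULL` if absent) and `sample_fields` (character
#'   matrix of raw per-sample fields, one column per sample).
#' @seealso [write_vcf()], [genotype_classes()], [locate_sample()]
#' @export
read_vcf <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read VCF: '", path, "' does not exist")
  con <- .vcf_connection(path)
  on.exit(close(con))
  lines <- readLines(con)
  is_hdr <- startsWith(lines, "#")
  n_hdr <- match(FALSE, is_hdr, nomatch = length(lines) + 1L) - 1L
  if (n_hdr == 0L || !startsWith(lines[n_hdr], "#CHROM"))
    stop("malformed VCF '", path, "': no #CHROM header line before the data")
  if (any(is_hdr[-seq_len(n_hdr)]))
    stop("malformed VCF '", path, "': header line found after data records")
  cols <- strsplit(lines[n_hdr], "\t", fixed = TRUE)[[1L]]
  n_cols <- length(cols)
  if (n_cols < 8L)
    stop("malformed VCF '", path, "': #CHROM line has fewer than 8 columns")
  samples <- if (n_cols > 9L) cols[-seq_len(9L)] else character()

  body <- lines[seq_len(length(lines) - n_hdr) + n_hdr]
  if (length(body)) {
    m <- .parse_body_chunk(body, n_cols, offset = n_hdr)
  } else {
    m <- matrix(character(), nrow = n_cols, ncol = 0L)
  }
  fixed <- t(m[seq_len(8L), , drop = FALSE])
  colnames(fixed) <- .VCF_FIXED
  sample_fields <- if (n_cols > 9L) {
    t(m[-seq_len(9L), , drop = FALSE])
  } else {
    matrix(character(), nrow = ncol(m), ncol = 0L)
  }
  colnames(sample_fields) <- samples
  structure(list(
    meta = lines[seq_len(max(n_hdr - 1L, 0L))],
    samples = samples,
    fixed = fixed,
    format = if (n_cols >= 9L) m[9L, ] else NULL,
    sample_fields = sample_fields
  ), class = "vcf")
}

#' Write a VCF object to disk
#'
#' Serialises a `vcf` object back to text. A path ending in `.gz` is written
#' BGZF-compressed (via [Rsamtools::bgzip()]), so the output is
#' tabix-indexable. Reading and writing with no mutation in between
#' reproduces the input records verbatim.
#'
#' @param x A `vcf` object from [read_vcf()].
#' @param path Destination path; `.gz` triggers bgzip compression.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "vcf"))
  header_cols <- c("#CHROM", .VCF_FIXED[-1L],
                   if (!is.null(x$format)) "FORMAT",
                   x$samples)
  body_cols <- c(
    lapply(seq_len(8L), function(j) x$fixed[, j]),
    if (!is.null(x$format)) list(x$format),
    lapply(seq_along(x$samples), function(j) x$sample_fields[, j])
  )
  body <- if (nrow(x$fixed)) {
    do.call(paste, c(body_cols, list(sep = "\t")))
  } else {
    character()
  }
  lines <- c(x$meta, paste(header_cols, collapse = "\t"), body)
  .write_vcf_lines(lines, path)
  invisible(path)
}

## Write text lines to `path`, bgzipping when the name ends in .gz.
.write_vcf_lines <- function(lines, path) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = ".vcf")
    on.exit(unlink(tmp))
    writeLines(lines, tmp)
    Rsamtools::bgzip(tmp, dest = path, overwrite = TRUE)
  } else {
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("cannot write VCF to '", path, "'")
  }
  path
}

#' Locate a sample column
#'
#' @param x A `vcf` object or a character vector of sample names.
#' @param sample Sample ID as it appears in the VCF header.
#' @return The 1-based index of the sample among the genotype columns.
#'   Errors if the sample is absent (listing the available IDs) or if the
#'   header carries duplicate sample names (the VCF spec requires
#'   uniqueness, so the reference is ambiguous).
#' @export
locate_sample <- function(x, sample) {
  samples <- if (inherits(x, "vcf")) x$samples else as.character(x)
  stopifnot(is.character(sample), length(sample) == 1L)
  idx <- which(samples == sample)
  if (length(idx) == 0L)
    stop("sample '", sample, "' not found; available samples: ",
         paste(samples, collapse = ", "))
  if (length(idx) > 1L)
    stop("sample '", sample, "' appears ", length(idx),
         " times in the header; sample IDs must be unique")
  idx
}

#' Extract GT strings for one or all samples
#'
#' Takes the first colon-separated subfield of each sample field; the VCF
#' specification requires GT to come first when present, which is checked
#' against the FORMAT column.
#'
#' @param x A `vcf` object.
#' @param sample Optional sample ID; if omitted, all samples.
#' @return A character vector (one sample) or matrix (all samples) of GT
#'   strings, one row per record.
#' @export
gt_strings <- function(x, sample = NULL) {
  stopifnot(inherits(x, "vcf"))
  if (!is.null(x$format) && length(x$format) &&
      !all(x$format == "GT" | startsWith(x$format, "GT:")))
    stop("FORMAT does not start with GT at record ",
         which(!(x$format == "GT" | startsWith(x$format, "GT:")))[1L])
  if (is.null(sample)) {
    out <- sub(":.*", "", x$sample_fields)
    dim(out) <- dim(x$sample_fields)
    colnames(out) <- x$samples
    return(out)
  }
  idx <- locate_sample(x, sample)
  sub(":.*", "", x$sample_fields[, idx])
}

#' Genotype classes for one sample
#'
#' @param x A `vcf` object.
#' @param sample Sample ID.
#' @return A factor of genotype classes (see [classify_gt()]), one per
#'   record.
#' @export
genotype_classes <- function(x, sample) {
  .class_factor(.classify_int(gt_strings(x, sample)))
}

#' @export
print.vcf <- function(x, ...) {
  cat("VCF: ", nrow(x$fixed), " records, ", length(x$samples), " sample",
      if (length(x$samples) != 1L) "s", "\n", sep = "")
  if (length(x$samples))
    cat("samples: ", paste(utils::head(x$samples, 8L), collapse = ", "),
        if (length(x$samples) > 8L) ", ...", "\n", sep = "")
  invisible(x)
}
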