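# Fixtures are built in code at test time; nothing binary ships with the
# package.

# Hand-written 3-site, 2-sample VCF exercising phased calls, an OTHER-class
# half call, extra FORMAT subfields and INFO annotations.
toy_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=20>",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele Frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB",
    "20\t100\trs1\tA\tG\t50\tPASS\tAF=0.2\tGT:DP\t1|0\t0/0",
    "20\t200\t.\tC\tT\t.\t.\tAF=0.5\tGT:DP\t0/1:12\t./1",
    "20\t300\trs3\tG\tA\t99\tPASS\tAF=0.1\tGT:DP\t1/1:7\t./.")
}

write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(toy_vcf_lines(), path)
  path
}

# Random multi-sample cohort VCF via the synthetic module.
write_random_vcf <- function(n_sites, n_samples, seed,
                             path = tempfile(fileext = ".vcf"),
                             maf_range = c(0.05, 0.5)) {
  f <- simulate_founders(cohort_config(n_sites = n_sites,
                                       maf_range = maf_range, seed = seed),
                         n_samples, ids = paste0("S", seq_len(n_samples)))
  write_cohort_vcf(f, path)
  path
}

# Random error spec with class sums capped below 1.
random_error_spec <- function() {
  p <- numeric(9)
  names(p) <- ERROR_MODES
  for (cls in list(1:3, 4:6, 7:9)) {
    raw <- stats::runif(3)
    p[cls] <- raw * stats::runif(1, 0, 0.9) / sum(raw)
  }
  do.call(error_spec, as.list(stats::setNames(p, paste0("p_", names(p)))))
}

# Read GT strings for one sample straight from file text, independently of
# the package's parsing (header-aware but deliberately simple-minded).
raw_gt_column <- function(path, sample) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  cols <- strsplit(hdr[length(hdr)], "\t", fixed = TRUE)[[1]]
  i <- which(cols == sample)
  body <- lines[!startsWith(lines, "#")]
  fields <- vapply(strsplit(body, "\t", fixed = TRUE), `[`, "", i)
  sub(":.*", "", fields)
}
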