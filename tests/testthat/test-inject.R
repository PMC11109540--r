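# The streaming injector: rate behaviour, non-target invariance,
# determinism, and report/output consistency.

test_that("the identity spec copies the file and counts nothing", {
  path <- write_random_vcf(400, 3, seed = 21)
  out <- tempfile(fileext = ".vcf")
  rep <- inject_errors(path, "S2", error_spec(), out, seed = 1)
  expect_identical(readLines(out), readLines(path))
  expect_equal(sum(rep$changes_by_mode), 0L)
  expect_equal(rep$sites_scanned, 400L)
})

test_that("certainty limits rewrite every eligible genotype canonically", {
  path <- write_random_vcf(300, 2, seed = 22)
  out <- tempfile(fileext = ".vcf")
  rep <- inject_errors(path, "S1", error_spec(p_ramm = 1), out, seed = 5)
  gt_in <- raw_gt_column(path, "S1")
  gt_out <- raw_gt_column(out, "S1")
  het <- classify_gt(gt_in) == "HET"
  expect_true(all(gt_out[het] == "./."))
  expect_true(all(gt_out[!het] == gt_in[!het]))
  expect_equal(unname(rep$changes_by_mode["ramm"]), sum(het))
})

test_that("non-target samples are byte identical across random runs (property)", {
  set.seed(303)
  for (i in 1:4) {
    path <- write_random_vcf(250, 4, seed = 300 + i)
    out <- tempfile(fileext = ".vcf")
    target <- sample(paste0("S", 1:4), 1)
    inject_errors(path, target, random_error_spec(), out,
                  seed = sample.int(10000, 1))
    x_in <- read_vcf(path)
    x_out <- read_vcf(out)
    others <- setdiff(x_in$samples, target)
    expect_identical(x_out$sample_fields[, others],
                     x_in$sample_fields[, others])
    expect_identical(x_out$fixed, x_in$fixed)
    expect_identical(x_out$format, x_in$format)
  }
})

test_that("output is deterministic under a fixed seed", {
  path <- write_random_vcf(500, 2, seed = 31)
  s <- error_spec(p_rarr = 0.2, p_rraa = 0.1, p_aamm = 0.3)
  o1 <- tempfile(fileext = ".vcf")
  o2 <- tempfile(fileext = ".vcf")
  o3 <- tempfile(fileext = ".vcf")
  inject_errors(path, "S1", s, o1, seed = 99)
  inject_errors(path, "S1", s, o2, seed = 99)
  inject_errors(path, "S1", s, o3, seed = 100)
  expect_identical(readLines(o1), readLines(o2))
  expect_false(identical(readLines(o1), readLines(o3)))
})

test_that("chunk boundaries do not change the draws", {
  path <- write_random_vcf(101, 2, seed = 32)
  s <- error_spec(p_rarr = 0.5, p_rrra = 0.5)
  o1 <- tempfile(fileext = ".vcf")
  o2 <- tempfile(fileext = ".vcf")
  inject_errors(path, "S1", s, o1, seed = 7, chunk_size = 10L)
  inject_errors(path, "S1", s, o2, seed = 7, chunk_size = 100000L)
  expect_identical(readLines(o1), readLines(o2))
})

test_that("the report reconciles exactly with an input/output genotype diff", {
  path <- write_random_vcf(2000, 3, seed = 41)
  out <- tempfile(fileext = ".vcf")
  s <- error_spec(p_rarr = 0.05, p_raaa = 0.02, p_ramm = 0.03,
                  p_rrra = 0.04, p_rraa = 0.01, p_rrmm = 0.02,
                  p_aara = 0.05, p_aarr = 0.02, p_aamm = 0.04)
  rep <- inject_errors(path, "S3", s, out, seed = 55)
  k_in <- as.integer(classify_gt(raw_gt_column(path, "S3")))
  k_out <- as.integer(classify_gt(raw_gt_column(out, "S3")))
  # re-derive per-mode counts from the genotype change alone
  src <- c(HOM_REF = 1L, HET = 2L, HOM_ALT = 3L)
  tgt <- c(rarr = 1L, raaa = 3L, ramm = 4L, rrra = 2L, rraa = 3L, rrmm = 4L,
           aara = 2L, aarr = 1L, aamm = 4L)
  src_of <- c(rarr = 2L, raaa = 2L, ramm = 2L, rrra = 1L, rraa = 1L,
              rrmm = 1L, aara = 3L, aarr = 3L, aamm = 3L)
  derived <- vapply(ERROR_MODES, function(m)
    sum(k_in == src_of[m] & k_out == tgt[m]), integer(1))
  expect_equal(derived, rep$changes_by_mode)
  # report invariants
  expect_equal(rep$sites_scanned,
               sum(rep$eligible_by_class) + rep$passthrough_other)
  expect_equal(unname(tabulate(k_in, 5)[1:3]), unname(rep$eligible_by_class))
})

test_that("rewritten genotypes are canonical unphased; untouched ones keep phase", {
  lines <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA",
             sprintf("1\t%d\t.\tA\tC\t.\t.\t.\tGT\t0|1", 1:50))
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  out <- tempfile(fileext = ".vcf")
  inject_errors(path, "A", error_spec(p_rarr = 0.5), out, seed = 3)
  gt <- raw_gt_column(out, "A")
  expect_true(all(gt %in% c("0|1", "0/0")))
  expect_true(any(gt == "0|1") && any(gt == "0/0"))
})

test_that("other FORMAT subfields of the target sample are preserved", {
  path <- write_toy_vcf()
  out <- tempfile(fileext = ".vcf")
  inject_errors(path, "A", error_spec(p_rarr = 1, p_aamm = 1), out, seed = 2)
  fields <- read_vcf(out)$sample_fields[, "A"]
  expect_equal(fields, c("0/0", "0/0:12", "./.:7"))
})

test_that("with no output path the VCF streams to standard output", {
  path <- write_random_vcf(20, 2, seed = 61)
  streamed <- capture.output(rep <- inject_errors(path, "S1", error_spec(),
                                                  seed = 1))
  expect_identical(streamed, readLines(path))
  expect_true(is.na(rep$output))
})

test_that("fatal errors leave no partial output file", {
  path <- write_random_vcf(20, 2, seed = 62)
  out <- tempfile(fileext = ".vcf")
  expect_error(inject_errors(path, "nope", error_spec(), out), "not found")
  expect_false(file.exists(out))
  expect_error(inject_errors(path, "S1", c(rarr = 2), out), "outside")
  expect_false(file.exists(out))
})

test_that("bgzipped input and output work end to end", {
  plain <- write_random_vcf(200, 2, seed = 63)
  gz_in <- tempfile(fileext = ".vcf.gz")
  write_vcf(read_vcf(plain), gz_in)
  gz_out <- tempfile(fileext = ".vcf.gz")
  rep <- inject_errors(gz_in, "S2", error_spec(p_rraa = 0.5), gz_out, seed = 8)
  expect_identical(readBin(gz_out, "raw", 2L), as.raw(c(0x1f, 0x8b)))
  x <- read_vcf(gz_out)
  expect_equal(nrow(x$fixed), 200L)
  expect_gt(rep$changes_by_mode["rraa"], 0L)
})
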