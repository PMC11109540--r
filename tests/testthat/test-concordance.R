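# Concordance tallies and non-reference concordance.

test_that("a file compared against itself is perfectly concordant", {
  path <- write_random_vcf(500, 3, seed = 70)
  tab <- genotype_concordance(path, path, "S2")
  expect_equal(tab$e_rr + tab$e_ra + tab$e_aa, 0L)
  k <- table(genotype_classes(read_vcf(path), "S2"))
  expect_equal(tab$m_rr, unname(k[["HOM_REF"]]))
  expect_equal(tab$m_ra, unname(k[["HET"]]))
  expect_equal(tab$m_aa, unname(k[["HOM_ALT"]]))
  expect_equal(nrc(tab), 1)
  expect_true(all(tab$transition_matrix ==
                    diag(diag(tab$transition_matrix))))
})

test_that("the transition matrix reproduces the injector's ledger (closure)", {
  path <- write_random_vcf(5000, 2, seed = 71)
  out <- tempfile(fileext = ".vcf")
  s <- error_spec(p_rarr = 0.05, p_raaa = 0.05, p_ramm = 0.05,
                  p_rrra = 0.05, p_rraa = 0.05, p_rrmm = 0.05,
                  p_aara = 0.05, p_aarr = 0.05, p_aamm = 0.05)
  rep <- inject_errors(path, "S1", s, out, seed = 72)
  tab <- genotype_concordance(path, out, "S1")
  tm <- tab$transition_matrix
  expect_equal(tm["HET", "HOM_REF"], unname(rep$changes_by_mode["rarr"]))
  expect_equal(tm["HET", "HOM_ALT"], unname(rep$changes_by_mode["raaa"]))
  expect_equal(tm["HET", "MISSING"], unname(rep$changes_by_mode["ramm"]))
  expect_equal(tm["HOM_REF", "HET"], unname(rep$changes_by_mode["rrra"]))
  expect_equal(tm["HOM_REF", "HOM_ALT"], unname(rep$changes_by_mode["rraa"]))
  expect_equal(tm["HOM_REF", "MISSING"], unname(rep$changes_by_mode["rrmm"]))
  expect_equal(tm["HOM_ALT", "HET"], unname(rep$changes_by_mode["aara"]))
  expect_equal(tm["HOM_ALT", "HOM_REF"], unname(rep$changes_by_mode["aarr"]))
  expect_equal(tm["HOM_ALT", "MISSING"], unname(rep$changes_by_mode["aamm"]))
})

test_that("row sums of the matrix reconcile with the e/m counts", {
  path <- write_random_vcf(3000, 2, seed = 73)
  out <- tempfile(fileext = ".vcf")
  inject_errors(path, "S2", error_spec(p_rarr = 0.1, p_ramm = 0.1,
                                       p_rraa = 0.05), out, seed = 74)
  tab <- genotype_concordance(path, out, "S2")
  tm <- tab$transition_matrix
  expect_equal(unname(tab$e_rr + tab$m_rr + tm["HOM_REF", "MISSING"]),
               unname(sum(tm["HOM_REF", ])))
  expect_equal(unname(tab$e_ra + tab$m_ra + tm["HET", "MISSING"]),
               unname(sum(tm["HET", ])))
  expect_equal(unname(tab$e_aa + tab$m_aa + tm["HOM_ALT", "MISSING"]),
               unname(sum(tm["HOM_ALT", ])))
})

test_that("site restriction limits the comparison to the targets file", {
  path <- write_random_vcf(100, 2, seed = 75)
  x <- read_vcf(path)
  sub <- x
  keep <- seq(5, 50, by = 5)  # 10 sites
  sub$fixed <- x$fixed[keep, , drop = FALSE]
  sub$format <- x$format[keep]
  sub$sample_fields <- x$sample_fields[keep, , drop = FALSE]
  sites <- tempfile(fileext = ".vcf")
  write_vcf(sub, sites)
  tab <- genotype_concordance(path, path, "S1", sites = sites)
  expect_equal(tab$n_compared + sum(tab$excluded), 10L)
  expect_equal(sum(tab$transition_matrix), 10L)
})

test_that("missing genotypes follow the chosen policy", {
  mk <- function(gts) {
    lines <- c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tX",
               sprintf("1\t%d\t.\tA\tC\t.\t.\t.\tGT\t%s",
                       seq_along(gts), gts))
    f <- tempfile(fileext = ".vcf")
    writeLines(lines, f)
    f
  }
  truth <- mk(c("0/1", "0/1", "0/0", "1/1", "./."))
  query <- mk(c("0/1", "./.", "0/0", "0/0", "0/1"))
  # default: missing on either side excluded from e/m
  tab <- genotype_concordance(truth, query, "X")
  expect_equal(c(tab$e_rr, tab$e_ra, tab$e_aa), c(0L, 0L, 1L))
  expect_equal(c(tab$m_rr, tab$m_ra, tab$m_aa), c(1L, 1L, 0L))
  expect_equal(unname(tab$excluded["missing"]), 2L)
  # alternative: query-missing counts as a mismatch of the truth class
  tab2 <- genotype_concordance(truth, query, "X", missing_as_mismatch = TRUE)
  expect_equal(c(tab2$e_rr, tab2$e_ra, tab2$e_aa), c(0L, 1L, 1L))
  expect_equal(unname(tab2$excluded["missing"]), 1L)  # truth-missing site
})

test_that("allele-mismatched and OTHER-class records are excluded and counted", {
  path <- write_random_vcf(50, 2, seed = 76)
  x <- read_vcf(path)
  y <- x
  y$fixed[3, "ALT"] <- "T"               # allele mismatch
  y$sample_fields[5, "S1"] <- "./1"      # OTHER in query
  qf <- tempfile(fileext = ".vcf")
  write_vcf(y, qf)
  tab <- genotype_concordance(path, qf, "S1")
  expect_equal(unname(tab$excluded["allele_mismatch"]), 1L)
  expect_equal(unname(tab$excluded["other_class"]), 1L)
  expect_equal(tab$n_compared, 48L)
})

test_that("a sample absent from either file is fatal", {
  path <- write_random_vcf(10, 2, seed = 77)
  expect_error(genotype_concordance(path, path, "S9"), "S9")
})

test_that("NRC evaluates the formula and its stated edge cases", {
  # perfect concordance
  expect_equal(nrc(concordance_table(m_ra = 50, m_aa = 50)), 1)
  # direct evaluation: e_ra = 1, m_ra = 9
  expect_equal(nrc(concordance_table(e_ra = 1, m_ra = 9)), 0.9)
  # mixed counts: (2+1+1)/(2+1+1+5+3)
  expect_equal(nrc(concordance_table(e_rr = 2, e_ra = 1, e_aa = 1,
                                     m_ra = 5, m_aa = 3)),
               1 - 4 / 12)
  # undefined without non-reference information
  expect_error(nrc(concordance_table(m_rr = 1000)), "undefined")
})

test_that("NRC is invariant to the hom-ref match count (property)", {
  base <- sapply(c(0, 1, 100, 1e6), function(mrr)
    nrc(concordance_table(e_rr = 1, e_ra = 2, m_rr = mrr,
                          m_ra = 10, m_aa = 5)))
  expect_equal(base, rep(base[1], 4))
})

test_that("NRC strictly decreases with mismatches, increases with matches", {
  set.seed(404)
  for (i in 1:10) {
    cnt <- as.list(stats::setNames(sample.int(50, 6, replace = TRUE),
                                   c("e_rr", "e_ra", "e_aa",
                                     "m_rr", "m_ra", "m_aa")))
    v0 <- nrc(do.call(concordance_table, cnt))
    for (e in c("e_rr", "e_ra", "e_aa")) {
      cnt2 <- cnt
      cnt2[[e]] <- cnt2[[e]] + 1
      expect_lt(nrc(do.call(concordance_table, cnt2)), v0)
    }
    for (m in c("m_ra", "m_aa")) {
      cnt2 <- cnt
      cnt2[[m]] <- cnt2[[m]] + 1
      expect_gt(nrc(do.call(concordance_table, cnt2)), v0)
    }
  }
})
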