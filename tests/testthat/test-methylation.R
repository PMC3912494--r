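# 4-unit toy amplicon: CpGs at offsets 0, 10, 20, 30; other Cs are
# conversion controls; phasing SNP at offset 38 (alleles A/T).
toy_amplicon <- function(snp = TRUE) {
  ref <- paste0("CGACTACATA", "CGTCCATTAA", "CGATTCCTTA", "CGACTCTTAA")
  bisulfite_amplicon(gintervals("chr1", 1000, 1040), ref,
                     snp_offset = if (snp) 38L else NULL,
                     snp_alleles = if (snp) c("A", "T") else NULL)
}

test_that("amplicon construction validates CpG offsets and detects CpGs", {
  amp <- toy_amplicon()
  expect_equal(amp$cpg_offsets, c(0L, 10L, 20L, 30L))
  expect_error(bisulfite_amplicon(gintervals("chr1", 0, 10),
                                  "ACGTACGTAA", cpg_offsets = 3L),
               "CpG")
  expect_error(bisulfite_amplicon(gintervals("chr1", 0, 10),
                                  "AATTAATTAA"), "no CpG")
})

test_that("clone tabulation reads methylation calls and conversion QC", {
  amp <- toy_amplicon()
  # fully converted, fully unmethylated clone: every C -> T
  unmeth <- gsub("C", "T", amp$ref_seq)
  # fully methylated at CpGs, fully converted elsewhere
  meth <- clones_from_matrix(amp, matrix(1L, 1, 4), allele = "T")
  mat <- tabulate_clones(amp, c(unmeth, meth))
  expect_equal(unname(mat$calls[1, ]), rep(0L, 4))
  expect_equal(unname(mat$calls[2, ]), rep(1L, 4))
  expect_equal(mat$conversion, c(1, 1))
  expect_equal(mat$excluded, c(FALSE, FALSE))
  expect_equal(mat$allele, c("A", "T"))  # SNP base labels each clone
  expect_error(tabulate_clones(amp, "ACGT"), "length")
})

test_that("clones failing the conversion threshold are excluded", {
  amp <- toy_amplicon(snp = FALSE)
  chars <- strsplit(amp$ref_seq, "")[[1]]
  non_cpg_c <- setdiff(which(chars == "C"), amp$cpg_offsets + 1L)
  # convert only half the non-CpG Cs -> conversion 0.5 < 0.98
  bad <- chars
  bad[non_cpg_c[seq(1, length(non_cpg_c), by = 2)]] <- "T"
  bad[amp$cpg_offsets + 1L] <- "T"
  mat <- tabulate_clones(amp, paste(bad, collapse = ""))
  expect_lt(mat$conversion[1], 0.98)
  expect_true(mat$excluded[1])
  expect_error(summarize_region(mat), "excluded")
})

test_that("matrix -> sequence -> matrix round-trips calls exactly", {
  amp <- toy_amplicon()
  set.seed(13)
  calls <- matrix(rbinom(10 * 4, 1, 0.5), 10, 4)
  alleles <- sample(c("A", "T"), 10, replace = TRUE)
  seqs <- clones_from_matrix(amp, calls, alleles)
  mat <- tabulate_clones(amp, seqs)
  expect_equal(unname(mat$calls), calls)
  expect_equal(mat$allele, alleles)
  expect_equal(mat$conversion, rep(1, 10))
})

test_that("region summary: hypomethylated, hypermethylated, intermediate", {
  amp <- toy_amplicon(snp = FALSE)
  all0 <- tabulate_clones(amp, clones_from_matrix(amp, matrix(0L, 16, 4)))
  s0 <- summarize_region(all0)
  expect_equal(s0$mean_fraction, 0)
  expect_equal(s0$status, "hypomethylated")
  all1 <- tabulate_clones(amp, clones_from_matrix(amp, matrix(1L, 16, 4)))
  expect_equal(summarize_region(all1)$status, "hypermethylated")
  half <- tabulate_clones(amp, clones_from_matrix(
    amp, matrix(rep(c(0L, 1L), each = 8 * 4), ncol = 4, byrow = FALSE)))
  sh <- summarize_region(half)
  expect_equal(sh$mean_fraction, 0.5)
  expect_equal(sh$status, "intermediate")
})

test_that("summary is monotone in single call flips", {
  amp <- toy_amplicon(snp = FALSE)
  set.seed(23)
  calls <- matrix(rbinom(16 * 4, 1, 0.3), 16, 4)
  base <- summarize_region(tabulate_clones(
    amp, clones_from_matrix(amp, calls)))
  zero_cells <- which(calls == 0L)
  for (cell in sample(zero_cells, min(10, length(zero_cells)))) {
    flipped <- calls
    flipped[cell] <- 1L
    s <- summarize_region(tabulate_clones(
      amp, clones_from_matrix(amp, flipped)))
    expect_true(all(s$per_cpg >= base$per_cpg))
  }
})

test_that("per-CpG exact test matches the hypergeometric enumeration oracle", {
  amp <- toy_amplicon()
  # 8 clones per allele, allele A fully methylated, allele T unmethylated
  calls <- rbind(matrix(1L, 8, 4), matrix(0L, 8, 4))
  alleles <- rep(c("A", "T"), each = 8)
  mat <- tabulate_clones(amp, clones_from_matrix(amp, calls, alleles))
  res <- allele_dmr_test(mat)
  expect_equal(res$verdict, "dmr")
  # all-or-nothing 8v8 table: p = 1 / choose(16, 8)
  expect_equal(res$per_cpg$p, rep(1 / choose(16, 8), 4))
  expect_equal(res$per_cpg$p[1],
               hypergeom_tail_oracle(8, 8, 0, 8))
  # partial random tables against the enumeration oracle
  set.seed(41)
  for (i in 1:25) {
    na_ <- sample(5:12, 1); nb_ <- sample(5:12, 1)
    xa <- rbinom(1, na_, 0.8); xb <- rbinom(1, nb_, 0.2)
    calls2 <- rbind(matrix(rep(c(1L, 0L), c(xa, na_ - xa)), na_, 4),
                    matrix(rep(c(1L, 0L), c(xb, nb_ - xb)), nb_, 4))
    mat2 <- tabulate_clones(amp, clones_from_matrix(
      amp, calls2, rep(c("A", "T"), c(na_, nb_))))
    got <- allele_dmr_test(mat2)$per_cpg$p
    fa <- xa / na_; fb <- xb / nb_
    expected <- if (fa >= fb) hypergeom_tail_oracle(xa, na_, xb, nb_) else
      hypergeom_tail_oracle(xb, nb_, xa, na_)
    expect_equal(got, rep(expected, 4), tolerance = 1e-12)
  }
})

test_that("DMR verdict requires a phasing SNP and enough clones per allele", {
  amp_no_snp <- toy_amplicon(snp = FALSE)
  calls <- matrix(0L, 16, 4)
  mat <- tabulate_clones(amp_no_snp, clones_from_matrix(amp_no_snp, calls))
  expect_equal(allele_dmr_test(mat)$verdict, "not_assessable")
  # SNP present but one allele under the clone minimum
  amp <- toy_amplicon()
  alleles <- rep(c("A", "T"), c(13, 3))
  mat2 <- tabulate_clones(amp, clones_from_matrix(amp, calls, alleles))
  expect_equal(allele_dmr_test(mat2)$verdict, "not_assessable")
  # identical methylation in both groups: no DMR
  calls3 <- matrix(rep(c(1L, 0L), each = 8 * 4), ncol = 4)
  mat3 <- tabulate_clones(amp, clones_from_matrix(
    amp, calls3, rep(c("A", "T"), 8)))
  expect_equal(allele_dmr_test(mat3)$verdict, "no_dmr")
})

test_that("planted allele split is detected; equal probabilities are not", {
  amp <- toy_amplicon()
  run_rep <- function(pa, pb, seed) {
    set.seed(seed)
    calls <- rbind(matrix(rbinom(16 * 4, 1, pa), 16, 4),
                   matrix(rbinom(16 * 4, 1, pb), 16, 4))
    mat <- tabulate_clones(amp, clones_from_matrix(
      amp, calls, rep(c("A", "T"), each = 16)))
    allele_dmr_test(mat)$verdict
  }
  split <- vapply(1:200, function(s) run_rep(0.95, 0.05, s), character(1))
  equal <- vapply(1:200, function(s) run_rep(0.05, 0.05, 1000 + s),
                  character(1))
  expect_gte(mean(split == "dmr"), 0.99)
  expect_lte(mean(equal == "dmr"), 0.01)
})
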