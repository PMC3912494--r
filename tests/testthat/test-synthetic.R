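cfg_small <- function(...) {
  truth_config(seed = 5, autosome_count = 2, autosome_length = 1.5e6,
               haploid_length = 8e5, genes_per_autosome = 40,
               genes_per_haploid = 20, ...)
}

test_that("truth building is deterministic and respects the layout", {
  t1 <- build_truth(cfg_small())
  t2 <- build_truth(cfg_small())
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
  g <- t1$genes
  expect_equal(nrow(g), 100L)
  # genes are non-overlapping within chromosomes
  for (ch in unique(g$chrom)) {
    gg <- g[g$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  # no imprinted or allele-biased gene on the haploid chromosome
  expect_false(any(g$chrom == "chrX" &
                     g$class %in% c("imprinted_maternal",
                                    "imprinted_paternal",
                                    "allele_biased")))
})

test_that("class counts are within one of the configured proportions", {
  t1 <- build_truth(cfg_small())
  counts <- table(factor(t1$genes$class,
                         levels = names(cfg_small()$class_proportions)))
  target <- cfg_small()$class_proportions * 100
  expect_true(all(abs(as.numeric(counts[names(target)]) - target) <= 1))
  # degenerate proportions: everything one class
  t2 <- build_truth(cfg_small(
    class_proportions = c(expressed_biallelic = 1, repressed = 0,
                          imprinted_maternal = 0, imprinted_paternal = 0,
                          allele_biased = 0)))
  expect_true(all(t2$genes$class == "expressed_biallelic"))
})

test_that("an infeasible gene layout errors", {
  expect_error(build_truth(truth_config(seed = 1, autosome_count = 1,
                                        autosome_length = 1e5,
                                        genes_per_autosome = 50)),
               "fit")
})

test_that("ChIP simulation plants class-consistent enrichment", {
  t1 <- build_truth(cfg_small())
  chip <- simulate_chip(t1)
  cfg <- t1$cfg
  bw <- cfg$bin_width
  mean_over_promoter <- function(track, gene) {
    b0 <- floor((gene$tss - 800) / bw) + 1
    b1 <- ceiling((gene$tss + 800) / bw)
    mean(track$counts[[gene$chrom]][b0:b1])
  }
  g <- t1$genes
  imp <- g[g$class == "imprinted_maternal", ][1, ]
  # imprinted promoter: each mark at background * (1 + fold/2) = 60
  for (m in c("H3K4me3", "H3K9Ac", "H3K9me3")) {
    expect_equal(mean_over_promoter(chip$treatment[[m]], imp),
                 cfg$background_rate * (1 + cfg$enrichment_fold / 2),
                 tolerance = 0.15)
  }
  # repressed gene: activation track flat at background over its promoter
  rep_gene <- g[g$class == "repressed" & g$chrom != "chrX", ][1, ]
  expect_equal(mean_over_promoter(chip$treatment$H3K4me3, rep_gene),
               cfg$background_rate, tolerance = 0.2)
  expect_gt(mean_over_promoter(chip$treatment$H3K9me3, rep_gene),
            cfg$background_rate * 5)
  # input is background everywhere
  expect_equal(mean(chip$input$counts[[1]]), cfg$background_rate,
               tolerance = 0.05)
})

test_that("unit enrichment fold yields essentially no peaks", {
  t1 <- build_truth(cfg_small(enrichment_fold = 1))
  chip <- simulate_chip(t1)
  peaks <- call_peaks(chip$treatment$H3K4me3, chip$input)
  # fold 1 doubles the promoter rate; with the local-background max rule
  # only scattered weak calls can appear, far fewer than the 80 genes
  expect_lt(nrow(peaks), 20)
})

test_that("allelic read simulation matches its sampling distributions", {
  t1 <- build_truth(cfg_small())
  reads <- simulate_allelic_reads(t1)
  g <- t1$genes
  # gDNA at het sites is binomial around 0.5 at depth 500
  het <- merge(reads$gdna[grepl("^f1", reads$gdna$sample), ],
               g[g$informative & g$expressed, "gene_id", drop = FALSE])
  frac <- het$count1 / (het$count1 + het$count2)
  expect_gt(mean(abs(frac - 0.5) <= 0.07), 0.99)
  # cDNA maternal fraction of planted imprinted genes centers on 0.9
  imp <- g$gene_id[g$class == "imprinted_maternal"]
  mf <- reads$cdna$maternal_count[reads$cdna$gene_id %in% imp] /
    t1$cfg$read_depth
  expect_lt(abs(mean(mf) - 0.9), 0.03)
  # biallelic genes center on 0.5
  bi <- g$gene_id[g$class == "expressed_biallelic" & g$chrom != "chrX"]
  mb <- reads$cdna$maternal_count[reads$cdna$gene_id %in% bi] /
    t1$cfg$read_depth
  expect_lt(abs(mean(mb) - 0.5), 0.02)
})

test_that("pyro replicates agree within 3 points in >= 95% of pairs", {
  # assessed at the default study scale (~1000 replicate pairs)
  reads <- simulate_allelic_reads(build_truth(truth_config(seed = 5)))
  spread <- tapply(reads$pyro$percent_allele1,
                   paste(reads$pyro$gene_id, reads$pyro$animal),
                   function(x) max(x) - min(x))
  expect_gte(mean(spread <= 3), 0.95)
})

test_that("bisulfite simulation respects planted methylation probabilities", {
  t1 <- build_truth(cfg_small())
  all0 <- simulate_bisulfite(t1, meth_prob = c(0, 0))
  mat0 <- tabulate_clones(all0[[1]]$amplicon, all0[[1]]$clones)
  expect_true(all(mat0$calls == 0L))
  all1 <- simulate_bisulfite(t1, meth_prob = c(1, 1))
  mat1 <- tabulate_clones(all1[[1]]$amplicon, all1[[1]]$clones)
  expect_true(all(mat1$calls == 1L))
  half <- simulate_bisulfite(t1, meth_prob = c(0.5, 0.5))
  math <- tabulate_clones(half[[1]]$amplicon, half[[1]]$clones)
  expect_lt(abs(mean(math$calls) - 0.5), 0.1)
})

test_that("simulated stages are reproducible end to end", {
  r1 <- simulate_allelic_reads(build_truth(cfg_small()))
  r2 <- simulate_allelic_reads(build_truth(cfg_small()))
  expect_identical(r1, r2)
  c1 <- simulate_chip(build_truth(cfg_small()))
  c2 <- simulate_chip(build_truth(cfg_small()))
  expect_identical(c1, c2)
  b1 <- simulate_bisulfite(build_truth(cfg_small()))
  b2 <- simulate_bisulfite(build_truth(cfg_small()))
  expect_identical(b1, b2)
})

test_that("overlap-count fixtures realize the requested counts exactly", {
  fx <- overlap_count_fixture(1000, 371)
  expect_equal(count_overlapping(fx$a, fx$b)$count, 371L)
  expect_error(overlap_count_fixture(10, 11), "n_overlapping")
})
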