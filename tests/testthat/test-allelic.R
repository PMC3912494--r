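test_that("genotype calls follow the coverage and minor-fraction rules", {
  expect_equal(call_het_snps(10, 9), "no_call")     # 19 reads < 20x
  expect_equal(call_het_snps(12, 8), "het")
  expect_equal(call_het_snps(20, 1), "hom1")        # minor 0.048 < 0.2
  expect_equal(call_het_snps(1, 20), "hom2")
  expect_equal(call_het_snps(c(10, 12, 20), c(9, 8, 1)),
               c("no_call", "het", "hom1"))
  # boundary: exactly 20x with exactly 20% minor fraction is het
  expect_equal(call_het_snps(16, 4), "het")
  # config is respected
  expect_equal(call_het_snps(10, 9, snp_config(min_coverage = 10)), "het")
})

test_that("trackable assigns parental origin only when unambiguous", {
  # fully informative: both parents homozygous for opposite alleles
  tr <- trackable("het", "hom1", "hom2")
  expect_equal(tr$status, "informative")
  expect_equal(c(tr$maternal_allele, tr$paternal_allele), c(1L, 2L))
  # ambiguous: both parents heterozygous
  expect_equal(trackable("het", "het", "het")$status, "uninformative")
  # one homozygous parent suffices: allele 2 cannot be maternal
  tr2 <- trackable("het", "hom1", "het")
  expect_equal(tr2$status, "informative")
  expect_equal(c(tr2$maternal_allele, tr2$paternal_allele), c(1L, 2L))
  # enumeration oracle for the hom-mother x het-father case: of the
  # father's transmissions {1, 2}, only 2 yields a het offspring with a
  # hom1 mother, so the assignment is forced
  father_transmissions <- c(1L, 2L)
  viable <- father_transmissions[vapply(father_transmissions,
                                        function(a) a != 1L, logical(1))]
  expect_equal(viable, 2L)
  # homozygous father, ambiguous mother
  tr3 <- trackable("het", "het", "hom2")
  expect_equal(c(tr3$maternal_allele, tr3$paternal_allele), c(1L, 2L))
  # non-het F1 is never informative
  expect_equal(trackable("hom1", "hom1", "hom2")$status, "uninformative")
  expect_equal(trackable("no_call", "hom1", "hom2")$status,
               "uninformative")
})

test_that("Mendelian inconsistencies are flagged, not called", {
  # het F1 from two identical homozygotes carries an impossible allele
  expect_equal(trackable("het", "hom1", "hom1")$status, "inconsistent")
  expect_equal(trackable("het", "hom2", "hom2")$status, "inconsistent")
})

test_that("replicate averaging and the discordance flag", {
  m <- allele_fraction(c(91, 93))
  expect_equal(m$fraction, 92)
  expect_false(m$discordant)
  m2 <- allele_fraction(c(50, 56))
  expect_equal(m2$fraction, 53)
  expect_true(m2$discordant)
  m3 <- allele_fraction(77)
  expect_equal(m3$fraction, 77)
  expect_false(m3$discordant)
  expect_error(allele_fraction(numeric()), "no replicates")
  expect_error(allele_fraction(c(50, 140)), "0, 100")
})

test_that("maternal bias in both cross directions is called imprinted", {
  m <- data.frame(animal = c("a1", "a2"), cross_type = c("AxB", "BxA"),
                  maternal_fraction = c(92, 77),
                  maternal_stock = c("A", "B"))
  call <- classify_gene(m)
  expect_equal(call$call, "imprinted_maternal_expressed")
  expect_equal(call$leakage, 15.5)
  # paternal mirror image
  m$maternal_fraction <- c(8, 23)
  call2 <- classify_gene(m)
  expect_equal(call2$call, "imprinted_paternal_expressed")
  expect_equal(call2$leakage, 15.5)
})

test_that("bias tracking a stock allele across crosses is allele-biased", {
  # stock-A allele favored regardless of which parent transmitted it
  m <- data.frame(animal = c("a1", "a2", "a3"),
                  cross_type = c("AxB", "BxA", "BxA"),
                  maternal_fraction = c(90, 12, 9),
                  maternal_stock = c("A", "B", "B"))
  call <- classify_gene(m)
  expect_equal(call$call, "allele_biased")
  expect_equal(call$leakage, mean(c(10, 12, 9)))
})

test_that("single-cross informativeness or conflict is undetermined", {
  one_cross <- data.frame(animal = c("a1", "a2"),
                          cross_type = c("AxB", "AxB"),
                          maternal_fraction = c(95, 91),
                          maternal_stock = c("A", "A"))
  call <- classify_gene(one_cross)
  expect_equal(call$call, "undetermined")
  expect_match(call$reason, "one cross")
  conflict <- data.frame(animal = c("a1", "a2", "a3"),
                         cross_type = c("AxB", "BxA", "BxA"),
                         maternal_fraction = c(92, 90, 8),
                         maternal_stock = c("A", "B", "B"))
  expect_equal(classify_gene(conflict)$call, "undetermined")
  expect_equal(classify_gene(NULL)$call, "undetermined")
})

test_that("all animals near 50% is biallelic", {
  m <- data.frame(animal = paste0("a", 1:4),
                  cross_type = c("AxB", "AxB", "BxA", "BxA"),
                  maternal_fraction = c(50, 52, 49, 51),
                  maternal_stock = c("A", "A", "B", "B"))
  expect_equal(classify_gene(m)$call, "biallelic")
})

test_that("classification is invariant to relabeling the reciprocal crosses", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    m <- data.frame(
      animal = paste0("a", seq_len(n)),
      cross_type = sample(c("AxB", "BxA"), n, replace = TRUE),
      maternal_fraction = round(runif(n, 0, 100)),
      stringsAsFactors = FALSE)
    m$maternal_stock <- ifelse(m$cross_type == "AxB", "A", "B")
    swapped <- m
    swapped$cross_type <- ifelse(m$cross_type == "AxB", "BxA", "AxB")
    swapped$maternal_stock <- ifelse(m$maternal_stock == "A", "B", "A")
    expect_equal(classify_gene(swapped)$call, classify_gene(m)$call)
  }
})

test_that("raw counts additionally require binomial significance for bias", {
  # 7 of 10 maternal reads exceeds the percent threshold but not the
  # exact binomial test at alpha = 0.01, so bias is not credited
  m <- data.frame(animal = c("a1", "a2"), cross_type = c("AxB", "BxA"),
                  maternal_fraction = c(70, 70),
                  maternal_stock = c("A", "B"),
                  maternal_count = c(7, 7), total_count = c(10, 10))
  expect_equal(classify_gene(m)$call, "biallelic")
  m$maternal_count <- c(350, 350); m$total_count <- c(500, 500)
  expect_equal(classify_gene(m)$call, "imprinted_maternal_expressed")
})

test_that("planted imprinted and biallelic genes classify correctly at depth", {
  set.seed(77)
  n_genes <- 100
  depth <- 500
  calls_imp <- character(n_genes)
  calls_bi <- character(n_genes)
  leakages <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    sim_animal <- function(theta, cross, stock) {
      k <- rbinom(1, depth, theta)
      data.frame(animal = paste0(cross, "_a"), cross_type = cross,
                 maternal_fraction = 100 * k / depth,
                 maternal_stock = stock)
    }
    m_imp <- rbind(sim_animal(0.9, "AxB", "A"),
                   sim_animal(0.9, "BxA", "B"))
    m_bi <- rbind(sim_animal(0.5, "AxB", "A"),
                  sim_animal(0.5, "BxA", "B"))
    ci <- classify_gene(m_imp)
    calls_imp[g] <- ci$call
    leakages[g] <- ci$leakage
    calls_bi[g] <- classify_gene(m_bi)$call
  }
  expect_true(all(calls_imp == "imprinted_maternal_expressed"))
  expect_lte(sum(grepl("^imprinted", calls_bi)), 1)
  # mean leakage recovers the planted 10% repressed-allele fraction
  expect_lt(abs(mean(leakages) - 10), 3)
})
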