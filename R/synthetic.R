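#' Configuration of the synthetic study design
#'
#' Defines a toy diploid genome (several autosomes plus one haploid
#' chromosome, modeling the single X of male cells), gene classes, and the
#' noise model for every simulated assay. Defaults emulate the screening
#' study design at desk scale: ~500 genes of which 10 are imprinted (5
#' maternally, 5 paternally expressed) and 10 allele-biased, an
#' expressed-allele fraction of 0.9 with mild overdispersion, ChIP
#' background of 10 fragments per 50-bp bin with 10-fold promoter
#' enrichment, 500-read allele pileups, two pyrosequencing replicates per
#' animal, and 16 bisulfite clones per allele.
#'
#' Imprinted and allele-biased promoters receive each mark at half the
#' homozygous enrichment fold because only one parental allele contributes
#' the mark while ChIP pools both alleles.
#'
#' @param seed master RNG seed (explicit; no implicit randomness).
#' @param autosome_count,autosome_length,haploid_length genome layout.
#' @param genes_per_autosome,genes_per_haploid gene counts per chromosome.
#' @param class_proportions named proportions over the five gene classes;
#'   must sum to 1.
#' @param expressed_fraction planted expressed-allele fraction for
#'   imprinted and allele-biased genes.
#' @param leakage_sd biological spread of the per-animal expressed-allele
#'   fraction.
#' @param overdispersion beta-binomial rho for allele counts (0 = exact
#'   binomial).
#' @param background_rate ChIP background fragments per bin.
#' @param enrichment_fold homozygous promoter enrichment fold (>= 1).
#' @param bin_width coverage bin width in bases.
#' @param read_depth reads per SNP pileup (gDNA and cDNA).
#' @param pyro_replicates,pyro_sd pyrosequencing replicate count and
#'   per-replicate Gaussian noise (percent); the default sd of 1 keeps
#'   replicate disagreement within 3 points in >= 95\% of draws.
#' @param clones_per_allele bisulfite clones sequenced per allele.
#' @param conversion_rate bisulfite conversion efficiency at non-CpG Cs.
#' @param meth_prob named or length-2 per-allele CpG methylation
#'   probabilities for promoter amplicons (default hypomethylated on both
#'   alleles).
#' @param cpg_prob per-class probability that a promoter carries an
#'   annotated CpG island.
#' @param uninformative_rate fraction of imprinted/allele-biased genes
#'   whose assay SNP does not segregate between the stocks (emulating
#'   candidates that cannot be tracked).
#' @param f1_per_family F1 animals sampled per cross direction.
#' @param amplicon_snp_prob probability that a bisulfite amplicon contains
#'   a phasing SNP.
#' @return list of class \code{truth_config}.
#' @export
truth_config <- function(seed = 1L,
                         autosome_count = 5,
                         autosome_length = 2e6,
                         haploid_length = 1.2e6,
                         genes_per_autosome = 90,
                         genes_per_haploid = 50,
                         class_proportions = c(expressed_biallelic = 0.66,
                                               repressed = 0.30,
                                               imprinted_maternal = 0.01,
                                               imprinted_paternal = 0.01,
                                               allele_biased = 0.02),
                         expressed_fraction = 0.9,
                         leakage_sd = 0.02,
                         overdispersion = 0.01,
                         background_rate = 10,
                         enrichment_fold = 10,
                         bin_width = 50,
                         read_depth = 500,
                         pyro_replicates = 2,
                         pyro_sd = 1,
                         clones_per_allele = 16,
                         conversion_rate = 0.995,
                         meth_prob = c(0.05, 0.05),
                         cpg_prob = c(expressed_biallelic = 0.5,
                                      repressed = 0.3,
                                      imprinted_maternal = 1,
                                      imprinted_paternal = 1,
                                      allele_biased = 1),
                         uninformative_rate = 0,
                         f1_per_family = 2,
                         amplicon_snp_prob = 1) {
  if (!setequal(names(class_proportions),
                c("expressed_biallelic", "repressed", "imprinted_maternal",
                  "imprinted_paternal", "allele_biased")) ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    fail("class_proportions must cover the five classes and sum to 1")
  }
  if (enrichment_fold < 1) fail("enrichment_fold must be >= 1")
  if (is.null(seed) || is.na(seed)) fail("an explicit seed is required")
  structure(as.list(environment()), class = "truth_config")
}

# Internal: integer class counts by largest remainder; within +/-1 of
# proportions * n.
apportion <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Build a truth-labeled synthetic genome and study design
#'
#' Deterministic for a fixed config: lays out non-overlapping genes on the
#' autosomes and haploid chromosome, assigns class labels (imprinted and
#' allele-biased genes never land on the haploid chromosome), plants
#' promoter CpG islands, 3'-UTR assay SNPs with stock-of-origin alleles,
#' two reciprocal families (stock A dam x stock B sire, and the reverse),
#' and bisulfite amplicons with per-allele methylation probabilities.
#'
#' @param cfg [truth_config()].
#' @return list of class \code{truth_set}: \code{cfg}, \code{annotation},
#'   \code{genes} (with truth columns \code{class}, \code{favored_stock},
#'   \code{snp_pos}, \code{informative}), \code{pedigree},
#'   \code{parent_stock}, \code{amplicons}.
#' @export
build_truth <- function(cfg) {
  stopifnot(inherits(cfg, "truth_config"))
  withr::with_seed(derive_seed(cfg$seed, 0L), build_truth_impl(cfg))
}

build_truth_impl <- function(cfg) {
  chroms <- c(paste0("chr", seq_len(cfg$autosome_count)), "chrX")
  lens <- stats::setNames(c(rep(cfg$autosome_length, cfg$autosome_count),
                            cfg$haploid_length), chroms)
  n_per <- c(rep(cfg$genes_per_autosome, cfg$autosome_count),
             cfg$genes_per_haploid)
  margin <- 10000
  rows <- list()
  for (ci in seq_along(chroms)) {
    n <- n_per[ci]
    spacing <- floor((lens[ci] - 2 * margin) / n)
    if (spacing < 12000) {
      fail("genes do not fit on %s: spacing %d < 12000 bases",
           chroms[ci], spacing)
    }
    tss <- margin + (seq_len(n) - 1) * spacing + 5000
    glen <- sample(2000:6000, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    start <- ifelse(strand == "+", tss, tss - glen + 1)
    end <- ifelse(strand == "+", tss + glen, tss + 1)
    rows[[ci]] <- data.frame(
      gene_id = sprintf("%s_g%03d", chroms[ci], seq_len(n)),
      chrom = chroms[ci], start = start, end = end, strand = strand,
      tss = tss, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  n_tot <- nrow(genes)
  counts <- apportion(cfg$class_proportions[c(
    "expressed_biallelic", "repressed", "imprinted_maternal",
    "imprinted_paternal", "allele_biased")], n_tot)
  class <- rep(NA_character_, n_tot)
  auto_idx <- which(genes$chrom != "chrX")
  special <- c(rep("imprinted_maternal", counts["imprinted_maternal"]),
               rep("imprinted_paternal", counts["imprinted_paternal"]),
               rep("allele_biased", counts["allele_biased"]))
  if (length(special) > length(auto_idx)) {
    fail("not enough autosomal genes for the planted special classes")
  }
  class[sample(auto_idx, length(special))] <- special
  rest <- which(is.na(class))
  filler <- sample(c(rep("expressed_biallelic",
                         counts["expressed_biallelic"]),
                     rep("repressed", counts["repressed"])))
  class[rest] <- filler[seq_along(rest)]
  genes$class <- class
  genes$expressed <- class != "repressed"
  genes$favored_stock <- ifelse(class == "allele_biased",
                                sample(c("A", "B"), n_tot, replace = TRUE),
                                NA_character_)
  # one 3'-UTR assay SNP per gene; stock A carries allele 1 ("A"), stock B
  # allele 2 ("G") when the SNP segregates between the stocks
  genes$snp_pos <- ifelse(genes$strand == "+", genes$end - 100,
                          genes$start + 100)
  special_idx <- which(class %in% c("imprinted_maternal",
                                    "imprinted_paternal", "allele_biased"))
  genes$informative <- TRUE
  if (cfg$uninformative_rate > 0 && length(special_idx)) {
    drop <- special_idx[stats::runif(length(special_idx)) <
                          cfg$uninformative_rate]
    genes$informative[drop] <- FALSE
  }
  other_idx <- which(!seq_len(n_tot) %in% special_idx)
  genes$informative[other_idx] <- stats::runif(length(other_idx)) < 0.8
  genes$informative[genes$chrom == "chrX"] <- FALSE
  # CpG islands at promoters, per-class probability; island straddles TSS
  has_cpg <- stats::runif(n_tot) < cfg$cpg_prob[genes$class]
  isl <- genes[has_cpg, , drop = FALSE]
  cpg_islands <- gintervals(isl$chrom, pmax(isl$tss - 300, 0),
                            isl$tss + 200)
  ann <- annotation(genes[, c("gene_id", "chrom", "start", "end", "strand",
                              "tss", "expressed")],
                    cpg_islands, lens, haploid_chroms = "chrX")
  pedigree <- data.frame(
    family_id = rep(c("fam1", "fam2"), each = cfg$f1_per_family),
    cross_type = rep(c("AxB", "BxA"), each = cfg$f1_per_family),
    mother = rep(c("damA_1", "damB_2"), each = cfg$f1_per_family),
    father = rep(c("sireB_1", "sireA_2"), each = cfg$f1_per_family),
    animal = c(paste0("f1_AxB_", seq_len(cfg$f1_per_family)),
               paste0("f1_BxA_", seq_len(cfg$f1_per_family))),
    stringsAsFactors = FALSE)
  parent_stock <- c(damA_1 = "A", sireB_1 = "B", damB_2 = "B",
                    sireA_2 = "A")
  amplicons <- build_amplicons(genes, cfg)
  structure(list(cfg = cfg, annotation = ann, genes = genes,
                 pedigree = pedigree, parent_stock = parent_stock,
                 amplicons = amplicons),
            class = "truth_set")
}

# Internal: a promoter CpG-island bisulfite amplicon per imprinted or
# allele-biased gene. The reference is built from 20-base units each
# starting with a CpG; the remaining bases avoid G so the only CpGs are
# the planted ones, and the non-CpG cytosines serve as conversion
# controls. The phasing SNP (alleles A/T) sits in the final unit.
build_amplicons <- function(genes, cfg) {
  targets <- which(genes$class %in% c("imprinted_maternal",
                                      "imprinted_paternal",
                                      "allele_biased"))
  amps <- list()
  for (i in targets) {
    units <- vapply(seq_len(16), function(u) {
      paste0("CG", paste(sample(c("A", "C", "T"), 17, replace = TRUE),
                         collapse = ""), "A")
    }, character(1))
    ref <- paste(units, collapse = "")
    snp_offset <- if (stats::runif(1) < cfg$amplicon_snp_prob) {
      nchar(ref) - 5L
    } else NULL
    ref_chars <- strsplit(ref, "")[[1]]
    if (!is.null(snp_offset)) ref_chars[snp_offset + 1L] <- "A"
    ref <- paste(ref_chars, collapse = "")
    region <- gintervals(genes$chrom[i], pmax(genes$tss[i] - 300, 0),
                         pmax(genes$tss[i] - 300, 0) + nchar(ref))
    mp <- cfg$meth_prob
    amps[[genes$gene_id[i]]] <- list(
      gene_id = genes$gene_id[i],
      amplicon = bisulfite_amplicon(region, ref,
                                    snp_offset = snp_offset,
                                    snp_alleles = if (!is.null(snp_offset))
                                      c("A", "T") else NULL),
      meth_prob = stats::setNames(as.numeric(mp)[1:2], c("A", "T")))
  }
  amps
}

#' Simulate ChIP coverage tracks from the planted truth
#'
#' Poisson background everywhere; over a 2-kb window centered on each TSS,
#' class-dependent enrichment: expressed biallelic genes get the marks of
#' activation (H3K4me3, H3K9Ac) at the full fold; repressed genes get
#' H3K9me3; imprinted and allele-biased genes get all three marks at half
#' the homozygous fold each, because only one of the two pooled alleles
#' carries each mark. Genes on the haploid chromosome carry only the marks
#' consistent with their single allele. The input track is background
#' only.
#'
#' @param truth [build_truth()] output.
#' @return list with \code{treatment} (named list of
#'   [coverage_track()]s per mark) and \code{input}.
#' @export
simulate_chip <- function(truth) {
  cfg <- truth$cfg
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    lens <- truth$annotation$chrom_lengths
    bw <- cfg$bin_width
    bins <- lapply(lens, function(L) as.integer(ceiling(L / bw)))
    marks <- c("H3K4me3", "H3K9Ac", "H3K9me3")
    # per-mark multiplicative rate per bin, then one Poisson draw per track
    rate <- lapply(marks, function(m) {
      lapply(bins, function(nb) rep(cfg$background_rate, nb))
    })
    names(rate) <- marks
    g <- truth$genes
    for (i in seq_len(nrow(g))) {
      cls <- g$class[i]
      enriched <- switch(cls,
        expressed_biallelic = c("H3K4me3", "H3K9Ac"),
        repressed = "H3K9me3",
        imprinted_maternal = marks,
        imprinted_paternal = marks,
        allele_biased = marks)
      frac <- if (cls %in% c("imprinted_maternal", "imprinted_paternal",
                             "allele_biased")) 0.5 else 1
      w0 <- max(0, g$tss[i] - 1000)
      w1 <- min(lens[[g$chrom[i]]], g$tss[i] + 1000)
      b0 <- floor(w0 / bw) + 1L
      b1 <- max(b0, ceiling(w1 / bw))
      for (m in enriched) {
        rate[[m]][[g$chrom[i]]][b0:b1] <-
          cfg$background_rate * (1 + frac * cfg$enrichment_fold)
      }
    }
    treatment <- lapply(rate, function(per_chrom) {
      coverage_track(lapply(per_chrom, function(r)
        stats::rpois(length(r), r)), bw)
    })
    input <- coverage_track(lapply(bins, function(nb)
      stats::rpois(nb, cfg$background_rate)), bw)
    list(treatment = treatment, input = input)
  })
}

# Internal: beta-binomial draw with mean p and overdispersion rho.
rbetabinom <- function(n, size, p, rho) {
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  if (rho <= 0) return(stats::rbinom(n, size, p))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

#' Simulate allele pileups and pyrosequencing replicates
#'
#' For every assayable gene: parental gDNA pileups homozygous for the
#' stock allele, F1 gDNA pileups binomial around 0.5 at heterozygous
#' sites, cDNA maternal-allele counts beta-binomial around the planted
#' class fraction (expressed-allele fraction for imprinted genes in the
#' parent-specific direction, stock-tracking for allele-biased genes, 0.5
#' for biallelic), and pyrosequencing replicate percentages centered on
#' the animal's realized cDNA allele ratio. Allele 1 is the stock-A
#' allele throughout.
#'
#' @param truth [build_truth()] output.
#' @return list with data.frames \code{gdna} (gene_id, sample, count1,
#'   count2), \code{cdna} (gene_id, animal, maternal_count, total,
#'   count1, count2), \code{pyro} (gene_id, animal, replicate,
#'   percent_allele1) and \code{pedigree}.
#' @export
simulate_allelic_reads <- function(truth) {
  cfg <- truth$cfg
  withr::with_seed(derive_seed(cfg$seed, 2L), {
    g <- truth$genes
    ped <- truth$pedigree
    parents <- unique(data.frame(sample = c(ped$mother, ped$father),
                                 stringsAsFactors = FALSE))$sample
    gdna <- list(); cdna <- list(); pyro <- list()
    for (i in seq_len(nrow(g))) {
      if (g$chrom[i] == "chrX") next  # assay targets autosomal candidates
      seg <- g$informative[i]
      for (s in parents) {
        stock <- truth$parent_stock[[s]]
        c1 <- if (!seg || stock == "A") cfg$read_depth else 0
        gdna[[length(gdna) + 1L]] <- data.frame(
          gene_id = g$gene_id[i], sample = s, count1 = c1,
          count2 = cfg$read_depth - c1, stringsAsFactors = FALSE)
      }
      for (r in seq_len(nrow(ped))) {
        animal <- ped$animal[r]
        mother_stock <- truth$parent_stock[[ped$mother[r]]]
        if (seg) {
          c1 <- stats::rbinom(1, cfg$read_depth, 0.5)
        } else {
          c1 <- cfg$read_depth
        }
        gdna[[length(gdna) + 1L]] <- data.frame(
          gene_id = g$gene_id[i], sample = animal, count1 = c1,
          count2 = cfg$read_depth - c1, stringsAsFactors = FALSE)
        if (!g$expressed[i]) next
        theta_m <- switch(g$class[i],
          expressed_biallelic = 0.5,
          imprinted_maternal = truncnorm1(cfg$expressed_fraction,
                                          cfg$leakage_sd),
          imprinted_paternal = 1 - truncnorm1(cfg$expressed_fraction,
                                              cfg$leakage_sd),
          allele_biased = {
            phi <- truncnorm1(cfg$expressed_fraction, cfg$leakage_sd)
            if (mother_stock == g$favored_stock[i]) phi else 1 - phi
          })
        m_count <- rbetabinom(1, cfg$read_depth, theta_m,
                              cfg$overdispersion)
        frac1 <- if (mother_stock == "A") m_count / cfg$read_depth else
          1 - m_count / cfg$read_depth
        cdna[[length(cdna) + 1L]] <- data.frame(
          gene_id = g$gene_id[i], animal = animal,
          maternal_count = m_count, total = cfg$read_depth,
          count1 = round(frac1 * cfg$read_depth),
          count2 = cfg$read_depth - round(frac1 * cfg$read_depth),
          stringsAsFactors = FALSE)
        if (seg) {
          reps <- pmin(pmax(
            100 * frac1 + stats::rnorm(cfg$pyro_replicates, 0,
                                       cfg$pyro_sd), 0), 100)
          pyro[[length(pyro) + 1L]] <- data.frame(
            gene_id = g$gene_id[i], animal = animal,
            replicate = seq_len(cfg$pyro_replicates),
            percent_allele1 = reps, stringsAsFactors = FALSE)
        }
      }
    }
    list(gdna = do.call(rbind, gdna), cdna = do.call(rbind, cdna),
         pyro = do.call(rbind, pyro), pedigree = ped)
  })
}

# Internal: one draw from N(mean, sd) truncated to [0, 1].
truncnorm1 <- function(mean, sd) {
  min(max(stats::rnorm(1, mean, sd), 0), 1)
}

#' Simulate bisulfite clone sequences for the truth amplicons
#'
#' Per clone: an allele (when the amplicon has a phasing SNP; equal
#' numbers per allele), per-CpG Bernoulli methylation with the planted
#' per-allele probability, and non-CpG cytosines converted independently
#' at the configured conversion rate.
#'
#' @param truth [build_truth()] output.
#' @param meth_prob optional override of the per-allele methylation
#'   probabilities (length 2, applied to every amplicon).
#' @return named list (per gene) with \code{amplicon} and \code{clones}
#'   (character vector of sequences).
#' @export
simulate_bisulfite <- function(truth, meth_prob = NULL) {
  cfg <- truth$cfg
  withr::with_seed(derive_seed(cfg$seed, 3L), {
    lapply(truth$amplicons, function(a) {
      amp <- a$amplicon
      mp <- if (is.null(meth_prob)) a$meth_prob else
        stats::setNames(as.numeric(meth_prob)[1:2], c("A", "T"))
      has_snp <- !is.null(amp$snp_offset)
      alleles <- if (has_snp) {
        rep(c("A", "T"), each = cfg$clones_per_allele)
      } else rep(NA_character_, cfg$clones_per_allele)
      p <- if (has_snp) mp[alleles] else rep(mp[1], length(alleles))
      clones <- vapply(seq_along(alleles), function(k) {
        generate_clone(amp, p[k], cfg$conversion_rate,
                       if (has_snp) alleles[k] else NULL)
      }, character(1))
      names(clones) <- paste0("clone_", seq_along(clones))
      list(gene_id = a$gene_id, amplicon = amp, clones = clones,
           alleles = alleles)
    })
  })
}

# Internal: one bisulfite clone sequence.
generate_clone <- function(amp, p_meth, conversion_rate, allele) {
  chars <- strsplit(amp$ref_seq, "")[[1]]
  cpg <- amp$cpg_offsets + 1L
  non_cpg_c <- setdiff(which(chars == "C"), cpg)
  if (!is.null(amp$snp_offset)) {
    non_cpg_c <- setdiff(non_cpg_c, amp$snp_offset + 1L)
  }
  conv <- stats::runif(length(non_cpg_c)) < conversion_rate
  chars[non_cpg_c[conv]] <- "T"
  meth <- stats::runif(length(cpg)) < p_meth
  chars[cpg] <- ifelse(meth, "C", "T")
  if (!is.null(amp$snp_offset) && !is.null(allele)) {
    chars[amp$snp_offset + 1L] <- allele
  }
  paste(chars, collapse = "")
}

#' Write the simulated inputs in the pipeline's file formats
#'
#' Emits exactly what the file-based pipeline entry points consume: gene
#' models TSV, chromosome sizes, CpG island BED, per-mark treatment and
#' input coverage bedGraphs, SNP pileup TSV, pedigree TSV, pyrosequencing
#' TSV, clone FASTA per amplicon, plus a truth-labels TSV for scoring.
#'
#' @param truth [build_truth()] output.
#' @param chip [simulate_chip()] output.
#' @param reads [simulate_allelic_reads()] output.
#' @param dir output directory (created if missing).
#' @param clones optional [simulate_bisulfite()] output.
#' @return \code{dir}, invisibly.
#' @export
write_truth_inputs <- function(truth, chip, reads, dir, clones = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- truth$genes
  utils::write.table(
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               tss = g$tss, start = g$start, end = g$end,
               expressed = g$expressed),
    file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  lens <- truth$annotation$chrom_lengths
  utils::write.table(
    data.frame(names(lens), format(lens, scientific = FALSE, trim = TRUE)),
    file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_intervals(truth$annotation$cpg_islands,
                  file.path(dir, "cpg_islands.bed"))
  bw <- truth$cfg$bin_width
  track_df <- function(ct) {
    do.call(rbind, lapply(names(ct$counts), function(ch) {
      n <- length(ct$counts[[ch]])
      data.frame(chrom = ch, start = (seq_len(n) - 1) * bw,
                 end = seq_len(n) * bw, value = ct$counts[[ch]])
    }))
  }
  for (m in names(chip$treatment)) {
    write_intervals(track_df(chip$treatment[[m]]),
                    file.path(dir, paste0(m, ".bedgraph")),
                    format = "bedgraph")
  }
  write_intervals(track_df(chip$input), file.path(dir, "input.bedgraph"),
                  format = "bedgraph")
  utils::write.table(reads$gdna, file.path(dir, "gdna_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(reads$pyro, file.path(dir, "pyro.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(reads$pedigree, file.path(dir, "pedigree.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    g[, c("gene_id", "chrom", "class", "favored_stock", "informative")],
    file.path(dir, "truth_labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(clones)) {
    for (nm in names(clones)) {
      seqs <- Biostrings::DNAStringSet(clones[[nm]]$clones)
      Biostrings::writeXStringSet(
        seqs, file.path(dir, paste0("clones_", nm, ".fasta")))
    }
  }
  invisible(dir)
}

#' Deterministic fixture realizing a given overlap count
#'
#' Builds two peak sets on one synthetic chromosome such that exactly
#' \code{n_overlapping} of the \code{n_a} query intervals overlap at least
#' one subject interval. Used to re-derive reported overlap percentages
#' from their printed numerator and denominator with the same engine that
#' screens real peak sets.
#'
#' @param n_a number of query intervals.
#' @param n_overlapping number of query intervals that must overlap a
#'   subject interval (\code{0 <= n_overlapping <= n_a}).
#' @return list with interval data.frames \code{a} and \code{b}.
#' @export
overlap_count_fixture <- function(n_a, n_overlapping) {
  if (n_overlapping > n_a || n_overlapping < 0) {
    fail("n_overlapping must lie in [0, n_a]")
  }
  pos <- (seq_len(n_a) - 1) * 1000
  a <- gintervals("chrF", pos, pos + 500)
  hit <- seq_len(n_overlapping)
  b <- gintervals("chrF", pos[hit] + 400, pos[hit] + 700)
  list(a = a, b = b)
}
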