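#' SNP-calling configuration
#'
#' @param min_coverage minimum total reads for any genotype call
#'   (default 20, the coverage rule used for candidate SNPs).
#' @param min_minor_fraction minimum fraction of the minor allele for a
#'   heterozygous call (default 0.2).
#' @return list of class \code{snp_config}.
#' @export
snp_config <- function(min_coverage = 20, min_minor_fraction = 0.2) {
  if (min_coverage < 1) fail("min_coverage must be >= 1")
  if (min_minor_fraction <= 0 || min_minor_fraction > 0.5) {
    fail("min_minor_fraction must be in (0, 0.5]")
  }
  structure(list(min_coverage = min_coverage,
                 min_minor_fraction = min_minor_fraction),
            class = "snp_config")
}

#' Genotype biallelic sites from allele counts
#'
#' A simple fraction rule replaces likelihood-based genotyping: sites under
#' \code{min_coverage} total reads are \code{no_call}; sites where both
#' allele fractions reach \code{min_minor_fraction} are \code{het};
#' otherwise the majority-allele homozygote is called.
#'
#' @param count1,count2 numeric vectors of reads supporting each allele.
#' @param cfg [snp_config()].
#' @return character vector in \code{c("hom1", "hom2", "het", "no_call")}.
#' @examples
#' call_het_snps(c(10, 12, 20), c(9, 8, 1))  # no_call, het, hom1
#' @export
call_het_snps <- function(count1, count2, cfg = snp_config()) {
  total <- count1 + count2
  # compare on counts (minor >= fraction * total) to keep the boundary
  # exact, e.g. 4 of 20 reads at a 0.2 threshold is heterozygous
  minor_ok <- pmin(count1, count2) >= cfg$min_minor_fraction * total - 1e-9
  ifelse(total < cfg$min_coverage, "no_call",
         ifelse(minor_ok, "het",
                ifelse(count1 >= count2, "hom1", "hom2")))
}

#' Assign the alleles of a heterozygous F1 to its parents
#'
#' A SNP is "trackable" for an F1 iff the F1 is heterozygous and the two
#' alleles can be unambiguously assigned to mother and father from the
#' parental genotypes: at least one parent must be homozygous, and any
#' called parent must be consistent with the transmission. An F1 allele
#' absent from both called parents is a Mendelian inconsistency, reported
#' as an error state rather than a call.
#'
#' @param f1,mother,father genotype strings from [call_het_snps()].
#' @return list with \code{status} in \code{c("informative",
#'   "uninformative", "inconsistent")} and, when informative,
#'   \code{maternal_allele} / \code{paternal_allele} (1 or 2).
#' @examples
#' trackable("het", "hom1", "hom2")  # maternal = allele 1
#' trackable("het", "hom1", "het")   # allele 2 must be paternal
#' @export
trackable <- function(f1, mother, father) {
  un <- list(status = "uninformative",
             maternal_allele = NA_integer_, paternal_allele = NA_integer_)
  if (f1 != "het") return(un)
  hom_allele <- function(g) switch(g, hom1 = 1L, hom2 = 2L, NA_integer_)
  m <- hom_allele(mother)
  f <- hom_allele(father)
  if (!is.na(m) && !is.na(f) && m == f) {
    # het F1 carries an allele absent from both homozygous parents
    return(list(status = "inconsistent",
                maternal_allele = NA_integer_,
                paternal_allele = NA_integer_))
  }
  if (!is.na(m)) {
    pat <- 3L - m
    if (father %in% c("hom1", "hom2") && hom_allele(father) != pat) {
      return(list(status = "inconsistent",
                  maternal_allele = NA_integer_,
                  paternal_allele = NA_integer_))
    }
    return(list(status = "informative",
                maternal_allele = m, paternal_allele = pat))
  }
  if (!is.na(f)) {
    mat <- 3L - f
    return(list(status = "informative",
                maternal_allele = mat, paternal_allele = f))
  }
  un
}

#' Average pyrosequencing replicates into one allele measurement
#'
#' The final expression percentage is the arithmetic mean of the technical
#' replicates; replicate spread beyond \code{tolerance} percentage points
#' raises a discordance flag (replicate variation is expected to be
#' negligible, <= 3 points).
#'
#' @param replicates numeric vector of per-replicate percentages (0-100).
#' @param tolerance maximum acceptable replicate range, in points.
#' @return list with \code{fraction} (mean \%), \code{replicates} and
#'   \code{discordant}.
#' @examples
#' allele_fraction(c(91, 93))  # 92, concordant
#' @export
allele_fraction <- function(replicates, tolerance = 3) {
  if (!length(replicates)) fail("allele_fraction: no replicates supplied")
  if (any(replicates < 0 | replicates > 100)) {
    fail("replicate percentages must lie in [0, 100]")
  }
  list(fraction = mean(replicates),
       replicates = replicates,
       discordant = (max(replicates) - min(replicates)) > tolerance)
}

#' Classify a gene from reciprocal-cross allele measurements
#'
#' Each measurement is one informative animal: its replicate-averaged
#' maternal-allele percentage, the reciprocal-cross direction it came from,
#' and which parental stock supplied the maternal allele. Per animal, bias
#' is maternal when the maternal fraction is at least \code{bias_threshold}
#' \%, paternal when at most \code{100 - bias_threshold}, else unbiased.
#'
#' Gene-level calls:
#' \itemize{
#'   \item \code{imprinted_maternal_expressed} / \code{_paternal_}: every
#'     informative animal biased toward the same parent, with informative
#'     animals in both reciprocal-cross directions (the reciprocal design
#'     is what separates parent-of-origin from allele identity);
#'   \item \code{allele_biased}: bias consistently tracks one stock's
#'     physical allele across both cross directions, regardless of which
#'     parent transmitted it;
#'   \item \code{biallelic}: every animal unbiased;
#'   \item \code{undetermined}: informative animals in only one cross
#'     direction, or conflicting per-animal patterns.
#' }
#' Leakage is the mean residual percentage from the repressed allele
#' (\code{100 -} expressed-allele fraction) over informative animals.
#'
#' When raw read counts are supplied (\code{maternal_count},
#' \code{total_count} columns), an exact binomial test against 0.5 at level
#' \code{alpha} is additionally required for an animal to count as biased.
#'
#' @param measurements data.frame with columns \code{animal},
#'   \code{cross_type}, \code{maternal_fraction} (percent),
#'   \code{maternal_stock}, and optionally \code{maternal_count} and
#'   \code{total_count}.
#' @param bias_threshold percent; default 70.
#' @param alpha level for the optional exact binomial test.
#' @param gene_id carried through to the result.
#' @return list of class \code{imprint_call}: \code{gene_id}, \code{call},
#'   \code{n_by_cross}, \code{leakage}, \code{reason}, \code{animals}.
#' @examples
#' m <- data.frame(animal = c("a1", "a2"), cross_type = c("AxB", "BxA"),
#'                 maternal_fraction = c(92, 77),
#'                 maternal_stock = c("A", "B"))
#' classify_gene(m)$call  # imprinted_maternal_expressed
#' @export
classify_gene <- function(measurements, bias_threshold = 70, alpha = 0.01,
                          gene_id = NA_character_) {
  res <- function(call, leakage = NA_real_, reason = NA_character_) {
    structure(list(gene_id = gene_id, call = call,
                   n_by_cross = table(factor(measurements$cross_type)),
                   leakage = leakage, reason = reason,
                   animals = measurements),
              class = "imprint_call")
  }
  if (is.null(measurements) || nrow(measurements) == 0L) {
    return(res("undetermined", reason = "no informative animals"))
  }
  mf <- measurements$maternal_fraction
  sig <- rep(TRUE, nrow(measurements))
  if (all(c("maternal_count", "total_count") %in% names(measurements))) {
    sig <- mapply(function(x, n) {
      stats::binom.test(round(x), round(n), p = 0.5)$p.value <= alpha
    }, measurements$maternal_count, measurements$total_count)
  }
  maternal_biased <- mf >= bias_threshold & sig
  paternal_biased <- mf <= 100 - bias_threshold & sig
  unbiased <- !maternal_biased & !paternal_biased
  crosses <- unique(measurements$cross_type)
  if (all(unbiased)) return(res("biallelic"))
  if (length(crosses) < 2L) {
    return(res("undetermined",
               reason = "informative animals in only one cross direction"))
  }
  if (all(maternal_biased)) {
    return(res("imprinted_maternal_expressed", leakage = mean(100 - mf)))
  }
  if (all(paternal_biased)) {
    return(res("imprinted_paternal_expressed", leakage = mean(mf)))
  }
  # allele-identity check: express each animal's bias as the fraction of
  # one reference stock's allele and test whether it tracks the stock
  stock0 <- measurements$maternal_stock[1]
  f_stock <- ifelse(measurements$maternal_stock == stock0, mf, 100 - mf)
  if (all(f_stock >= bias_threshold & sig)) {
    return(res("allele_biased", leakage = mean(100 - f_stock)))
  }
  if (all(f_stock <= 100 - bias_threshold & sig)) {
    return(res("allele_biased", leakage = mean(f_stock)))
  }
  res("undetermined", reason = "conflicting per-animal bias pattern")
}

#' @export
print.imprint_call <- function(x, ...) {
  cat(sprintf("gene %s: %s", x$gene_id, x$call))
  if (!is.na(x$leakage)) {
    cat(sprintf(" (repressed-allele leakage %.1f%%)", x$leakage))
  }
  if (!is.na(x$reason)) cat(sprintf(" [%s]", x$reason))
  cat("\n")
  invisible(x)
}
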