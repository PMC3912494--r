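#' Build per-promoter histone-mark profiles
#'
#' For every gene, derives the putative promoter and records whether it
#' overlaps (by at least one base) a significant peak of each of H3K4me3,
#' H3K9Ac and H3K9me3, and an annotated CpG island; genes carrying all
#' three marks are additionally tested with the strict
#' [full_overlap_tier()]. The chromosome class flags genes on declared
#' haploid chromosomes.
#'
#' @param ann [annotation()] object.
#' @param peaksets named list of interval data.frames containing exactly
#'   the marks \code{H3K4me3}, \code{H3K9Ac}, \code{H3K9me3} (additional
#'   marks, e.g. a diffuse H3K27me3 set kept for diagnostics, are ignored
#'   by selection).
#' @param cfg [promoter_config()].
#' @return data.frame with one row per gene: \code{gene_id}, promoter
#'   coordinates, \code{has_k4me3}, \code{has_k9ac}, \code{has_k9me3},
#'   \code{has_cpg}, \code{full_overlap}, \code{chrom_class}.
#' @export
profile_promoters <- function(ann, peaksets, cfg = promoter_config()) {
  marks <- c("H3K4me3", "H3K9Ac", "H3K9me3")
  miss <- setdiff(marks, names(peaksets))
  if (length(miss)) fail("missing peak set for mark '%s'", miss[1])
  prom <- derive_promoters(ann$genes, cfg, ann$chrom_lengths)
  has <- lapply(peaksets[marks], function(s) overlaps_any(prom, s))
  has_cpg <- overlaps_any(prom, ann$cpg_islands)
  all3 <- has[[1]] & has[[2]] & has[[3]]
  full <- logical(nrow(prom))
  for (i in which(all3)) {
    full[i] <- full_overlap_tier(prom[i, , drop = FALSE], peaksets[marks])
  }
  data.frame(
    gene_id = prom$gene_id,
    chrom = prom$chrom,
    promoter_start = prom$start,
    promoter_end = prom$end,
    has_k4me3 = has[[1]],
    has_k9ac = has[[2]],
    has_k9me3 = has[[3]],
    has_cpg = has_cpg,
    full_overlap = full,
    chrom_class = ifelse(prom$chrom %in% ann$haploid_chroms,
                         "haploid", "autosome"),
    stringsAsFactors = FALSE
  )
}

#' Select candidate-imprinted genes
#'
#' A gene is a candidate iff its promoter is concurrently marked by
#' significant H3K4me3, H3K9Ac and H3K9me3 peaks and contains an annotated
#' CpG island. Known-imprinted genes that lack the signature can be carried
#' forward via \code{force_include} (they are appended after the screened
#' candidates and never satisfy the boolean criterion themselves).
#'
#' @param profiles output of [profile_promoters()].
#' @param force_include gene ids appended regardless of profile.
#' @return character vector of gene ids in stable (input) order.
#' @export
select_candidates <- function(profiles, force_include = character()) {
  sel <- profiles$gene_id[profiles$has_k4me3 & profiles$has_k9ac &
                            profiles$has_k9me3 & profiles$has_cpg]
  c(sel, setdiff(force_include, sel))
}

#' Haploid-chromosome internal control
#'
#' In cells with a single copy of a chromosome (e.g. the X of a male),
#' every expressed gene is effectively monoallelic, so a well-behaved
#' screen must call no candidates there; any hit signals a false-positive
#' process. Returns the offending candidates (empty = control passed).
#'
#' @param candidates character vector of candidate gene ids.
#' @param ann [annotation()] object with \code{haploid_chroms} declared.
#' @return character vector of violating gene ids.
#' @export
haploid_control_check <- function(candidates, ann) {
  if (!length(ann$haploid_chroms)) {
    warning("no haploid chromosomes declared; control check is vacuous",
            call. = FALSE)
    return(character())
  }
  g <- ann$genes
  bad <- g$gene_id[g$gene_id %in% candidates &
                     g$chrom %in% ann$haploid_chroms]
  bad
}

#' Genomic distribution of a peak set
#'
#' Assigns each peak to the first matching category in the priority order
#' promoter > genic > intergenic and reports category fractions (a
#' diagnostic used, e.g., to recognize diffuse marks that mostly occupy
#' intergenic space and are useless for promoter screening).
#'
#' @param peaks interval data.frame.
#' @param ann [annotation()] object.
#' @param cfg [promoter_config()] defining the promoter windows.
#' @return named numeric vector of fractions over
#'   \code{c(promoter, genic, intergenic)}; sums to 1.
#' @export
mark_distribution <- function(peaks, ann, cfg = promoter_config()) {
  if (nrow(peaks) == 0L) fail("mark_distribution: empty peak set")
  prom <- derive_promoters(ann$genes, cfg, ann$chrom_lengths)
  in_prom <- overlaps_any(peaks, prom)
  in_gene <- overlaps_any(peaks, ann$genes) & !in_prom
  n <- nrow(peaks)
  c(promoter = sum(in_prom) / n,
    genic = sum(in_gene) / n,
    intergenic = (n - sum(in_prom) - sum(in_gene)) / n)
}

#' Nested filter-layer totals for the candidate screen
#'
#' Layers: all promoters; marked by H3K4me3; H3K4me3 plus CpG island; all
#' three marks plus CpG island (the candidate criterion); candidates in the
#' strict full-overlap tier. Layer counts are checked to be monotonically
#' non-increasing on every call.
#'
#' @param profiles output of [profile_promoters()].
#' @return list of class \code{screen_summary} with \code{layers} (named
#'   integer vector) and \code{per_chrom} (candidate counts by chromosome).
#' @export
screen_summary <- function(profiles) {
  cand <- profiles$has_k4me3 & profiles$has_k9ac & profiles$has_k9me3 &
    profiles$has_cpg
  layers <- c(
    promoters = nrow(profiles),
    k4me3 = sum(profiles$has_k4me3),
    k4me3_cpg = sum(profiles$has_k4me3 & profiles$has_cpg),
    all_marks_cpg = sum(cand),
    full_overlap = sum(cand & profiles$full_overlap)
  )
  if (any(diff(layers) > 0)) fail("screen layers are not nested")
  per_chrom <- table(profiles$chrom[cand])
  structure(list(layers = layers,
                 per_chrom = stats::setNames(as.integer(per_chrom),
                                             names(per_chrom))),
            class = "screen_summary")
}

#' Write a screen summary as JSON
#'
#' @param s a \code{screen_summary} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_screen_summary <- function(s, path) {
  jsonlite::write_json(list(layers = as.list(s$layers),
                            per_chrom = as.list(s$per_chrom)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
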