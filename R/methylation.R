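#' Describe a bisulfite PCR amplicon
#'
#' Bisulfite treatment deaminates unmethylated cytosines to uracil (read as
#' T), while methylated CpG cytosines stay C; a sequenced clone therefore
#' reports per-CpG methylation, and the non-CpG cytosines double as a
#' conversion-efficiency control. CpG positions are auto-detected from the
#' reference when not given. An optional phasing SNP inside the amplicon
#' lets clones be partitioned by allele.
#'
#' @param region single-row interval data.frame (genomic location).
#' @param ref_seq reference sequence of the amplicon (character).
#' @param cpg_offsets 0-based offsets within the amplicon of CpG cytosines;
#'   each must point at a C followed by G.
#' @param snp_offset optional 0-based offset of a phasing SNP.
#' @param snp_alleles length-2 character vector of the SNP alleles
#'   (required with \code{snp_offset}).
#' @return list of class \code{bisulfite_amplicon}.
#' @export
bisulfite_amplicon <- function(region, ref_seq, cpg_offsets = NULL,
                               snp_offset = NULL, snp_alleles = NULL) {
  ref_seq <- toupper(ref_seq)
  chars <- strsplit(ref_seq, "")[[1]]
  if (is.null(cpg_offsets)) {
    hits <- gregexpr("CG", ref_seq, fixed = TRUE)[[1]]
    cpg_offsets <- if (hits[1] == -1) integer() else as.integer(hits - 1L)
  }
  if (!length(cpg_offsets)) fail("amplicon contains no CpG dinucleotides")
  bad <- which(chars[cpg_offsets + 1] != "C" |
                 chars[cpg_offsets + 2] != "G")
  if (length(bad)) {
    fail("cpg offset %d does not point at a CpG", cpg_offsets[bad[1]])
  }
  if (!is.null(snp_offset) &&
      (is.null(snp_alleles) || length(snp_alleles) != 2L)) {
    fail("snp_offset requires exactly two snp_alleles")
  }
  structure(list(region = region, ref_seq = ref_seq,
                 cpg_offsets = as.integer(cpg_offsets),
                 snp_offset = snp_offset,
                 snp_alleles = toupper(snp_alleles)),
            class = "bisulfite_amplicon")
}

#' Tabulate aligned bisulfite clones into a methylation matrix
#'
#' At each CpG cytosine, C is read as methylated, T as unmethylated,
#' anything else as missing. Per-clone conversion efficiency is the
#' fraction of non-CpG reference cytosines read as T; clones under
#' \code{min_conversion} are flagged and excluded from downstream
#' summaries. When the amplicon carries a phasing SNP, each clone is
#' labeled with the allele its SNP base matches.
#'
#' @param amplicon [bisulfite_amplicon()].
#' @param clone_seqs character vector (or Biostrings XStringSet) of clone
#'   sequences gaplessly aligned to the amplicon reference (same length).
#' @param min_conversion minimum conversion efficiency (default 0.98).
#' @return list of class \code{methylation_matrix}: \code{calls} (clones x
#'   CpGs; 1 methylated, 0 unmethylated, NA missing), \code{conversion},
#'   \code{excluded}, \code{allele}, \code{cpg_offsets}.
#' @export
tabulate_clones <- function(amplicon, clone_seqs, min_conversion = 0.98) {
  stopifnot(inherits(amplicon, "bisulfite_amplicon"))
  clone_seqs <- toupper(as.character(clone_seqs))
  if (!length(clone_seqs)) fail("no clone sequences supplied")
  ref_len <- nchar(amplicon$ref_seq)
  if (any(nchar(clone_seqs) != ref_len)) {
    fail("clone %d length differs from the amplicon reference",
         which(nchar(clone_seqs) != ref_len)[1])
  }
  ref_chars <- strsplit(amplicon$ref_seq, "")[[1]]
  non_cpg_c <- setdiff(which(ref_chars == "C"), amplicon$cpg_offsets + 1L)
  if (!is.null(amplicon$snp_offset)) {
    non_cpg_c <- setdiff(non_cpg_c, amplicon$snp_offset + 1L)
  }
  mat <- matrix(NA_integer_, nrow = length(clone_seqs),
                ncol = length(amplicon$cpg_offsets),
                dimnames = list(names(clone_seqs) %||%
                                  paste0("clone_", seq_along(clone_seqs)),
                                NULL))
  conversion <- numeric(length(clone_seqs))
  allele <- rep(NA_character_, length(clone_seqs))
  for (i in seq_along(clone_seqs)) {
    chars <- strsplit(clone_seqs[i], "")[[1]]
    base <- chars[amplicon$cpg_offsets + 1L]
    mat[i, ] <- ifelse(base == "C", 1L, ifelse(base == "T", 0L, NA))
    ctrl <- chars[non_cpg_c]
    informative <- ctrl %in% c("C", "T")
    conversion[i] <- if (any(informative)) {
      sum(ctrl == "T") / sum(informative)
    } else NA_real_
    if (!is.null(amplicon$snp_offset)) {
      sb <- chars[amplicon$snp_offset + 1L]
      if (sb %in% amplicon$snp_alleles) allele[i] <- sb
    }
  }
  structure(list(calls = mat, conversion = conversion,
                 excluded = !is.na(conversion) &
                   conversion < min_conversion,
                 allele = allele,
                 cpg_offsets = amplicon$cpg_offsets),
            class = "methylation_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruct bisulfite-read sequences from a methylation matrix
#'
#' Inverse of [tabulate_clones()] for fully called clones: every non-CpG
#' cytosine is written as converted (T), each CpG cytosine as C or T per
#' the call, and the phasing SNP base per the allele label. Used by the
#' clone simulator and by round-trip checks.
#'
#' @param amplicon [bisulfite_amplicon()].
#' @param calls clones x CpGs 0/1 matrix.
#' @param allele optional per-clone allele labels.
#' @return character vector of sequences.
#' @export
clones_from_matrix <- function(amplicon, calls, allele = NULL) {
  ref_chars <- strsplit(amplicon$ref_seq, "")[[1]]
  conv <- ref_chars
  conv[conv == "C"] <- "T"
  conv[amplicon$cpg_offsets + 1L] <- "C"   # restored below per call
  vapply(seq_len(nrow(calls)), function(i) {
    chars <- conv
    chars[amplicon$cpg_offsets + 1L] <-
      ifelse(calls[i, ] == 1L, "C", "T")
    if (!is.null(amplicon$snp_offset) && !is.null(allele) &&
        !is.na(allele[i])) {
      chars[amplicon$snp_offset + 1L] <- allele[i]
    }
    paste(chars, collapse = "")
  }, character(1))
}

#' Summarize regional methylation state
#'
#' Per-CpG methylated fractions are computed over clones passing the
#' conversion QC; the region status comes from the mean per-CpG fraction:
#' at most \code{hypo} is hypomethylated, at least \code{hyper} is
#' hypermethylated, otherwise intermediate.
#'
#' @param mat \code{methylation_matrix}.
#' @param hypo,hyper thresholds on the mean fraction (defaults 0.2 / 0.8).
#' @return list with \code{per_cpg} (fractions), \code{mean_fraction},
#'   \code{status}, \code{n_clones}.
#' @export
summarize_region <- function(mat, hypo = 0.2, hyper = 0.8) {
  keep <- !mat$excluded
  if (!any(keep)) fail("all clones excluded by conversion QC")
  m <- mat$calls[keep, , drop = FALSE]
  per_cpg <- colMeans(m, na.rm = TRUE)
  mean_fraction <- mean(per_cpg, na.rm = TRUE)
  status <- if (mean_fraction <= hypo) "hypomethylated"
  else if (mean_fraction >= hyper) "hypermethylated"
  else "intermediate"
  list(per_cpg = per_cpg, mean_fraction = mean_fraction,
       status = status, n_clones = sum(keep))
}

#' Allele-partitioned differential-methylation test
#'
#' Clones are split by the phasing-SNP allele; at each CpG a 2x2 exact test
#' (methylated/unmethylated x allele) is computed as the one-sided
#' hypergeometric tail in the direction of the overall observed
#' methylation difference, with Benjamini-Hochberg correction across CpGs.
#' The region is called a DMR iff more than half the CpGs pass the
#' adjusted \code{alpha} and the mean per-CpG fraction difference between
#' alleles is at least \code{min_diff}. Without a phasing SNP, or with
#' fewer than \code{min_clones} passing clones on either allele, the
#' verdict is \code{not_assessable}.
#'
#' @param mat \code{methylation_matrix} with allele labels.
#' @param alpha adjusted-p threshold (default 0.01).
#' @param min_diff minimum mean fraction difference (default 0.5).
#' @param min_clones minimum passing clones per allele (default 5).
#' @return list with \code{verdict} in \code{c("dmr", "no_dmr",
#'   "not_assessable")}, \code{per_cpg} (data.frame of fractions, p and
#'   adjusted p) and \code{mean_diff}.
#' @export
allele_dmr_test <- function(mat, alpha = 0.01, min_diff = 0.5,
                            min_clones = 5) {
  keep <- !mat$excluded & !is.na(mat$allele)
  alleles <- sort(unique(mat$allele[keep]))
  if (length(alleles) < 2L) {
    return(list(verdict = "not_assessable", per_cpg = NULL,
                mean_diff = NA_real_,
                reason = "no phasing SNP partitions the clones"))
  }
  ga <- keep & mat$allele == alleles[1]
  gb <- keep & mat$allele == alleles[2]
  if (sum(ga) < min_clones || sum(gb) < min_clones) {
    return(list(verdict = "not_assessable", per_cpg = NULL,
                mean_diff = NA_real_,
                reason = "too few clones on one allele"))
  }
  ma <- mat$calls[ga, , drop = FALSE]
  mb <- mat$calls[gb, , drop = FALSE]
  fa <- colMeans(ma, na.rm = TRUE)
  fb <- colMeans(mb, na.rm = TRUE)
  dir_a_higher <- mean(fa - fb, na.rm = TRUE) >= 0
  p <- vapply(seq_len(ncol(ma)), function(j) {
    xa <- sum(ma[, j] == 1L, na.rm = TRUE)
    na_ <- sum(!is.na(ma[, j]))
    xb <- sum(mb[, j] == 1L, na.rm = TRUE)
    nb_ <- sum(!is.na(mb[, j]))
    if (na_ == 0 || nb_ == 0) return(NA_real_)
    # one-sided hypergeometric tail for the 2x2 table, in the overall
    # direction: P(methylated on the higher allele >= observed | margins)
    if (dir_a_higher) {
      stats::phyper(xa - 1, xa + xb, na_ + nb_ - xa - xb, na_,
                    lower.tail = FALSE)
    } else {
      stats::phyper(xb - 1, xa + xb, na_ + nb_ - xa - xb, nb_,
                    lower.tail = FALSE)
    }
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  mean_diff <- abs(mean(fa - fb, na.rm = TRUE))
  n_pass <- sum(padj <= alpha, na.rm = TRUE)
  verdict <- if (n_pass > sum(!is.na(padj)) / 2 && mean_diff >= min_diff) {
    "dmr"
  } else "no_dmr"
  list(verdict = verdict,
       per_cpg = data.frame(fraction_a = fa, fraction_b = fb,
                            p = p, p_adj = padj),
       mean_diff = mean_diff,
       alleles = alleles)
}

#' Lollipop-style methylation plot
#'
#' One row per passing clone, one circle per CpG: filled = methylated,
#' open = unmethylated, absent = missing call.
#'
#' @param mat \code{methylation_matrix}.
#' @param main plot title.
#' @return invisibly, the plotted call matrix.
#' @export
plot_methylation <- function(mat, main = "CpG methylation") {
  m <- mat$calls[!mat$excluded, , drop = FALSE]
  nc <- ncol(m)
  nr <- nrow(m)
  graphics::plot(NULL, xlim = c(0.5, nc + 0.5), ylim = c(0.5, nr + 0.5),
                 xlab = "CpG site", ylab = "clone", main = main,
                 axes = FALSE)
  graphics::axis(1, at = seq_len(nc))
  graphics::axis(2, at = seq_len(nr), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.6)
  for (i in seq_len(nr)) {
    y <- nr - i + 1
    graphics::lines(c(1, nc), c(y, y), col = "grey70")
    called <- which(!is.na(m[i, ]))
    graphics::points(called, rep(y, length(called)), pch = 21,
                     bg = ifelse(m[i, called] == 1L, "black", "white"),
                     cex = 1.2)
  }
  invisible(m)
}
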