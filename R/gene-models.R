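#' Read gene models from GTF gene rows or a minimal TSV
#'
#' GTF coordinates (1-based, closed) are converted to the internal 0-based
#' half-open convention on read. The minimal TSV format carries one row per
#' gene with columns \code{gene_id}, \code{chrom}, \code{strand},
#' \code{tss} and optionally \code{start}, \code{end}, \code{expressed};
#' when the gene body is absent the model is stored as the 1-base interval
#' at the TSS. The TSS is the strand-aware 5' end: \code{start} on the plus
#' strand, \code{end - 1} on the minus strand.
#'
#' Expression state is an input flag (it is not computed here); for GTF
#' input pass the expressed gene ids via \code{expressed_ids}.
#'
#' @param path file path.
#' @param format \code{"gtf"} or \code{"tsv"}.
#' @param expressed_ids character vector of gene ids flagged as expressed
#'   (used for GTF, or for TSV files lacking an \code{expressed} column).
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{tss}, \code{expressed},
#'   sorted by (chrom, start).
#' @export
read_gene_models <- function(path, format = c("gtf", "tsv"),
                             expressed_ids = character()) {
  format <- match.arg(format)
  if (!file.exists(path)) fail("file not found: %s", path)
  if (format == "gtf") {
    lines <- readLines(path)
    keep <- which(nzchar(lines) & !startsWith(lines, "#"))
    if (!length(keep)) return(empty_gene_models())
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 9)) {
      fail("%s line %d: expected 9 tab-separated GTF fields",
           path, keep[which(nf < 9)[1]])
    }
    feat <- vapply(fields, `[[`, "", 3L)
    gene_rows <- which(feat == "gene")
    if (!length(gene_rows)) return(empty_gene_models())
    fields <- fields[gene_rows]
    lineno <- keep[gene_rows]
    start1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
    end1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    strand <- vapply(fields, `[[`, "", 7L)
    attrs <- vapply(fields, `[[`, "", 9L)
    m <- regmatches(attrs, regexpr('gene_id "[^"]+"', attrs))
    bad <- which(is.na(start1) | is.na(end1) | start1 > end1 |
                   !strand %in% c("+", "-") |
                   !grepl('gene_id "', attrs, fixed = TRUE))
    if (length(bad)) fail("%s line %d: malformed gene row", path,
                          lineno[bad[1]])
    gene_id <- sub('gene_id "([^"]+)"', "\\1", m)
    df <- data.frame(
      gene_id = gene_id,
      chrom = vapply(fields, `[[`, "", 1L),
      start = start1 - 1,          # 1-based closed -> 0-based half-open
      end = end1,
      strand = strand,
      stringsAsFactors = FALSE
    )
    df$expressed <- df$gene_id %in% expressed_ids
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss")
    miss <- setdiff(need, names(df))
    if (length(miss)) fail("%s: missing column '%s'", path, miss[1])
    bad <- which(is.na(df$tss) | !df$strand %in% c("+", "-"))
    if (length(bad)) fail("%s line %d: malformed gene row", path,
                          bad[1] + 1L)  # +1 for the header line
    if (!"start" %in% names(df)) {
      df$start <- ifelse(df$strand == "+", df$tss, df$tss)
      df$end <- df$tss + 1
    }
    if (!"expressed" %in% names(df)) {
      df$expressed <- df$gene_id %in% expressed_ids
    }
    df$expressed <- as.logical(df$expressed)
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) fail("%s: duplicate gene_id '%s'", path, dup[1])
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df <- df[order(df$chrom, df$start), c("gene_id", "chrom", "start", "end",
                                        "strand", "tss", "expressed")]
  rownames(df) <- NULL
  validate_intervals(df, what = "gene model")
  df
}

empty_gene_models <- function() {
  data.frame(gene_id = character(), chrom = character(), start = numeric(),
             end = numeric(), strand = character(), tss = numeric(),
             expressed = logical(), stringsAsFactors = FALSE)
}

#' Promoter-window configuration
#'
#' The putative promoter is the window from \code{upstream} bases upstream
#' to \code{downstream} bases downstream of the annotated transcription
#' start site (defaults 5000 and 500).
#'
#' @param upstream,downstream non-negative base counts; not both zero.
#' @return list of class \code{promoter_config}.
#' @export
promoter_config <- function(upstream = 5000, downstream = 500) {
  if (upstream < 0 || downstream < 0 || (upstream == 0 && downstream == 0)) {
    fail("promoter window must be non-negative and non-empty")
  }
  structure(list(upstream = upstream, downstream = downstream),
            class = "promoter_config")
}

#' Derive strand-aware putative promoters
#'
#' On the plus strand the promoter is \code{[tss - upstream, tss +
#' downstream)}; on the minus strand it is the mirror image \code{[tss -
#' downstream + 1, tss + upstream + 1)}. Windows are clipped to the
#' chromosome.
#'
#' @param genes gene-model data.frame (see [read_gene_models()]).
#' @param cfg [promoter_config()].
#' @param chrom_lengths named vector of chromosome lengths.
#' @return interval data.frame with a \code{gene_id} column, one promoter
#'   per gene, in the input gene order.
#' @examples
#' g <- data.frame(gene_id = "g1", chrom = "chr1", start = 10000,
#'                 end = 12000, strand = "+", tss = 10000, expressed = TRUE)
#' derive_promoters(g, promoter_config(), c(chr1 = 1e6))
#' @export
derive_promoters <- function(genes, cfg = promoter_config(),
                             chrom_lengths = NULL) {
  stopifnot(inherits(cfg, "promoter_config"))
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - cfg$upstream,
                  genes$tss - cfg$downstream + 1)
  end <- ifelse(plus, genes$tss + cfg$downstream,
                genes$tss + cfg$upstream + 1)
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[genes$chrom]
    if (anyNA(len)) {
      fail("gene '%s' lies on an unknown chromosome",
           genes$gene_id[which(is.na(len))[1]])
    }
    if (any(genes$tss < 0 | genes$tss >= len)) {
      fail("gene '%s' has a TSS outside its chromosome",
           genes$gene_id[which(genes$tss < 0 | genes$tss >= len)[1]])
    }
    end <- pmin(end, len)
  }
  if (any(start >= end)) {
    fail("promoter of gene '%s' is empty after clipping",
         genes$gene_id[which(start >= end)[1]])
  }
  df <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                   start = start, end = end, strand = genes$strand,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  validate_intervals(df, what = "promoter")
  df
}

#' Bundle genes, CpG islands and chromosome metadata
#'
#' @param genes gene-model data.frame.
#' @param cpg_islands interval data.frame of annotated CpG islands.
#' @param chrom_lengths named numeric vector.
#' @param haploid_chroms chromosomes present in a single copy in the
#'   assayed cells (e.g. the X of a male), used as the internal control: no
#'   candidate-imprinted gene should lie on them.
#' @return list of class \code{annotation}.
#' @export
annotation <- function(genes, cpg_islands, chrom_lengths,
                       haploid_chroms = character()) {
  validate_intervals(genes, chrom_lengths, what = "gene model")
  validate_intervals(cpg_islands, chrom_lengths, what = "CpG island")
  extra <- setdiff(haploid_chroms, names(chrom_lengths))
  if (length(extra)) fail("haploid chromosome '%s' not in chrom_lengths",
                          extra[1])
  structure(list(genes = genes, cpg_islands = sort_intervals(cpg_islands),
                 chrom_lengths = chrom_lengths,
                 haploid_chroms = haploid_chroms),
            class = "annotation")
}
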