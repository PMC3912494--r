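#' Binned fragment-coverage track
#'
#' Coverage is stored as fragment counts per fixed-width bin, one vector per
#' chromosome. This is the substrate the peak caller scores; read-level
#' processing (alignment, duplicate filtering, fragment-shift modeling) is
#' upstream of the package.
#'
#' @param counts named list of non-negative count vectors, one per
#'   chromosome.
#' @param bin_width bin width in bases.
#' @return list of class \code{coverage_track} with \code{counts},
#'   \code{bin_width} and \code{total_fragments}.
#' @export
coverage_track <- function(counts, bin_width) {
  if (!is.list(counts) || is.null(names(counts)) || !length(counts)) {
    fail("counts must be a non-empty named list of per-chromosome vectors")
  }
  if (any(vapply(counts, function(x) any(x < 0 | is.na(x)), logical(1)))) {
    fail("coverage counts must be non-negative")
  }
  structure(list(counts = lapply(counts, as.numeric),
                 bin_width = bin_width,
                 total_fragments = sum(vapply(counts, sum, numeric(1)))),
            class = "coverage_track")
}

#' Peak-caller configuration
#'
#' Defaults follow common narrow-peak calling practice: 50-bp bins, local
#' background windows of 5 and 10 kb, significance threshold p <= 1e-5,
#' significant bins merged across gaps of up to 100 bp, and peaks shorter
#' than 200 bp discarded. \code{lambda_floor} is a pseudocount rate (counts
#' per bin, applied after depth scaling) that prevents p = 0 artifacts over
#' empty control regions.
#'
#' @param p_threshold significance threshold on the Poisson upper tail.
#' @param bin_width bin width in bases.
#' @param local_scales window widths (bases) for local background rates.
#' @param merge_gap maximum gap (bases) across which significant windows
#'   are merged.
#' @param min_length minimum peak length in bases.
#' @param lambda_floor minimum expected count per bin.
#' @return list of class \code{peak_caller_config}.
#' @export
peak_caller_config <- function(p_threshold = 1e-5, bin_width = 50,
                               local_scales = c(5000, 10000),
                               merge_gap = 100, min_length = 200,
                               lambda_floor = 0.1) {
  if (p_threshold <= 0 || p_threshold >= 1) fail("p_threshold must be in (0,1)")
  if (any(local_scales <= bin_width)) {
    fail("local background scales must exceed the bin width")
  }
  structure(list(p_threshold = p_threshold, bin_width = bin_width,
                 local_scales = local_scales, merge_gap = merge_gap,
                 min_length = min_length, lambda_floor = lambda_floor),
            class = "peak_caller_config")
}

#' Poisson upper-tail probability P(X >= count)
#'
#' Survival function of the Poisson distribution, numerically stable down
#' to p ~ 1e-300 (computed in the upper tail, not as 1 - CDF).
#'
#' @param count observed count(s), >= 0.
#' @param lam expected count(s), > 0.
#' @return probability vector.
#' @examples
#' poisson_sf(10, 1)  # ~1.11e-7
#' @export
poisson_sf <- function(count, lam) {
  if (any(lam <= 0)) fail("poisson_sf: lam must be > 0")
  if (any(count < 0)) fail("poisson_sf: count must be >= 0")
  stats::ppois(count - 1, lam, lower.tail = FALSE)
}

# Internal: centered running mean over a window of `k` bins, truncated at
# the chromosome ends (partial windows use the bins that exist).
running_mean <- function(x, k) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- floor(k / 2)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Internal: per-bin expected treatment count for one chromosome.
# max(genome-wide control rate, each local-scale control rate) scaled by
# treat_total / control_total, floored at the pseudocount rate.
lambda_per_bin <- function(ctrl_counts, genome_rate, cfg, depth_ratio) {
  lam <- rep(genome_rate, length(ctrl_counts))
  for (w in cfg$local_scales) {
    k <- max(1L, round(w / cfg$bin_width))
    lam <- pmax(lam, running_mean(ctrl_counts, k))
  }
  pmax(lam * depth_ratio, cfg$lambda_floor)
}

#' Local background rate for one window
#'
#' Expected treatment fragment count over a window: the maximum of the
#' genome-wide control rate and the control rates over each local scale
#' centered on the window, scaled by sequencing-depth ratio and window
#' length, floored at the pseudocount rate.
#'
#' @param control \code{coverage_track} of the input/control sample.
#' @param window single-row interval data.frame.
#' @param cfg [peak_caller_config()].
#' @param treat_total treatment fragment total used for depth scaling.
#' @return expected count (lambda) for the window.
#' @export
local_lambda <- function(control, window, cfg = peak_caller_config(),
                         treat_total = control$total_fragments) {
  cc <- control$counts[[window$chrom]]
  if (is.null(cc) || !length(cc)) fail("control has no bins on %s",
                                       window$chrom)
  n_bins_total <- sum(lengths(control$counts))
  genome_rate <- control$total_fragments / n_bins_total
  bw <- control$bin_width
  b0 <- floor(window$start / bw) + 1L
  b1 <- ceiling(window$end / bw)
  center <- floor((b0 + b1) / 2)
  rate <- genome_rate
  for (w in cfg$local_scales) {
    k <- max(1L, round(w / bw))
    half <- floor(k / 2)
    lo <- max(1L, center - half)
    hi <- min(length(cc), center + half)
    rate <- max(rate, mean(cc[lo:hi]))
  }
  ratio <- treat_total / control$total_fragments
  window_bins <- b1 - b0 + 1L
  max(rate * ratio, cfg$lambda_floor) * window_bins
}

#' Call significant enrichment peaks from treatment vs input coverage
#'
#' Every bin is scored with [poisson_sf()] against a local-background
#' expectation from the control track (maximum of genome-wide and local
#' rates, depth-scaled). Significant bins (p <= threshold) are merged when
#' separated by gaps of at most \code{merge_gap} bases, and merged peaks
#' shorter than \code{min_length} are dropped. Output is deterministic,
#' sorted and non-overlapping within a mark.
#'
#' @param treatment,control \code{coverage_track}s on the same chromosomes
#'   with the same bin width.
#' @param cfg [peak_caller_config()].
#' @return interval data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{min_p} (smallest bin p-value),
#'   \code{summit} (offset from peak start of the maximum-count bin).
#' @export
call_peaks <- function(treatment, control, cfg = peak_caller_config()) {
  if (treatment$bin_width != control$bin_width ||
      treatment$bin_width != cfg$bin_width) {
    fail("treatment, control and config bin widths must match")
  }
  if (!setequal(names(treatment$counts), names(control$counts))) {
    fail("treatment and control cover different chromosomes")
  }
  n_bins_total <- sum(lengths(control$counts))
  genome_rate <- control$total_fragments / n_bins_total
  ratio <- treatment$total_fragments / control$total_fragments
  bw <- cfg$bin_width
  out <- list()
  for (ch in sort(names(treatment$counts))) {
    tr <- treatment$counts[[ch]]
    cc <- control$counts[[ch]]
    if (length(tr) != length(cc)) {
      fail("mismatched bin counts on %s", ch)
    }
    lam <- lambda_per_bin(cc, genome_rate, cfg, ratio)
    p <- poisson_sf(tr, lam)
    sig <- which(p <= cfg$p_threshold)
    if (!length(sig)) next
    gap_bins <- max(0L, floor(cfg$merge_gap / bw))
    brk <- which(diff(sig) > gap_bins + 1L)
    run_start <- sig[c(1L, brk + 1L)]
    run_end <- sig[c(brk, length(sig))]
    for (r in seq_along(run_start)) {
      bins <- run_start[r]:run_end[r]
      start <- (run_start[r] - 1L) * bw
      end <- run_end[r] * bw
      if (end - start < cfg$min_length) next
      max_bin <- bins[which.max(tr[bins])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = start, end = end, strand = ".",
        min_p = min(p[bins]),
        summit = (max_bin - 1L) * bw - start,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      min_p = numeric(), summit = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write peaks in narrowPeak-style BED6+ format
#'
#' Columns: chrom, start, end, name, -log10(p) score, strand ".",
#' summit offset.
#'
#' @param peaks output of [call_peaks()].
#' @param path output path.
#' @param label name stem for the peak ids.
#' @return \code{path}, invisibly.
#' @export
write_peaks <- function(peaks, path, label = "peak") {
  score <- round(-log10(pmax(peaks$min_p, 1e-300)), 2)
  out <- data.frame(peaks$chrom,
                    format(peaks$start, scientific = FALSE, trim = TRUE),
                    format(peaks$end, scientific = FALSE, trim = TRUE),
                    paste0(label, "_", seq_len(nrow(peaks))),
                    score, ".",
                    format(peaks$summit, scientific = FALSE, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
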