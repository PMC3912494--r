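#' Do two intervals overlap?
#'
#' Two features overlap iff they share at least one base: same chromosome
#' and \code{max(starts) < min(ends)} under the half-open convention.
#' Abutting intervals do not overlap. Strand is ignored everywhere in the
#' engine (histone peaks are unstranded).
#'
#' @param a,b single-row interval data.frames (or equal-length tables,
#'   compared elementwise).
#' @return logical vector.
#' @examples
#' interval_overlaps(gintervals("chr1", 0, 10), gintervals("chr1", 9, 20))
#' @export
interval_overlaps <- function(a, b) {
  a$chrom == b$chrom & pmax(a$start, b$start) < pmin(a$end, b$end)
}

# Internal: logical vector over rows of `a`: does each a-interval overlap
# at least one b-interval?  IRanges per chromosome; 1-based closed ranges
# [start+1, end] represent half-open [start, end) exactly.
overlaps_any <- function(a, b) {
  hit <- logical(nrow(a))
  if (nrow(a) == 0L || nrow(b) == 0L) return(hit)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    ra <- IRanges::IRanges(a$start[ia] + 1, a$end[ia])
    rb <- IRanges::IRanges(b$start[ib] + 1, b$end[ib])
    hit[ia] <- IRanges::overlapsAny(ra, rb)
  }
  hit
}

#' Count source intervals of one set overlapping another
#'
#' Counting is per source interval (an A peak counts once however many B
#' peaks it touches), matching how peak-overlap totals are reported; merged
#' regions are never formed. The reported percentage is rounded to the
#' nearest integer, ties away from zero.
#'
#' @param a_set,b_set interval data.frames.
#' @return list with \code{count} (A intervals overlapping >= 1 B interval)
#'   and \code{percent} (rounded; 0 with a warning when \code{a_set} is
#'   empty).
#' @export
count_overlapping <- function(a_set, b_set) {
  if (nrow(a_set) == 0L) {
    warning("empty query set: percent overlap undefined, reporting 0",
            call. = FALSE)
    return(list(count = 0L, percent = 0))
  }
  n <- sum(overlaps_any(a_set, b_set))
  list(count = as.integer(n),
       percent = round_half_up(100 * n / nrow(a_set)))
}

#' Which feature sets does a region co-occur with?
#'
#' @param region single-row interval data.frame.
#' @param sets named list of interval data.frames (one per mark).
#' @return named logical vector: region overlaps >= 1 interval of each set.
#' @export
cooccurs_at <- function(region, sets) {
  vapply(sets, function(s) any(overlaps_any(region, s)), logical(1))
}

#' Strict full-overlap refinement tier
#'
#' For a region co-occurring with every set, select per set the peak with
#' the longest intersection with the region, and declare full overlap iff
#' the shortest selected peak is contained in every other selected peak --
#' equivalently, the length of the joint intersection of the selected peaks
#' equals the shortest peak's length. This is the strictest notion of
#' "100\% peak overlap" that does not demand identical peak boundaries.
#' Ties on intersection length break to the leftmost, then shortest, peak.
#'
#' @param region single-row interval data.frame.
#' @param sets named list of interval data.frames.
#' @return single logical; \code{FALSE} whenever some set has no
#'   overlapping peak.
#' @examples
#' r <- gintervals("chr1", 200, 300)
#' peaks <- list(a = gintervals("chr1", 100, 500),
#'               b = gintervals("chr1", 50, 600),
#'               c = gintervals("chr1", 0, 700))
#' full_overlap_tier(r, peaks)  # nested peaks -> TRUE
#' @export
full_overlap_tier <- function(region, sets) {
  picked <- lapply(sets, function(s) {
    s <- s[s$chrom == region$chrom, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    isect <- pmin(s$end, region$end) - pmax(s$start, region$start)
    s <- s[isect > 0, , drop = FALSE]
    isect <- isect[isect > 0]
    if (nrow(s) == 0L) return(NULL)
    ord <- order(-isect, s$start, s$end - s$start)
    s[ord[1], , drop = FALSE]
  })
  if (any(vapply(picked, is.null, logical(1)))) return(FALSE)
  starts <- vapply(picked, function(p) p$start, numeric(1))
  ends <- vapply(picked, function(p) p$end, numeric(1))
  isect_len <- min(ends) - max(starts)
  shortest <- min(ends - starts)
  isect_len > 0 && isect_len == shortest
}

#' Pairwise and three-way overlap counts for three peak sets
#'
#' Counts are of source intervals, not merged regions: entry \code{(A, B)}
#' is the number of A intervals overlapping at least one B interval, so the
#' matrix is not symmetric. The three-way count, per set, is the number of
#' its intervals overlapping at least one interval of each other set.
#'
#' @param sets named list of exactly three interval data.frames.
#' @return list of class \code{venn_counts} with \code{totals} (named),
#'   \code{pairwise} (3x3 matrix, diagonal = totals) and \code{triple}
#'   (named vector).
#' @export
venn_counts <- function(sets) {
  if (length(sets) != 3L || is.null(names(sets))) {
    fail("venn_counts expects a named list of exactly three sets")
  }
  nm <- names(sets)
  totals <- vapply(sets, nrow, integer(1))
  pw <- matrix(0L, 3, 3, dimnames = list(nm, nm))
  hits <- list()
  for (i in 1:3) {
    for (j in 1:3) {
      if (i == j) {
        pw[i, j] <- totals[i]
      } else {
        h <- overlaps_any(sets[[i]], sets[[j]])
        hits[[paste(i, j)]] <- h
        pw[i, j] <- sum(h)
      }
    }
  }
  triple <- vapply(1:3, function(i) {
    others <- setdiff(1:3, i)
    sum(hits[[paste(i, others[1])]] & hits[[paste(i, others[2])]])
  }, numeric(1))
  names(triple) <- nm
  structure(list(totals = totals, pairwise = pw, triple = triple),
            class = "venn_counts")
}

#' Write Venn counts as JSON
#'
#' @param v a \code{venn_counts} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_venn_json <- function(v, path) {
  obj <- list(totals = as.list(v$totals),
              pairwise = apply(v$pairwise, 1, as.list, simplify = FALSE),
              triple = as.list(v$triple))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
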