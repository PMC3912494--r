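#' Construct a validated genomic-interval table
#'
#' All coordinates inside the package are 0-based, half-open \code{[start,
#' end)}. BED input is native to this convention; GTF input is converted on
#' read. Intervals are plain data.frames so they compose with base R; the
#' overlap engine converts to IRanges internally.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end numeric vectors, \code{0 <= start < end}.
#' @param strand character vector in \code{c("+", "-", ".")}; recycled.
#' @param ... additional columns (e.g. \code{value} for bedGraph intervals),
#'   recycled to the common length.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{strand} plus any extra columns.
#' @examples
#' gintervals("chr1", 0, 10)
#' @export
gintervals <- function(chrom, start, end, strand = ".", ...) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep(as.character(strand), length.out = length(chrom)),
    ...,
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' Validate an interval table against the package invariants
#'
#' @param x data.frame with \code{chrom}, \code{start}, \code{end} columns.
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   supplied, every interval must name a known chromosome and lie within it.
#' @param what label used in error messages.
#' @return \code{x}, invisibly.
#' @export
validate_intervals <- function(x, chrom_lengths = NULL, what = "interval") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    fail("%s table must be a data.frame with chrom/start/end columns", what)
  }
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    fail("%s table has empty chromosome names", what)
  }
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0 | x$start >= x$end)
  if (length(bad)) {
    fail("%s row %d invalid: need 0 <= start < end (got [%s, %s))",
         what, bad[1], format(x$start[bad[1]]), format(x$end[bad[1]]))
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
    fail("%s table has strand values outside +/-/.", what)
  }
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_lengths))
    if (length(unknown)) {
      fail("%s table names unknown chromosome '%s'", what, unknown[1])
    }
    over <- which(x$end > chrom_lengths[x$chrom])
    if (length(over)) {
      fail("%s row %d extends past the end of %s", what, over[1],
           x$chrom[over[1]])
    }
  }
  invisible(x)
}

# Internal: canonical (chrom, start, end) ordering.
sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Read intervals from BED or bedGraph
#'
#' BED is consumed natively as 0-based half-open. Files out of canonical
#' (chrom, start) order are returned sorted with a warning. Writing then
#' reading a sorted canonical BED3 file round-trips byte-identically.
#'
#' @param path file path.
#' @param format \code{"bed"} (3 or 6 columns) or \code{"bedgraph"}
#'   (4 columns, the 4th returned as a \code{value} column).
#' @param chrom_lengths optional named lengths for validation.
#' @return interval data.frame (see [gintervals()]).
#' @export
read_intervals <- function(path, format = c("bed", "bedgraph"),
                           chrom_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) fail("file not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE,
                           col.names = paste0("V", 1:12), fill = TRUE,
                           blank.lines.skip = TRUE)
  if (nrow(raw) == 0L) {
    return(gintervals(character(), numeric(), numeric()))
  }
  start <- suppressWarnings(as.numeric(raw$V2))
  end <- suppressWarnings(as.numeric(raw$V3))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) fail("%s line %d: malformed coordinates", path, bad[1])
  df <- data.frame(chrom = raw$V1, start = start, end = end,
                   strand = ".", stringsAsFactors = FALSE)
  if (format == "bedgraph") {
    val <- suppressWarnings(as.numeric(raw$V4))
    if (anyNA(val)) {
      fail("%s line %d: bedGraph value missing or non-numeric",
           path, which(is.na(val))[1])
    }
    df$value <- val
  } else if (!all(is.na(raw$V6) | raw$V6 == "")) {
    st <- raw$V6
    st[is.na(st) | st == ""] <- "."
    df$strand <- st
  }
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    fail("%s line %d: empty or inverted interval [%s, %s)", path, bad[1],
         format(df$start[bad[1]]), format(df$end[bad[1]]))
  }
  validate_intervals(df, chrom_lengths, what = basename(path))
  sorted <- sort_intervals(df)
  if (!identical(sorted$start, df$start) ||
      !identical(sorted$chrom, df$chrom)) {
    warning(sprintf("%s was not coordinate-sorted; returning sorted order",
                    basename(path)), call. = FALSE)
  }
  rownames(sorted) <- NULL
  sorted
}

#' Write intervals as BED3/BED6 or bedGraph
#'
#' @param x interval data.frame.
#' @param path output path.
#' @param format \code{"bed"} writes BED3, or BED6 when strand is
#'   informative; \code{"bedgraph"} writes chrom/start/end/value.
#' @return \code{path}, invisibly.
#' @export
write_intervals <- function(x, path, format = c("bed", "bedgraph")) {
  format <- match.arg(format)
  x <- sort_intervals(x)
  if (format == "bedgraph") {
    if (!"value" %in% names(x)) fail("bedGraph output needs a value column")
    out <- data.frame(x$chrom, format(x$start, scientific = FALSE,
                                      trim = TRUE),
                      format(x$end, scientific = FALSE, trim = TRUE),
                      format(x$value, scientific = FALSE, trim = TRUE))
  } else if ("strand" %in% names(x) && any(x$strand != ".")) {
    out <- data.frame(x$chrom, format(x$start, scientific = FALSE,
                                      trim = TRUE),
                      format(x$end, scientific = FALSE, trim = TRUE),
                      ".", 0L, x$strand)
  } else {
    out <- data.frame(x$chrom, format(x$start, scientific = FALSE,
                                      trim = TRUE),
                      format(x$end, scientific = FALSE, trim = TRUE))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome-sizes file
#'
#' @param path TSV with chromosome name and length.
#' @return named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2 || !is.numeric(tab[[2]])) {
    fail("%s: expected <chrom>\\t<length> rows", path)
  }
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}
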