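#' Count query intervals overlapping a subject set
#'
#' An overlap is any shared base: half-open intervals `[s1,e1)` and `[s2,e2)`
#' intersect iff `s1 < e2` and `s2 < e1`; abutting intervals do not overlap.
#' Each query interval is counted at most once however many subject intervals
#' it touches. No minimum-fraction rule is applied.
#'
#' @param query,subject `RegionSet` objects sharing a genome model.
#' @return A list with `n` (number of query intervals overlapping at least
#'   one subject interval) and `hits` (logical flag per query interval, in
#'   query order).
#' @export
count_overlapping <- function(query, subject) {
  stopifnot(inherits(query, "RegionSet"), inherits(subject, "RegionSet"))
  if (!same_genome(rs_genome(query), rs_genome(subject))) {
    stop("mismatched genome models between query and subject")
  }
  hits <- IRanges::overlapsAny(rs_ranges(query), rs_ranges(subject),
                               type = "any", minoverlap = 1L)
  list(n = sum(hits), hits = hits)
}

#' Extend intervals symmetrically and clamp to chromosome bounds
#'
#' Each interval `[s, e)` becomes `[max(0, s - window), min(L, e + window))`
#' where `L` is the chromosome length. Order and names are preserved and
#' overlapping outputs are deliberately NOT merged: downstream enrichment
#' counts each (extended) variant independently, so merging would silently
#' change support semantics.
#'
#' @param points A `RegionSet` (typically single-base variant positions).
#' @param window Non-negative extension in bp applied up- and downstream.
#' @return A `RegionSet` with the same number of intervals.
#' @export
extend_and_clamp <- function(points, window) {
  stopifnot(inherits(points, "RegionSet"))
  if (length(window) != 1L || is.na(window) || window < 0) {
    stop("window must be a single non-negative number")
  }
  df <- as.data.frame(points)
  genome <- rs_genome(points)
  if (nrow(df) == 0L) return(points)
  lens <- GenomeInfoDb::seqlengths(genome)[df$chrom]
  start <- pmax(0, df$start - window)
  end <- pmin(as.numeric(lens), df$end + window)
  gr <- rs_ranges(points)
  region_set(df$chrom, start, end,
             name = if (is.null(names(gr))) NULL else names(gr),
             genome = genome, label = points$label)
}

#' Merge overlapping intervals
#'
#' Returns the minimal sorted set of disjoint intervals covering the same
#' bases. A utility only: it is never applied inside the enrichment path
#' (see [extend_and_clamp()]).
#'
#' @param regions A `RegionSet`.
#' @return A `RegionSet` of disjoint sorted intervals.
#' @export
merge_overlapping <- function(regions) {
  stopifnot(inherits(regions, "RegionSet"))
  red <- GenomicRanges::reduce(rs_ranges(regions))
  new_region_set(red, regions$label)
}
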