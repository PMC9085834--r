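#' Construct a region set
#'
#' An ordered collection of genomic intervals on a shared genome model.
#' Coordinates follow the BED convention: 0-based, half-open `[start, end)`.
#' Internally the intervals live in a [GenomicRanges::GRanges] (1-based,
#' closed), converted on the way in and out; the original order is preserved.
#' Strand is ignored throughout: variants are points and regulatory elements
#' act irrespective of orientation.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive starts.
#' @param end Integer vector, exclusive ends; `start < end` required.
#' @param name Optional character vector of interval names (e.g. SNP rsIDs).
#' @param genome A `Seqinfo` genome model; all intervals are validated
#'   against it (`end <= chromosome length`).
#' @param label Identifier for the set (used in result tables).
#' @return A `RegionSet` object.
#' @examples
#' gm <- genome_model("chr1", 1000)
#' rs <- region_set("chr1", c(10, 30), c(20, 40), genome = gm, label = "toy")
#' @export
region_set <- function(chrom, start, end, name = NULL, genome, label = "regions") {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1L && n > 1L) chrom <- rep(chrom, n)
  if (length(start) != n || length(end) != n || length(chrom) != n) {
    stop("chrom, start and end must have equal length")
  }
  if (n > 0L) {
    bad_chrom <- !(chrom %in% GenomeInfoDb::seqnames(genome))
    if (any(bad_chrom)) {
      stop("chromosome(s) not in genome model: ",
           paste(unique(chrom[bad_chrom]), collapse = ", "))
    }
    if (anyNA(start) || anyNA(end) || any(start < 0) || any(start >= end)) {
      stop("invalid coordinates: require 0 <= start < end")
    }
    lens <- GenomeInfoDb::seqlengths(genome)[chrom]
    if (any(end > lens)) {
      stop("interval end exceeds chromosome length for ",
           sum(end > lens), " interval(s)")
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = GenomeInfoDb::seqnames(genome)),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    seqinfo = genome
  )
  if (!is.null(name)) {
    if (length(name) != n) stop("name must match the number of intervals")
    names(gr) <- as.character(name)
  }
  new_region_set(gr, label)
}

# internal: wrap an existing GRanges (assumed valid, seqinfo set)
new_region_set <- function(gr, label) {
  structure(list(ranges = gr, label = as.character(label)),
            class = "RegionSet")
}

#' @export
length.RegionSet <- function(x) length(x$ranges)

#' Genome model of a region set
#' @param x A `RegionSet`.
#' @return The `Seqinfo` genome model.
#' @export
rs_genome <- function(x) GenomeInfoDb::seqinfo(x$ranges)

#' Underlying GRanges of a region set
#' @param x A `RegionSet`.
#' @return The internal `GRanges` (1-based, closed coordinates).
#' @export
rs_ranges <- function(x) x$ranges

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet '%s': %d interval(s) on %d chromosome(s)\n",
              x$label, length(x),
              length(GenomeInfoDb::seqnames(rs_genome(x)))))
  invisible(x)
}

#' @export
as.data.frame.RegionSet <- function(x, ...) {
  gr <- x$ranges
  nm <- names(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (is.null(nm)) rep(".", length(gr)) else nm,
    stringsAsFactors = FALSE
  )
}

#' Construct a region collection
#'
#' A labelled list of [region_set()] objects sharing one genome model, e.g.
#' a database of regulatory-region sets or the DBR sets of several molecular
#' transducers.
#'
#' @param sets List of `RegionSet` objects; their labels must be unique.
#' @param provenance Optional character vector of source tags, one per set.
#' @return A `RegionCollection` object (a named list of sets).
#' @export
region_collection <- function(sets, provenance = NULL) {
  if (!is.list(sets) || !all(vapply(sets, inherits, TRUE, "RegionSet"))) {
    stop("sets must be a list of RegionSet objects")
  }
  labels <- vapply(sets, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate set labels in collection: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (length(sets) > 1L) {
    g1 <- rs_genome(sets[[1L]])
    ok <- vapply(sets[-1L], function(s) same_genome(rs_genome(s), g1), TRUE)
    if (!all(ok)) stop("all sets in a collection must share one genome model")
  }
  names(sets) <- labels
  if (!is.null(provenance)) {
    if (length(provenance) != length(sets)) {
      stop("provenance must have one tag per set")
    }
    attr(sets, "provenance") <- stats::setNames(provenance, labels)
  }
  class(sets) <- c("RegionCollection", "list")
  sets
}

#' @export
print.RegionCollection <- function(x, ...) {
  cat(sprintf("RegionCollection: %d set(s)\n", length(x)))
  for (s in x) cat(sprintf("  %s: %d interval(s)\n", s$label, length(s)))
  invisible(x)
}
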