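#' Read a BED file into a region set
#'
#' Accepts 3+ column tab-delimited BED (0-based, half-open). Column 4, when
#' present, is stored as the interval name. Lines failing validation
#' (non-integer coordinates, `start >= end`, unknown chromosome, end beyond
#' the chromosome) are an error naming the first offending line; under
#' `permissive = TRUE` they are skipped and counted instead (count available
#' as `attr(x, "n_skipped")`).
#'
#' @param path Path to the BED file.
#' @param genome A `Seqinfo` genome model covering every chromosome used.
#' @param label Label for the resulting set; defaults to the file name.
#' @param permissive Skip-and-count malformed lines instead of failing.
#' @return A `RegionSet`, intervals in file order.
#' @export
read_bed <- function(path, genome, label = NULL,
                     permissive = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(label)) label <- sub("\\.bed$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    rs <- region_set(character(0), integer(0), integer(0),
                     genome = genome, label = label)
    attr(rs, "n_skipped") <- 0L
    return(rs)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  chrom <- vapply(fields, `[`, character(1), 1L)
  start_raw <- vapply(fields, `[`, character(1), 2L)
  end_raw <- vapply(fields, `[`, character(1), 3L)
  name <- ifelse(nf >= 4L, vapply(fields, `[`, character(1), 4L), NA_character_)

  start <- suppressWarnings(as.numeric(start_raw))
  end <- suppressWarnings(as.numeric(end_raw))
  int_ok <- !is.na(start) & !is.na(end) &
    start == floor(start) & end == floor(end) &
    grepl("^[0-9]+$", start_raw) & grepl("^[0-9]+$", end_raw)
  chrom_ok <- chrom %in% GenomeInfoDb::seqnames(genome)
  lens <- GenomeInfoDb::seqlengths(genome)[chrom]
  ok <- nf >= 3L & int_ok & chrom_ok &
    !is.na(start) & !is.na(end) & start >= 0 & start < end &
    !is.na(lens) & end <= lens
  if (!all(ok)) {
    if (!permissive) {
      stop(sprintf("malformed BED line %d in %s: '%s'",
                   which(!ok)[1L], path, lines[which(!ok)[1L]]))
    }
    n_skipped <- sum(!ok)
    keep <- ok
  } else {
    n_skipped <- 0L
    keep <- rep(TRUE, length(ok))
  }
  has_name <- any(!is.na(name[keep]))
  rs <- region_set(chrom[keep], start[keep], end[keep],
                   name = if (has_name) ifelse(is.na(name[keep]), ".", name[keep]) else NULL,
                   genome = genome, label = label)
  attr(rs, "n_skipped") <- as.integer(n_skipped)
  rs
}

#' Write a region set to a 4-column BED file
#'
#' One tab-delimited line per interval, in the set's order; intervals with no
#' name get `"."`. Reading the result back with [read_bed()] reproduces the
#' file byte-identically for canonical 4-column input.
#'
#' @param regions A `RegionSet`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(inherits(regions, "RegionSet"))
  df <- as.data.frame(regions)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(df) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end, df$name),
               con = con, sep = "\n")
  }
  invisible(path)
}

#' Read every BED file in a directory as a region collection
#'
#' @param dir Directory containing `*.bed` files; each becomes one set
#'   labelled by its file name (without extension).
#' @param genome A `Seqinfo` genome model.
#' @param permissive Passed to [read_bed()].
#' @return A `RegionCollection`.
#' @export
read_bed_collection <- function(dir, genome, permissive = FALSE) {
  paths <- sort(list.files(dir, pattern = "\\.bed$", full.names = TRUE))
  if (length(paths) == 0L) stop("no .bed files found in ", dir)
  region_collection(lapply(paths, read_bed, genome = genome,
                           permissive = permissive))
}
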