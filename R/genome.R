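#' Construct a genome model
#'
#' A genome model is the set of chromosome names and lengths that every
#' region set is validated against. It is represented as a
#' [GenomeInfoDb::Seqinfo] object, the standard Bioconductor container for
#' sequence metadata.
#'
#' @param chroms Character vector of chromosome names; must be unique.
#' @param lengths Integer vector of chromosome lengths in base pairs; every
#'   length must be at least 1.
#' @return A `Seqinfo` object.
#' @examples
#' gm <- genome_model(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_model <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  if (length(chroms) == 0L) stop("genome model needs at least one chromosome")
  if (anyDuplicated(chroms)) {
    stop("duplicate chromosome names: ",
         paste(unique(chroms[duplicated(chroms)]), collapse = ", "))
  }
  lengths <- suppressWarnings(as.numeric(lengths))
  if (length(lengths) != length(chroms) || anyNA(lengths) || any(lengths < 1)) {
    stop("every chromosome length must be a positive integer")
  }
  GenomeInfoDb::Seqinfo(seqnames = chroms, seqlengths = as.integer(lengths))
}

#' Read a genome model from a chrom.sizes file
#'
#' Two-column tab-delimited file (UCSC chrom.sizes dialect):
#' chromosome name, length in bp.
#'
#' @param path Path to the chrom.sizes file.
#' @return A `Seqinfo` object.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2L) stop("chrom.sizes file needs two columns: ", path)
  genome_model(dt[[1L]], dt[[2L]])
}

#' Write a genome model as a chrom.sizes file
#'
#' @param genome A `Seqinfo` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  dt <- data.table::data.table(chrom = GenomeInfoDb::seqnames(genome),
                               length = GenomeInfoDb::seqlengths(genome))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# TRUE iff two Seqinfo objects describe the same genome
same_genome <- function(a, b) {
  identical(GenomeInfoDb::seqnames(a), GenomeInfoDb::seqnames(b)) &&
    identical(GenomeInfoDb::seqlengths(a), GenomeInfoDb::seqlengths(b))
}

genome_size <- function(genome) {
  sum(as.numeric(GenomeInfoDb::seqlengths(genome)))
}
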