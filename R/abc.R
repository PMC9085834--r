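#' Default column mapping for ABC prediction tables
#'
#' Matches the published Activity-By-Contact pipeline output dialect.
#' @export
abc_default_columns <- list(
  chrom = "chr", start = "start", end = "end",
  gene = "TargetGene", score = "ABC.Score", cell = "CellType"
)

#' Load precomputed Activity-By-Contact enhancer-gene predictions
#'
#' Headered TSV, one row per enhancer-gene link with the enhancer interval
#' (BED-style half-open coordinates), target gene symbol, ABC score in
#' `[0, 1]`, and cell type. Rows failing validation (bad coordinates,
#' unknown chromosome, score outside `[0, 1]`, empty gene) are an error, or
#' are dropped and counted under `permissive = TRUE`
#' (`attr(x, "n_rejected")`).
#'
#' @param path Path to the TSV file.
#' @param genome A `Seqinfo` genome model.
#' @param columns Column mapping as in [abc_default_columns].
#' @param permissive Drop-and-count invalid rows instead of failing.
#' @return A `data.table` of links: `chrom`, `start`, `end`, `gene`,
#'   `score`, `cell`.
#' @export
load_abc_predictions <- function(path, genome, columns = abc_default_columns,
                                 permissive = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  for (f in names(abc_default_columns)) {
    if (!columns[[f]] %in% names(dt)) {
      stop("missing mandatory column '", columns[[f]], "' in ", path)
    }
  }
  links <- data.table::data.table(
    chrom = as.character(dt[[columns$chrom]]),
    start = suppressWarnings(as.numeric(dt[[columns$start]])),
    end = suppressWarnings(as.numeric(dt[[columns$end]])),
    gene = as.character(dt[[columns$gene]]),
    score = suppressWarnings(as.numeric(dt[[columns$score]])),
    cell = as.character(dt[[columns$cell]])
  )
  if (nrow(links) == 0L) {
    attr(links, "n_rejected") <- 0L
    return(links[])
  }
  lens <- GenomeInfoDb::seqlengths(genome)[links$chrom]
  ok <- links$chrom %in% GenomeInfoDb::seqnames(genome) &
    !is.na(links$start) & !is.na(links$end) &
    links$start >= 0 & links$start < links$end &
    !is.na(lens) & links$end <= lens &
    !is.na(links$score) & links$score >= 0 & links$score <= 1 &
    !is.na(links$gene) & nzchar(links$gene)
  if (!all(ok) && !permissive) {
    stop(sprintf("invalid ABC row %d in %s", which(!ok)[1L], path))
  }
  out <- links[ok]
  attr(out, "n_rejected") <- sum(!ok)
  out[]
}

#' Map hotspot variants to genes through ABC enhancer-gene links
#'
#' A hotspot maps to every link whose enhancer interval overlaps the
#' (optionally extended) hotspot position. Genes are deduplicated per
#' hotspot keeping, for each gene, the maximum-score link (its cell type is
#' retained; score ties resolved by cell-type label for determinism).
#' Hotspots with no link are omitted from the table but counted:
#' `attr(x, "n_unmapped")` and `attr(x, "unmapped")`.
#'
#' @param hotspots Named `RegionSet` of hotspot variants.
#' @param links Link table from [load_abc_predictions()] (or equivalent).
#' @param window Extension in bp applied to each hotspot before the join
#'   (default 0: direct overlap of the variant with the enhancer element).
#' @return A `data.table`: `snp`, `chrom`, `pos`, `gene`, `cell`, `score`.
#' @export
map_hotspots_to_genes <- function(hotspots, links, window = 0) {
  stopifnot(inherits(hotspots, "RegionSet"))
  genome <- rs_genome(hotspots)
  ext <- extend_and_clamp(hotspots, window)
  df <- as.data.frame(hotspots)
  empty <- data.table::data.table(
    snp = character(0), chrom = character(0), pos = integer(0),
    gene = character(0), cell = character(0), score = numeric(0)
  )
  if (length(hotspots) == 0L || nrow(links) == 0L) {
    attr(empty, "n_unmapped") <- length(hotspots)
    attr(empty, "unmapped") <- df$name
    return(empty[])
  }
  link_gr <- GenomicRanges::GRanges(
    seqnames = factor(links$chrom, levels = GenomeInfoDb::seqnames(genome)),
    ranges = IRanges::IRanges(start = as.integer(links$start) + 1L,
                              end = as.integer(links$end)),
    seqinfo = genome
  )
  ov <- GenomicRanges::findOverlaps(rs_ranges(ext), link_gr)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  if (length(qi) == 0L) {
    attr(empty, "n_unmapped") <- length(hotspots)
    attr(empty, "unmapped") <- df$name
    return(empty[])
  }
  hits <- data.table::data.table(
    snp = df$name[qi], chrom = df$chrom[qi], pos = df$start[qi] + 1L,
    gene = links$gene[si], cell = links$cell[si], score = links$score[si]
  )
  # per (hotspot, gene): keep the maximum-score link
  data.table::setorder(hits, snp, gene, -score, cell)
  out <- hits[!duplicated(paste(snp, gene))]
  data.table::setorder(out, snp, -score, gene)
  mapped <- unique(out$snp)
  unmapped <- setdiff(df$name, mapped)
  attr(out, "n_unmapped") <- length(unmapped)
  attr(out, "unmapped") <- unmapped
  out[]
}

#' Top-scoring gene per hotspot
#'
#' The argmax-score gene for each mapped hotspot; score ties broken
#' lexicographically by gene symbol.
#'
#' @param maps Table from [map_hotspots_to_genes()].
#' @return A `data.table`: `snp`, `top_gene`, `score`.
#' @export
top_gene_per_hotspot <- function(maps) {
  if (nrow(maps) == 0L) {
    return(data.table::data.table(snp = character(0), top_gene = character(0),
                                  score = numeric(0)))
  }
  m <- data.table::copy(maps)
  data.table::setorder(m, snp, -score, gene)
  top <- m[!duplicated(snp), .(snp, top_gene = gene, score)]
  top[]
}

#' Annotate an ABC gene map with the top-gene flag and write as TSV
#'
#' Output columns: `snp`, `chrom`, `pos`, `gene`, `cell_type`, `abc_score`,
#' `is_top_gene` (0/1).
#'
#' @param maps Table from [map_hotspots_to_genes()].
#' @param path Output path.
#' @return The annotated `data.table`, invisibly.
#' @export
write_abc_map <- function(maps, path) {
  top <- top_gene_per_hotspot(maps)
  out <- data.table::copy(maps)
  key_top <- paste(top$snp, top$top_gene)
  out[, is_top_gene := as.integer(paste(snp, gene) %in% key_top)]
  data.table::setnames(out, c("cell", "score"), c("cell_type", "abc_score"))
  data.table::fwrite(out, path, sep = "\t")
  invisible(out[])
}
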