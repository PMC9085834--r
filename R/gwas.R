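#' Default GWAS-catalog column mapping
#'
#' Maps the internal record fields to the column names of a GWAS-catalog
#' style association table.
#' @export
gwas_default_columns <- list(
  snp = "SNPS",
  chrom = "CHR_ID",
  pos = "CHR_POS",
  trait = "MAPPED_TRAIT_URI",
  gene = "REPORTED GENE(S)",
  study = "STUDY ACCESSION"
)

#' Read a GWAS-catalog-like association table
#'
#' Headered TSV with configurable column names. Records mapped to multiple
#' positions (semicolon-separated chromosome/position fields) are expanded to
#' one record per position, preserving every GWAS-verified signal. Positions
#' are 1-based as published.
#'
#' @param path Path to the TSV file.
#' @param columns Column mapping as in [gwas_default_columns]; `snp`,
#'   `chrom` and `pos` are mandatory, the rest optional.
#' @return A `data.table` of records: `snp`, `chrom`, `pos_raw` (character),
#'   `trait`, `gene`, `study`.
#' @export
read_gwas_table <- function(path, columns = gwas_default_columns) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  for (f in c("snp", "chrom", "pos")) {
    if (!columns[[f]] %in% names(dt)) {
      stop("missing mandatory column '", columns[[f]], "' in ", path)
    }
  }
  get_col <- function(f) {
    cn <- columns[[f]]
    if (!is.null(cn) && cn %in% names(dt)) dt[[cn]] else rep(NA_character_, nrow(dt))
  }
  rec <- data.table::data.table(
    snp = get_col("snp"),
    chrom = get_col("chrom"),
    pos_raw = get_col("pos"),
    trait = get_col("trait"),
    gene = get_col("gene"),
    study = get_col("study")
  )
  expand_gwas_records(rec)
}

# one record per mapped position; multi-mapped SNPs carry ";"-separated
# chromosome and position fields of equal arity
expand_gwas_records <- function(rec) {
  multi <- grepl(";", rec$chrom, fixed = TRUE) |
    grepl(";", rec$pos_raw, fixed = TRUE)
  if (!any(multi)) return(rec[])
  single <- rec[!multi]
  rows <- rec[multi]
  expanded <- data.table::rbindlist(lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i]
    ch <- trimws(strsplit(r$chrom, ";", fixed = TRUE)[[1L]])
    po <- trimws(strsplit(r$pos_raw, ";", fixed = TRUE)[[1L]])
    if (length(ch) != length(po)) {
      # unequal arity is unintelligible -> keep one malformed record
      ch <- NA_character_; po <- NA_character_
    }
    data.table::data.table(snp = r$snp, chrom = ch, pos_raw = po,
                           trait = r$trait, gene = r$gene, study = r$study)
  }))
  data.table::rbindlist(list(single, expanded), use.names = TRUE)[]
}

# per-record parseability against a genome model: integer position >= 1,
# known chromosome, position within the chromosome
gwas_parse_positions <- function(rec, genome) {
  pos <- suppressWarnings(as.numeric(rec$pos_raw))
  ok_int <- !is.na(pos) & pos >= 1 & pos == floor(pos) &
    grepl("^[0-9]+$", rec$pos_raw)
  ok_chrom <- !is.na(rec$chrom) & rec$chrom %in% GenomeInfoDb::seqnames(genome)
  lens <- GenomeInfoDb::seqlengths(genome)[rec$chrom]
  ok_len <- ok_int & ok_chrom & !is.na(lens) & pos <= lens
  list(pos = pos, ok = ok_int & ok_chrom & ok_len)
}

#' Build the region of interest (ROI) from GWAS records
#'
#' Keeps records passing the trait filter, drops records with unparseable or
#' unknown coordinates ("malformed"), drops exact positional duplicates by
#' `(chromosome, position)` — uniqueness is positional, not by rsID — and
#' emits single-base intervals `[pos - 1, pos)` named by SNP id. A QC report
#' accompanies the set so the ingest drop rate is always visible.
#'
#' @param records Record table from [read_gwas_table()] (or equivalent).
#' @param trait Either a character scalar matched exactly against the trait
#'   column (with optional substring fallback, see `fallback_substring`), or
#'   a predicate `function(records) -> logical`.
#' @param genome A `Seqinfo` genome model.
#' @param label Label for the resulting set.
#' @param fallback_substring If exact trait matching selects nothing, retry
#'   as a fixed substring match against the trait column.
#' @return A list: `roi` (`RegionSet`) and `qc` (list with `n_selected`,
#'   `kept`, `dropped_malformed`, `dropped_duplicate`, `drop_rate`).
#' @export
build_roi <- function(records, trait, genome, label = "roi",
                      fallback_substring = TRUE) {
  records <- data.table::as.data.table(records)
  if (is.function(trait)) {
    sel <- trait(records)
    sel <- !is.na(sel) & sel
  } else {
    sel <- !is.na(records$trait) & records$trait == trait
    if (!any(sel) && fallback_substring) {
      sel <- !is.na(records$trait) & grepl(trait, records$trait, fixed = TRUE)
    }
  }
  rec <- records[which(sel)]
  if (nrow(rec) == 0L) stop("empty ROI: trait filter matched no records")
  parsed <- gwas_parse_positions(rec, genome)
  n_malformed <- sum(!parsed$ok)
  rec <- rec[parsed$ok]
  pos <- parsed$pos[parsed$ok]
  dup <- duplicated(paste(rec$chrom, pos))
  n_duplicate <- sum(dup)
  rec <- rec[!dup]
  pos <- pos[!dup]
  if (nrow(rec) == 0L) stop("empty ROI: no record passed coordinate QC")
  roi <- region_set(rec$chrom, pos - 1, pos, name = rec$snp,
                    genome = genome, label = label)
  qc <- list(
    n_selected = sum(sel),
    kept = nrow(rec),
    dropped_malformed = as.integer(n_malformed),
    dropped_duplicate = as.integer(n_duplicate),
    drop_rate = (n_malformed + n_duplicate) / sum(sel)
  )
  list(roi = roi, qc = qc)
}

#' Build the background universe from GWAS records
#'
#' All records — no trait filter — deduplicated by `(chromosome, position)`
#' after dropping unparseable coordinates. Any ROI built from the same record
#' table is a positional subset of this universe, as the contingency
#' construction requires.
#'
#' @param records Record table from [read_gwas_table()] (or equivalent).
#' @param genome A `Seqinfo` genome model.
#' @param label Label for the resulting set.
#' @return A `RegionSet` of single-base intervals.
#' @export
build_universe <- function(records, genome, label = "universe") {
  records <- data.table::as.data.table(records)
  parsed <- gwas_parse_positions(records, genome)
  rec <- records[parsed$ok]
  pos <- parsed$pos[parsed$ok]
  dup <- duplicated(paste(rec$chrom, pos))
  rec <- rec[!dup]
  pos <- pos[!dup]
  region_set(rec$chrom, pos - 1, pos, name = rec$snp,
             genome = genome, label = label)
}
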