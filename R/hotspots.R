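#' Per-variant membership across transducer DBR sets
#'
#' Flags each unique ROI variant position for overlap with each transducer's
#' DNA binding regions (DBRs) after symmetric window extension. Variants are
#' considered once per unique `(chromosome, position)` however many input
#' rows or matches they have. When `window` has several values the flags are
#' pooled (a variant is a member if any extension overlaps), mirroring
#' match pooling across extensions.
#'
#' @param roi `RegionSet` of point variants.
#' @param dbrs `RegionCollection` of DBR sets, one per transducer (e.g.
#'   VDR, AID, EBNA2, EBNA3C).
#' @param window Extension(s) in bp applied to each variant (default
#'   50000, i.e. +/-50 kb).
#' @return A `data.table` with columns `snp`, `chrom`, `pos` (1-based), one
#'   logical column per transducer, and `k` (number of transducers bound);
#'   transducer labels stored in `attr(, "transducers")`.
#' @export
transducer_membership <- function(roi, dbrs, window = 50000) {
  stopifnot(inherits(roi, "RegionSet"), inherits(dbrs, "RegionCollection"))
  if (length(dbrs) == 0L) stop("empty DBR collection")
  if (length(window) < 1L || any(window < 0)) {
    stop("window must be one or more non-negative numbers")
  }
  df <- as.data.frame(roi)
  keep <- !duplicated(paste(df$chrom, df$start))
  uniq <- region_set(df$chrom[keep], df$start[keep], df$end[keep],
                     name = df$name[keep], genome = rs_genome(roi),
                     label = roi$label)
  labels <- names(dbrs)
  n <- length(uniq)
  flags <- matrix(FALSE, nrow = n, ncol = length(labels),
                  dimnames = list(NULL, labels))
  for (w in window) {
    ext <- extend_and_clamp(uniq, w)
    for (lab in labels) {
      flags[, lab] <- flags[, lab] | count_overlapping(ext, dbrs[[lab]])$hits
    }
  }
  out <- data.table::data.table(
    snp = df$name[keep],
    chrom = df$chrom[keep],
    pos = df$start[keep] + 1L
  )
  for (lab in labels) data.table::set(out, j = lab, value = flags[, lab])
  data.table::set(out, j = "k", value = as.integer(rowSums(flags)))
  data.table::setattr(out, "transducers", labels)
  out[]
}

#' Exclusive Venn combination counts of transducer membership
#'
#' Exact count for each of the `2^T - 1` nonempty label combinations under
#' standard Venn semantics: a variant counts in exactly the cell of the
#' transducers it binds, so cells are exclusive and sum to the number of
#' variants bound by at least one transducer. Marginal totals per `k` are
#' returned alongside.
#'
#' @param memberships Table from [transducer_membership()].
#' @return A list: `cells` (named integer vector, names are sorted label
#'   combinations joined by `+`), `by_k` (integer vector, count of variants
#'   with exactly `k` transducers, `k = 1..T`), and `n_multi` (variants with
#'   `k >= 2`).
#' @export
venn_counts <- function(memberships) {
  labels <- attr(memberships, "transducers")
  if (is.null(labels)) stop("memberships lack transducer labels")
  T <- length(labels)
  combos <- unlist(lapply(seq_len(T), function(k) {
    apply(utils::combn(labels, k), 2L, paste, collapse = "+")
  }))
  cells <- stats::setNames(integer(length(combos)), combos)
  flag_mat <- as.matrix(memberships[, labels, with = FALSE])
  if (nrow(flag_mat) > 0L) {
    keys <- apply(flag_mat, 1L, function(fl) paste(labels[fl], collapse = "+"))
    tab <- table(keys[nzchar(keys)])
    cells[names(tab)] <- as.integer(tab)
  }
  k <- memberships$k
  by_k <- stats::setNames(vapply(seq_len(T), function(i) sum(k == i), 0L),
                          as.character(seq_len(T)))
  list(cells = cells, by_k = by_k, n_multi = sum(k >= 2))
}

#' Select multi-transducer hotspot variants
#'
#' Variants bound by at least `min_k` transducers — the "hotspots" where
#' genetic risk signals and multiple non-genetic molecular transducers
#' converge. Monotone: raising `min_k` never adds regions.
#'
#' @param memberships Table from [transducer_membership()].
#' @param min_k Minimum number of transducers (default 2).
#' @param genome A `Seqinfo` genome model for the returned set.
#' @param label Label for the returned set.
#' @return A `RegionSet` of single-base variant positions, names preserved.
#' @export
select_hotspots <- function(memberships, min_k = 2L, genome,
                            label = "hotspots") {
  if (min_k < 1L) stop("min_k must be at least 1")
  sel <- memberships[k >= min_k]
  region_set(sel$chrom, sel$pos - 1, sel$pos, name = sel$snp,
             genome = genome, label = label)
}

#' Write a transducer membership table as TSV (flags as 0/1)
#'
#' @param memberships Table from [transducer_membership()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_membership <- function(memberships, path) {
  out <- data.table::copy(memberships)
  for (lab in attr(memberships, "transducers")) {
    out[[lab]] <- as.integer(out[[lab]])
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write Venn combination counts as JSON
#'
#' @param counts Result of [venn_counts()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_venn_json <- function(counts, path) {
  jsonlite::write_json(
    list(cells = as.list(counts$cells), by_k = as.list(counts$by_k),
         n_multi = counts$n_multi),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
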