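#' Construct a gene-set collection
#'
#' Named gene sets plus the size of the background gene universe. Gene
#' symbols are case-normalized to uppercase on ingest (ontology sources mix
#' cases) and deduplicated within each set.
#'
#' @param sets Named list of character vectors of gene symbols; every set
#'   must be nonempty.
#' @param background Number of genes in the universe (default 20000,
#'   whole-genome semantics); must be at least the size of any set.
#' @param descriptions Optional character vector of per-set descriptions
#'   (second GMT field); defaults to the set names.
#' @return A `GeneSetCollection` object.
#' @export
gene_set_collection <- function(sets, background = 20000,
                                descriptions = NULL) {
  if (!is.list(sets)) stop("sets must be a named list")
  if (length(sets) > 0L &&
      (is.null(names(sets)) || any(!nzchar(names(sets))))) {
    stop("every gene set must be named")
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  if (any(lengths(sets) == 0L)) stop("gene sets must be nonempty")
  if (length(sets) > 0L && background < max(lengths(sets))) {
    stop("background must be at least the size of the largest set")
  }
  if (is.null(descriptions)) descriptions <- names(sets)
  if (length(descriptions) != length(sets)) {
    stop("descriptions must match the number of sets")
  }
  structure(list(sets = sets, background = as.integer(background),
                 descriptions = stats::setNames(descriptions,
                                                names(sets))),
            class = "GeneSetCollection")
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d set(s), background %d genes\n",
              length(x), x$background))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene symbols. Duplicate genes within a line are collapsed. A line
#' with fewer than 3 fields is an error naming the line.
#'
#' @param path Path to the GMT file.
#' @param background Background universe size (see [gene_set_collection()]).
#' @return A `GeneSetCollection`.
#' @export
read_gmt <- function(path, background = 20000) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(gene_set_collection(stats::setNames(list(), character(0)),
                               background = background))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("GMT line %d has fewer than 3 fields in %s",
                 short[1L], path))
  }
  nms <- vapply(fields, `[`, character(1), 1L)
  desc <- vapply(fields, `[`, character(1), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  gene_set_collection(stats::setNames(sets, nms), background = background,
                      descriptions = desc)
}

#' Write a gene-set collection as a GMT file
#'
#' @param collection A `GeneSetCollection`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0L) writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

#' Accumulative hypergeometric gene-set enrichment p-value
#'
#' Upper-tail ("accumulative") hypergeometric probability of seeing at least
#' the observed overlap between a query gene list and one gene set:
#' `p = sum_{k >= x} C(K,k) C(N-K, n-k) / C(N,n)` with `N` the background
#' size, `K` the set size, `n` the query size and `x` the overlap.
#'
#' @param query Character vector of query gene symbols.
#' @param set Character vector of gene-set symbols.
#' @param background Background universe size `N`.
#' @return A list: `p` and `overlap` (the observed `x`).
#' @export
hypergeom_enrich <- function(query, set, background) {
  query <- unique(toupper(as.character(query)))
  set <- unique(toupper(as.character(set)))
  N <- background
  K <- length(set)
  n <- length(query)
  if (K > N || n > N) stop("set or query larger than the background universe")
  x <- length(intersect(query, set))
  p <- stats::phyper(x - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
  list(p = p, overlap = x)
}

#' Rank a gene-set collection by enrichment in a query list
#'
#' Per-set accumulative hypergeometric p via [hypergeom_enrich()], BH
#' q-values across the collection, sorted ascending by p (ties by label).
#'
#' @param query Character vector of query gene symbols.
#' @param collection A `GeneSetCollection`.
#' @return A `data.table`: `set`, `overlap`, `set_size`, `p`, `q`.
#' @export
enrich_all <- function(query, collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (length(collection) == 0L) {
    return(data.table::data.table(set = character(0), overlap = integer(0),
                                  set_size = integer(0), p = numeric(0),
                                  q = numeric(0)))
  }
  rows <- lapply(names(collection$sets), function(nm) {
    h <- hypergeom_enrich(query, collection$sets[[nm]],
                          collection$background)
    data.table::data.table(set = nm, overlap = h$overlap,
                           set_size = length(collection$sets[[nm]]),
                           p = h$p)
  })
  res <- data.table::rbindlist(rows)
  res[, q := bh_adjust(p)]
  data.table::setorder(res, p, set)
  res[]
}
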