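#' Construct the 2x2 overlap contingency table
#'
#' The table behind every enrichment test, in LOLA's parameterization:
#' \describe{
#'   \item{a}{"support" — ROI regions overlapping the database set}
#'   \item{b}{ROI regions not overlapping}
#'   \item{c}{non-ROI universe regions overlapping}
#'   \item{d}{non-ROI universe regions not overlapping}
#' }
#' so that `a + b = |ROI|` and `a + b + c + d = |Universe|`. Support counts
#' ROI-side regions — not database regions or base pairs.
#'
#' The ROI must be a positional subset of the universe: every ROI interval
#' has to overlap at least one universe interval. If the universe's overlap
#' count with the database set is smaller than the ROI's (possible only when
#' the two sets disagree), `c` is clamped at 0 with a warning.
#'
#' @param roi,dbset,universe `RegionSet` objects on one genome model.
#' @return A `contingency_table` object (list with integer `a`, `b`, `c`, `d`).
#' @export
build_contingency <- function(roi, dbset, universe) {
  in_universe <- count_overlapping(roi, universe)
  if (in_universe$n < length(roi)) {
    missing <- as.data.frame(roi)[!in_universe$hits, , drop = FALSE]
    stop("ROI is not contained in the universe; offending region(s): ",
         paste(utils::head(sprintf("%s:%d-%d", missing$chrom, missing$start,
                                   missing$end), 5L), collapse = ", "))
  }
  a <- count_overlapping(roi, dbset)$n
  b <- length(roi) - a
  u <- count_overlapping(universe, dbset)$n
  cc <- u - a
  if (cc < 0L) {
    warning("universe overlap count below ROI overlap count; clamping c at 0")
    cc <- 0L
  }
  d <- length(universe) - length(roi) - cc
  contingency_table(a, b, cc, d)
}

#' Create a contingency table from counts
#'
#' @param a,b,c,d Non-negative counts (see [build_contingency()]).
#' @return A `contingency_table` object.
#' @export
contingency_table <- function(a, b, c, d) {
  vals <- c(a = a, b = b, c = c, d = d)
  if (anyNA(vals) || any(vals < 0) || any(vals != floor(vals))) {
    stop("contingency counts must be non-negative integers")
  }
  structure(list(a = as.integer(a), b = as.integer(b),
                 c = as.integer(c), d = as.integer(d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 contingency: a=%d b=%d c=%d d=%d (N=%d)\n",
              x$a, x$b, x$c, x$d, x$a + x$b + x$c + x$d))
  invisible(x)
}

#' One-sided (enrichment) Fisher's exact p-value
#'
#' Exact upper-tail probability `P[X >= a]` for `X` hypergeometric with the
#' table's margins — the "greater" alternative, matching the one-sided
#' enrichment convention of region-set overlap analysis. Computed through the
#' exact hypergeometric distribution function; no normal approximation.
#'
#' @param table A `contingency_table`.
#' @return The p-value in `[0, 1]`.
#' @export
fisher_greater <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  if (a + b == 0L) stop("degenerate margins: empty ROI (a + b = 0)")
  if (a == 0L) return(1.0)
  # margins: a+c overlapping universe regions, b+d non-overlapping, a+b
  # drawn; summing the point masses directly avoids the cancellation of a
  # complemented CDF and keeps the closed-form cases exact
  k <- a:min(a + cc, a + b)
  min(1, sum(stats::dhyper(k, m = a + cc, n = b + d, k = a + b)))
}

#' Odds ratio of a 2x2 table
#'
#' `(a*d)/(b*c)` with no continuity correction. A zero denominator with a
#' positive numerator gives `Inf`, as does the saturated case where every
#' ROI region overlaps (`b = 0`, `a > 0`) even if `d = 0`; zero over zero
#' with no overlap at all is `NaN` (undefined).
#'
#' @param table A `contingency_table`.
#' @return A numeric scalar, possibly `Inf` or `NaN`.
#' @export
odds_ratio <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  num <- as.numeric(table$a) * as.numeric(table$d)
  den <- as.numeric(table$b) * as.numeric(table$c)
  if (den == 0) {
    if (num > 0 || (table$a > 0 && table$b == 0)) return(Inf)
    return(NaN)
  }
  num / den
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard BH false-discovery-rate adjustment,
#' `q_i = min_{j : p_(j) >= p_(i)} p_(j) * m / rank(j)` clamped at 1,
#' returned in input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values aligned to the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Harmonic composite ranking score
#'
#' Combines the three evidence channels of one colocalization match — the
#' `-log10` p-value, the support, and the odds ratio — into a single ranking
#' score inspired by the weighted harmonic mean:
#'
#' `HS = kp * (w1 + w2 + w3) / (w1/neglogp + w2/support + w3/oddsratio)`
#'
#' with spacing parameter `kp = 10.0` and equal unit weights by default. The
#' harmonic mean is dominated by the weakest contributor, so a match ranks
#' high only when all three channels agree. Conventions: any zero contributor
#' gives `HS = 0` (the harmonic-mean limit, keeping the ranking total); an
#' infinite odds ratio contributes a zero reciprocal term.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param neglogp `-log10(p)`; must be >= 0.
#' @param support ROI overlap count; must be >= 0.
#' @param oddsratio Odds ratio; must be >= 0 (may be `Inf`).
#' @param kp Spacing parameter (default 10.0).
#' @param weights Length-3 non-negative weights for the three contributors.
#' @return Numeric vector of scores, all >= 0.
#' @examples
#' harmonic_score(10.658, 158, 1.790) # ~45.5
#' harmonic_score(1, 1, 1)            # exactly 10
#' @export
harmonic_score <- function(neglogp, support, oddsratio, kp = 10.0,
                           weights = c(1, 1, 1)) {
  if (length(weights) != 3L || anyNA(weights) || any(weights < 0)) {
    stop("weights must be three non-negative numbers")
  }
  n <- max(length(neglogp), length(support), length(oddsratio))
  neglogp <- rep_len(as.numeric(neglogp), n)
  support <- rep_len(as.numeric(support), n)
  oddsratio <- rep_len(as.numeric(oddsratio), n)
  if (anyNA(neglogp) || anyNA(support) ||
      any(neglogp < 0) || any(support < 0) ||
      any(!is.na(oddsratio) & oddsratio < 0)) {
    stop("harmonic score contributors must be non-negative")
  }
  recip <- function(x, w) ifelse(is.infinite(x), 0, w / x)
  denom <- recip(neglogp, weights[1L]) + recip(support, weights[2L]) +
    recip(oddsratio, weights[3L])
  hs <- kp * sum(weights) / denom
  # zero contributor (or NaN odds ratio) -> score 0 by convention
  zero <- neglogp == 0 | support == 0 | is.na(oddsratio) | oddsratio == 0
  hs[zero] <- 0
  hs
}

#' Ranked colocalization of an ROI against a region collection
#'
#' One enrichment result per collection member: the 2x2 contingency table
#' against the shared universe, one-sided Fisher p, BH q across the
#' collection (the FDR family is the collection of one run), odds ratio, and
#' the harmonic score. Results are sorted by harmonic score descending, ties
#' broken by smaller p, then larger support, then set label.
#'
#' @param roi `RegionSet` of (typically extended) variant regions.
#' @param collection `RegionCollection` of database sets.
#' @param universe Background `RegionSet`; the ROI must be contained in it.
#' @param kp,weights Passed to [harmonic_score()].
#' @return A `data.table` with columns `roi`, `dbset`, `a`, `b`, `c`, `d`,
#'   `p`, `neg_log10_p`, `q`, `odds_ratio`, `support`, `db_size`,
#'   `harmonic_score`.
#' @export
run_colocalization <- function(roi, collection, universe, kp = 10.0,
                               weights = c(1, 1, 1)) {
  stopifnot(inherits(collection, "RegionCollection"))
  if (length(collection) == 0L) return(empty_coloc_results())
  rows <- lapply(collection, function(dbset) {
    ct <- build_contingency(roi, dbset, universe)
    data.table::data.table(
      roi = roi$label, dbset = dbset$label,
      a = ct$a, b = ct$b, c = ct$c, d = ct$d,
      p = fisher_greater(ct), odds_ratio = odds_ratio(ct),
      support = ct$a, db_size = length(dbset)
    )
  })
  res <- data.table::rbindlist(rows)
  res[, q := bh_adjust(p)]
  res[, neg_log10_p := -log10(p)]
  res[, harmonic_score := harmonic_score(neg_log10_p, support, odds_ratio,
                                         kp = kp, weights = weights)]
  data.table::setorder(res, -harmonic_score, p, -support, dbset)
  data.table::setcolorder(res, c("roi", "dbset", "a", "b", "c", "d", "p",
                                 "neg_log10_p", "q", "odds_ratio", "support",
                                 "db_size", "harmonic_score"))
  res[]
}

empty_coloc_results <- function() {
  data.table::data.table(
    roi = character(0), dbset = character(0),
    a = integer(0), b = integer(0), c = integer(0), d = integer(0),
    p = numeric(0), neg_log10_p = numeric(0), q = numeric(0),
    odds_ratio = numeric(0), support = integer(0), db_size = integer(0),
    harmonic_score = numeric(0)
  )
}

#' Write colocalization results as headered TSV
#'
#' @param results Result table from [run_colocalization()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_coloc_results <- function(results, path) {
  data.table::fwrite(results, path, sep = "\t")
  invisible(path)
}

#' Write colocalization results as JSON (mirrors the TSV columns)
#'
#' @param results Result table from [run_colocalization()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_coloc_json <- function(results, path) {
  jsonlite::write_json(results, path, dataframe = "rows", na = "string",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
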