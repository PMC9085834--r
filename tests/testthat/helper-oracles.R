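# shared fixtures and independent oracles, built before (and kept apart
# from) the implementation paths they check

toy_genome <- function(n_chrom = 2L, len = 10000L) {
  genome_model(paste0("chr", seq_len(n_chrom)), rep(len, n_chrom))
}

# random region set with small intervals, reproducible under the caller seed
random_region_set <- function(genome, n, label = "rand", named = TRUE,
                              max_len = 50L) {
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- GenomeInfoDb::seqlengths(genome)
  idx <- sample.int(length(chroms), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (lens[idx] - len))
  region_set(chroms[idx], start, start + len,
             name = if (named) paste0("r", seq_len(n)) else NULL,
             genome = genome, label = label)
}

# brute-force hypergeometric upper-tail oracle: explicit sum of point
# masses from log binomial coefficients
fisher_tail_oracle <- function(a, b, c, d) {
  K <- a + c
  N <- a + b + c + d
  n <- a + b
  k <- a:min(K, n)
  sum(exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)))
}

# naive O(m^2) BH step-up: q_i = min over p_(j) >= p_(i) of p_(j)*m/rank(j)
bh_naive <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# count of distinct covered bases, by direct position enumeration
covered_bases_oracle <- function(rs) {
  df <- as.data.frame(rs)
  if (nrow(df) == 0L) return(0L)
  sum(vapply(split(df, df$chrom), function(g) {
    length(unique(unlist(Map(function(s, e) seq(s, e - 1L), g$start, g$end))))
  }, numeric(1)))
}

# toy coordinates realizing the (a,b,c,d) = (2,2,1,5) contingency layout:
# 4 ROI points of which 2 overlap the db set; 10-point universe containing
# the ROI, 3 universe points total overlapping the db set
toy_contingency_fixture <- function() {
  gm <- genome_model("chr1", 1000L)
  roi <- region_set("chr1", c(10, 20, 30, 40), c(11, 21, 31, 41),
                    name = paste0("rs", 1:4), genome = gm, label = "roi")
  universe <- region_set("chr1",
                         c(10, 20, 30, 40, 100, 200, 300, 400, 500, 600),
                         c(11, 21, 31, 41, 101, 201, 301, 401, 501, 601),
                         name = paste0("u", 1:10), genome = gm,
                         label = "universe")
  dbset <- region_set("chr1", c(5, 95), c(25, 105), genome = gm,
                      label = "db")
  list(genome = gm, roi = roi, universe = universe, dbset = dbset)
}

# printed ranking-table triples (-log10 p, support, odds ratio) with their
# published harmonic scores: DBR-vs-variant matches at three extensions,
# then transcript-list matches split by half-life
published_hs_rows <- function() {
  rbind(
    data.frame(neglogp = c(10.658, 8.616, 15.444), support = c(158, 239, 421),
               oddsratio = c(1.790, 1.509, 1.542), hs = c(45.544, 38.327, 41.913)),
    data.frame(neglogp = c(0.614, 1.647, 3.448), support = c(55, 109, 199),
               oddsratio = c(1.108, 1.227, 1.294), hs = c(11.765, 20.956, 28.098)),
    data.frame(neglogp = c(4.963, 3.890, 13.924), support = c(99, 153, 309),
               oddsratio = c(1.596, 1.374, 1.619), hs = c(35.793, 30.259, 43.308)),
    data.frame(neglogp = c(19.348, 19.181, 32.090), support = c(474, 767, 1329),
               oddsratio = c(1.575, 1.422, 1.424), hs = c(43.564, 39.635, 40.872)),
    data.frame(neglogp = c(0.023, 0.062, 1.879), support = c(3, 8, 33),
               oddsratio = c(0.478, 0.717, 1.531), hs = c(0.644, 1.708, 24.679)),
    data.frame(neglogp = c(6.163, 3.241, 8.945), support = c(69, 95, 189),
               oddsratio = c(1.920, 1.433, 1.610), hs = c(43.011, 29.496, 40.642)),
    data.frame(neglogp = c(0.064, 0.006, 0.182), support = c(2, 2, 11),
               oddsratio = c(0.572, 0.321, 0.914), hs = c(1.669, 0.185, 4.500)),
    data.frame(neglogp = c(0.070, 0.023, 0.066), support = c(16, 28, 58),
               oddsratio = c(0.794, 0.752, 0.875), hs = c(1.923, 0.661, 1.841)),
    data.frame(neglogp = c(0.089, 0.283, 0.051), support = c(3, 8, 11),
               oddsratio = c(0.682, 1.024, 0.726), hs = c(2.303, 6.477, 1.432)),
    data.frame(neglogp = c(1.769, 1.346, 3.954), support = c(37, 59, 119),
               oddsratio = c(1.465, 1.267, 1.442), hs = c(23.531, 19.367, 31.416)),
    data.frame(neglogp = c(1.737, 0.845, 2.315), support = c(32, 45, 97),
               oddsratio = c(1.502, 1.187, 1.322), hs = c(23.571, 14.646, 25.031)),
    data.frame(neglogp = c(2.221, 2.336, 11.478), support = c(152, 267, 548),
               oddsratio = c(1.239, 1.181, 1.367), hs = c(23.734, 23.460, 36.561))
  )
}
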