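# 6 variants x 4 transducers with hand-placed overlaps at window 0:
#   s1 in A only; s2 in A and B; s3 in nothing; s4 in A, B and C;
#   s5 in all four; s6 in D only
toy_hotspot_layout <- function() {
  gm <- genome_model("chr1", 200000L)
  pos <- c(100, 5000, 20000, 40000, 60000, 90000)
  roi <- region_set("chr1", pos, pos + 1, name = paste0("s", 1:6),
                    genome = gm, label = "roi")
  mk <- function(starts, ends, lab) {
    region_set(rep("chr1", length(starts)), starts, ends, genome = gm,
               label = lab)
  }
  dbrs <- region_collection(list(
    mk(c(50, 4900, 39900, 59900), c(200, 5100, 40100, 60100), "A"),
    mk(c(4950, 39950, 59950), c(5050, 40050, 60050), "B"),
    mk(c(39990, 59990), c(40010, 60010), "C"),
    mk(c(59999, 89950), c(60002, 90050), "D")
  ))
  expected <- matrix(c(
    TRUE, FALSE, FALSE, FALSE,
    TRUE, TRUE, FALSE, FALSE,
    FALSE, FALSE, FALSE, FALSE,
    TRUE, TRUE, TRUE, FALSE,
    TRUE, TRUE, TRUE, TRUE,
    FALSE, FALSE, FALSE, TRUE
  ), ncol = 4, byrow = TRUE, dimnames = list(paste0("s", 1:6),
                                             c("A", "B", "C", "D")))
  list(genome = gm, roi = roi, dbrs = dbrs, expected = expected)
}

test_that("transducer membership equals the hand enumeration at window 0", {
  fx <- toy_hotspot_layout()
  mem <- transducer_membership(fx$roi, fx$dbrs, window = 0)
  got <- as.matrix(mem[, c("A", "B", "C", "D"), with = FALSE])
  rownames(got) <- mem$snp
  expect_identical(got, fx$expected)
  expect_equal(mem$k, as.integer(rowSums(fx$expected)))
  expect_error(transducer_membership(fx$roi, region_collection(list())),
               "empty DBR")
})

test_that("window extension reaches distant DBRs and variants count once", {
  gm <- genome_model("chr1", 200000L)
  # variant 40 kb away from the DBR: window 50 kb reaches it, 10 kb does not
  roi <- region_set("chr1", 10000, 10001, name = "s", genome = gm,
                    label = "roi")
  dbrs <- region_collection(list(
    region_set("chr1", 50000, 50100, genome = gm, label = "A")
  ))
  expect_false(transducer_membership(roi, dbrs, window = 10000)$A)
  expect_true(transducer_membership(roi, dbrs, window = 50000)$A)
  # union pooling over several windows
  expect_true(transducer_membership(roi, dbrs, window = c(10000, 50000))$A)

  # duplicated variant positions collapse to a single membership row
  dup <- region_set("chr1", c(10000, 10000), c(10001, 10001),
                    name = c("s", "s_alias"), genome = gm, label = "roi")
  expect_equal(nrow(transducer_membership(dup, dbrs, window = 50000)), 1L)
})

# independent brute-force subset enumeration over membership rows
venn_oracle <- function(flags, labels) {
  combos <- unlist(lapply(seq_along(labels), function(k) {
    apply(combn(labels, k), 2, paste, collapse = "+")
  }))
  out <- setNames(integer(length(combos)), combos)
  for (i in seq_len(nrow(flags))) {
    on <- labels[flags[i, ]]
    if (length(on) > 0) {
      key <- paste(on, collapse = "+")
      out[key] <- out[key] + 1L
    }
  }
  out
}

test_that("venn_counts gives exclusive cells matching brute-force enumeration", {
  fx <- toy_hotspot_layout()
  mem <- transducer_membership(fx$roi, fx$dbrs, window = 0)
  vc <- venn_counts(mem)
  expect_equal(sum(vc$cells), sum(mem$k >= 1))
  expect_equal(vc$cells[["A"]], 1L)
  expect_equal(vc$cells[["A+B"]], 1L)
  expect_equal(vc$cells[["A+B+C+D"]], 1L)
  expect_equal(vc$n_multi, 3L)

  # one region in all four sets
  one <- data.table::data.table(snp = "x", chrom = "chr1", pos = 1L,
                                A = TRUE, B = TRUE, C = TRUE, D = TRUE,
                                k = 4L)
  data.table::setattr(one, "transducers", c("A", "B", "C", "D"))
  vc1 <- venn_counts(one)
  expect_equal(vc1$cells[["A+B+C+D"]], 1L)
  expect_equal(sum(vc1$cells), 1L)

  set.seed(5)
  labels <- c("A", "B", "C", "D")
  flags <- matrix(runif(50 * 4) < 0.4, ncol = 4,
                  dimnames = list(NULL, labels))
  m <- data.table::data.table(snp = paste0("s", 1:50), chrom = "chr1",
                              pos = 1:50)
  for (lab in labels) data.table::set(m, j = lab, value = flags[, lab])
  data.table::set(m, j = "k", value = as.integer(rowSums(flags)))
  data.table::setattr(m, "transducers", labels)
  vc <- venn_counts(m)
  expect_equal(vc$cells, venn_oracle(flags, labels))
  expect_equal(unname(vc$by_k),
               vapply(1:4, function(k) sum(rowSums(flags) == k), 0L))
})

test_that("select_hotspots matches the hand enumeration and is monotone", {
  fx <- toy_hotspot_layout()
  mem <- transducer_membership(fx$roi, fx$dbrs, window = 0)
  h2 <- select_hotspots(mem, 2, fx$genome)
  expect_setequal(as.data.frame(h2)$name, c("s2", "s4", "s5"))
  h1 <- select_hotspots(mem, 1, fx$genome)
  expect_setequal(as.data.frame(h1)$name, c("s1", "s2", "s4", "s5", "s6"))
  expect_equal(length(select_hotspots(mem, 5, fx$genome)), 0L)
  expect_error(select_hotspots(mem, 0, fx$genome), "at least 1")
  for (k in 1:4) {
    expect_true(all(as.data.frame(select_hotspots(mem, k + 1, fx$genome))$name
                    %in% as.data.frame(select_hotspots(mem, k, fx$genome))$name))
  }
})

test_that("planted co-binding probabilities are recovered at window 0", {
  # direct-overlap membership recovers each transducer's planted binding
  # probability within binomial error
  probs <- c(VDR = 0.40, AID = 0.20, EBNA2 = 0.30, EBNA3C = 0.10)
  rates <- matrix(NA_real_, nrow = 10, ncol = 4,
                  dimnames = list(NULL, names(probs)))
  for (s in 1:10) {
    cfg <- sim_config(seed = 300 + s)
    sim <- simulate_universe_and_roi(cfg)
    dbrs <- simulate_dbr_sets(cfg, sim, bind_prob = probs)
    mem <- transducer_membership(sim$roi, dbrs$dbrs, window = 0)
    rates[s, ] <- colMeans(as.matrix(mem[, names(probs), with = FALSE]))
  }
  got <- colMeans(rates)
  # background coverage adds a small upward bias; tolerance covers it
  expect_true(all(abs(got - probs) < 0.05))
})
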