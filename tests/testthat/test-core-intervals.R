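test_that("region_set validates coordinates against the genome model", {
  gm <- toy_genome()
  expect_s3_class(region_set("chr1", 0, 1, genome = gm), "RegionSet")
  expect_error(region_set("chr9", 0, 1, genome = gm), "not in genome")
  expect_error(region_set("chr1", 5, 5, genome = gm), "start < end")
  expect_error(region_set("chr1", -1, 5, genome = gm), "start < end")
  expect_error(region_set("chr1", 0, 20001, genome = gm),
               "exceeds chromosome length")
})

test_that("read_bed parses canonical BED and the empty file", {
  gm <- toy_genome()
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), f)
  rs <- read_bed(f, gm)
  expect_equal(length(rs), 0L)

  writeLines(c("chr1\t10\t20", "chr1\t30\t40", "chr2\t5\t8"), f)
  rs <- read_bed(f, gm)
  df <- as.data.frame(rs)
  expect_equal(df$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(df$start, c(10, 30, 5))
  expect_equal(df$end, c(20, 40, 8))
})

test_that("malformed BED lines error with the line number or are skip-counted", {
  gm <- toy_genome()
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tok", "chr1\t30\t25\tbad", "chrZ\t1\t2\tbad2"), f)
  expect_error(read_bed(f, gm), "line 2")
  rs <- read_bed(f, gm, permissive = TRUE)
  expect_equal(length(rs), 1L)
  expect_equal(attr(rs, "n_skipped"), 2L)
  writeLines(c("chr1\t1.5\t20", "chr1\tx\t20"), f)
  expect_error(read_bed(f, gm), "line 1")
})

test_that("write_bed emits 4 columns and round-trips byte-identically", {
  gm <- toy_genome()
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(region_set(character(0), integer(0), integer(0), genome = gm), f)
  expect_identical(readBin(f, "raw", 10), raw(0))

  write_bed(region_set("chr1", 0, 1, name = "rs1", genome = gm), f)
  expect_identical(readLines(f), "chr1\t0\t1\trs1")

  set.seed(41)
  for (i in 1:100) {
    rs <- random_region_set(toy_genome(3L, 5000L), sample(1:30, 1))
    f1 <- withr::local_tempfile(fileext = ".bed")
    f2 <- withr::local_tempfile(fileext = ".bed")
    write_bed(rs, f1)
    write_bed(read_bed(f1, toy_genome(3L, 5000L)), f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
})

test_that("overlap counting is half-open and counts each query at most once", {
  gm <- toy_genome()
  q <- region_set("chr1", 10, 20, genome = gm, label = "q")
  expect_equal(count_overlapping(q, region_set("chr1", 19, 25, genome = gm))$n, 1L)
  expect_equal(count_overlapping(q, region_set("chr1", 20, 30, genome = gm))$n, 0L)
  expect_equal(count_overlapping(q, region_set("chr2", 10, 20, genome = gm))$n, 0L)
  # one query touching many subjects still counts once
  s <- region_set("chr1", c(10, 12, 14), c(11, 13, 15), genome = gm)
  expect_equal(count_overlapping(q, s)$n, 1L)
  expect_error(
    count_overlapping(q, region_set("chr1", 0, 1, genome = toy_genome(1L))),
    "mismatched genome"
  )
})

test_that("overlap is symmetric and bounded by query size", {
  gm <- toy_genome(2L, 2000L)
  set.seed(7)
  for (i in 1:25) {
    a <- random_region_set(gm, sample(1:15, 1), label = "a")
    b <- random_region_set(gm, sample(1:15, 1), label = "b")
    fa <- count_overlapping(a, b)
    fb <- count_overlapping(b, a)
    # symmetry of the predicate: a has any hit iff b has any hit
    expect_identical(any(fa$hits), any(fb$hits))
    expect_lte(fa$n, length(a))
  }
  whole <- region_set(c("chr1", "chr2"), c(0, 0), c(2000, 2000), genome = gm)
  q <- random_region_set(gm, 10)
  expect_equal(count_overlapping(q, whole)$n, length(q))
})

test_that("extend_and_clamp clamps at chromosome bounds and never merges", {
  gm <- genome_model("chr1", 120000L)
  pt <- region_set("chr1", 100000, 100001, name = "s", genome = gm)
  ext <- extend_and_clamp(pt, 50000)
  df <- as.data.frame(ext)
  expect_equal(df$start, 50000)
  expect_equal(df$end, 120000)
  expect_equal(df$name, "s")

  expect_equal(as.data.frame(extend_and_clamp(pt, 0)), as.data.frame(pt))

  two <- region_set("chr1", c(50000, 60000), c(50001, 60001),
                    name = c("a", "b"), genome = gm)
  ext2 <- extend_and_clamp(two, 50000)
  expect_equal(length(ext2), 2L)
  expect_equal(as.data.frame(ext2)$name, c("a", "b"))

  expect_error(extend_and_clamp(two, -1), "non-negative")

  set.seed(11)
  for (i in 1:20) {
    rs <- random_region_set(toy_genome(2L, 3000L), 10)
    e <- as.data.frame(extend_and_clamp(rs, sample(0:5000, 1)))
    expect_true(all(e$start >= 0))
    expect_true(all(e$end <= 3000))
  }
})

test_that("merge_overlapping yields disjoint sorted cover conserving bases", {
  gm <- toy_genome(1L)
  rs <- region_set("chr1", c(10, 15), c(20, 25), genome = gm)
  m <- as.data.frame(merge_overlapping(rs))
  expect_equal(m$start, 10)
  expect_equal(m$end, 25)

  disj <- region_set("chr1", c(30, 10), c(40, 20), genome = gm)
  md <- as.data.frame(merge_overlapping(disj))
  expect_equal(md$start, c(10, 30))

  set.seed(23)
  for (i in 1:20) {
    rs <- random_region_set(toy_genome(2L, 500L), 12)
    m <- merge_overlapping(rs)
    df <- as.data.frame(m)
    expect_equal(sum(df$end - df$start), covered_bases_oracle(rs))
    # disjoint after merge: no pair on one chromosome overlaps
    for (g in split(df, df$chrom)) {
      if (nrow(g) > 1L) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    }
  }
})
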