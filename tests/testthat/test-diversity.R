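test_that("clonality counts unique identity keys", {
  r <- repertoire(data.frame(cdr3_nt = c("TGTGCC", "TGTGCC", "TGTTTT"),
                             cdr3_aa = NA, v_gene = "TRBV1", j_gene = "TRBJ1-1",
                             reads = c(1L, 2L, 3L)))
  expect_equal(clonality(r, "nt"), 2L)
  er <- suppressWarnings(
    repertoire(data.frame(cdr3_nt = character(0), cdr3_aa = character(0),
                          v_gene = character(0), j_gene = character(0),
                          reads = integer(0))))
  expect_equal(clonality(er), 0L)
  # synonymous codons collapse at aa level: aa clonality <= nt clonality
  set.seed(7)
  for (i in 1:5) {
    n <- 200
    nt <- vapply(sample(3:5, n, replace = TRUE), function(k)
      paste(sample(c("TGT", "TGC", "GCA", "GCC"), k, replace = TRUE),
            collapse = ""), character(1))
    rr <- repertoire(data.frame(cdr3_nt = nt, cdr3_aa = NA, v_gene = "TRBV1",
                                j_gene = "TRBJ1-1",
                                reads = sample.int(5, n, replace = TRUE)))
    expect_lte(clonality(rr, "aa"), clonality(rr, "nt"))
  }
})

test_that("D50 matches its definition on analytic cases", {
  # uniform repertoire: 100 clones, 1 read each -> rank 50 -> 50.0
  u <- d50(make_rep(rep(1L, 100)))
  expect_equal(u$d50, 50.0)
  expect_equal(u$branch, "lt10k")
  # dominant clone: reads [91, 1 x 9] -> rank 1 holds >= 50 -> 1 * 100 / 10
  dom <- d50(make_rep(c(91L, rep(1L, 9))))
  expect_equal(dom$d50, 10.0)
  expect_equal(dom$clonality, 10L)
  expect_error(d50(suppressWarnings(repertoire(
    data.frame(cdr3_nt = character(0), cdr3_aa = character(0),
               v_gene = character(0), j_gene = character(0),
               reads = integer(0))))), "empty")
})

test_that("D50 branch switches exactly at 10,000 unique clones", {
  for (U in c(9999L, 10000L, 10001L)) {
    res <- d50(make_rep(rep(1L, U)))
    if (U < 10000L) {
      expect_equal(res$branch, "lt10k")
      expect_equal(res$d50, ceiling(U / 2) * 100 / U)
    } else {
      expect_equal(res$branch, "ge10k")
      expect_equal(res$d50, 50.0)  # 5000 * 100 / 10000 for uniform reads
    }
  }
})

test_that("D50 is scale-invariant and non-increasing under concentration", {
  for (seed in 1:20) {
    r <- random_rep(sample(c(50, 500, 2000), 1), seed, heavy = TRUE)
    base <- d50(r)$d50
    scaled <- r
    scaled$clones$reads <- scaled$clones$reads * 7L
    scaled$total_reads <- sum(scaled$clones$reads)
    expect_equal(d50(scaled)$d50, base)
    boosted <- r
    boosted$clones$reads[1] <- boosted$clones$reads[1] +
      as.integer(sample.int(1000, 1))
    boosted$total_reads <- sum(boosted$clones$reads)
    expect_lte(d50(boosted)$d50, base)
  }
})

test_that("D50 agrees with the brute-force oracle on both branches", {
  for (seed in 1:40) {
    set.seed(seed)
    U <- sample(c(50:200, 9000:11000), 1)
    reads <- pmax(1L, as.integer(round(stats::rlnorm(U, 1, 1.3))))
    r <- make_rep(reads)
    expect_identical(d50(r)$d50,
                     d50_oracle(reads, nt_from_int(seq_along(reads) - 1L)),
                     label = paste("seed", seed))
  }
})

test_that("the large-repertoire branch supports both 50% reference totals", {
  set.seed(99)
  reads <- c(rep(1000L, 50), rep(1L, 12000))
  r <- make_rep(reads)
  trunc <- d50(r, reference_total = "truncated")
  full <- d50(r, reference_total = "all")
  # truncated total = 50*1000 + 9950 = 59950; half = 29975 -> rank 30
  expect_equal(trunc$d50, 30 * 100 / 10000)
  # full total = 62000; half = 31000 -> cumulative reaches 31000 at rank 31
  expect_equal(full$d50, 31 * 100 / 10000)
  expect_equal(trunc$branch, "ge10k")
})

test_that("homeostasis bins partition read mass over the fixed rank bins", {
  # exactly 10 clones -> all mass in the first bin
  h10 <- homeostasis_profile(make_rep(rep(3L, 10)))
  expect_equal(h10$proportions, c(1, 0, 0, 0, 0, 0))
  # 35 uniform clones -> 10/35 then 25/35
  h35 <- homeostasis_profile(make_rep(rep(1L, 35)))
  expect_equal(h35$proportions, c(10 / 35, 25 / 35, 0, 0, 0, 0))
  # random repertoires below the last edge: proportions sum to 1
  for (seed in 1:10) {
    h <- homeostasis_profile(random_rep(5000, seed, heavy = TRUE))
    expect_equal(sum(h$proportions), 1, tolerance = 1e-12)
    expect_true(all(h$proportions >= 0 & h$proportions <= 1))
    expect_equal(h$remainder, 0)
  }
  expect_error(homeostasis_profile(suppressWarnings(repertoire(
    data.frame(cdr3_nt = character(0), cdr3_aa = character(0),
               v_gene = character(0), j_gene = character(0),
               reads = integer(0))))), "empty")
})

test_that("top-n proportion matches ranked reads and the first homeostasis bin", {
  expect_equal(top_n_proportion(make_rep(rep(2L, 10)), 10), 1.0)
  expect_equal(top_n_proportion(make_rep(c(50L, 30L, 20L)), 1), 0.5)
  expect_equal(top_n_proportion(make_rep(c(5L, 3L)), 99), 1.0)
  expect_error(top_n_proportion(make_rep(5L), 0), "n must be")
  for (seed in 1:5) {
    r <- random_rep(300, seed, heavy = TRUE)
    expect_equal(top_n_proportion(r, 10),
                 homeostasis_profile(r)$proportions[1])
    tc <- top_clones(r, 10)
    expect_equal(top_n_proportion(r, 10), sum(tc$reads) / r$total_reads)
  }
})

test_that("read-threshold counts and the median clone frequency behave", {
  r <- make_rep(c(3L, 2L, 1L, 1L))
  expect_equal(count_clones_at_least(r, 2), 2L)
  expect_equal(count_clones_at_least(r, 1), clonality(r))
  expect_error(count_clones_at_least(r, 0), "min_reads")
  # monotone non-increasing in the threshold
  rr <- random_rep(500, 11, heavy = TRUE)
  counts <- sapply(1:10, function(m) count_clones_at_least(rr, m))
  expect_true(all(diff(counts) <= 0))

  # lower-median convention
  expect_equal(median_clone_frequency(make_rep(c(1L, 1L, 2L, 5L))), 1L)
  expect_equal(median_clone_frequency(make_rep(7L)), 7L)
  # sort-and-index oracle on random repertoires
  for (seed in 1:50) {
    r <- random_rep(sample(3:40, 1), seed, max_reads = 9L)
    sorted <- sort(r$clones$reads)
    expect_equal(median_clone_frequency(r),
                 sorted[(length(sorted) + 1) %/% 2])
  }
})
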