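test_that("gene frequencies respect weighting and stay on the simplex", {
  r <- repertoire(data.frame(cdr3_nt = c("TGTGCC", "TGTTTT"), cdr3_aa = NA,
                             v_gene = c("TRBV1", "TRBV2"),
                             j_gene = c("TRBJ1-1", "TRBJ1-2"),
                             reads = c(3L, 1L)))
  fr <- gene_frequencies(r, "V", "reads")
  expect_equal(unname(fr[c("TRBV1", "TRBV2")]), c(0.75, 0.25))
  fc <- gene_frequencies(r, "V", "clones")
  expect_equal(unname(fc[c("TRBV1", "TRBV2")]), c(0.5, 0.5))
  single <- repertoire(data.frame(cdr3_nt = "TGTGCC", cdr3_aa = NA,
                                  v_gene = "TRBV19", j_gene = "TRBJ1-1",
                                  reads = 4L))
  expect_equal(as.numeric(gene_frequencies(single, "V")), 1.0)
  fj <- gene_frequencies(r, "J")
  expect_equal(sum(fj), 1)
})

test_that("usage matrices are dense over the gene union with unit row sums", {
  a <- repertoire(data.frame(cdr3_nt = "TGTGCC", cdr3_aa = NA,
                             v_gene = "TRBV1", j_gene = "TRBJ1-1", reads = 2L),
                  sample_id = "a")
  b <- repertoire(data.frame(cdr3_nt = "TGTTTT", cdr3_aa = NA,
                             v_gene = "TRBV2", j_gene = "TRBJ1-1", reads = 3L),
                  sample_id = "b")
  m <- usage_matrix(list(a, b), "V")
  expect_equal(unclass(m)[, c("TRBV1", "TRBV2")],
               matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"),
                                                        c("TRBV1", "TRBV2"))))
  reps <- lapply(1:4, function(i) {
    set.seed(i)
    n <- 50
    repertoire(data.frame(cdr3_nt = nt_from_int(1:n), cdr3_aa = NA,
                          v_gene = sample(c("TRBV2", "TRBV12-1", "TRBV3"), n, TRUE),
                          j_gene = "TRBJ1-1",
                          reads = sample.int(9, n, TRUE)),
               sample_id = paste0("s", i))
  })
  mm <- usage_matrix(reps, "V")
  expect_equal(unname(rowSums(mm)), rep(1, 4), tolerance = 1e-9)
  # numeric-aware gene order: TRBV2 and TRBV3 before TRBV12-1
  expect_equal(colnames(mm), c("TRBV2", "TRBV3", "TRBV12-1"))
  # per-sample recomputation oracle
  for (i in 1:4) {
    f <- gene_frequencies(reps[[i]], "V")
    expect_equal(unclass(mm)[paste0("s", i), names(f)], f,
                 ignore_attr = TRUE)
  }
  expect_error(usage_matrix(list(a, a)), "duplicate")
  expect_error(usage_matrix(list(a)), "at least 2")
})

test_that("usage PCA has the documented conventions and reconstructs the data", {
  set.seed(3)
  base <- matrix(stats::runif(8 * 6), 8, 6)
  base <- base / rowSums(base)
  colnames(base) <- paste0("TRBV", 1:6)
  rownames(base) <- paste0("s", 1:8)
  p <- usage_pca(base, n_components = 5)
  # orthonormal loadings
  expect_equal(crossprod(p$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  # non-increasing explained variance, sums to <= 1
  expect_true(all(diff(p$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(p$explained_variance_fraction), 1 + 1e-9)
  # sign convention: the largest-magnitude loading of each component positive
  for (j in 1:5)
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  # full-rank reconstruction of the centered matrix
  centered <- sweep(base, 2, p$center)
  k <- min(nrow(base) - 1, ncol(base))
  pf <- usage_pca(base, n_components = k)
  expect_equal(pf$scores %*% t(pf$loadings), centered, tolerance = 1e-6,
               ignore_attr = TRUE)
  # duplicated samples get identical scores
  dup <- rbind(base, base[1, , drop = FALSE])
  rownames(dup)[9] <- "s1b"
  pd <- usage_pca(dup, 2)
  expect_equal(unname(pd$scores["s1", ]), unname(pd$scores["s1b", ]),
               tolerance = 1e-9)
  # variation confined to one gene: component 1 loads on it alone
  flat <- matrix(1 / 6, 8, 6, dimnames = dimnames(base))
  flat[, "TRBV3"] <- flat[, "TRBV3"] + seq(0, 0.07, length.out = 8)
  p1 <- usage_pca(flat, 1)
  expect_equal(p1$explained_variance_fraction[1], 1, tolerance = 1e-9)
  expect_equal(abs(unname(p1$loadings["TRBV3", 1])), 1, tolerance = 1e-6)
  # invariant to sample order up to the sign convention
  perm <- sample(nrow(base))
  pp <- usage_pca(base[perm, ], 2)
  expect_equal(pp$scores[rownames(base), ], usage_pca(base, 2)$scores,
               tolerance = 1e-9)
  expect_error(usage_pca(base[1:2, ], 1), "at least 3")
  expect_error(usage_pca(base, 8), "n_components")
})

test_that("Sidak correction matches its closed form and flags forced shifts", {
  set.seed(11)
  for (i in 1:20) {
    p <- stats::runif(sample(1:30, 1))
    m <- length(p)
    expect_equal(sidak_adjust(p), pmin(1, 1 - (1 - p)^m))
  }
  # identical groups: nothing flagged
  g <- matrix(stats::runif(12), 4, 3,
              dimnames = list(paste0("s", 1:4), paste0("TRBV", 1:3)))
  g <- g / rowSums(g)
  cmp <- compare_gene_usage(g, g)
  expect_false(any(cmp$significant))
  # a single strongly shifted gene with jitter elsewhere: only it is flagged
  set.seed(5)
  a <- matrix(0.2 + stats::rnorm(20, 0, 0.001), 4, 5,
              dimnames = list(paste0("a", 1:4), paste0("TRBV", 1:5)))
  b <- a + stats::rnorm(20, 0, 0.001)
  rownames(b) <- paste0("b", 1:4)
  b[, "TRBV4"] <- b[, "TRBV4"] + 0.5
  cmp2 <- compare_gene_usage(a, b)
  expect_true(cmp2$significant[cmp2$gene == "TRBV4"])
  expect_false(any(cmp2$significant[cmp2$gene != "TRBV4"]))
  expect_error(compare_gene_usage(g[1, , drop = FALSE], g), "at least 2")
  # two-factor layout over gene x group detects the same shift
  an <- gene_usage_anova(a, b)
  expect_lt(an$p_value[an$effect == "gene:group"], 0.05)
})
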