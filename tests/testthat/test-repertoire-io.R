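test_that("repertoire construction validates, strips alleles and orders deterministically", {
  r <- repertoire(data.frame(
    cdr3_nt = c("TGTGCCTTT", "TGTGCCAGC", "TGTGCCAAA"), cdr3_aa = NA,
    v_gene = c("TRBV12-1*01", "TRBV2", "TRBV12-1"),
    j_gene = "TRBJ2-7*02", reads = c(3L, 5L, 3L)), sample_id = "s1")
  expect_s3_class(r, "tcr_repertoire")
  expect_equal(r$total_reads, 11L)
  expect_equal(r$clones$v_gene, c("TRBV2", "TRBV12-1", "TRBV12-1"))
  expect_true(all(r$clones$j_gene == "TRBJ2-7"))
  # reads desc, tie broken by lexicographically smaller cdr3_nt
  expect_equal(r$clones$cdr3_nt, c("TGTGCCAGC", "TGTGCCAAA", "TGTGCCTTT"))
  # translation derived where absent
  expect_equal(r$clones$cdr3_aa[1], "CAS")

  expect_error(repertoire(data.frame(cdr3_nt = "TGT", v_gene = "V", j_gene = "J",
                                     reads = 0L)), "positive integers")
  expect_error(repertoire(data.frame(cdr3_nt = "TGN", v_gene = "V", j_gene = "J",
                                     reads = 1L)), "outside")
  expect_error(repertoire(data.frame(cdr3_nt = "TGTGCTA", cdr3_aa = "CA_",
                                     v_gene = "V", j_gene = "J", reads = 1L)),
               "_")
  expect_error(repertoire(data.frame(cdr3_nt = "TGT", v_gene = "V", j_gene = "J",
                                     reads = 1L), tissue = "spleen"),
               "tissue")
})

test_that("collapse merges identity keys, conserves reads and is idempotent", {
  # same cdr3_nt, reads 4 + 6 -> one clone with 10
  r <- repertoire(data.frame(cdr3_nt = c("TGTGCC", "TGTGCC"), cdr3_aa = NA,
                             v_gene = c("TRBV1", "TRBV2"), j_gene = "TRBJ1-1",
                             reads = c(4L, 6L)))
  rc <- collapse_clones(r, "nt")
  expect_equal(nrow(rc$clones), 1L)
  expect_equal(rc$clones$reads, 10L)
  expect_equal(rc$clones$v_gene, "TRBV2")  # representative = highest-reads member

  # distinct nt, same aa translation, collapse at aa level
  r2 <- repertoire(data.frame(cdr3_nt = c("TGTGCC", "TGCGCA"), cdr3_aa = NA,
                              v_gene = "TRBV1", j_gene = "TRBJ1-1",
                              reads = c(2L, 1L)))
  expect_equal(r2$clones$cdr3_aa, c("CA", "CA"))
  expect_equal(nrow(collapse_clones(r2, "aa")$clones), 1L)
  expect_equal(nrow(collapse_clones(r2, "nt")$clones), 2L)
  # nt_vj separates what nt alone merges
  r3 <- repertoire(data.frame(cdr3_nt = c("TGTGCC", "TGTGCC"), cdr3_aa = NA,
                              v_gene = c("TRBV1", "TRBV2"), j_gene = "TRBJ1-1",
                              reads = c(4L, 6L)))
  expect_equal(nrow(collapse_clones(r3, "nt_vj")$clones), 2L)

  # conservation + idempotence on random repertoires
  for (seed in 1:5) {
    rr <- random_rep(200, seed)
    for (level in c("nt", "aa", "nt_vj", "aa_vj")) {
      cc <- collapse_clones(rr, level)
      expect_equal(cc$total_reads, rr$total_reads)
      expect_identical(collapse_clones(cc, level)$clones, cc$clones)
    }
  }
})

test_that("pooling concatenates, collapses and conserves reads", {
  a <- make_rep(c(5L, 3L, 2L), sample_id = "a", tissue = "pLN")
  b <- make_rep(c(3L, 2L), sample_id = "b", offset = 100L, tissue = "pLN")
  pool <- pool_repertoires(list(a, b))
  expect_equal(nrow(pool$clones), 5L)
  expect_equal(pool$total_reads, 15L)

  # identical repertoires: clone set preserved, reads doubled
  dbl <- pool_repertoires(list(a, a))
  expect_equal(nrow(dbl$clones), 3L)
  expect_equal(dbl$clones$reads, 2L * collapse_clones(a, "nt")$clones$reads)

  # union oracle on random repertoires with overlapping key ranges
  r1 <- random_rep(80, 1, offset = 0L)
  r2 <- random_rep(80, 2, offset = 40L)
  r3 <- random_rep(80, 3, offset = 90L)
  pool3 <- pool_repertoires(list(r1, r2, r3))
  union_keys <- unique(c(clone_keys(r1, "nt"), clone_keys(r2, "nt"),
                         clone_keys(r3, "nt")))
  expect_equal(nrow(pool3$clones), length(union_keys))
  expect_lte(nrow(pool3$clones), sum(sapply(list(r1, r2, r3), clonality)))
  expect_equal(pool3$total_reads, r1$total_reads + r2$total_reads + r3$total_reads)

  expect_error(pool_repertoires(list()), "at least one")
  expect_warning(pool_repertoires(list(a, make_rep(2L, tissue = "joint"))),
                 "tissue")
})

test_that("translation follows the standard codon table", {
  expect_equal(translate_cdr3("TGTGCC"), "CA")
  expect_equal(translate_cdr3("TGA"), "*")
  expect_equal(translate_cdr3(c("ATG", "TTTAAA")), c("M", "FK"))
  expect_error(translate_cdr3("TGTGC"), "multiple of 3")
  expect_error(translate_cdr3("TGN"), "outside")
})

test_that("AIRR reader validates columns and counts", {
  path <- write_airr_fixture(tempfile(fileext = ".tsv"), counts = c(5L, 3L, 1L))
  r <- read_airr(path, tissue = "pLN")
  expect_equal(r$total_reads, 9L)
  expect_equal(nrow(r$clones), 3L)
  expect_false(any(grepl("\\*", r$clones$v_gene)))

  # missing mandatory column named in the error
  broken <- tempfile(fileext = ".tsv")
  tab <- utils::read.delim(path)
  utils::write.table(tab[, setdiff(names(tab), "v_call")], broken, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_airr(broken), "v_call")

  # zero counts: rejected in strict mode, imputed to 1 in lenient mode
  zero <- tempfile(fileext = ".tsv")
  tab$duplicate_count[2] <- 0L
  utils::write.table(tab, zero, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_airr(zero), "line 2")
  expect_equal(read_airr(zero, strict_counts = FALSE)$total_reads, 7L)

  # unparseable count reported with its line
  bad <- tempfile(fileext = ".tsv")
  tab$duplicate_count <- c("5", "x", "1")
  utils::write.table(tab, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_airr(bad), "line 2")
})

test_that("clone-table dialects map onto the same repertoire as the AIRR reader", {
  nt <- nt_from_int(1:2)
  mixcr <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(cloneCount = c(10L, 1L), nSeqCDR3 = nt,
               aaSeqCDR3 = translate_cdr3(nt),
               allVHitsWithScore = c("TRBV12-1*00(1289.5),TRBV12-2*00(478)",
                                     "TRBV2*00(900)"),
               allJHitsWithScore = "TRBJ2-7*00(250)"),
    mixcr, sep = "\t", quote = FALSE, row.names = FALSE)
  rm <- read_clone_table(mixcr, dialect = "mixcr")
  expect_equal(nrow(rm$clones), 2L)
  expect_equal(rm$total_reads, 11L)
  expect_equal(rm$clones$v_gene[rm$clones$reads == 10L], "TRBV12-1")

  # generic dialect with a user map reproduces the AIRR reader's repertoire
  airr <- write_airr_fixture(tempfile(fileext = ".tsv"))
  gen <- tempfile(fileext = ".tsv")
  tab <- utils::read.delim(airr)
  names(tab) <- c("seq", "aa", "vg", "jg", "n")
  utils::write.table(tab, gen, sep = "\t", quote = FALSE, row.names = FALSE)
  rg <- read_clone_table(gen, dialect = "generic",
                         column_map = c(cdr3_nt = "seq", cdr3_aa = "aa",
                                        v_gene = "vg", j_gene = "jg",
                                        reads = "n"),
                         sample_id = "x")
  ra <- read_airr(airr, sample_id = "x")
  expect_identical(rg$clones, ra$clones)

  expect_error(read_clone_table(gen, dialect = "nonsense"), "dialect")
  expect_error(read_clone_table(gen, dialect = "generic"), "column_map")

  # header-only table: empty repertoire with a warning
  empty <- tempfile(fileext = ".tsv")
  writeLines(paste(c("junction", "junction_aa", "v_call", "j_call",
                     "duplicate_count"), collapse = "\t"), empty)
  expect_warning(re <- read_airr(empty), "no clones")
  expect_equal(re$total_reads, 0L)
  expect_equal(nrow(re$clones), 0L)
})

test_that("write/read round trips are the identity on validated repertoires", {
  for (seed in 1:3) {
    r <- random_rep(50, seed, sample_id = "rt")
    for (fmt in c("airr", "generic_tsv")) {
      path <- tempfile(fileext = ".tsv")
      write_repertoire(r, path, format = fmt)
      back <- if (fmt == "airr") read_airr(path, sample_id = "rt")
              else read_clone_table(path, dialect = "generic",
                                    column_map = c(cdr3_nt = "cdr3_nt",
                                                   cdr3_aa = "cdr3_aa",
                                                   v_gene = "v_gene",
                                                   j_gene = "j_gene",
                                                   reads = "reads"),
                                    sample_id = "rt")
      expect_identical(back$clones, r$clones)
    }
  }
  # deterministic output ordering: reads desc, then cdr3_nt
  r <- make_rep(c(2L, 7L, 2L))
  path <- tempfile(fileext = ".tsv")
  write_repertoire(r, path)
  written <- utils::read.delim(path)
  expect_equal(written$duplicate_count, sort(written$duplicate_count,
                                             decreasing = TRUE))
  # empty repertoire -> header-only file
  er <- suppressWarnings(
    repertoire(data.frame(cdr3_nt = character(0), cdr3_aa = character(0),
                          v_gene = character(0), j_gene = character(0),
                          reads = integer(0))))
  p2 <- tempfile(fileext = ".tsv")
  write_repertoire(er, p2)
  expect_equal(length(readLines(p2)), 1L)
})
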