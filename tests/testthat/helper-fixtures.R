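# Fixture builders and independent oracles shared across the suite.

# deterministic, distinct DNA strings: base-4 encoding of an integer over
# {A,C,G,T}, fixed width (a multiple of 3 so translation is defined)
nt_from_int <- function(i, width = 15L) {
  bases <- c("A", "C", "G", "T")
  x <- as.integer(i)
  cols <- vector("list", width)
  for (j in width:1) {
    cols[[j]] <- bases[x %% 4L + 1L]
    x <- x %/% 4L
  }
  do.call(paste0, cols)
}

# repertoire with synthetic clone keys; cdr3_aa is set equal to cdr3_nt so
# nt- and aa-level identities coincide and no translation is involved
make_rep <- function(reads, sample_id = "s", offset = 0L, v_gene = "TRBV1",
                     j_gene = "TRBJ1-1", ...) {
  n <- length(reads)
  nt <- nt_from_int(offset + seq_len(n) - 1L)
  repertoire(data.frame(cdr3_nt = nt, cdr3_aa = nt,
                        v_gene = v_gene, j_gene = j_gene,
                        reads = as.integer(reads), stringsAsFactors = FALSE),
             sample_id = sample_id, ...)
}

random_rep <- function(n_clones, seed, max_reads = 20L,
                       sample_id = paste0("r", seed), heavy = FALSE,
                       offset = 0L) {
  set.seed(seed)
  reads <- if (heavy) {
    pmax(1L, as.integer(round(stats::rlnorm(n_clones, 1, 1.5))))
  } else {
    sample.int(max_reads, n_clones, replace = TRUE)
  }
  make_rep(reads, sample_id = sample_id, offset = offset)
}

# Independent brute-force D50 oracle: explicit accumulation loop over the
# ranked reads, written directly from the two-branch definition.
d50_oracle <- function(reads, keys = as.character(seq_along(reads))) {
  ord <- order(-reads, keys, method = "radix")
  reads <- reads[ord]
  U <- length(reads)
  if (U >= 10000L) {
    reads <- reads[1:10000]
    ref <- sum(as.numeric(reads))
    denom <- 10000
  } else {
    ref <- sum(as.numeric(reads))
    denom <- U
  }
  acc <- 0
  r <- NA_integer_
  for (k in seq_along(reads)) {
    acc <- acc + reads[k]
    if (acc >= ref / 2) { r <- k; break }
  }
  r * 100 / denom
}

# tiny AIRR fixture writer used by the IO tests
write_airr_fixture <- function(path, counts = c(5L, 3L, 1L)) {
  n <- length(counts)
  df <- data.frame(junction = nt_from_int(seq_len(n)),
                   junction_aa = translate_cdr3(nt_from_int(seq_len(n))),
                   v_call = paste0("TRBV", seq_len(n), "*01"),
                   j_call = "TRBJ2-7*01",
                   duplicate_count = counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
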