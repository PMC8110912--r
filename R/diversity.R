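#' Clonality: the number of unique CDR3 sequences
#'
#' Clonality here is a richness count — the number of unique clone identity
#' keys in the repertoire — not an evenness score. The default level counts
#' unique CDR3 nucleotide sequences.
#'
#' @inheritParams clone_keys
#' @return non-negative integer.
#' @export
clonality <- function(rep, level = c("nt", "aa", "nt_vj", "aa_vj")) {
  level <- match.arg(level)
  if (nrow(rep$clones) == 0L) return(0L)
  length(unique(clone_keys(rep, level)))
}

#' D50 diversity index
#'
#' The D50 index is the percentage of ranked clones needed to account for
#' half of the reads. Clones are sorted by reads descending (ties broken by
#' CDR3 nucleotide sequence). With `U` unique clones:
#'
#' * `U >= 10000` (`ge10k` branch): restrict to the top 10,000 clones, let
#'   `T` be their summed reads, find the smallest rank `r` whose cumulative
#'   reads reach `T/2`; D50 = `r * 100 / 10000`.
#' * `U < 10000` (`lt10k` branch): `T` is the total reads; D50 =
#'   `r * 100 / U`.
#'
#' "Reaches `T/2`" means cumulative reads `>= T/2` at rank `r` — the rank is
#' integral, no interpolation. In the `ge10k` branch the 50% reference total
#' is, by default, computed within the top-10,000 truncation
#' (`reference_total = "truncated"`); `reference_total = "all"` instead
#' measures 50% against all reads, an alternative reading of the same
#' vendor formula.
#'
#' Low D50 means domination by few clones; a perfectly uniform repertoire
#' has D50 near 50.
#'
#' @inheritParams clone_keys
#' @param reference_total reference total for the 50% point in the `ge10k`
#'   branch: `"truncated"` (default) or `"all"`.
#' @return list with `sample_id`, `clonality`, `d50`, `branch`
#'   (`"ge10k"`/`"lt10k"`).
#' @export
d50 <- function(rep, level = c("nt", "aa", "nt_vj", "aa_vj"),
                reference_total = c("truncated", "all")) {
  level <- match.arg(level)
  reference_total <- match.arg(reference_total)
  rep <- collapse_clones(rep, level)
  reads <- rep$clones$reads  # already sorted desc with deterministic ties
  U <- length(reads)
  if (U == 0L) stop("D50 is undefined for an empty repertoire", call. = FALSE)
  if (U >= 10000L) {
    top <- reads[1:10000]
    ref <- if (reference_total == "truncated") sum(top) else sum(reads)
    r <- which(cumsum(top) >= ref / 2)[1]
    if (is.na(r)) r <- 10000L  # only possible under reference_total = "all"
    value <- r * 100 / 10000
    branch <- "ge10k"
  } else {
    r <- which(cumsum(reads) >= sum(reads) / 2)[1]
    value <- r * 100 / U
    branch <- "lt10k"
  }
  list(sample_id = rep$sample_id, clonality = U, d50 = value, branch = branch)
}

#' Clonal-space homeostasis profile
#'
#' Partition of the repertoire's read mass across fixed rank bins of clones:
#' the top 10 most frequent clones, then the next 25, 500, 3,000, 10,000 and
#' 100,000 (rank boundaries 10, 35, 535, 3,535, 13,535, 113,535). Read mass
#' of clones ranked beyond 113,535 is reported in `remainder`. For
#' repertoires with at most 113,535 unique clones the six proportions sum to
#' one.
#'
#' @inheritParams clone_keys
#' @return list with `sample_id`, `bin_edges`, `bin_labels`, `proportions`
#'   (length 6) and `remainder`.
#' @export
homeostasis_profile <- function(rep, level = c("nt", "aa", "nt_vj", "aa_vj")) {
  level <- match.arg(level)
  rep <- collapse_clones(rep, level)
  reads <- rep$clones$reads
  if (length(reads) == 0L)
    stop("homeostasis profile is undefined for an empty repertoire", call. = FALSE)
  edges <- c(10L, 35L, 535L, 3535L, 13535L, 113535L)
  lower <- c(0L, edges[-6])
  total <- sum(reads)
  csum <- c(0, cumsum(as.numeric(reads)))
  U <- length(reads)
  mass_to <- function(r) csum[min(r, U) + 1L]
  props <- vapply(seq_along(edges), function(i) {
    (mass_to(edges[i]) - mass_to(lower[i])) / total
  }, numeric(1))
  list(sample_id = rep$sample_id,
       bin_edges = edges,
       bin_labels = c("top10", "next25", "next500", "next3000", "next10000",
                      "next100000"),
       proportions = props,
       remainder = (total - mass_to(edges[6])) / total)
}

#' Read-mass proportion of the top n clones
#'
#' @inheritParams clone_keys
#' @param n positive integer; when `n` exceeds the unique clone count the
#'   proportion is 1.
#' @return real in `[0, 1]`.
#' @export
top_n_proportion <- function(rep, n = 10, level = c("nt", "aa", "nt_vj", "aa_vj")) {
  level <- match.arg(level)
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  rep <- collapse_clones(rep, level)
  reads <- rep$clones$reads
  if (length(reads) == 0L)
    stop("top-n proportion is undefined for an empty repertoire", call. = FALSE)
  sum(reads[seq_len(min(n, length(reads)))]) / sum(reads)
}

#' Count clones at or above a read threshold
#'
#' Used with a data-driven threshold (e.g. the median clone read count of a
#' control sample) to count clones assumed to have expanded.
#'
#' @inheritParams clone_keys
#' @param min_reads positive integer threshold.
#' @return non-negative integer; `min_reads = 1` recovers clonality.
#' @export
count_clones_at_least <- function(rep, min_reads,
                                  level = c("nt", "aa", "nt_vj", "aa_vj")) {
  level <- match.arg(level)
  if (length(min_reads) != 1L || is.na(min_reads) || min_reads < 1)
    stop("min_reads must be >= 1", call. = FALSE)
  rep <- collapse_clones(rep, level)
  sum(rep$clones$reads >= min_reads)
}

#' Median clone read count
#'
#' Lower-median convention for even clone counts, so the threshold is always
#' an achievable integer read count.
#'
#' @inheritParams clone_keys
#' @return the lower median of the clone read-count distribution.
#' @export
median_clone_frequency <- function(rep, level = c("nt", "aa", "nt_vj", "aa_vj")) {
  level <- match.arg(level)
  rep <- collapse_clones(rep, level)
  reads <- sort(rep$clones$reads)
  n <- length(reads)
  if (n == 0L) stop("median is undefined for an empty repertoire", call. = FALSE)
  reads[(n + 1L) %/% 2L]
}

#' Per-sample diversity summary table
#'
#' Convenience wrapper producing one row per repertoire with clonality, D50,
#' the branch applied and the six homeostasis bin proportions.
#'
#' @param reps list of `tcr_repertoire` objects.
#' @inheritParams d50
#' @return data.frame with one row per sample.
#' @export
diversity_table <- function(reps, level = "nt", reference_total = "truncated") {
  rows <- lapply(reps, function(r) {
    d <- d50(r, level = level, reference_total = reference_total)
    h <- homeostasis_profile(r, level = level)
    out <- data.frame(sample_id = r$sample_id, subject_id = r$subject_id,
                      tissue = r$tissue, phase = r$phase,
                      condition = r$condition, total_reads = r$total_reads,
                      clonality = d$clonality, d50 = d$d50, branch = d$branch,
                      stringsAsFactors = FALSE)
    props <- as.data.frame(as.list(h$proportions))
    names(props) <- h$bin_labels
    cbind(out, props)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
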