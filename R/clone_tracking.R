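#' Top-ranked clones of a repertoire
#'
#' Ranks are dense (1 = most abundant, no ties) under the deterministic
#' ordering: reads descending, tie broken by the lexicographically smallest
#' identity key.
#'
#' @inheritParams clone_keys
#' @param n number of clones to return (all clones if `n` exceeds the
#'   unique count).
#' @return data.frame with `key`, `reads`, `rank`, `sample_id`.
#' @export
top_clones <- function(rep, n = 10, level = c("nt", "aa", "nt_vj", "aa_vj")) {
  level <- match.arg(level)
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  ranked <- ranked_clones(rep, level)
  utils::head(ranked, n)
}

# full dense ranking at a level: collapse, then order by reads desc / key asc
ranked_clones <- function(rep, level) {
  rep <- collapse_clones(rep, level)
  keys <- clone_keys(rep, level)
  ord <- order(-rep$clones$reads, keys, method = "radix")
  data.frame(key = keys[ord], reads = rep$clones$reads[ord],
             rank = seq_along(ord), sample_id = rep$sample_id,
             stringsAsFactors = FALSE)
}

#' Rank of a clone within a repertoire
#'
#' @inheritParams clone_keys
#' @param key identity key (or vector of keys) to look up.
#' @return integer rank(s); `NA` marks a key absent from the repertoire.
#' @export
rank_of <- function(rep, key, level = c("nt", "aa", "nt_vj", "aa_vj")) {
  level <- match.arg(level)
  ranked <- ranked_clones(rep, level)
  ranked$rank[match(key, ranked$key)]
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the skewness and kurtosis normality statistics into the K2
#' omnibus statistic, referred to a chi-squared distribution with 2 degrees
#' of freedom. Requires n >= 8 (the kurtosis transform is undefined below
#' that); used here as an informational gate reported next to rank
#' correlations, never to switch estimators.
#'
#' @param x numeric vector.
#' @return list with `statistic` (K2), `p_value`, `z_skewness`,
#'   `z_kurtosis`, `n`, and `note` when the test cannot be run.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x[!is.na(x)])
  n <- length(x)
  if (n < 8L)
    return(list(statistic = NA_real_, p_value = NA_real_,
                z_skewness = NA_real_, z_kurtosis = NA_real_, n = n,
                note = "test requires n >= 8"))
  if (stats::var(x) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_,
                z_skewness = NA_real_, z_kurtosis = NA_real_, n = n,
                note = "constant data"))
  m <- function(k) mean((x - mean(x))^k)
  # skewness transform
  b1 <- m(3) / m(2)^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform
  b2 <- m(4) / m(2)^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term2 <- sign(denom) * ((1 - 2 / a) / abs(denom))^(1 / 3)
  z2 <- ((1 - 2 / (9 * a)) - term2) / sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skewness = z1, z_kurtosis = z2, n = n, note = NA_character_)
}

#' Cross-site ranks of the most expanded clones
#'
#' Takes the top `n` clones of the joint repertoire and looks up each one's
#' rank in the paired lymph-node repertoire (matching exact identity keys,
#' amino-acid level by default). A joint clone absent from the node is, under
#' the default `"censor"` policy, assigned rank `U + 1` (one past the node's
#' unique clone count) before correlation — all top joint clones stay in the
#' plot even when not all are present in the node; under `"drop"` it is
#' excluded. Spearman's rank correlation and its p-value are computed on the
#' resulting pairs; the D'Agostino-Pearson normality statistic of the node
#' ranks is reported alongside as information only. The orientation is
#' joint -> node by construction; transposing the arguments asks a different
#' question.
#'
#' @param joint,pln `tcr_repertoire` objects from the same subject (a
#'   warning is issued otherwise).
#' @param n number of top joint clones to track.
#' @param level identity level for the cross-site match (default `"aa"`).
#' @param absent_policy `"censor"` (default) or `"drop"`.
#' @return a `cross_site_ranks` object: list with `subject_id`, `pairs`
#'   (data.frame: key, reads_joint, rank_joint, rank_pln, rank_used,
#'   absent), `n_absent`, `rho`, `p_value`, `normality`, `reason` (set when
#'   the correlation is undefined).
#' @export
cross_site_ranks <- function(joint, pln, n = 10,
                             level = c("aa", "nt", "nt_vj", "aa_vj"),
                             absent_policy = c("censor", "drop")) {
  level <- match.arg(level)
  absent_policy <- match.arg(absent_policy)
  if (!is.na(joint$subject_id) && !is.na(pln$subject_id) &&
      joint$subject_id != pln$subject_id)
    warning("repertoires come from different subjects: ", joint$subject_id,
            " vs ", pln$subject_id, call. = FALSE)
  top <- top_clones(joint, n = n, level = level)
  u_pln <- clonality(pln, level)
  pairs <- data.frame(key = top$key, reads_joint = top$reads,
                      rank_joint = top$rank,
                      rank_pln = rank_of(pln, top$key, level),
                      stringsAsFactors = FALSE)
  pairs$absent <- is.na(pairs$rank_pln)
  pairs$rank_used <- ifelse(pairs$absent,
                            if (absent_policy == "censor") u_pln + 1L else NA_integer_,
                            pairs$rank_pln)
  usable <- !is.na(pairs$rank_used)
  rho <- p_value <- NA_real_
  reason <- NA_character_
  if (sum(usable) < 3L) {
    reason <- sprintf("only %d usable pair(s); correlation undefined", sum(usable))
  } else if (stats::var(pairs$rank_used[usable]) == 0 ||
             stats::var(pairs$rank_joint[usable]) == 0) {
    reason <- "ranks constant after censoring; correlation undefined"
  } else {
    ct <- suppressWarnings(
      stats::cor.test(pairs$rank_joint[usable], pairs$rank_used[usable],
                      method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate)
    p_value <- ct$p.value
  }
  structure(list(subject_id = joint$subject_id, pairs = pairs,
                 n_absent = sum(pairs$absent), rho = rho, p_value = p_value,
                 normality = dagostino_pearson(pairs$rank_used),
                 absent_policy = absent_policy, level = level,
                 reason = reason),
            class = "cross_site_ranks")
}

#' @export
print.cross_site_ranks <- function(x, ...) {
  cat(sprintf("<cross_site_ranks> subject %s: rho = %.3f (p = %.3g), %d/%d absent\n",
              x$subject_id, x$rho, x$p_value, x$n_absent, nrow(x$pairs)))
  invisible(x)
}

#' Presence/absence of clone keys across samples
#'
#' @param keys character vector of identity keys.
#' @param reps list of `tcr_repertoire` objects.
#' @param level identity level of the keys.
#' @return logical matrix, keys x samples; `TRUE` where the key occurs.
#' @export
presence_table <- function(keys, reps, level = c("aa", "nt", "nt_vj", "aa_vj")) {
  level <- match.arg(level)
  if (length(keys) == 0L) stop("keys must be non-empty", call. = FALSE)
  ids <- vapply(reps, function(r) r$sample_id, character(1))
  out <- vapply(reps, function(r) keys %in% unique(clone_keys(r, level)),
                logical(length(keys)))
  out <- matrix(out, nrow = length(keys), dimnames = list(keys, ids))
  out
}
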