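#' Per-sample V/J gene usage frequencies
#'
#' Fraction of the repertoire attributable to each TRBV (or TRBJ) gene,
#' weighted either by reads (each read counts; the default, matching
#' read-derived repertoire frequencies) or by clones (each unique clone
#' counts once). Unresolvable labels (empty after allele stripping) are
#' excluded from the simplex and returned in the `"unknown"` attribute.
#'
#' @param rep a `tcr_repertoire`.
#' @param segment `"V"` or `"J"`.
#' @param weighting `"reads"` or `"clones"`.
#' @return named numeric vector of frequencies summing to 1 over resolvable
#'   labels, sorted in numeric-aware gene order.
#' @export
gene_frequencies <- function(rep, segment = c("V", "J"),
                             weighting = c("reads", "clones")) {
  segment <- match.arg(segment)
  weighting <- match.arg(weighting)
  cl <- rep$clones
  genes <- if (segment == "V") cl$v_gene else cl$j_gene
  w <- if (weighting == "reads") as.numeric(cl$reads) else rep(1, nrow(cl))
  known <- !is.na(genes) & nzchar(genes)
  tot <- sum(w[known])
  if (tot == 0) stop("no resolvable ", segment, " gene labels in sample '",
                     rep$sample_id, "'", call. = FALSE)
  freq <- rowsum(w[known], group = genes[known])[, 1] / tot
  freq <- freq[order_genes(names(freq))]
  attr(freq, "unknown") <- sum(!known)
  freq
}

#' Gene usage matrix across samples
#'
#' Dense samples-by-genes frequency matrix over the union of genes observed
#' in any sample; genes absent from a sample get frequency 0, so every row
#' sums to 1. Gene columns follow a numeric-aware order (TRBV2 before
#' TRBV12-1).
#'
#' @param reps list of `tcr_repertoire` objects (>= 2, unique sample ids).
#' @inheritParams gene_frequencies
#' @return a `usage_matrix`: numeric matrix with sample ids as rownames and
#'   attributes `weighting` and `segment`.
#' @export
usage_matrix <- function(reps, segment = c("V", "J"),
                         weighting = c("reads", "clones")) {
  segment <- match.arg(segment)
  weighting <- match.arg(weighting)
  if (length(reps) < 2L) stop("usage matrix needs at least 2 samples", call. = FALSE)
  ids <- vapply(reps, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ", ids[duplicated(ids)][1], call. = FALSE)
  freqs <- lapply(reps, gene_frequencies, segment = segment, weighting = weighting)
  genes <- order_genes_values(unique(unlist(lapply(freqs, names))))
  m <- matrix(0, length(reps), length(genes), dimnames = list(ids, genes))
  for (i in seq_along(freqs)) m[i, names(freqs[[i]])] <- freqs[[i]]
  structure(m, weighting = weighting, segment = segment,
            class = c("usage_matrix", "matrix", "array"))
}

# numeric-aware gene ordering: split "TRBV12-1" into ("TRBV", 12, 1) and sort
# by prefix, then numerically by family and member.
order_genes <- function(genes) {
  prefix <- sub("[0-9].*$", "", genes)
  rest <- sub("^[^0-9]*", "", genes)
  fam <- suppressWarnings(as.numeric(sub("[-.].*$", "", rest)))
  mem <- suppressWarnings(as.numeric(sub("^[0-9]+[-.]", "", rest)))
  mem[is.na(mem) | sub("[-.].*$", "", rest) == rest] <- 0
  fam[is.na(fam)] <- Inf
  order(prefix, fam, mem, genes, method = "radix")
}

order_genes_values <- function(genes) genes[order_genes(genes)]

#' PCA of gene usage
#'
#' Principal component analysis of the samples-by-genes frequency matrix.
#' Rows are column-centered but not variance-scaled by default: the
#' frequencies already share a scale, and scaling would inflate the
#' contribution of rare genes. Component signs follow a deterministic
#' convention (the largest-magnitude loading of each component is positive).
#'
#' @param m a `usage_matrix` (or plain samples-by-genes matrix).
#' @param n_components number of components to keep
#'   (`<= min(samples - 1, genes)`).
#' @param scale. variance-scale the columns before the decomposition.
#' @return a `usage_pca` object: list with `scores` (samples x components),
#'   `loadings` (genes x components), `explained_variance_fraction` and
#'   `center`.
#' @export
usage_pca <- function(m, n_components = 2, scale. = FALSE) {
  m <- unclass(m)
  if (nrow(m) < 3L) stop("PCA needs at least 3 samples", call. = FALSE)
  if (n_components > min(nrow(m) - 1L, ncol(m)))
    stop("n_components must be <= min(samples - 1, genes)", call. = FALSE)
  # drop constant columns under scaling to avoid division by zero
  if (scale.) {
    keep <- apply(m, 2, stats::sd) > 0
    m <- m[, keep, drop = FALSE]
  }
  p <- stats::prcomp(m, center = TRUE, scale. = scale.)
  evf <- p$sdev^2 / sum(p$sdev^2)
  k <- seq_len(n_components)
  loadings <- p$rotation[, k, drop = FALSE]
  scores <- p$x[, k, drop = FALSE]
  for (j in k) {
    flip <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (flip < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = evf[k],
                 center = p$center),
            class = "usage_pca")
}

#' Sidak family-wise correction
#'
#' Adjusted p-value `1 - (1 - p)^m` for `m` simultaneous tests.
#'
#' @param p numeric vector of raw p-values.
#' @param m family size (defaults to `length(p)`).
#' @return numeric vector of adjusted p-values.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  pmin(1, 1 - (1 - p)^m)
}

#' Per-gene group comparison of usage frequencies
#'
#' Compares each gene's usage frequency between two groups of samples with a
#' two-sample test per gene (Welch by default) and Sidak family-wise
#' correction over the genes — mirroring a per-gene multiple-comparisons
#' readout without assuming a particular ANOVA layout. A gene x group
#' two-factor ANOVA over the pooled long layout is available via
#' [gene_usage_anova()].
#'
#' @param group_a,group_b samples-by-genes frequency matrices (e.g. rows of
#'   a [usage_matrix()]), at least 2 samples each; gene columns are
#'   densified to the union.
#' @param alpha family-wise significance level.
#' @param var_equal use the pooled-variance (Student) statistic instead of
#'   Welch.
#' @return data.frame with one row per gene: mean frequencies, test
#'   statistic, raw and Sidak-adjusted p-values, and a `significant` flag at
#'   `alpha`.
#' @export
compare_gene_usage <- function(group_a, group_b, alpha = 0.05,
                               var_equal = FALSE) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (nrow(group_a) < 2L || nrow(group_b) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  genes <- order_genes_values(union(colnames(group_a), colnames(group_b)))
  densify <- function(m) {
    out <- matrix(0, nrow(m), length(genes), dimnames = list(rownames(m), genes))
    out[, colnames(m)] <- m
    out
  }
  a <- densify(group_a); b <- densify(group_b)
  res <- lapply(genes, function(g) {
    cmp <- if (var_equal) student_t(a[, g], b[, g], alpha = alpha)
           else welch_t(a[, g], b[, g], alpha = alpha)
    data.frame(gene = g, mean_a = mean(a[, g]), mean_b = mean(b[, g]),
               statistic = cmp$statistic, p_value = cmp$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- sidak_adjust(out$p_value)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}

#' Two-factor ANOVA over gene usage (gene x group)
#'
#' Long-format two-way ANOVA of frequency on gene, group and their
#' interaction (Type II sums of squares), the figure-style alternative to
#' the per-gene procedure of [compare_gene_usage()].
#'
#' @inheritParams compare_gene_usage
#' @return data.frame of effects with F statistics and p-values.
#' @export
gene_usage_anova <- function(group_a, group_b) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  genes <- union(colnames(group_a), colnames(group_b))
  long <- function(m, label) {
    data.frame(value = as.vector(m), gene = rep(colnames(m), each = nrow(m)),
               group = label, stringsAsFactors = FALSE)
  }
  d <- rbind(long(group_a, "a"), long(group_b, "b"))
  two_way_anova(d$value, d$gene, d$group,
                factor_names = c("gene", "group"))
}
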