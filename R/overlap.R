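#' Count exactly shared CDR3 sequences between two repertoires
#'
#' Size of the intersection of unique clone identity keys, by default exact
#' CDR3 amino-acid sequence matches.
#'
#' @param a,b `tcr_repertoire` objects.
#' @param level identity level for the match (default `"aa"`).
#' @return non-negative integer.
#' @export
shared_sequences <- function(a, b, level = c("aa", "nt", "nt_vj", "aa_vj")) {
  level <- match.arg(level)
  if (nrow(a$clones) == 0L || nrow(b$clones) == 0L) return(0L)
  length(intersect(unique(clone_keys(a, level)), unique(clone_keys(b, level))))
}

#' Normalised overlap index
#'
#' The number of exactly shared CDR3 amino-acid sequences divided by the
#' product of the two repertoires' total read counts:
#' `shared / (total_reads_a * total_reads_b)`. The read-product denominator
#' accounts for repertoire size and makes the index symmetric; raw values
#' are very small, so a reporting `scale` (display multiplier, e.g. `1e6`)
#' can be applied — it never changes stored counts. A variant denominator
#' using the product of unique clone counts is available as
#' `denominator = "clones"` for sensitivity analysis.
#'
#' @inheritParams shared_sequences
#' @param scale reporting multiplier (default 1).
#' @param denominator `"reads"` (the index as defined) or `"clones"`.
#' @return non-negative real.
#' @export
normalized_overlap <- function(a, b, level = c("aa", "nt", "nt_vj", "aa_vj"),
                               scale = 1, denominator = c("reads", "clones")) {
  level <- match.arg(level)
  denominator <- match.arg(denominator)
  if (nrow(a$clones) == 0L || nrow(b$clones) == 0L)
    stop("normalised overlap is undefined for an empty repertoire (",
         if (nrow(a$clones) == 0L) a$sample_id else b$sample_id, ")",
         call. = FALSE)
  s <- shared_sequences(a, b, level)
  den <- if (denominator == "reads") {
    as.numeric(a$total_reads) * as.numeric(b$total_reads)
  } else {
    as.numeric(clonality(a, level)) * as.numeric(clonality(b, level))
  }
  s / den * scale
}

#' All-pairs overlap matrix
#'
#' Element `[i, j]` is the normalised overlap index between `rows[[i]]` and
#' `cols[[j]]`; a parallel matrix of raw shared-sequence counts is kept.
#' Rows and columns are ordered by sample id so the matrix is reproducible,
#' and symmetric whenever `rows` and `cols` are the same collection.
#'
#' @param rows,cols lists of non-empty `tcr_repertoire` objects.
#' @inheritParams normalized_overlap
#' @return an `overlap_matrix`: list with `values`, `raw_shared`, `row_ids`,
#'   `col_ids`, `scale`, `level`.
#' @export
overlap_matrix <- function(rows, cols = rows,
                           level = c("aa", "nt", "nt_vj", "aa_vj"),
                           scale = 1, denominator = c("reads", "clones")) {
  level <- match.arg(level)
  denominator <- match.arg(denominator)
  for (r in c(rows, cols))
    if (nrow(r$clones) == 0L)
      stop("empty repertoire in overlap matrix: ", r$sample_id, call. = FALSE)
  rows <- rows[order(vapply(rows, function(r) r$sample_id, character(1)),
                     method = "radix")]
  cols <- cols[order(vapply(cols, function(r) r$sample_id, character(1)),
                     method = "radix")]
  row_ids <- vapply(rows, function(r) r$sample_id, character(1))
  col_ids <- vapply(cols, function(r) r$sample_id, character(1))
  if (anyDuplicated(row_ids) || anyDuplicated(col_ids))
    stop("duplicate sample ids in overlap matrix", call. = FALSE)
  row_keys <- lapply(rows, function(r) unique(clone_keys(r, level)))
  col_keys <- lapply(cols, function(r) unique(clone_keys(r, level)))
  shared <- matrix(0L, length(rows), length(cols),
                   dimnames = list(row_ids, col_ids))
  for (i in seq_along(rows))
    for (j in seq_along(cols))
      shared[i, j] <- length(intersect(row_keys[[i]], col_keys[[j]]))
  den <- if (denominator == "reads") {
    outer(vapply(rows, function(r) as.numeric(r$total_reads), numeric(1)),
          vapply(cols, function(r) as.numeric(r$total_reads), numeric(1)))
  } else {
    outer(vapply(rows, function(r) as.numeric(clonality(r, level)), numeric(1)),
          vapply(cols, function(r) as.numeric(clonality(r, level)), numeric(1)))
  }
  structure(list(values = shared / den * scale, raw_shared = shared,
                 row_ids = row_ids, col_ids = col_ids, scale = scale,
                 level = level, denominator = denominator),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix> %d x %d, level=%s, scale=%g\n",
              length(x$row_ids), length(x$col_ids), x$level, x$scale))
  print(x$values)
  invisible(x)
}

#' Paired (same-subject) overlap values
#'
#' Extracts the within-subject pairs from an overlap matrix — e.g. each
#' lymph node against the joint of the same animal (the "diagonal" of a
#' paired heatmap). Pairing is by sample id, not by position, so column
#' order does not matter.
#'
#' @param m an `overlap_matrix`.
#' @param pairing named character vector: `names` are row sample ids, values
#'   are the matching column sample ids.
#' @return data.frame with `row_id`, `col_id`, `shared`, `value`, in the
#'   order of `pairing`.
#' @export
paired_diagonal <- function(m, pairing) {
  stopifnot(inherits(m, "overlap_matrix"))
  if (is.null(names(pairing)) || any(!nzchar(names(pairing))))
    stop("pairing must be a named vector (row id -> column id)", call. = FALSE)
  ri <- match(names(pairing), m$row_ids)
  ci <- match(unname(pairing), m$col_ids)
  if (anyNA(ri))
    stop("unpaired row sample(s): ",
         paste(names(pairing)[is.na(ri)], collapse = ", "), call. = FALSE)
  if (anyNA(ci))
    stop("unpaired column sample(s): ",
         paste(pairing[is.na(ci)], collapse = ", "), call. = FALSE)
  data.frame(row_id = names(pairing), col_id = unname(pairing),
             shared = m$raw_shared[cbind(ri, ci)],
             value = m$values[cbind(ri, ci)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Long-format overlap table
#'
#' @param m an `overlap_matrix`.
#' @return data.frame with one row per (row sample, column sample) pair.
#' @export
overlap_long <- function(m) {
  stopifnot(inherits(m, "overlap_matrix"))
  grid <- expand.grid(row_id = m$row_ids, col_id = m$col_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$shared <- as.vector(m$raw_shared)
  grid$value <- as.vector(m$values)
  grid
}
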