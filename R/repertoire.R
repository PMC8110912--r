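#' Construct a TCR-beta repertoire
#'
#' A repertoire is one sample's set of clonotypes together with sample
#' metadata. Each clone carries the CDR3-beta nucleotide sequence, its
#' amino-acid translation, TRBV/TRBJ gene labels and a read count. On
#' construction, gene-allele suffixes (e.g. `"*01"`) are stripped, the
#' amino-acid sequence is derived by translation where absent and derivable,
#' and clones are put into the package's deterministic order: reads
#' descending, ties broken by the lexicographically smallest CDR3 nucleotide
#' sequence (C locale). All ranking downstream relies on that order.
#'
#' @param clones data.frame with columns `cdr3_nt`, `cdr3_aa`, `v_gene`,
#'   `j_gene`, `reads`. `cdr3_aa` may be `NA` (derived by translation when
#'   the nucleotide length is a multiple of 3). `cdr3_nt` may be `NA` only
#'   when `cdr3_aa` is present (amino-acid-only inputs); nucleotide-level
#'   operations then refuse to run.
#' @param sample_id,subject_id sample and subject identifiers.
#' @param tissue one of `"pLN"`, `"joint"`, or `NA`.
#' @param phase one of `"early"`, `"late"`, or `NA`.
#' @param condition one of `"inflamed"`, `"control"`, or `NA`.
#' @return An object of class `tcr_repertoire`: a list with the metadata
#'   fields, the validated `clones` data.frame and `total_reads`.
#' @examples
#' rep <- repertoire(data.frame(
#'   cdr3_nt = c("TGTGCCAGC", "TGTGCCTTT"), cdr3_aa = NA,
#'   v_gene = "TRBV12-1*01", j_gene = "TRBJ2-7", reads = c(5L, 3L)
#' ), sample_id = "s1")
#' rep$total_reads
#' @export
repertoire <- function(clones, sample_id = "sample", subject_id = NA_character_,
                       tissue = NA_character_, phase = NA_character_,
                       condition = NA_character_) {
  clones <- normalize_clones(clones)
  rep <- structure(
    list(sample_id = as.character(sample_id),
         subject_id = as.character(subject_id),
         tissue = check_enum(tissue, c("pLN", "joint"), "tissue"),
         phase = check_enum(phase, c("early", "late"), "phase"),
         condition = check_enum(condition, c("inflamed", "control"), "condition"),
         clones = clones,
         total_reads = sum(clones$reads)),
    class = "tcr_repertoire")
  validate_repertoire(rep)
}

check_enum <- function(x, levels, what) {
  x <- as.character(x)
  if (length(x) != 1L) stop(what, " must be a single value", call. = FALSE)
  if (!is.na(x) && !x %in% levels)
    stop(what, " must be one of ", paste(levels, collapse = ", "),
         " (got '", x, "')", call. = FALSE)
  x
}

# Coerce, strip alleles, translate, deterministically order.
normalize_clones <- function(clones) {
  required <- c("cdr3_nt", "v_gene", "j_gene", "reads")
  missing <- setdiff(required, names(clones))
  if (length(missing) > 0)
    stop("clone table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"cdr3_aa" %in% names(clones)) clones$cdr3_aa <- NA_character_

  clones <- data.frame(
    cdr3_nt = toupper(as.character(clones$cdr3_nt)),
    cdr3_aa = toupper(as.character(clones$cdr3_aa)),
    v_gene = strip_allele(clones$v_gene),
    j_gene = strip_allele(clones$j_gene),
    reads = clones$reads,
    stringsAsFactors = FALSE)
  clones$cdr3_nt[!nzchar(clones$cdr3_nt) | clones$cdr3_nt == "NA"] <- NA_character_
  clones$cdr3_aa[!nzchar(clones$cdr3_aa) | clones$cdr3_aa == "NA"] <- NA_character_

  derivable <- is.na(clones$cdr3_aa) & !is.na(clones$cdr3_nt) &
    nchar(clones$cdr3_nt) %% 3L == 0L &
    !grepl("[^ACGT]", clones$cdr3_nt)
  if (any(derivable))
    clones$cdr3_aa[derivable] <- translate_cdr3(clones$cdr3_nt[derivable])

  ord <- order(-clones$reads,
               ifelse(is.na(clones$cdr3_nt), clones$cdr3_aa, clones$cdr3_nt),
               method = "radix")
  clones <- clones[ord, , drop = FALSE]
  rownames(clones) <- NULL
  clones
}

#' Strip allele suffixes from V/J gene labels
#'
#' `"TRBV12-1*01"` aggregates with `"TRBV12-1"`: usage is reported at the
#' gene level, so the `*NN` allele designation is removed on ingest.
#'
#' @param genes character vector of gene labels.
#' @return character vector without allele suffixes.
#' @export
strip_allele <- function(genes) {
  sub("\\*.*$", "", trimws(as.character(genes)))
}

validate_repertoire <- function(rep) {
  cl <- rep$clones
  if (nrow(cl) > 0) {
    if (any(is.na(cl$reads)) || any(cl$reads != as.integer(cl$reads)) ||
        any(cl$reads < 1))
      stop("clone read counts must be positive integers (sample '",
           rep$sample_id, "')", call. = FALSE)
    bad_nt <- !is.na(cl$cdr3_nt) & grepl("[^ACGT]", cl$cdr3_nt)
    if (any(bad_nt))
      stop("cdr3_nt contains characters outside {A,C,G,T} in ",
           sum(bad_nt), " clone(s)", call. = FALSE)
    if (any(is.na(cl$cdr3_nt) & is.na(cl$cdr3_aa)))
      stop("each clone needs cdr3_nt or cdr3_aa", call. = FALSE)
    if (any(grepl("_", cl$cdr3_aa, fixed = TRUE), na.rm = TRUE))
      stop("cdr3_aa contains '_' (out-of-frame marker); such clones are not accepted",
           call. = FALSE)
    if (any(!nzchar(cl$v_gene)) || any(!nzchar(cl$j_gene)) ||
        any(is.na(cl$v_gene)) || any(is.na(cl$j_gene)))
      stop("v_gene and j_gene must be non-empty labels", call. = FALSE)
  }
  stopifnot(rep$total_reads == sum(cl$reads))
  rep
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("<tcr_repertoire> %s  [%s/%s/%s, subject %s]\n",
              x$sample_id, x$tissue, x$phase, x$condition, x$subject_id))
  cat(sprintf("  %d clones, %d total reads\n", nrow(x$clones), x$total_reads))
  invisible(x)
}

#' Clone identity keys
#'
#' The identity key fixes what counts as "the same clone". Four levels are
#' supported: `nt` (CDR3 nucleotide sequence alone), `aa` (amino-acid
#' sequence alone), and `nt_vj`/`aa_vj` which append the V and J gene labels.
#' Clonality is counted at `nt` by default; overlap between repertoires is
#' matched at `aa`.
#'
#' @param rep a `tcr_repertoire`.
#' @param level one of `"nt"`, `"aa"`, `"nt_vj"`, `"aa_vj"`.
#' @return character vector of keys, one per clone row.
#' @export
clone_keys <- function(rep, level = c("nt", "aa", "nt_vj", "aa_vj")) {
  level <- match.arg(level)
  cl <- rep$clones
  base <- if (level %in% c("nt", "nt_vj")) cl$cdr3_nt else cl$cdr3_aa
  if (anyNA(base))
    stop("identity level '", level, "' needs ",
         if (startsWith(level, "nt")) "cdr3_nt" else "cdr3_aa",
         " for every clone in sample '", rep$sample_id, "'", call. = FALSE)
  if (endsWith(level, "_vj")) paste(base, cl$v_gene, cl$j_gene, sep = "|")
  else base
}

#' Collapse clones to unique identity keys
#'
#' Clones sharing the identity key are merged with read counts summed. The
#' representative sequence/gene fields of a merged clone are taken from the
#' member with the highest reads (ties: lexicographically smallest
#' `cdr3_nt`). Total reads are conserved; the operation is idempotent.
#'
#' @inheritParams clone_keys
#' @return a `tcr_repertoire` with unique keys at `level`.
#' @export
collapse_clones <- function(rep, level = c("nt", "aa", "nt_vj", "aa_vj")) {
  level <- match.arg(level)
  cl <- rep$clones
  if (nrow(cl) <= 1L) return(rep)
  keys <- clone_keys(rep, level)
  # clones are already in deterministic order, so the first row of each key
  # group is the representative (max reads, tie -> smallest cdr3_nt)
  reads_by_key <- rowsum(cl$reads, group = keys, reorder = FALSE)
  first <- !duplicated(keys)
  merged <- cl[first, , drop = FALSE]
  merged$reads <- as.integer(reads_by_key[match(keys[first], rownames(reads_by_key)), 1])
  rep$clones <- normalize_clones(merged)
  rep$total_reads <- sum(rep$clones$reads)
  validate_repertoire(rep)
}

#' Pool repertoires into a single sample
#'
#' Concatenates the clone lists of several repertoires and collapses at the
#' given identity level, mirroring the situation where low-recovery samples
#' must be pooled before sequencing. Total reads of the pool equal the sum
#' over inputs. A warning is issued when the inputs disagree on
#' tissue/phase/condition.
#'
#' @param reps list of `tcr_repertoire` objects (at least one).
#' @param level identity level for the collapse.
#' @param sample_id sample id of the pooled repertoire.
#' @return a pooled `tcr_repertoire`.
#' @export
pool_repertoires <- function(reps, level = c("nt", "aa", "nt_vj", "aa_vj"),
                             sample_id = "pooled") {
  level <- match.arg(level)
  if (length(reps) < 1L) stop("need at least one repertoire to pool", call. = FALSE)
  stopifnot(all(vapply(reps, inherits, logical(1), "tcr_repertoire")))
  for (field in c("tissue", "phase", "condition")) {
    vals <- unique(vapply(reps, function(r) r[[field]], character(1)))
    if (length(vals) > 1L)
      warning("pooling repertoires with differing ", field, ": ",
              paste(vals, collapse = ", "), call. = FALSE)
  }
  all_clones <- do.call(rbind, lapply(reps, function(r) r$clones))
  pooled <- repertoire(all_clones, sample_id = sample_id,
                       subject_id = NA_character_,
                       tissue = reps[[1]]$tissue, phase = reps[[1]]$phase,
                       condition = reps[[1]]$condition)
  collapse_clones(pooled, level)
}

#' Translate CDR3 nucleotide sequences
#'
#' Standard-codon-table translation; stop codons are rendered `"*"`.
#'
#' @param cdr3_nt character vector of DNA strings over `{A,C,G,T}` with
#'   length a multiple of 3.
#' @return character vector of amino-acid strings.
#' @export
translate_cdr3 <- function(cdr3_nt) {
  cdr3_nt <- toupper(as.character(cdr3_nt))
  if (any(nchar(cdr3_nt) %% 3L != 0L))
    stop("cdr3_nt length must be a multiple of 3", call. = FALSE)
  if (any(grepl("[^ACGT]", cdr3_nt)))
    stop("cdr3_nt contains bases outside {A,C,G,T}", call. = FALSE)
  tab <- codon_table()
  vapply(cdr3_nt, function(s) {
    n <- nchar(s)
    paste(tab[substring(s, seq(1L, n, 3L), seq(3L, n, 3L))], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# standard codon table, built once from seqinr and cached
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      bases <- c("T", "C", "A", "G")
      codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
      tab <<- stats::setNames(
        vapply(codons,
               function(cd) seqinr::translate(strsplit(cd, "")[[1]]),
               character(1)),
        codons)
    }
    tab
  }
})
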