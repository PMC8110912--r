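#' Read an AIRR Rearrangement TSV into a repertoire
#'
#' Expects the community-standard tab-separated schema with at least
#' `junction` (or `junction_aa`), `v_call`, `j_call` and `duplicate_count`
#' columns. Gene calls are stripped of allele suffixes. Rows with a missing
#' or zero count are rejected in strict mode (the default) or read as one
#' read in lenient mode.
#'
#' @param path path to the TSV file.
#' @param sample_id,subject_id,tissue,phase,condition sample metadata; the
#'   default sample id is the file name without extension.
#' @param strict_counts reject rows with zero/absent `duplicate_count`
#'   (`TRUE`, default) or impute them to 1 (`FALSE`).
#' @return a validated `tcr_repertoire`.
#' @export
read_airr <- function(path, sample_id = NULL, subject_id = NA, tissue = NA,
                      phase = NA, condition = NA, strict_counts = TRUE) {
  tab <- read_tsv_checked(path)
  if (!"junction" %in% names(tab) && !"junction_aa" %in% names(tab))
    stop("AIRR file '", path, "' lacks mandatory column: junction", call. = FALSE)
  for (col in c("v_call", "j_call", "duplicate_count"))
    if (!col %in% names(tab))
      stop("AIRR file '", path, "' lacks mandatory column: ", col, call. = FALSE)
  build_repertoire_from_table(
    tab, path,
    map = c(cdr3_nt = "junction", cdr3_aa = "junction_aa",
            v_gene = "v_call", j_gene = "j_call", reads = "duplicate_count"),
    sample_id = sample_id %||% file_stem(path),
    subject_id = subject_id, tissue = tissue, phase = phase,
    condition = condition, strict_counts = strict_counts)
}

#' Read a MiXCR-style or generic clone table
#'
#' Column-name dialects map clone tables produced by upstream aligners onto
#' the package's clone fields. `mixcr` expects `cloneCount`, `nSeqCDR3`,
#' `aaSeqCDR3`, `allVHitsWithScore`, `allJHitsWithScore`; `irepertoire`
#' expects `copy`, `CDR3_nt`, `CDR3_aa`, `V`, `J`; `generic` takes a
#' user-supplied `column_map` naming the columns for `reads`, `cdr3_nt`,
#' `cdr3_aa`, `v_gene`, `j_gene`.
#'
#' @param path path to the TSV file.
#' @param dialect one of `"mixcr"`, `"irepertoire"`, `"generic"`.
#' @param column_map named character vector (generic dialect only).
#' @inheritParams read_airr
#' @return a validated `tcr_repertoire`.
#' @export
read_clone_table <- function(path, dialect = c("mixcr", "irepertoire", "generic"),
                             column_map = NULL, sample_id = NULL,
                             subject_id = NA, tissue = NA, phase = NA,
                             condition = NA, strict_counts = TRUE) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unknown clone-table dialect: ",
                                               dialect[1], call. = FALSE))
  map <- switch(dialect,
    mixcr = c(cdr3_nt = "nSeqCDR3", cdr3_aa = "aaSeqCDR3",
              v_gene = "allVHitsWithScore", j_gene = "allJHitsWithScore",
              reads = "cloneCount"),
    irepertoire = c(cdr3_nt = "CDR3_nt", cdr3_aa = "CDR3_aa",
                    v_gene = "V", j_gene = "J", reads = "copy"),
    generic = {
      need <- c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene", "reads")
      if (is.null(column_map) || !all(need %in% names(column_map)))
        stop("generic dialect needs a column_map naming: ",
             paste(need, collapse = ", "), call. = FALSE)
      column_map[need]
    })
  tab <- read_tsv_checked(path)
  missing <- setdiff(unname(map[c("reads", "v_gene", "j_gene")]), names(tab))
  if (!map[["cdr3_nt"]] %in% names(tab) && !map[["cdr3_aa"]] %in% names(tab))
    missing <- c(map[["cdr3_nt"]], missing)
  if (length(missing) > 0)
    stop("clone table '", path, "' lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  build_repertoire_from_table(
    tab, path, map = map,
    sample_id = sample_id %||% file_stem(path),
    subject_id = subject_id, tissue = tissue, phase = phase,
    condition = condition, strict_counts = strict_counts)
}

#' Write a repertoire to disk
#'
#' Output is readable by the matching reader with identical clone content.
#' Clone rows are written in the deterministic package order (reads
#' descending, then CDR3 nucleotide sequence), so output files are
#' byte-reproducible.
#'
#' @param rep a `tcr_repertoire`.
#' @param path output file path.
#' @param format `"airr"` (junction/junction_aa/v_call/j_call/duplicate_count)
#'   or `"generic_tsv"` (cdr3_nt/cdr3_aa/v_gene/j_gene/reads).
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path, format = c("airr", "generic_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(rep, "tcr_repertoire"))
  cl <- rep$clones
  out <- if (format == "airr") {
    data.frame(junction = cl$cdr3_nt, junction_aa = cl$cdr3_aa,
               v_call = cl$v_gene, j_call = cl$j_gene,
               duplicate_count = cl$reads, stringsAsFactors = FALSE)
  } else {
    cl[, c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene", "reads")]
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write repertoire to '", path, "'", call. = FALSE)
  invisible(path)
}

# shared reader plumbing -----------------------------------------------------

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = c("NA", ""))
}

build_repertoire_from_table <- function(tab, path, map, sample_id, subject_id,
                                        tissue, phase, condition, strict_counts) {
  if (nrow(tab) == 0L) {
    warning("'", path, "' contains a header but no clones; returning an empty repertoire",
            call. = FALSE)
    return(empty_repertoire(sample_id, subject_id, tissue, phase, condition))
  }
  get_col <- function(field) {
    col <- map[[field]]
    if (!is.null(col) && col %in% names(tab)) tab[[col]] else NA_character_
  }
  raw_counts <- get_col("reads")
  reads <- suppressWarnings(as.numeric(raw_counts))
  bad <- which(is.na(reads) & !is.na(raw_counts) & nzchar(raw_counts))
  if (length(bad) > 0)
    stop("unparseable count '", raw_counts[bad[1]], "' at data line ",
         bad[1], " of '", path, "'", call. = FALSE)
  zeroish <- which(is.na(reads) | reads < 1)
  if (length(zeroish) > 0) {
    if (strict_counts)
      stop("zero or missing count at data line ", zeroish[1], " of '", path,
           "' (use strict_counts = FALSE to read such rows as 1)", call. = FALSE)
    reads[zeroish] <- 1
  }
  # MiXCR hit lists look like "TRBV12-1*00(1289.5),TRBV12-2*00(478)": keep the
  # top-scoring hit before stripping the allele.
  clean_gene <- function(x) strip_allele(sub("\\(.*$", "", sub(",.*$", "", x)))
  clones <- data.frame(
    cdr3_nt = get_col("cdr3_nt"),
    cdr3_aa = get_col("cdr3_aa"),
    v_gene = clean_gene(get_col("v_gene")),
    j_gene = clean_gene(get_col("j_gene")),
    reads = as.integer(round(reads)),
    stringsAsFactors = FALSE)
  repertoire(clones, sample_id = sample_id, subject_id = subject_id,
             tissue = tissue, phase = phase, condition = condition)
}

empty_repertoire <- function(sample_id = "empty", subject_id = NA, tissue = NA,
                             phase = NA, condition = NA) {
  repertoire(data.frame(cdr3_nt = character(0), cdr3_aa = character(0),
                        v_gene = character(0), j_gene = character(0),
                        reads = integer(0)),
             sample_id = sample_id, subject_id = subject_id, tissue = tissue,
             phase = phase, condition = condition)
}

file_stem <- function(path) sub("\\.[^.]*$", "", basename(path))

`%||%` <- function(a, b) if (is.null(a)) b else a
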