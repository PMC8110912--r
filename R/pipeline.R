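#' Analysis configuration
#'
#' Collects the interpretation-sensitive knobs of the whole analysis in one
#' validated object: clone identity level for clonality/diversity, overlap
#' matching level and display scale, gene-usage weighting, the policy for
#' top joint clones absent from the node ranking, and the significance
#' level.
#'
#' @param identity identity level for clonality, D50 and ranking.
#' @param overlap_level identity level for cross-repertoire matching.
#' @param overlap_scale display multiplier for the normalised overlap index.
#' @param weighting gene-usage weighting (`"reads"` or `"clones"`).
#' @param absent_policy `"censor"` or `"drop"` for cross-site ranks.
#' @param d50_reference_total `"truncated"` or `"all"` (see [d50()]).
#' @param top_n number of top clones tracked across sites.
#' @param alpha significance level.
#' @param pca_components components retained in the V-usage PCA.
#' @return a `pipeline_config` list with a deterministic `hash`.
#' @export
pipeline_config <- function(identity = "nt", overlap_level = "aa",
                            overlap_scale = 1, weighting = "reads",
                            absent_policy = "censor",
                            d50_reference_total = "truncated", top_n = 10,
                            alpha = 0.05, pca_components = 2) {
  cfg <- list(identity = match.arg(identity, c("nt", "aa", "nt_vj", "aa_vj")),
              overlap_level = match.arg(overlap_level,
                                        c("aa", "nt", "nt_vj", "aa_vj")),
              overlap_scale = overlap_scale,
              weighting = match.arg(weighting, c("reads", "clones")),
              absent_policy = match.arg(absent_policy, c("censor", "drop")),
              d50_reference_total = match.arg(d50_reference_total,
                                              c("truncated", "all")),
              top_n = top_n, alpha = alpha, pca_components = pca_components)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(cfg[order(names(cfg))]), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

#' Validate a study manifest
#'
#' A manifest has one row per sample with columns `sample_id`, `subject_id`,
#' `tissue`, `phase`, `condition` and (when repertoires are read from disk)
#' `path`. Pairing of node and joint samples is derived from `subject_id`.
#'
#' @param manifest data.frame.
#' @param require_paths check that every `path` exists.
#' @return the manifest, invisibly, after validation.
#' @export
validate_manifest <- function(manifest, require_paths = FALSE) {
  need <- c("sample_id", "subject_id", "tissue", "phase", "condition")
  missing <- setdiff(need, names(manifest))
  if (length(missing) > 0)
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(manifest$sample_id))
    stop("duplicate sample_id in manifest: ",
         manifest$sample_id[duplicated(manifest$sample_id)][1], call. = FALSE)
  if (require_paths) {
    if (!"path" %in% names(manifest))
      stop("manifest lacks column(s): path", call. = FALSE)
    gone <- manifest$path[!file.exists(manifest$path)]
    if (length(gone) > 0)
      stop("manifest references missing file(s): ",
           paste(gone, collapse = ", "), call. = FALSE)
  }
  invisible(manifest)
}

#' Read a manifest TSV
#'
#' @param path path to a tab-separated manifest (as written by
#'   [generate_cohort()]).
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  validate_manifest(m)
  m
}

#' Run the full repertoire analysis
#'
#' Executes every stage on a cohort: per-sample diversity (clonality, D50,
#' homeostasis bins), per-phase node-by-joint overlap matrices with the
#' same-subject paired diagonal, V-gene usage matrix with PCA and a per-gene
#' early-vs-late node comparison, top-clone joint-to-node rank tracking with
#' Spearman correlation, and the group comparisons the study design implies
#' (early vs late within tissue, inflamed vs control within phase, paired
#' overlap early vs late). A failure in any sample aborts the run with a
#' named error.
#'
#' @param manifest study manifest (see [validate_manifest()]); `path` is
#'   required unless `reps` is given.
#' @param reps optional named list of `tcr_repertoire` objects keyed by
#'   `sample_id`, bypassing file reading.
#' @param config a [pipeline_config()].
#' @return a `results_bundle`: list with `diversity`, `overlap` (per phase:
#'   `matrix`, `diagonal`), `usage` (`matrix`, `pca`, `group_labels`,
#'   `comparison`), `tracking`, `comparisons`, `manifest`, `config`.
#' @export
run_pipeline <- function(manifest, reps = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_manifest(manifest, require_paths = is.null(reps))
  if (is.null(reps)) {
    reps <- lapply(seq_len(nrow(manifest)), function(i) {
      read_airr(manifest$path[i], sample_id = manifest$sample_id[i],
                subject_id = manifest$subject_id[i],
                tissue = manifest$tissue[i], phase = manifest$phase[i],
                condition = manifest$condition[i])
    })
    names(reps) <- manifest$sample_id
  } else {
    gone <- setdiff(manifest$sample_id, names(reps))
    if (length(gone) > 0)
      stop("repertoire list lacks sample(s): ", paste(gone, collapse = ", "),
           call. = FALSE)
    reps <- reps[manifest$sample_id]
  }

  diversity <- diversity_table(reps, level = config$identity,
                               reference_total = config$d50_reference_total)

  inflamed <- manifest[manifest$condition == "inflamed", , drop = FALSE]
  overlap <- list()
  tracking_rows <- list()
  for (ph in sort(unique(inflamed$phase))) {
    sub <- inflamed[inflamed$phase == ph, , drop = FALSE]
    pln_ids <- sub$sample_id[sub$tissue == "pLN"]
    joint_ids <- sub$sample_id[sub$tissue == "joint"]
    if (length(pln_ids) == 0 || length(joint_ids) == 0) next
    m <- overlap_matrix(reps[pln_ids], reps[joint_ids],
                        level = config$overlap_level,
                        scale = config$overlap_scale)
    pairing <- subject_pairing(sub)
    overlap[[ph]] <- list(matrix = m,
                          diagonal = paired_diagonal(m, pairing))
    for (i in seq_along(pairing)) {
      joint_rep <- reps[[unname(pairing[i])]]
      pln_rep <- reps[[names(pairing)[i]]]
      cs <- cross_site_ranks(joint_rep, pln_rep, n = config$top_n,
                             level = config$overlap_level,
                             absent_policy = config$absent_policy)
      tracking_rows[[length(tracking_rows) + 1L]] <- data.frame(
        subject_id = joint_rep$subject_id, phase = ph,
        condition = "inflamed", rho = cs$rho, p_value = cs$p_value,
        n_absent = cs$n_absent, stringsAsFactors = FALSE)
    }
  }
  tracking <- if (length(tracking_rows) > 0) do.call(rbind, tracking_rows)
              else NULL

  usage <- NULL
  if (nrow(inflamed) >= 3) {
    um <- usage_matrix(reps[inflamed$sample_id], segment = "V",
                       weighting = config$weighting)
    labels <- paste(inflamed$tissue, inflamed$phase, sep = ".")
    names(labels) <- inflamed$sample_id
    labels <- labels[rownames(um)]
    pca <- usage_pca(um, n_components = min(config$pca_components,
                                            nrow(um) - 1L, ncol(um)))
    pln_e <- rownames(um)[labels == "pLN.early"]
    pln_l <- rownames(um)[labels == "pLN.late"]
    comparison <- if (length(pln_e) >= 2 && length(pln_l) >= 2)
      compare_gene_usage(um[pln_e, , drop = FALSE], um[pln_l, , drop = FALSE],
                         alpha = config$alpha) else NULL
    usage <- list(matrix = um, pca = pca, group_labels = labels,
                  comparison = comparison)
  }

  comparisons <- study_comparisons(diversity, overlap, tracking,
                                   alpha = config$alpha)

  structure(list(diversity = diversity, overlap = overlap, usage = usage,
                 tracking = tracking, comparisons = comparisons,
                 manifest = manifest, config = config),
            class = "results_bundle")
}

# same-subject pairing pLN -> joint from manifest rows of one phase
subject_pairing <- function(sub) {
  pln <- sub[sub$tissue == "pLN", ]
  joint <- sub[sub$tissue == "joint", ]
  common <- intersect(pln$subject_id, joint$subject_id)
  stats::setNames(joint$sample_id[match(common, joint$subject_id)],
                  pln$sample_id[match(common, pln$subject_id)])
}

# enumerate the design's group comparisons from whatever factor levels the
# manifest actually contains
study_comparisons <- function(diversity, overlap, tracking, alpha = 0.05) {
  rows <- list()
  add <- function(label, a, b) {
    if (length(a) >= 2 && length(b) >= 2) {
      cmp <- welch_t(a, b, alpha = alpha)
      rows[[length(rows) + 1L]] <<- data.frame(
        comparison = label, n_a = cmp$n_a, n_b = cmp$n_b,
        mean_a = mean(a), mean_b = mean(b), statistic = cmp$statistic,
        p_value = cmp$p_value, significant = cmp$significant,
        stringsAsFactors = FALSE)
    }
  }
  d <- diversity
  pick <- function(tissue, phase, cond, what)
    d[[what]][d$tissue == tissue & d$phase == phase & d$condition == cond]
  for (tissue in c("pLN", "joint")) {
    for (what in c("d50", "clonality", "top10")) {
      add(sprintf("%s %s early-vs-late inflamed", tissue, what),
          pick(tissue, "early", "inflamed", what),
          pick(tissue, "late", "inflamed", what))
      add(sprintf("%s %s inflamed-vs-control late", tissue, what),
          pick(tissue, "late", "inflamed", what),
          pick(tissue, "late", "control", what))
    }
  }
  if (!is.null(overlap$early) && !is.null(overlap$late))
    add("paired overlap early-vs-late inflamed",
        overlap$early$diagonal$value, overlap$late$diagonal$value)
  if (!is.null(tracking))
    add("joint-top clone rank correlation early-vs-late inflamed",
        tracking$rho[tracking$phase == "early"],
        tracking$rho[tracking$phase == "late"])
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean silhouette of one group against the rest
#'
#' Simple silhouette score on a score matrix (e.g. PCA component 1):
#' positive values mean the group's samples sit closer to each other than to
#' the other samples.
#'
#' @param x numeric vector or matrix of coordinates (rows = samples).
#' @param labels group labels per sample.
#' @param group the group whose separation is scored (default: all groups,
#'   averaged).
#' @return mean silhouette width.
#' @export
group_silhouette <- function(x, labels, group = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  dmat <- as.matrix(stats::dist(x))
  sil <- vapply(seq_along(labels), function(i) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (length(own) == 0) return(0)
    a <- mean(dmat[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(dmat[i, labels == g])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  if (is.null(group)) mean(sil) else mean(sil[labels == group])
}

#' Write the results bundle as tab-separated tables
#'
#' Every table carries the configuration hash in a comment header so a
#' results directory is self-describing; reruns with identical inputs and
#' configuration are byte-identical.
#'
#' @param bundle a `results_bundle`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# config_hash: %s | overlap_scale: %g | identity: %s",
                 bundle$config$hash, bundle$config$overlap_scale,
                 bundle$config$identity)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    writeLines(hdr, path)
    suppressWarnings(
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE))
    path
  }
  wt(bundle$diversity, "diversity.tsv")
  for (ph in names(bundle$overlap)) {
    wt(overlap_long(bundle$overlap[[ph]]$matrix),
       sprintf("overlap_%s.tsv", ph))
    wt(bundle$overlap[[ph]]$diagonal, sprintf("overlap_diagonal_%s.tsv", ph))
  }
  if (!is.null(bundle$usage)) {
    um <- as.data.frame(unclass(bundle$usage$matrix))
    um <- cbind(sample_id = rownames(um), um)
    wt(um, "v_usage.tsv")
    sc <- as.data.frame(bundle$usage$pca$scores)
    sc <- cbind(sample_id = rownames(sc), group = bundle$usage$group_labels, sc)
    wt(sc, "v_usage_pca_scores.tsv")
    ld <- as.data.frame(bundle$usage$pca$loadings)
    ld <- cbind(gene = rownames(ld), ld)
    wt(ld, "v_usage_pca_loadings.tsv")
    if (!is.null(bundle$usage$comparison))
      wt(bundle$usage$comparison, "v_usage_comparison.tsv")
  }
  if (!is.null(bundle$tracking)) wt(bundle$tracking, "tracking.tsv")
  if (!is.null(bundle$comparisons)) wt(bundle$comparisons, "comparisons.tsv")
  invisible(out_dir)
}

#' Render basic figures for a results bundle
#'
#' Plot analogues of the study-level readouts: homeostasis stacked bars, D50
#' and clonality dot plots, overlap heatmaps, the V-usage PCA scatter and
#' the per-subject rank-correlation summary. Plotting failures never corrupt
#' the tables; missing optional sections are skipped with a note in the
#' index.
#'
#' @param bundle a `results_bundle`.
#' @param out_dir output directory.
#' @return character vector of figure paths, invisibly.
#' @export
render_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  figs <- character(0)
  notes <- character(0)
  save_fig <- function(p, name) {
    path <- file.path(out_dir, name)
    ok <- tryCatch({
      ggplot2::ggsave(path, p, width = 7, height = 5)
      TRUE
    }, error = function(e) FALSE)
    if (ok) figs <<- c(figs, path)
    else notes <<- c(notes, paste("failed to render", name))
  }

  d <- bundle$diversity
  bins <- c("top10", "next25", "next500", "next3000", "next10000", "next100000")
  hm <- do.call(rbind, lapply(bins, function(b) {
    data.frame(sample_id = d$sample_id, group = paste(d$tissue, d$phase, d$condition),
               bin = factor(b, levels = bins), proportion = d[[b]])
  }))
  save_fig(ggplot2::ggplot(hm, ggplot2::aes(x = .data$sample_id,
                                            y = .data$proportion,
                                            fill = .data$bin)) +
             ggplot2::geom_col() +
             ggplot2::facet_grid(. ~ group, scales = "free_x", space = "free_x") +
             ggplot2::theme_minimal() +
             ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
             ggplot2::labs(y = "proportion of reads", x = NULL),
           "homeostasis.pdf")

  d$group <- paste(d$tissue, d$phase, d$condition)
  save_fig(ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$d50)) +
             ggplot2::geom_jitter(width = 0.1, height = 0) +
             ggplot2::theme_minimal() +
             ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
             ggplot2::labs(y = "D50 diversity index", x = NULL),
           "d50.pdf")
  save_fig(ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$clonality)) +
             ggplot2::geom_jitter(width = 0.1, height = 0) +
             ggplot2::theme_minimal() +
             ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
             ggplot2::labs(y = "unique CDR3 sequences", x = NULL),
           "clonality.pdf")

  if (length(bundle$overlap) > 0) {
    ol <- do.call(rbind, lapply(names(bundle$overlap), function(ph) {
      x <- overlap_long(bundle$overlap[[ph]]$matrix)
      x$phase <- ph
      x
    }))
    save_fig(ggplot2::ggplot(ol, ggplot2::aes(x = .data$col_id, y = .data$row_id,
                                              fill = .data$value)) +
               ggplot2::geom_tile() +
               ggplot2::facet_wrap(~phase, scales = "free") +
               ggplot2::theme_minimal() +
               ggplot2::theme(axis.text = ggplot2::element_blank()) +
               ggplot2::labs(x = "joint", y = "pLN", fill = "overlap"),
             "overlap_heatmap.pdf")
  } else notes <- c(notes, "no overlap section (no paired inflamed samples)")

  if (!is.null(bundle$usage)) {
    sc <- as.data.frame(bundle$usage$pca$scores)
    sc$group <- bundle$usage$group_labels
    save_fig(ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                              colour = .data$group)) +
               ggplot2::geom_point(size = 2) + ggplot2::theme_minimal() +
               ggplot2::labs(title = "PCA of TRBV gene usage"),
             "v_usage_pca.pdf")
  } else notes <- c(notes, "no usage section (fewer than 3 inflamed samples)")

  if (!is.null(bundle$tracking)) {
    save_fig(ggplot2::ggplot(bundle$tracking,
                             ggplot2::aes(x = .data$phase, y = .data$rho)) +
               ggplot2::geom_jitter(width = 0.05, height = 0) +
               ggplot2::theme_minimal() +
               ggplot2::labs(y = "Spearman rho (joint top clones vs pLN rank)"),
             "rank_correlation.pdf")
  } else notes <- c(notes, "no tracking section")

  writeLines(c("# Report index", paste("-", basename(figs)),
               if (length(notes) > 0) c("", "Notes:", paste("-", notes))),
             file.path(out_dir, "index.md"))
  invisible(figs)
}
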