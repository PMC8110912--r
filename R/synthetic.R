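#' Specification of one synthetic repertoire
#'
#' A repertoire is simulated as a mixture of a few expanded (dominant)
#' clones that together hold `expanded_mass` of the read probability, and a
#' heavy-tailed background of `n_background` clones whose probabilities
#' follow a power law (Zipf) with exponent `tail_exponent`, normalised to
#' `1 - expanded_mass`. Reads are then drawn once from a multinomial at the
#' given `depth`; clones that receive zero reads are dropped, which is the
#' only source of discrepancy between designed and realised quantities.
#'
#' @param n_expanded number of dominant clones (>= 0); they share
#'   `expanded_mass` uniformly unless `expanded_weights` is given.
#' @param expanded_mass total read-probability mass of the dominant clones,
#'   in `[0, 1)`.
#' @param n_background number of background clones (>= 1).
#' @param tail_exponent Zipf exponent of the background (> 0; larger =
#'   heavier domination within the background).
#' @param depth total reads to sample.
#' @param v_profile,j_profile named probability vectors over TRBV/TRBJ gene
#'   labels; see [trbv_profile()] and [trbj_profile()].
#' @param expanded_weights optional positive weights (length `n_expanded`)
#'   splitting `expanded_mass` unevenly across the dominant clones.
#' @param seed integer seed making the repertoire reproducible.
#' @return a `repertoire_spec` list.
#' @export
repertoire_spec <- function(n_expanded = 10, expanded_mass = 0.2,
                            n_background = 5000, tail_exponent = 0.6,
                            depth = 5e4, v_profile = trbv_profile(),
                            j_profile = trbj_profile(),
                            expanded_weights = NULL, seed = 1) {
  stopifnot(n_expanded >= 0, n_background >= 1,
            expanded_mass >= 0, expanded_mass < 1,
            tail_exponent > 0, depth >= 1)
  if (n_expanded == 0 && expanded_mass > 0)
    stop("expanded_mass > 0 requires n_expanded > 0", call. = FALSE)
  if (!is.null(expanded_weights)) {
    stopifnot(length(expanded_weights) == n_expanded, all(expanded_weights > 0))
  }
  check_profile(v_profile, "v_profile")
  check_profile(j_profile, "j_profile")
  structure(list(n_expanded = as.integer(n_expanded),
                 expanded_mass = expanded_mass,
                 n_background = as.integer(n_background),
                 tail_exponent = tail_exponent, depth = as.integer(depth),
                 v_profile = v_profile, j_profile = j_profile,
                 expanded_weights = expanded_weights,
                 seed = as.integer(seed)),
            class = "repertoire_spec")
}

check_profile <- function(p, what) {
  if (is.null(names(p)) || any(!nzchar(names(p))) || any(p < 0) || sum(p) <= 0)
    stop(what, " must be a named non-negative vector with positive sum",
         call. = FALSE)
  invisible(p)
}

#' Built-in TRBV/TRBJ usage profiles
#'
#' Two mouse TRBV profiles over a 20-gene panel: `"focused"` (the default)
#' concentrates usage on the TRBV12-1/12-2/13-1 family, the pattern of
#' antigen-focused repertoires; `"broad"` boosts TRBV1/2/3/5/19 and flattens
#' the rest, emulating a repertoire whose V usage has broadened. TRBJ usage
#' is near-uniform over 12 genes in both settings.
#'
#' @param kind `"focused"` or `"broad"`.
#' @return named probability vector.
#' @export
trbv_profile <- function(kind = c("focused", "broad")) {
  kind <- match.arg(kind)
  genes <- c("TRBV1", "TRBV2", "TRBV3", "TRBV4", "TRBV5", "TRBV12-1",
             "TRBV12-2", "TRBV13-1", "TRBV13-2", "TRBV13-3", "TRBV14",
             "TRBV15", "TRBV16", "TRBV17", "TRBV19", "TRBV20", "TRBV23",
             "TRBV26", "TRBV29", "TRBV31")
  w <- stats::setNames(rep(0.5, length(genes)), genes)
  if (kind == "focused") {
    w[c("TRBV12-1", "TRBV12-2", "TRBV13-1")] <- c(5, 4, 4)
  } else {
    w[] <- 1
    w[c("TRBV1", "TRBV2", "TRBV3", "TRBV5", "TRBV19")] <- 3
  }
  w / sum(w)
}

#' @rdname trbv_profile
#' @export
trbj_profile <- function() {
  genes <- c(paste0("TRBJ1-", 1:5), paste0("TRBJ2-", 1:7))
  stats::setNames(rep(1 / length(genes), length(genes)), genes)
}

# Random in-frame CDR3 nucleotide sequences: 9-15 sense codons (27-45 nt),
# so translation is well-defined and stop-free. Uniqueness is enforced at
# the amino-acid level so identity-key sets behave as designed.
random_cdr3 <- function(n, forbidden_aa = character(0)) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G")), 1, paste, collapse = "")
  codons <- setdiff(codons, stops)
  gen <- function(k) {
    lens <- sample(9:15, k, replace = TRUE)
    vapply(lens, function(l) paste(sample(codons, l, replace = TRUE),
                                   collapse = ""), character(1))
  }
  nt <- gen(n)
  aa <- translate_cdr3(nt)
  for (iter in 1:100) {
    bad <- duplicated(aa) | aa %in% forbidden_aa
    if (!any(bad)) break
    nt[bad] <- gen(sum(bad))
    aa[bad] <- translate_cdr3(nt[bad])
  }
  if (anyDuplicated(aa) || any(aa %in% forbidden_aa))
    stop("could not generate unique CDR3 sequences", call. = FALSE)
  data.frame(cdr3_nt = nt, cdr3_aa = aa, stringsAsFactors = FALSE)
}

# Clone universe for a spec: sequences, gene labels and sampling
# probabilities. Uses the current RNG state (callers seed it).
make_universe <- function(spec, forbidden_aa = character(0)) {
  n <- spec$n_expanded + spec$n_background
  seqs <- random_cdr3(n, forbidden_aa)
  w_exp <- spec$expanded_weights %||% rep(1, spec$n_expanded)
  p_exp <- if (spec$n_expanded > 0)
    spec$expanded_mass * w_exp / sum(w_exp) else numeric(0)
  w_bg <- seq_len(spec$n_background)^(-spec$tail_exponent)
  p_bg <- (1 - spec$expanded_mass) * w_bg / sum(w_bg)
  data.frame(
    cdr3_nt = seqs$cdr3_nt, cdr3_aa = seqs$cdr3_aa,
    v_gene = sample(names(spec$v_profile), n, replace = TRUE,
                    prob = spec$v_profile),
    j_gene = sample(names(spec$j_profile), n, replace = TRUE,
                    prob = spec$j_profile),
    prob = c(p_exp, p_bg),
    expanded = rep(c(TRUE, FALSE), c(spec$n_expanded, spec$n_background)),
    stringsAsFactors = FALSE)
}

sample_reads <- function(universe, depth, sample_id, subject_id = NA,
                         tissue = NA, phase = NA, condition = NA) {
  reads <- as.vector(stats::rmultinom(1, depth, universe$prob))
  keep <- reads > 0
  repertoire(data.frame(cdr3_nt = universe$cdr3_nt[keep],
                        cdr3_aa = universe$cdr3_aa[keep],
                        v_gene = universe$v_gene[keep],
                        j_gene = universe$j_gene[keep],
                        reads = reads[keep], stringsAsFactors = FALSE),
             sample_id = sample_id, subject_id = subject_id, tissue = tissue,
             phase = phase, condition = condition)
}

#' Generate one synthetic repertoire
#'
#' Builds the clone universe defined by the spec and samples reads from it
#' once. Same spec and seed give an identical repertoire.
#'
#' @param spec a [repertoire_spec()].
#' @param sample_id,subject_id,tissue,phase,condition sample metadata.
#' @return a `tcr_repertoire`.
#' @export
generate_repertoire <- function(spec, sample_id = "synthetic",
                                subject_id = NA, tissue = NA, phase = NA,
                                condition = NA) {
  stopifnot(inherits(spec, "repertoire_spec"))
  set.seed(spec$seed)
  universe <- make_universe(spec)
  sample_reads(universe, spec$depth, sample_id, subject_id, tissue, phase,
               condition)
}

#' Generate a paired lymph-node/joint sample
#'
#' Builds the node and joint clone universes with an exactly realised number
#' of shared CDR3 amino-acid sequences (`sharing`), then samples reads for
#' each tissue independently. The construction rule controls where the
#' joint's expanded clones come from:
#'
#' * `"late"` — all of the joint's expanded clones are copies of the node's
#'   most abundant clones, in matching abundance order (the joint's expanded
#'   probabilities decrease linearly so the designed rank order is realised).
#' * `"early"` / `"control"` — a fraction `absent_fraction` of the joint's
#'   expanded clones are de novo (absent from the node); the rest are drawn
#'   from the node's top clones and assigned to expanded slots in shuffled
#'   order.
#'
#' The remaining shared sequences are copied from randomly chosen node
#' background clones into randomly chosen joint background slots. Because
#' read sampling can drop clones, realised overlap after sequencing can fall
#' slightly below the designed `sharing`.
#'
#' @param rule `"early"`, `"late"` or `"control"`.
#' @param pln_spec,joint_spec [repertoire_spec()] objects for the two
#'   tissues (their own `seed` fields are ignored; `seed` below governs the
#'   whole pair).
#' @param sharing designed count of CDR3 amino-acid sequences common to the
#'   two universes; must be realisable (at most the node universe size, and
#'   at least the number of shared expanded clones the rule implies).
#' @param seed integer seed for the pair.
#' @param subject_id,phase,condition metadata stamped on both repertoires.
#' @param absent_fraction fraction of joint expanded clones that are de novo
#'   under the early/control rules.
#' @return list with `pln`, `joint` (both `tcr_repertoire`) and `design`
#'   (the realised design parameters).
#' @export
generate_paired_sample <- function(rule = c("early", "late", "control"),
                                   pln_spec, joint_spec, sharing, seed,
                                   subject_id = "subject", phase = NA,
                                   condition = NA, absent_fraction = 0.5) {
  rule <- match.arg(rule)
  stopifnot(inherits(pln_spec, "repertoire_spec"),
            inherits(joint_spec, "repertoire_spec"))
  set.seed(seed)
  pln_univ <- make_universe(pln_spec)
  n_exp <- joint_spec$n_expanded
  n_shared_exp <- if (rule == "late") n_exp
                  else n_exp - round(absent_fraction * n_exp)
  if (sharing < n_shared_exp)
    stop("sharing (", sharing, ") is below the ", n_shared_exp,
         " expanded clones the '", rule, "' rule shares by construction",
         call. = FALSE)
  if (sharing > nrow(pln_univ))
    stop("sharing exceeds the node universe size", call. = FALSE)

  # joint universe: expanded probabilities decrease linearly so designed
  # rank order survives multinomial sampling
  jspec <- joint_spec
  jspec$expanded_weights <- jspec$expanded_weights %||%
    seq(1.5, 0.5, length.out = n_exp)
  joint_univ <- make_universe(jspec, forbidden_aa = pln_univ$cdr3_aa)

  pln_order <- order(-pln_univ$prob)
  seq_cols <- c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene")
  if (rule == "late") {
    donors <- pln_order[seq_len(n_exp)]
    joint_univ[seq_len(n_exp), seq_cols] <- pln_univ[donors, seq_cols]
  } else if (n_shared_exp > 0) {
    donors <- sample(pln_order[seq_len(n_exp)], n_shared_exp)
    slots <- sample(seq_len(n_exp), n_shared_exp)
    joint_univ[slots, seq_cols] <- pln_univ[donors, seq_cols]
  } else {
    donors <- integer(0)
  }
  n_bg_shared <- sharing - n_shared_exp
  if (n_bg_shared > 0) {
    bg_donors <- sample(setdiff(seq_len(nrow(pln_univ)), donors), n_bg_shared)
    bg_slots <- sample(which(!joint_univ$expanded), n_bg_shared)
    joint_univ[bg_slots, seq_cols] <- pln_univ[bg_donors, seq_cols]
  }
  stopifnot(length(intersect(pln_univ$cdr3_aa, joint_univ$cdr3_aa)) == sharing)

  pln <- sample_reads(pln_univ, pln_spec$depth,
                      sample_id = paste0(subject_id, "_pLN"),
                      subject_id = subject_id, tissue = "pLN", phase = phase,
                      condition = condition)
  joint <- sample_reads(joint_univ, jspec$depth,
                        sample_id = paste0(subject_id, "_joint"),
                        subject_id = subject_id, tissue = "joint",
                        phase = phase, condition = condition)
  list(pln = pln, joint = joint,
       design = list(rule = rule, sharing = sharing,
                     n_shared_expanded = n_shared_exp, seed = seed,
                     absent_fraction = if (rule == "late") 0 else absent_fraction))
}

#' Default study arms for the synthetic cohort
#'
#' Three arms emulating a paired-tissue inflammatory-arthritis design at two
#' phases plus late-phase adjuvant-only controls:
#'
#' * early inflamed — node: top-10 mass 0.18 over ~4,000 background clones
#'   (focused V profile); joint: top-10 mass 0.44 over ~2,000 clones; high
#'   designed node/joint sharing (400 sequences), half of the joint's
#'   expanded clones absent from the node.
#' * late inflamed — node: top-10 mass 0.02 over ~9,000 clones with the
#'   broad V profile (more clones, lower frequencies, broadened V usage);
#'   joint unchanged; low sharing (100) but every expanded joint clone drawn
#'   from the node's most abundant clones.
#' * late control — smaller, less dominated joint (top-10 mass 0.29 over
#'   ~900 clones), intermediate sharing, early-style rule.
#'
#' @param depth reads per sample.
#' @return named list of arm definitions.
#' @export
default_arms <- function(depth = 5e4) {
  list(
    early_inflamed = list(
      phase = "early", condition = "inflamed", rule = "early",
      sharing = 400, absent_fraction = 0.5,
      pln = repertoire_spec(10, 0.18, 4000, 0.6, depth,
                            v_profile = trbv_profile("focused")),
      joint = repertoire_spec(10, 0.44, 2000, 0.6, depth,
                              v_profile = trbv_profile("focused"))),
    late_inflamed = list(
      phase = "late", condition = "inflamed", rule = "late",
      sharing = 100, absent_fraction = 0,
      pln = repertoire_spec(10, 0.02, 9000, 0.6, depth,
                            v_profile = trbv_profile("broad")),
      joint = repertoire_spec(10, 0.44, 2000, 0.6, depth,
                              v_profile = trbv_profile("focused"))),
    late_control = list(
      phase = "late", condition = "control", rule = "control",
      sharing = 150, absent_fraction = 0.5,
      pln = repertoire_spec(10, 0.05, 4500, 0.6, depth,
                            v_profile = trbv_profile("focused")),
      joint = repertoire_spec(10, 0.29, 900, 0.6, depth,
                              v_profile = trbv_profile("focused"))))
}

#' Specification of a full synthetic cohort
#'
#' @param n_subjects subjects per arm.
#' @param depth reads per sample.
#' @param master_seed integer; per-pair seeds are derived by a documented
#'   counter scheme (`master_seed + 7919 * pair_index`, mod 2^31 - 1) so any
#'   single pair is regenerable in isolation.
#' @param arms arm definitions as produced by [default_arms()].
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 5, depth = 5e4, master_seed = 20210427,
                        arms = default_arms(depth)) {
  stopifnot(n_subjects >= 1, master_seed == as.integer(master_seed))
  structure(list(n_subjects = as.integer(n_subjects), depth = depth,
                 master_seed = as.integer(master_seed), arms = arms),
            class = "cohort_spec")
}

pair_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 7919 * index) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' Generates every subject's paired node/joint repertoires for each arm and
#' assembles a manifest recording the design parameters and per-pair seed of
#' every sample. When `out_dir` is given, each repertoire is written as an
#' AIRR TSV and the manifest as `manifest.tsv`; regenerating from the same
#' spec reproduces byte-identical files.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional output directory.
#' @return list with `repertoires` (named list of `tcr_repertoire`) and
#'   `manifest` (data.frame).
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  reps <- list()
  rows <- list()
  idx <- 0L
  for (arm_name in names(spec$arms)) {
    arm <- spec$arms[[arm_name]]
    for (s in seq_len(spec$n_subjects)) {
      idx <- idx + 1L
      seed <- pair_seed(spec$master_seed, idx)
      subject <- sprintf("%s_s%d", arm_name, s)
      pair <- generate_paired_sample(
        rule = arm$rule, pln_spec = arm$pln, joint_spec = arm$joint,
        sharing = arm$sharing, seed = seed, subject_id = subject,
        phase = arm$phase, condition = arm$condition,
        absent_fraction = arm$absent_fraction)
      for (tissue in c("pln", "joint")) {
        r <- pair[[tissue]]
        reps[[r$sample_id]] <- r
        tspec <- if (tissue == "pln") arm$pln else arm$joint
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = r$sample_id, subject_id = subject,
          tissue = r$tissue, phase = arm$phase, condition = arm$condition,
          path = NA_character_, seed = seed, rule = arm$rule,
          sharing = arm$sharing, absent_fraction = arm$absent_fraction,
          n_expanded = tspec$n_expanded, expanded_mass = tspec$expanded_mass,
          n_background = tspec$n_background,
          tail_exponent = tspec$tail_exponent, depth = tspec$depth,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(out_dir, paste0(manifest$sample_id, ".airr.tsv"))
    for (i in seq_len(nrow(manifest)))
      write_repertoire(reps[[manifest$sample_id[i]]], manifest$path[i],
                       format = "airr")
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(repertoires = reps, manifest = manifest)
}
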