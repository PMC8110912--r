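#' Two-sample t tests with explicit degenerate handling
#'
#' `student_t()` is the pooled-variance unpaired two-sample t test;
#' `welch_t()` uses Welch-Satterthwaite degrees of freedom. Both are
#' two-sided. Degenerate inputs are handled explicitly rather than erroring:
#' when both groups have zero variance the statistic is 0 with p = 1 if the
#' means agree, and infinite with p = 0 (flagged `degenerate = TRUE`) if
#' they differ.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param alpha significance level for the `significant` flag.
#' @return a `group_comparison`: list with `statistic_name`, `n_a`, `n_b`,
#'   `statistic`, `df`, `p_value`, `alpha`, `significant`, `degenerate`.
#' @export
student_t <- function(a, b, alpha = 0.05) {
  two_sample_t(a, b, var_equal = TRUE, alpha = alpha)
}

#' @rdname student_t
#' @export
welch_t <- function(a, b, alpha = 0.05) {
  two_sample_t(a, b, var_equal = FALSE, alpha = alpha)
}

two_sample_t <- function(a, b, var_equal, alpha) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  name <- if (var_equal) "student_t" else "welch_t"
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(statistic = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
                df = NA_real_, p_value = if (equal) 1 else 0,
                degenerate = TRUE)
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, degenerate = FALSE)
  }
  structure(list(statistic_name = name, n_a = length(a), n_b = length(b),
                 statistic = res$statistic, df = res$df,
                 p_value = res$p_value, alpha = alpha,
                 significant = res$p_value < alpha,
                 degenerate = res$degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s> n = %d vs %d: statistic = %.4g, p = %.4g%s\n",
              x$statistic_name, x$n_a, x$n_b, x$statistic, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Two-way ANOVA (Type II sums of squares)
#'
#' Main effects and interaction of two crossed factors, using Type II sums
#' of squares so unbalanced layouts (unequal group sizes) are handled in a
#' stated, reproducible way. The fully degenerate case where every value is
#' identical is reported as F = 0, p = 1 for all effects.
#'
#' @param values numeric response vector.
#' @param factor1,factor2 factor labels, same length as `values`; each must
#'   have at least two levels.
#' @param factor_names column names for the two factors in the output.
#' @param alpha significance level for the `significant` flags.
#' @return data.frame with one row per effect (`factor1`, `factor2`,
#'   `interaction`): sum of squares, df, F, p-value, significance flag.
#' @export
two_way_anova <- function(values, factor1, factor2,
                          factor_names = c("factor1", "factor2"),
                          alpha = 0.05) {
  f1 <- factor(factor1); f2 <- factor(factor2)
  if (nlevels(f1) < 2L || nlevels(f2) < 2L)
    stop("each factor needs at least two levels", call. = FALSE)
  stopifnot(length(values) == length(f1), length(values) == length(f2))
  effects <- c(factor_names, paste(factor_names, collapse = ":"))
  if (stats::var(values) == 0) {
    out <- data.frame(effect = effects, sum_sq = 0, df = NA_real_,
                      statistic = 0, p_value = 1, stringsAsFactors = FALSE)
  } else {
    fit <- stats::lm(values ~ f1 * f2)
    an <- car::Anova(fit, type = 2)
    keep <- c("f1", "f2", "f1:f2")
    an <- an[keep, , drop = FALSE]
    out <- data.frame(effect = effects, sum_sq = an[["Sum Sq"]],
                      df = an[["Df"]], statistic = an[["F value"]],
                      p_value = an[["Pr(>F)"]], stringsAsFactors = FALSE)
  }
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  rownames(out) <- NULL
  out
}
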