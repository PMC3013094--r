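#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample mean and SD. Advisory: downstream t-tests proceed regardless, a
#' rejection only raises a warning in the pipeline. (Estimating the reference
#' parameters from the sample makes the test conservative; it is used here as
#' a screening device, matching common practice in physiology reporting.)
#'
#' @param values Numeric vector, n >= 3 with positive SD.
#' @return List with `statistic` (D), `p_value` and `n`.
#' @export
check_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) {
    stop("need at least 3 values for a normality check", call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) {
    stop("degenerate sample: zero standard deviation", call. = FALSE)
  }
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean = mean(values), sd = s)
  )
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n = length(values))
}

#' Percent difference of a value relative to a reference
#'
#' `100 * (a - reference) / reference`: how much larger (positive) or smaller
#' (negative) `a` is than the reference group mean.
#'
#' @param a Value of interest (e.g. swimmer group mean).
#' @param reference Reference value (e.g. rester group mean), non-zero.
#' @return Percent difference.
#' @export
percent_difference <- function(a, reference) {
  if (any(reference == 0)) stop("reference value must be non-zero", call. = FALSE)
  100 * (a - reference) / reference
}

#' Pre/post and between-group growth comparison
#'
#' Runs the designated Student t-test variant on a morphometric variable of a
#' cohort table (see [read_cohort_csv()] for the dialect):
#' \describe{
#'   \item{`paired_t_one_tailed`}{within one group, post vs pre, pairing fish
#'     by `fish_id`; requires `group` and a declared `alternative`.}
#'   \item{`unpaired_t_one_tailed`, `unpaired_t_two_tailed`}{between the two
#'     `groups` at one `stage`; classical pooled-variance Student test by
#'     default, Welch via `welch = TRUE`.}
#' }
#' The one-tailed direction is never inferred from the data: `alternative`
#' states the hypothesis (`"greater"` means post > pre, or first group >
#' second group). A KS normality screen is applied to each sample first and a
#' warning issued on rejection.
#'
#' @param cohort Cohort data frame (`fish_id,group,...,stage`).
#' @param variable `"total_tl_cm"` or `"body_weight_g"` (any numeric column).
#' @param test One of `"paired_t_one_tailed"`, `"unpaired_t_one_tailed"`,
#'   `"unpaired_t_two_tailed"`.
#' @param group Group for the paired test.
#' @param groups Length-2 character vector for the unpaired tests; the first
#'   is the group of interest, the second the reference.
#' @param stage Stage compared in the unpaired tests (`"post"` default).
#' @param alternative `"greater"`, `"less"` (one-tailed tests) — ignored with
#'   a two-sided test.
#' @param welch Use the Welch unequal-variance form (default `FALSE`, pooled).
#' @return An object of class `growth_comparison`: list with the test name,
#'   group means +/- SEM, `t`, `df`, `p_value` and `percent_difference`
#'   (first vs reference for unpaired; post vs pre for paired).
#' @export
compare_growth <- function(cohort, variable,
                           test = c("paired_t_one_tailed",
                                    "unpaired_t_one_tailed",
                                    "unpaired_t_two_tailed"),
                           group = NULL, groups = NULL, stage = "post",
                           alternative = "greater", welch = FALSE) {
  test <- match.arg(test)
  if (!variable %in% names(cohort)) {
    stop("variable '", variable, "' not found in cohort table", call. = FALSE)
  }
  two_sided <- test == "unpaired_t_two_tailed"
  alt <- if (two_sided) "two.sided" else match.arg(alternative,
                                                   c("greater", "less"))
  warn_nonnormal <- function(x, label) {
    if (length(x) >= 3L && stats::sd(x) > 0) {
      p <- check_normality(x)$p_value
      if (p < 0.05) {
        warning(sprintf("KS normality check rejected for %s (p = %.3g)",
                        label, p), call. = FALSE)
      }
    }
  }
  if (test == "paired_t_one_tailed") {
    if (is.null(group)) stop("paired test needs 'group'", call. = FALSE)
    d <- cohort[cohort$group == group, c("fish_id", "stage", variable)]
    pre <- d[d$stage == "pre", ]
    post <- d[d$stage == "post", ]
    ids <- intersect(pre$fish_id, post$fish_id)
    if (length(ids) < 2L ||
        anyDuplicated(pre$fish_id) || anyDuplicated(post$fish_id)) {
      stop("paired comparison needs uniquely matched pre/post fish_ids",
           call. = FALSE)
    }
    x <- post[match(ids, post$fish_id), variable]
    y <- pre[match(ids, pre$fish_id), variable]
    warn_nonnormal(x - y, paste(group, "pre/post differences"))
    if (stats::sd(x - y) == 0 && mean(x - y) == 0) {
      # degenerate but well-defined: no change at all -> t = 0, one-tailed 0.5
      ht <- list(statistic = c(t = 0), parameter = c(df = length(x) - 1),
                 p.value = 0.5)
    } else {
      ht <- stats::t.test(x, y, paired = TRUE, alternative = alt)
    }
    res <- list(
      test = test, variable = variable, groups = group,
      mean_a = mean(x), sem_a = stats::sd(x) / sqrt(length(x)),
      mean_b = mean(y), sem_b = stats::sd(y) / sqrt(length(y)),
      n = length(ids),
      t = unname(ht$statistic), df = unname(ht$parameter),
      p_value = ht$p.value,
      percent_difference = percent_difference(mean(x), mean(y))
    )
  } else {
    if (is.null(groups) || length(groups) != 2L) {
      stop("unpaired test needs 'groups' of length 2", call. = FALSE)
    }
    d <- cohort[cohort$stage == stage, ]
    x <- d[d$group == groups[1L], variable]
    y <- d[d$group == groups[2L], variable]
    if (length(x) < 2L || length(y) < 2L) {
      stop("each group needs at least 2 observations", call. = FALSE)
    }
    warn_nonnormal(x, groups[1L])
    warn_nonnormal(y, groups[2L])
    ht <- stats::t.test(x, y, alternative = alt, var.equal = !welch)
    res <- list(
      test = test, variable = variable, groups = groups,
      mean_a = mean(x), sem_a = stats::sd(x) / sqrt(length(x)),
      mean_b = mean(y), sem_b = stats::sd(y) / sqrt(length(y)),
      n = c(length(x), length(y)),
      t = unname(ht$statistic), df = unname(ht$parameter),
      p_value = ht$p.value,
      percent_difference = percent_difference(mean(x), mean(y))
    )
  }
  structure(res, class = "growth_comparison")
}

#' @export
print.growth_comparison <- function(x, ...) {
  cat(sprintf("%s on %s [%s]\n", x$test, x$variable,
              paste(x$groups, collapse = " vs ")))
  cat(sprintf("  %.4g +/- %.2g  vs  %.4g +/- %.2g\n",
              x$mean_a, x$sem_a, x$mean_b, x$sem_b))
  cat(sprintf("  t = %.3f (df %.4g), p = %.3g, difference %+.1f%%\n",
              x$t, x$df, x$p_value, x$percent_difference))
  invisible(x)
}
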