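#' Muscle growth marker gene vocabulary
#'
#' The 14 target genes plus the housekeeping gene `rps18`, with the primer
#' set each was assayed under. Set A and set B use different `rps18` primer
#' pairs, so normalisation must stay within a set.
#'
#' @return Data frame with `gene` and `primer_set`.
#' @export
qpcr_gene_table <- function() {
  data.frame(
    gene = c("rps18", "ghra", "ghrb", "igf1ra", "igf1rb", "igf1", "ztor",
             "foxo5", "pgc1a",
             "rps18", "stnnc", "smyhc1", "tnni2", "myhz2", "mstnb", "myog"),
    primer_set = c(rep("A", 9L), rep("B", 7L)),
    stringsAsFactors = FALSE
  )
}

#' Primer reference metadata
#'
#' The primer pairs of the assay (gene symbol, GenBank accession, forward and
#' reverse sequence, primer set), shipped as reference metadata only — no
#' computation uses the sequences.
#'
#' @return Data frame with columns `primer_set,gene,genbank,forward,reverse`.
#' @export
qpcr_primers <- function() {
  utils::read.delim(system.file("extdata", "qpcr_primers.tsv",
                                package = "swimfit"),
                    stringsAsFactors = FALSE)
}

#' Aggregate triplicate Ct values
#'
#' Arithmetic mean of the three technical replicates of a well group, with a
#' quality flag when the replicate SD exceeds `sd_threshold` cycles
#' (pipetting or amplification inconsistency).
#'
#' @param ct_values Numeric vector of exactly 3 replicate Ct values, each in
#'   (0, 40].
#' @param sd_threshold Replicate-SD QC threshold, cycles (default 0.5).
#' @return List with `mean_ct`, `sd`, `qc_pass`.
#' @examples
#' aggregate_triplicates(c(20.0, 20.2, 19.8))
#' @export
aggregate_triplicates <- function(ct_values, sd_threshold = 0.5) {
  if (length(ct_values) != 3L) {
    stop("plate format error: expected exactly 3 replicate Ct values",
         call. = FALSE)
  }
  if (any(!is.finite(ct_values)) || any(ct_values <= 0 | ct_values > 40)) {
    stop("Ct values must lie in (0, 40]", call. = FALSE)
  }
  s <- stats::sd(ct_values)
  list(mean_ct = mean(ct_values), sd = s, qc_pass = s <= sd_threshold)
}

#' Normalise a target Ct against the housekeeping gene
#'
#' `dCt = target - housekeeping`, both mean Cts from the same fish and the
#' same primer set (sets A and B use different rps18 primers, so
#' cross-set normalisation is refused).
#'
#' @param target_ct Mean Ct of the target gene.
#' @param housekeeping_ct Mean Ct of rps18 for the same fish.
#' @param target_set,housekeeping_set Primer-set labels; must match.
#' @return dCt in cycles.
#' @export
normalize_dct <- function(target_ct, housekeeping_ct,
                          target_set = "A", housekeeping_set = target_set) {
  if (!identical(target_set, housekeeping_set)) {
    stop("normalization error: target and housekeeping Cts come from ",
         "different primer sets", call. = FALSE)
  }
  target_ct - housekeeping_ct
}

#' Relative fold change by the 2^-ddCt method
#'
#' Livak relative quantification of swimmers against the rester group: each
#' swimmer's ddCt is its dCt minus the rester-group mean dCt, and its fold
#' change `fc_j = 2^-ddCt_j` (amplification efficiency fixed at 2.0; an
#' efficiency-corrected base can be supplied for assays with measured
#' standard-curve efficiencies). The reported fold change is the arithmetic
#' mean of the per-swimmer `fc_j` with its SEM; a geometric mean is also
#' returned for log-scale reporting.
#'
#' @param swimmer_dct dCt values of the swimmer group (>= 2).
#' @param rester_dct dCt values of the rester group (>= 2).
#' @param efficiency Amplification efficiency base (default 2.0, pure Livak).
#' @return List with `fold_change_mean`, `fold_change_sem`,
#'   `fold_change_geometric`, `per_fish_fc`, `n_swimmers`, `n_resters`.
#' @examples
#' fold_change(c(4, 4.2, 3.8), c(5, 5.1, 4.9))  # up-regulated ~2x
#' @export
fold_change <- function(swimmer_dct, rester_dct, efficiency = 2.0) {
  swimmer_dct <- swimmer_dct[is.finite(swimmer_dct)]
  rester_dct <- rester_dct[is.finite(rester_dct)]
  if (length(swimmer_dct) < 2L || length(rester_dct) < 2L) {
    stop("need at least 2 fish per group after QC", call. = FALSE)
  }
  if (efficiency <= 1) stop("amplification efficiency must exceed 1", call. = FALSE)
  ddct <- swimmer_dct - mean(rester_dct)
  fc <- efficiency^(-ddct)
  list(
    fold_change_mean = mean(fc),
    fold_change_sem = stats::sd(fc) / sqrt(length(fc)),
    fold_change_geometric = exp(mean(log(fc))),
    per_fish_fc = fc,
    n_swimmers = length(swimmer_dct),
    n_resters = length(rester_dct)
  )
}

grubbs_critical <- function(n, alpha = 0.05) {
  # two-sided Grubbs critical value from the t distribution
  tq <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Iterative Grubbs outlier removal
#'
#' Repeatedly applies the two-sided Grubbs test at level `alpha` to the most
#' extreme value, removing it while significant, up to `max_removals`
#' removals. Small samples (n < 4) are returned unchanged with a warning —
#' the test has no power there.
#'
#' @param values Numeric vector.
#' @param max_removals Maximum number of removals (default 2, the observed
#'   per-gene, per-group maximum in practice).
#' @param alpha Significance level of each Grubbs step (default 0.05).
#' @return List with `values` (kept), `removed_indices` (positions in the
#'   input) and `removed_values`.
#' @examples
#' remove_outliers(c(1, 1.1, 0.9, 1.0, 15))
#' @export
remove_outliers <- function(values, max_removals = 2, alpha = 0.05) {
  removed <- integer(0)
  if (max_removals <= 0) {
    return(list(values = values, removed_indices = integer(0),
                removed_values = numeric(0)))
  }
  keep <- seq_along(values)
  while (length(removed) < max_removals) {
    x <- values[keep]
    n <- length(x)
    if (n < 4L) {
      if (length(removed) == 0L) {
        warning("fewer than 4 values: outlier screen skipped", call. = FALSE)
      }
      break
    }
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    if (g <= grubbs_critical(n, alpha)) break
    worst <- keep[which.max(dev)]
    removed <- c(removed, worst)
    keep <- setdiff(keep, worst)
  }
  list(values = values[keep], removed_indices = removed,
       removed_values = values[removed])
}

#' Mann-Whitney U test
#'
#' Two-sample rank test comparing the two groups. The exact null distribution
#' is used for combined n <= 20 without ties; otherwise the normal
#' approximation with tie correction (and continuity correction) applies.
#'
#' @param group_a,group_b Numeric vectors, each n >= 1.
#' @param alternative `"two.sided"` (default), `"greater"`, `"less"`.
#' @return List with `u` (the U statistic of `group_a` over `group_b`),
#'   `p_value`, `exact` (logical).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(group_a, group_b, alternative = "two.sided") {
  if (length(group_a) < 1L || length(group_b) < 1L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n_tot <- length(group_a) + length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- n_tot <= 20 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = alternative,
                       exact = exact, correct = !exact)
  )
  list(u = unname(ht$statistic), p_value = ht$p.value, exact = exact)
}

#' Housekeeping-gene stability check
#'
#' Flags a dataset in which the mean rps18 Ct differs between swimmer and
#' rester groups (two-sided Student t-test at `alpha`); ddCt normalisation is
#' only valid when the housekeeping gene is stable across groups.
#'
#' @param swimmer_hk_ct,rester_hk_ct Per-fish mean rps18 Cts.
#' @param alpha Flag threshold (default 0.05).
#' @return List with `p_value` and `stable`.
#' @export
housekeeping_stability <- function(swimmer_hk_ct, rester_hk_ct, alpha = 0.05) {
  if (stats::sd(swimmer_hk_ct) == 0 && stats::sd(rester_hk_ct) == 0) {
    # degenerate (noise-free) data: stable iff the constants agree
    p <- if (mean(swimmer_hk_ct) == mean(rester_hk_ct)) 1 else 0
    return(list(p_value = p, stable = p >= alpha))
  }
  ht <- stats::t.test(swimmer_hk_ct, rester_hk_ct)
  list(p_value = ht$p.value, stable = ht$p.value >= alpha)
}

#' Read a triplicate Ct plate CSV
#'
#' Dialect: `fish_id,group,gene,primer_set,rep1_ct,rep2_ct,rep3_ct,dilution`.
#' @param path Path to the CSV.
#' @return Data frame.
#' @export
read_ct_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("fish_id", "group", "gene", "primer_set",
                "rep1_ct", "rep2_ct", "rep3_ct")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("Ct CSV ", path, " missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Full relative-quantification analysis of a Ct plate table
#'
#' For each target gene: aggregates triplicates per fish, normalises against
#' the same-fish, same-primer-set rps18 mean Ct, screens each group's dCt
#' values with the Grubbs test, computes the swimmer-over-rester fold change
#' by 2^-ddCt and a two-sided Mann-Whitney U test on the per-fish relative
#' expression (2^-dCt). Also reports the housekeeping stability check.
#'
#' @param plates Plate table as from [read_ct_csv()] or
#'   [simulate_ct_table()].
#' @param sd_threshold Triplicate-SD QC threshold, cycles.
#' @param max_removals Grubbs removals allowed per gene per group.
#' @param alpha Grubbs significance level.
#' @param efficiency Amplification efficiency base.
#' @return An object of class `qpcr_result`: list with `genes` (data frame:
#'   gene, fold_change_mean, fold_change_sem, n_swimmers, n_resters,
#'   n_removed, u_statistic, p_value), `removed` (log of removed dCt values)
#'   and `housekeeping` (stability check).
#' @export
qpcr_pipeline <- function(plates, sd_threshold = 0.5, max_removals = 2,
                          alpha = 0.05, efficiency = 2.0) {
  vocab <- qpcr_gene_table()
  plates$primer_set <- as.character(plates$primer_set)
  # per-row triplicate means
  reps <- as.matrix(plates[, c("rep1_ct", "rep2_ct", "rep3_ct")])
  agg <- apply(reps, 1L, aggregate_triplicates, sd_threshold = sd_threshold)
  plates$mean_ct <- vapply(agg, `[[`, numeric(1L), "mean_ct")
  plates$qc_pass <- vapply(agg, `[[`, logical(1L), "qc_pass")
  n_flag <- sum(!plates$qc_pass)
  if (n_flag > 0) {
    warning(sprintf("%d well group(s) exceeded the triplicate-SD threshold",
                    n_flag), call. = FALSE)
  }
  hk <- plates[plates$gene == "rps18", ]
  targets <- setdiff(unique(plates$gene), "rps18")
  hk_key <- paste(hk$fish_id, hk$primer_set)
  removed_log <- list()
  rows <- lapply(targets, function(g) {
    d <- plates[plates$gene == g, ]
    idx <- match(paste(d$fish_id, d$primer_set), hk_key)
    if (anyNA(idx)) {
      stop("no matching rps18 wells (same fish, same primer set) for gene ",
           g, call. = FALSE)
    }
    d$dct <- normalize_dct(d$mean_ct, hk$mean_ct[idx],
                           target_set = d$primer_set[1L],
                           housekeeping_set = hk$primer_set[idx][1L])
    sw <- d$dct[d$group == "swimmer"]
    re <- d$dct[d$group == "rester"]
    sw_scr <- remove_outliers(sw, max_removals = max_removals, alpha = alpha)
    re_scr <- remove_outliers(re, max_removals = max_removals, alpha = alpha)
    n_rm <- length(sw_scr$removed_indices) + length(re_scr$removed_indices)
    if (n_rm > 0) {
      removed_log[[g]] <<- list(swimmer = sw_scr$removed_values,
                                rester = re_scr$removed_values)
    }
    fc <- fold_change(sw_scr$values, re_scr$values, efficiency = efficiency)
    # rank test on per-fish linearized expression (monotone in -dCt)
    mw <- mann_whitney(efficiency^(-sw_scr$values),
                       efficiency^(-re_scr$values))
    data.frame(gene = g,
               fold_change_mean = fc$fold_change_mean,
               fold_change_sem = fc$fold_change_sem,
               n_swimmers = fc$n_swimmers, n_resters = fc$n_resters,
               n_removed = n_rm,
               u_statistic = mw$u, p_value = mw$p_value,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  ord <- match(genes$gene, vocab$gene)
  genes <- genes[order(ifelse(is.na(ord), 99L, ord)), ]
  rownames(genes) <- NULL
  hk_stab <- local({
    sw <- hk$mean_ct[hk$group == "swimmer"]
    re <- hk$mean_ct[hk$group == "rester"]
    if (length(sw) >= 2L && length(re) >= 2L) {
      housekeeping_stability(sw, re)
    } else {
      list(p_value = NA_real_, stable = NA)
    }
  })
  if (isFALSE(hk_stab$stable)) {
    warning("rps18 mean Ct differs between groups; normalisation suspect",
            call. = FALSE)
  }
  structure(list(genes = genes, removed = removed_log,
                 housekeeping = hk_stab),
            class = "qpcr_result")
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat("Relative quantification (swimmers over resters, 2^-ddCt)\n")
  g <- x$genes
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-7s fc %5.2f +/- %4.2f  (n %d/%d%s)  U = %g, p = %.3g%s\n",
                g$gene[i], g$fold_change_mean[i], g$fold_change_sem[i],
                g$n_swimmers[i], g$n_resters[i],
                if (g$n_removed[i] > 0)
                  sprintf(", %d outlier(s) removed", g$n_removed[i]) else "",
                g$u_statistic[i], g$p_value[i],
                if (g$p_value[i] < 0.05) " *" else ""))
  }
  if (!is.na(x$housekeeping$p_value)) {
    cat(sprintf("  rps18 stability: p = %.3g (%s)\n", x$housekeeping$p_value,
                if (isTRUE(x$housekeeping$stable)) "stable" else "UNSTABLE"))
  }
  invisible(x)
}
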