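#' Build a run configuration
#'
#' Collects input paths, the tunnel specification and analysis options for
#' [run_pipeline()]. Can also be loaded from a YAML file via
#' [read_run_config()].
#'
#' @param traces,trials,cohort,ct Paths to the input CSVs (trace, trial,
#'   cohort morphometrics, Ct plates). Any may be `NULL`; the corresponding
#'   stage is skipped.
#' @param tunnel A [tunnel_spec()].
#' @param out_dir Output directory (created if missing).
#' @param speed_axis Speed axis of the metabolic curves
#'   (`"pct_ucrit"`/`"cm_s"`).
#' @param outlier_alpha Grubbs significance level.
#' @param max_removals Grubbs removals per gene per group.
#' @param ct_sd_threshold Triplicate-SD QC threshold, cycles.
#' @param min_r_squared Decline-fit QC threshold.
#' @param efficiency qPCR amplification efficiency base.
#' @param default_body_mass Body mass (g) used for trace conversion when a
#'   fish has no morphometrics record.
#' @param seed Integer seed recorded in the outputs (the analysis itself is
#'   deterministic; the seed matters when the config is used to simulate).
#' @return A list of class `run_config`.
#' @export
run_config <- function(traces = NULL, trials = NULL, cohort = NULL, ct = NULL,
                       tunnel = tunnel_spec(), out_dir = tempfile("swimfit"),
                       speed_axis = "pct_ucrit", outlier_alpha = 0.05,
                       max_removals = 2, ct_sd_threshold = 0.5,
                       min_r_squared = 0.9, efficiency = 2.0,
                       default_body_mass = 0.43, seed = 1L) {
  for (p in c(traces, trials, cohort, ct)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file does not exist: ", p, call. = FALSE)
    }
  }
  structure(
    list(traces = traces, trials = trials, cohort = cohort, ct = ct,
         tunnel = tunnel, out_dir = out_dir,
         speed_axis = match.arg(speed_axis, c("pct_ucrit", "cm_s")),
         outlier_alpha = outlier_alpha, max_removals = max_removals,
         ct_sd_threshold = ct_sd_threshold, min_r_squared = min_r_squared,
         efficiency = efficiency, default_body_mass = default_body_mass,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Flat YAML mapping of the [run_config()] arguments, with the tunnel given
#' as a `tunnel:` mapping (`volume`, `temperature`, `salinity`,
#' `barometric_pressure`, `flow_calibration: [slope, intercept]`).
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  tun <- do.call(tunnel_spec, c(
    y$tunnel[setdiff(names(y$tunnel), "flow_calibration")],
    if (!is.null(y$tunnel$flow_calibration)) {
      list(flow_calibration = unlist(y$tunnel$flow_calibration))
    }
  ))
  args <- y[setdiff(names(y), "tunnel")]
  do.call(run_config, c(args, list(tunnel = tun)))
}

#' Validate the input files of a run configuration
#'
#' Schema check of every CSV dialect the pipeline consumes. Report-only:
#' returns a data frame of issues (empty when all inputs are valid);
#' [run_pipeline()] refuses to start on a non-empty report unless forced.
#'
#' @param config A [run_config()].
#' @return Data frame with columns `file`, `issue`.
#' @export
validate_inputs <- function(config) {
  issues <- list()
  note <- function(file, issue) {
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, issue = issue, stringsAsFactors = FALSE)
  }
  check_cols <- function(df, required, path) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      note(path, paste("missing column(s):", paste(missing, collapse = ", ")))
      FALSE
    } else TRUE
  }
  if (!is.null(config$traces)) {
    df <- utils::read.csv(config$traces, stringsAsFactors = FALSE)
    if (check_cols(df, c("fish_id", "time_s", "o2_pct_as", "phase",
                         "speed_pct_ucrit"), config$traces)) {
      bad <- !df$phase %in% c("closed", "flush")
      if (any(bad)) {
        note(config$traces, paste("invalid phase value(s):",
                                  paste(unique(df$phase[bad]), collapse = ", ")))
      }
      if (any(df$o2_pct_as < 0 | df$o2_pct_as > 120, na.rm = TRUE)) {
        note(config$traces, "oxygen outside [0, 120] %AS")
      }
    }
  }
  if (!is.null(config$trials)) {
    df <- utils::read.csv(config$trials, stringsAsFactors = FALSE)
    if (check_cols(df, c("fish_id", "u_i_ms", "u_ii_ms", "t_i_s", "t_ii_s"),
                   config$trials)) {
      if (any(df$t_i_s > df$t_ii_s, na.rm = TRUE)) {
        note(config$trials, "t_i exceeds t_ii")
      }
      if (any(df$u_ii_ms <= 0, na.rm = TRUE)) {
        note(config$trials, "non-positive velocity increment")
      }
    }
  }
  if (!is.null(config$cohort)) {
    df <- utils::read.csv(config$cohort, stringsAsFactors = FALSE)
    if (check_cols(df, c("fish_id", "group", "standard_bl_cm", "total_tl_cm",
                         "body_weight_g", "stage"), config$cohort)) {
      bad <- !df$stage %in% c("pre", "post")
      if (any(bad)) note(config$cohort, "invalid stage value(s)")
      bad <- !df$group %in% c("swimmer", "rester", "individual")
      if (any(bad)) note(config$cohort, "invalid group value(s)")
      both <- is.finite(df$standard_bl_cm) & is.finite(df$total_tl_cm)
      if (any(df$standard_bl_cm[both] >= df$total_tl_cm[both])) {
        note(config$cohort, "standard BL not smaller than total TL")
      }
    }
  }
  if (!is.null(config$ct)) {
    df <- utils::read.csv(config$ct, stringsAsFactors = FALSE)
    if (check_cols(df, c("fish_id", "group", "gene", "primer_set",
                         "rep1_ct", "rep2_ct", "rep3_ct"), config$ct)) {
      reps <- df[, c("rep1_ct", "rep2_ct", "rep3_ct")]
      if (any(!is.finite(as.matrix(reps)))) {
        note(config$ct, "row(s) with fewer than 3 finite replicate Cts")
      }
      unknown <- setdiff(unique(df$gene), qpcr_gene_table()$gene)
      if (length(unknown)) {
        note(config$ct, paste("unknown gene(s):",
                              paste(unknown, collapse = ", ")))
      }
    }
  }
  if (length(issues)) do.call(rbind, issues) else {
    data.frame(file = character(0), issue = character(0),
               stringsAsFactors = FALSE)
  }
}

#' Run the full analysis pipeline
#'
#' Executes, in order, whichever stages the configuration provides inputs
#' for: U_crit from the trial records; oxygen traces to mass-specific uptake
#' points; per-fish swimming-economy fits (SMR, VO2max, U_opt, COT_opt) with
#' group summaries and a pooled group-curve mode; the pre/post and
#' between-group growth test battery; and the qPCR relative-quantification
#' analysis. Writes tidy CSVs, a machine-readable `summary.json` and a
#' human-readable `summary.txt` into `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param force Run even if [validate_inputs()] reports issues.
#' @return Invisibly, a list with all stage results and the output paths.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  issues <- validate_inputs(config)
  if (nrow(issues) > 0 && !force) {
    stop("input validation failed (", nrow(issues), " issue(s)); ",
         "first: ", issues$issue[1L], call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(seed = config$seed)

  cohort <- if (!is.null(config$cohort)) read_cohort_csv(config$cohort)

  if (!is.null(config$trials)) {
    trials <- read_trial_csv(config$trials)
    results$ucrit <- ucrit_from_trials(trials)
    utils::write.csv(results$ucrit,
                     file.path(config$out_dir, "ucrit.csv"), row.names = FALSE)
  }

  if (!is.null(config$traces)) {
    traces <- read_trace_csv(config$traces)
    mass_of <- function(id) {
      if (!is.null(cohort)) {
        m <- cohort$body_weight_g[cohort$fish_id == id & cohort$stage == "pre"]
        if (length(m)) return(m[1L])
      }
      config$default_body_mass
    }
    pts <- lapply(traces, function(tr) {
      fit <- fit_decline(tr, config$tunnel,
                         min_r_squared = config$min_r_squared)
      data.frame(fish_id = attr(tr, "fish_id"),
                 speed_pct_ucrit = attr(tr, "speed_pct_ucrit"),
                 mo2_umol_g_h = mo2(fit, config$tunnel,
                                    mass_of(attr(tr, "fish_id"))),
                 r_squared = fit$r_squared, stringsAsFactors = FALSE)
    })
    results$points <- do.call(rbind, pts)
    rownames(results$points) <- NULL
    utils::write.csv(results$points,
                     file.path(config$out_dir, "mo2_points.csv"),
                     row.names = FALSE)
  }

  if (!is.null(results$points) && !is.null(results$ucrit)) {
    bl_of <- function(id) {
      if (!is.null(cohort)) {
        b <- cohort$standard_bl_cm[cohort$fish_id == id &
                                     cohort$stage == "pre"]
        if (length(b)) return(b[1L])
      }
      NA_real_
    }
    per_fish <- list()
    for (id in unique(results$points$fish_id)) {
      p <- results$points[results$points$fish_id == id, ]
      uc <- results$ucrit$ucrit_ms[results$ucrit$fish_id == id]
      if (!length(uc) || nrow(p) < 3L) next
      fit_pts <- p[p$speed_pct_ucrit > 5, ]          # RMR point not fitted
      rmr <- if (any(p$speed_pct_ucrit <= 5)) {
        p$mo2_umol_g_h[p$speed_pct_ucrit <= 5][1L]
      } else NA_real_
      per_fish[[id]] <- swim_fitness(fit_pts$speed_pct_ucrit,
                                     fit_pts$mo2_umol_g_h, uc[1L],
                                     standard_bl_cm = bl_of(id), rmr = rmr)
    }
    results$per_fish <- per_fish
    if (length(per_fish) >= 1L) {
      scalar <- do.call(rbind, lapply(names(per_fish), function(id) {
        f <- per_fish[[id]]
        data.frame(fish_id = id, ucrit_ms = f$ucrit_ms,
                   ucrit_bls = f$ucrit_bls, smr = f$smr, rmr = f$rmr,
                   vo2max = f$vo2max, uopt_pct = f$uopt_pct,
                   uopt_ms = f$uopt_ms, uopt_bls = f$uopt_bls,
                   cot_opt_curve = f$cot_opt_curve,
                   cot_opt_per_m = f$cot_opt_per_m, stringsAsFactors = FALSE)
      }))
      utils::write.csv(scalar, file.path(config$out_dir, "swim_fitness.csv"),
                       row.names = FALSE)
      results$fitness_table <- scalar
      if (nrow(scalar) >= 2L) {
        results$fitness_summary <- summarize_group(scalar)
      }
    }
    # pooled group-curve mode over all fish's points
    fit_pts <- results$points[results$points$speed_pct_ucrit > 5, ]
    if (length(unique(fit_pts$speed_pct_ucrit)) >= 3L) {
      gv <- fit_vo2_curve(fit_pts$speed_pct_ucrit, fit_pts$mo2_umol_g_h)
      gc <- fit_cot_curve(fit_pts$speed_pct_ucrit,
                          cot_from_vo2(fit_pts$mo2_umol_g_h,
                                       fit_pts$speed_pct_ucrit, "curve"))
      results$group_curves <- list(vo2 = gv, cot = gc,
                                   opt = find_uopt(gc))
    }
  }

  if (!is.null(cohort) &&
      all(c("swimmer", "rester") %in% cohort$group)) {
    gs <- list(
      baseline_tl = compare_growth(cohort, "total_tl_cm",
                                   "unpaired_t_two_tailed",
                                   groups = c("swimmer", "rester"),
                                   stage = "pre"),
      baseline_bw = compare_growth(cohort, "body_weight_g",
                                   "unpaired_t_two_tailed",
                                   groups = c("swimmer", "rester"),
                                   stage = "pre"),
      swimmer_tl = compare_growth(cohort, "total_tl_cm",
                                  "paired_t_one_tailed", group = "swimmer",
                                  alternative = "greater"),
      swimmer_bw = compare_growth(cohort, "body_weight_g",
                                  "paired_t_one_tailed", group = "swimmer",
                                  alternative = "greater"),
      rester_bw = compare_growth(cohort, "body_weight_g",
                                 "paired_t_one_tailed", group = "rester",
                                 alternative = "less"),
      post_tl = compare_growth(cohort, "total_tl_cm",
                               "unpaired_t_one_tailed",
                               groups = c("swimmer", "rester"),
                               stage = "post", alternative = "greater"),
      post_bw = compare_growth(cohort, "body_weight_g",
                               "unpaired_t_one_tailed",
                               groups = c("swimmer", "rester"),
                               stage = "post", alternative = "greater")
    )
    results$growth <- gs
    growth_df <- do.call(rbind, lapply(names(gs), function(nm) {
      g <- gs[[nm]]
      data.frame(comparison = nm, variable = g$variable, test = g$test,
                 mean_a = g$mean_a, sem_a = g$sem_a, mean_b = g$mean_b,
                 sem_b = g$sem_b, t = g$t, df = g$df, p_value = g$p_value,
                 percent_difference = g$percent_difference,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(growth_df, file.path(config$out_dir, "growth.csv"),
                     row.names = FALSE)
  }

  if (!is.null(config$ct)) {
    plates <- read_ct_csv(config$ct)
    results$qpcr <- qpcr_pipeline(plates,
                                  sd_threshold = config$ct_sd_threshold,
                                  max_removals = config$max_removals,
                                  alpha = config$outlier_alpha,
                                  efficiency = config$efficiency)
    utils::write.csv(results$qpcr$genes,
                     file.path(config$out_dir, "fold_changes.csv"),
                     row.names = FALSE)
  }

  write_pipeline_summary(results, config$out_dir)
  invisible(results)
}

# JSON + text summaries of all derived quantities
write_pipeline_summary <- function(results, out_dir) {
  js <- list(seed = results$seed)
  if (!is.null(results$fitness_summary)) {
    fs <- results$fitness_summary
    js$swim_fitness <- stats::setNames(
      lapply(seq_len(nrow(fs)),
             function(i) list(mean = fs$mean[i], sem = fs$sem[i], n = fs$n[i])),
      fs$variable)
  }
  if (!is.null(results$group_curves)) {
    g <- results$group_curves
    js$group_curves <- list(
      vo2 = list(smr = g$vo2$smr, a = g$vo2$a, b = g$vo2$b,
                 r_squared = g$vo2$r_squared),
      cot = list(a2 = g$cot$a2, b2 = g$cot$b2, c2 = g$cot$c2,
                 r_squared = g$cot$r_squared),
      uopt_pct = g$opt$uopt, cot_opt = g$opt$cot_opt)
  }
  if (!is.null(results$growth)) {
    js$growth <- lapply(results$growth, function(g) {
      list(variable = g$variable, test = g$test, mean_a = g$mean_a,
           mean_b = g$mean_b, t = g$t, p_value = g$p_value,
           percent_difference = g$percent_difference)
    })
  }
  if (!is.null(results$qpcr)) {
    js$qpcr <- list(
      genes = results$qpcr$genes,
      housekeeping_p = results$qpcr$housekeeping$p_value)
  }
  jsonlite::write_json(js, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  txt <- file.path(out_dir, "summary.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("swimfit pipeline summary (seed %d)", results$seed)
  if (!is.null(results$fitness_summary)) {
    w("\nSwimming economy (per-fish means +/- SEM, n = %d):",
      results$fitness_summary$n[1L])
    fs <- results$fitness_summary
    for (i in seq_len(nrow(fs))) {
      w("  %-14s %10.4g +/- %.3g", fs$variable[i], fs$mean[i], fs$sem[i])
    }
  }
  if (!is.null(results$group_curves)) {
    g <- results$group_curves
    w("\nPooled group curves (%%U_crit axis):")
    w("  VO2 = %.4g %+.4g*U^2 %+.4g*U (r2 = %.3f)",
      g$vo2$smr, g$vo2$a, g$vo2$b, g$vo2$r_squared)
    w("  COT = %.4g*U^2 %+.4g*U %+.4g (r2 = %.3f)",
      g$cot$a2, g$cot$b2, g$cot$c2, g$cot$r_squared)
    w("  U_opt = %.2f %%U_crit, COT_opt = %.2f", g$opt$uopt, g$opt$cot_opt)
  }
  if (!is.null(results$growth)) {
    w("\nGrowth comparisons:")
    for (nm in names(results$growth)) {
      g <- results$growth[[nm]]
      w("  %-12s %-14s t = %7.3f, p = %.3g, diff %+.1f%%",
        nm, g$variable, g$t, g$p_value, g$percent_difference)
    }
  }
  if (!is.null(results$qpcr)) {
    w("\nqPCR fold changes (swimmers over resters):")
    q <- results$qpcr$genes
    for (i in seq_len(nrow(q))) {
      w("  %-7s fc %5.2f +/- %4.2f  p = %.3g%s", q$gene[i],
        q$fold_change_mean[i], q$fold_change_sem[i], q$p_value[i],
        if (q$p_value[i] < 0.05) " *" else "")
    }
  }
  invisible(NULL)
}

#' Write a full synthetic input set
#'
#' Emits the exact CSV dialects the pipeline consumes (traces, trials,
#' cohort morphometrics for the individually tested fish and the training
#' cohorts, Ct plates) plus a `truth.json` sidecar recording every generator
#' parameter for recovery tests.
#'
#' @param truth A [synthetic_truth()].
#' @param dir Output directory (created if missing).
#' @param n_fish Individually tested fish (default 10).
#' @param n_swimmers,n_resters Training cohort sizes.
#' @param n_qpcr Fish per group on the Ct plates (default 8).
#' @param speeds Trace speeds, %U_crit (default the 5/25/50/75/100 protocol).
#' @param spec A [tunnel_spec()].
#' @return Named list of the file paths written.
#' @export
write_synthetic_inputs <- function(truth, dir, n_fish = 10, n_swimmers = 83,
                                   n_resters = 79, n_qpcr = 8,
                                   speeds = c(5, 25, 50, 75, 100),
                                   spec = tunnel_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("fish%02d", seq_len(n_fish))

  # individual fish morphometrics (group 'individual'), reference-like sizes
  ind <- do.call(rbind, lapply(ids, function(id) {
    set_stream_seed(truth$seed, paste0("ind/", id))
    bl <- stats::rnorm(1L, 3.05, 0.13)
    bw <- max(stats::rnorm(1L, 0.43, 0.09), 0.05)
    data.frame(fish_id = id, group = "individual", standard_bl_cm = bl,
               total_tl_cm = bl * 3.60 / 3.05, body_weight_g = bw,
               stage = "pre", stringsAsFactors = FALSE)
  }))
  cohort <- rbind(ind, simulate_cohort(truth, n_swimmers, n_resters))

  traces <- do.call(rbind, lapply(ids, function(id) {
    mass <- ind$body_weight_g[ind$fish_id == id]
    do.call(rbind, lapply(speeds, function(sp) {
      tr <- simulate_o2_trace(truth, body_mass = mass, speed_pct = sp,
                              duration = 1200, spec = spec, fish_id = id)
      data.frame(fish_id = id, time_s = tr$time_s, o2_pct_as = tr$oxygen,
                 phase = tr$phase, speed_pct_ucrit = sp,
                 stringsAsFactors = FALSE)
    }))
  }))

  trials <- do.call(rbind, lapply(ids, function(id) {
    simulate_ucrit_trial(truth, fish_id = id)
  }))

  plates <- simulate_ct_table(truth, n_per_group = n_qpcr)

  paths <- list(
    traces = file.path(dir, "traces.csv"),
    trials = file.path(dir, "trials.csv"),
    cohort = file.path(dir, "cohort.csv"),
    ct = file.path(dir, "ct_plates.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(traces, paths$traces, row.names = FALSE)
  utils::write.csv(trials, paths$trials, row.names = FALSE)
  utils::write.csv(cohort, paths$cohort, row.names = FALSE)
  utils::write.csv(plates, paths$ct, row.names = FALSE)
  jsonlite::write_json(unclass(truth), paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
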