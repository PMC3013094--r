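#' Ground truth for the synthetic-data generators
#'
#' Bundles every parameter the generators need, with defaults set to the
#' study conditions of the reference experiment so that a default synthetic
#' run reproduces the headline quantities: the group metabolic curve
#' (SMR 43.79 umol/g/h, a = 0.0081, b = -0.4353 on the %U_crit axis), a true
#' U_crit of 0.548 m/s, 2-s oxygen sampling, the swimmer/rester growth
#' effects (TL 3.59 -> 3.77 cm and BW 0.41 -> 0.51 g for swimmers; stable TL
#' and BW 0.42 -> 0.35 g for resters) and the per-gene true fold changes of
#' the muscle growth markers.
#'
#' @param seed Root integer seed. Per-fish random streams are derived from it
#'   by stable hashing of the fish id, so adding a fish never perturbs the
#'   data of the others.
#' @param smr,a,b Metabolic-curve parameters on the %U_crit axis.
#' @param true_ucrit True critical swimming speed, m/s.
#' @param trace_noise_sd Gaussian sensor noise on oxygen readings, %AS.
#' @param sample_interval Oxygen sampling interval, s.
#' @param cohort Named list of group growth effects: per-group baseline mean/
#'   SD for TL (cm) and BW (g) and mean/SD of the pre-to-post change.
#' @param true_fold_changes Named numeric vector of true swimmer-over-rester
#'   fold changes per target gene (genes absent from the map default to 1 in
#'   [simulate_ct_table()]).
#' @param ct_noise_sd Replicate Ct noise SD, cycles.
#' @param housekeeping_ct Mean rps18 Ct, cycles (stable across groups).
#' @param baseline_dct Rester-group dCt baseline (target minus rps18),
#'   cycles; single value or named per-gene vector.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(seed = 1L,
                            smr = 43.79, a = 0.0081, b = -0.4353,
                            true_ucrit = 0.548,
                            trace_noise_sd = 0.5,
                            sample_interval = 2,
                            cohort = list(
                              swimmer = list(tl_mean = 3.59, tl_sd = 0.18,
                                             bw_mean = 0.41, bw_sd = 0.09,
                                             d_tl_mean = 0.18, d_tl_sd = 0.05,
                                             d_bw_mean = 0.10, d_bw_sd = 0.03),
                              rester = list(tl_mean = 3.60, tl_sd = 0.18,
                                            bw_mean = 0.42, bw_sd = 0.09,
                                            d_tl_mean = 0.00, d_tl_sd = 0.05,
                                            d_bw_mean = -0.07, d_bw_sd = 0.03)
                            ),
                            true_fold_changes = c(
                              ghra = 1, ghrb = 0.58, igf1ra = 0.53,
                              igf1rb = 1, igf1 = 1, ztor = 1, foxo5 = 1,
                              pgc1a = 1, stnnc = 3.47, smyhc1 = 3.60,
                              tnni2 = 3.42, myhz2 = 7.92, mstnb = 5.44,
                              myog = 1),
                            ct_noise_sd = 0.2,
                            housekeeping_ct = 18,
                            baseline_dct = 8) {
  stopifnot(trace_noise_sd >= 0, ct_noise_sd >= 0, sample_interval > 0,
            true_ucrit > 0)
  if (any(true_fold_changes <= 0)) {
    stop("true fold changes must be positive", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), smr = smr, a = a, b = b,
         true_ucrit = true_ucrit, trace_noise_sd = trace_noise_sd,
         sample_interval = sample_interval, cohort = cohort,
         true_fold_changes = true_fold_changes, ct_noise_sd = ct_noise_sd,
         housekeeping_ct = housekeeping_ct, baseline_dct = baseline_dct),
    class = "synthetic_truth"
  )
}

# stable 31-bit string hash; deterministic across sessions/platforms
stable_hash <- function(x) {
  h <- 0
  for (code in utf8ToInt(as.character(x))) {
    h <- (h * 31 + code) %% 2147483647
  }
  h
}

# derive and set a per-stream seed from the root seed and a label
set_stream_seed <- function(root_seed, label) {
  s <- (as.numeric(root_seed) * 48271 + stable_hash(label)) %% 2147483647
  set.seed(as.integer(s))
}

#' True metabolic rate of the synthetic fish at a given speed
#' @param truth A [synthetic_truth()].
#' @param speed_pct Speed, %U_crit.
#' @return MO2 in umol g^-1 h^-1.
#' @export
true_mo2 <- function(truth, speed_pct) {
  truth$smr + truth$a * speed_pct^2 + truth$b * speed_pct
}

#' Simulate a closed-phase oxygen trace
#'
#' Dissolved O2 starts at 100 %AS at tunnel closure and declines linearly at
#' the rate implied by the fish's true metabolic rate at the given speed
#' (`rate = MO2 * mass / volume` umol/L/h), sampled every
#' `truth$sample_interval` seconds with i.i.d. Gaussian sensor noise.
#' Readings that would fall below 0 %AS are truncated with a warning.
#'
#' @param truth A [synthetic_truth()].
#' @param body_mass Fish body mass, g.
#' @param speed_pct Swimming speed, %U_crit.
#' @param duration Closed-phase duration, s (must exceed two sampling
#'   intervals; the protocol default is a 20-min step).
#' @param spec A [tunnel_spec()].
#' @param fish_id Fish identifier (seeds the noise stream).
#' @return An [oxygen_trace()].
#' @export
simulate_o2_trace <- function(truth, body_mass = 0.43, speed_pct = 50,
                              duration = 1200, spec = tunnel_spec(),
                              fish_id = "fish01") {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(spec, "tunnel_spec"))
  if (duration <= 2 * truth$sample_interval) {
    stop("duration must exceed two sampling intervals", call. = FALSE)
  }
  sat <- o2_saturation(spec$temperature, spec$salinity,
                       spec$barometric_pressure)
  rate <- true_mo2(truth, speed_pct) * body_mass / spec$volume  # umol/L/h
  t_s <- seq(0, duration, by = truth$sample_interval)
  conc <- sat - rate * t_s / 3600
  pct <- conc / sat * 100
  set_stream_seed(truth$seed, paste0("trace/", fish_id, "/", speed_pct))
  if (truth$trace_noise_sd > 0) {
    pct <- pct + stats::rnorm(length(pct), 0, truth$trace_noise_sd)
  }
  if (any(pct < 0)) {
    warning("trace truncated at 0 %AS (fish would deplete the tunnel)",
            call. = FALSE)
    pct <- pmax(pct, 0)
  }
  oxygen_trace(t_s, pct, phase = "closed", fish_id = fish_id,
               speed_pct_ucrit = speed_pct)
}

#' Simulate an incremental-velocity fatigue trial
#'
#' The synthetic fish completes every interval whose speed does not exceed
#' its true U_crit; in the first exceeding interval it fatigues at
#' `t_i = t_ii * (true_ucrit - u_i) / u_ii`, so that the Brett interpolation
#' recovers the true U_crit exactly in the noiseless case. Optional Gaussian
#' jitter on the fatigue time emulates behavioural variability. The protocol
#' is repeated for `n_events` fatigue events (the reference protocol fatigues
#' each fish three times).
#'
#' @param truth A [synthetic_truth()].
#' @param fish_id Fish identifier.
#' @param protocol List with `start` (first speed, m/s), `u_ii` (increment,
#'   m/s) and `t_ii` (interval length, s); defaults 0.05 / 0.05 / 600.
#' @param jitter_sd SD of Gaussian jitter on the fatigue time, s (default 0).
#' @param n_events Number of repeated fatigue events (default 3).
#' @return Data frame in the trial-CSV dialect:
#'   `fish_id,u_i_ms,u_ii_ms,t_i_s,t_ii_s,fatigue_index`.
#' @export
simulate_ucrit_trial <- function(truth, fish_id = "fish01",
                                 protocol = list(start = 0.05, u_ii = 0.05,
                                                 t_ii = 600),
                                 jitter_sd = 0, n_events = 3) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (protocol$start >= truth$true_ucrit) {
    stop("degenerate protocol: start speed at or above the true U_crit",
         call. = FALSE)
  }
  set_stream_seed(truth$seed, paste0("trial/", fish_id))
  # highest protocol speed fully sustainable
  n_full <- floor((truth$true_ucrit - protocol$start) / protocol$u_ii + 1e-9)
  u_i <- protocol$start + n_full * protocol$u_ii
  if (u_i > truth$true_ucrit) u_i <- u_i - protocol$u_ii
  rows <- lapply(seq_len(n_events), function(k) {
    u_k <- u_i
    t_i <- protocol$t_ii * (truth$true_ucrit - u_k) / protocol$u_ii
    if (jitter_sd > 0) {
      t_i <- t_i + stats::rnorm(1L, 0, jitter_sd)
      # jitter may push fatigue into the neighbouring interval
      while (t_i > protocol$t_ii) {
        u_k <- u_k + protocol$u_ii
        t_i <- t_i - protocol$t_ii
      }
      while (t_i < 0 && u_k > protocol$start) {
        u_k <- u_k - protocol$u_ii
        t_i <- t_i + protocol$t_ii
      }
      t_i <- min(max(t_i, 0), protocol$t_ii)
    }
    data.frame(fish_id = fish_id, u_i_ms = u_k, u_ii_ms = protocol$u_ii,
               t_i_s = t_i, t_ii_s = protocol$t_ii, fatigue_index = k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a pre/post growth cohort
#'
#' Gaussian individual baselines per group, plus group-specific pre-to-post
#' change distributions, with the paired structure preserved through
#' `fish_id`. Standard BL is derived from TL by the ratio of the reference
#' morphometrics (3.05 cm BL at ~3.60 cm TL).
#'
#' @param truth A [synthetic_truth()].
#' @param n_swimmers,n_resters Group sizes (defaults 83 and 79, the surviving
#'   cohort sizes of the reference experiment).
#' @return Data frame in the cohort-CSV dialect:
#'   `fish_id,group,standard_bl_cm,total_tl_cm,body_weight_g,stage`.
#' @export
simulate_cohort <- function(truth, n_swimmers = 83, n_resters = 79) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_swimmers < 2L || n_resters < 2L) {
    stop("need at least 2 fish per group", call. = FALSE)
  }
  bl_tl_ratio <- 3.05 / 3.60
  one_group <- function(group, n) {
    p <- truth$cohort[[group]]
    rows <- lapply(seq_len(n), function(i) {
      id <- sprintf("%s%03d", substr(group, 1L, 2L), i)
      set_stream_seed(truth$seed, paste0("cohort/", id))
      tl0 <- stats::rnorm(1L, p$tl_mean, p$tl_sd)
      bw0 <- max(stats::rnorm(1L, p$bw_mean, p$bw_sd), 0.05)
      tl1 <- tl0 + stats::rnorm(1L, p$d_tl_mean, p$d_tl_sd)
      bw1 <- max(bw0 + stats::rnorm(1L, p$d_bw_mean, p$d_bw_sd), 0.05)
      data.frame(fish_id = id, group = group,
                 standard_bl_cm = c(tl0, tl1) * bl_tl_ratio,
                 total_tl_cm = c(tl0, tl1),
                 body_weight_g = c(bw0, bw1),
                 stage = c("pre", "post"), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- rbind(one_group("swimmer", n_swimmers),
               one_group("rester", n_resters))
  rownames(out) <- NULL
  out
}

#' Simulate triplicate qPCR Ct plates
#'
#' Each rester carries the per-gene baseline dCt; each swimmer's dCt is the
#' baseline minus log2 of the gene's true fold change. Triplicate wells add
#' i.i.d. Gaussian Ct noise; the housekeeping gene rps18 is stable across
#' groups (same mean Ct) and is emitted once per fish per primer set used.
#'
#' @param truth A [synthetic_truth()].
#' @param n_per_group Fish per group (default 8).
#' @param genes Target genes to simulate (default: all genes in the truth's
#'   fold-change map). Must be a subset of the assay vocabulary.
#' @return Data frame in the Ct-CSV dialect:
#'   `fish_id,group,gene,primer_set,rep1_ct,rep2_ct,rep3_ct,dilution`.
#' @export
simulate_ct_table <- function(truth, n_per_group = 8,
                              genes = names(truth$true_fold_changes)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  vocab <- qpcr_gene_table()
  unknown <- setdiff(genes, vocab$gene)
  if (length(unknown)) {
    stop("unknown gene(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  genes <- setdiff(genes, "rps18")
  sets_needed <- unique(vocab$primer_set[vocab$gene %in% genes])
  base_dct <- function(g) {
    if (length(truth$baseline_dct) > 1L) truth$baseline_dct[[g]]
    else truth$baseline_dct
  }
  rows <- list()
  for (group in c("swimmer", "rester")) {
    for (i in seq_len(n_per_group)) {
      id <- sprintf("q_%s%02d", substr(group, 1L, 2L), i)
      set_stream_seed(truth$seed, paste0("ct/", id))
      for (ps in sets_needed) {
        rows[[length(rows) + 1L]] <- data.frame(
          fish_id = id, group = group, gene = "rps18", primer_set = ps,
          rep1_ct = truth$housekeeping_ct + stats::rnorm(1L, 0, truth$ct_noise_sd),
          rep2_ct = truth$housekeeping_ct + stats::rnorm(1L, 0, truth$ct_noise_sd),
          rep3_ct = truth$housekeeping_ct + stats::rnorm(1L, 0, truth$ct_noise_sd),
          dilution = 25, stringsAsFactors = FALSE)
      }
      for (g in genes) {
        fc <- if (g %in% names(truth$true_fold_changes)) {
          truth$true_fold_changes[[g]]
        } else 1
        dct <- base_dct(g) - if (group == "swimmer") log2(fc) else 0
        mu <- truth$housekeeping_ct + dct
        rows[[length(rows) + 1L]] <- data.frame(
          fish_id = id, group = group, gene = g,
          primer_set = vocab$primer_set[match(g, vocab$gene)],
          rep1_ct = mu + stats::rnorm(1L, 0, truth$ct_noise_sd),
          rep2_ct = mu + stats::rnorm(1L, 0, truth$ct_noise_sd),
          rep3_ct = mu + stats::rnorm(1L, 0, truth$ct_noise_sd),
          dilution = 10, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
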