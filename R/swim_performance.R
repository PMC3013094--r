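#' Critical swimming speed from an incremental-velocity trial
#'
#' Brett interpolation for the stepped-velocity fatigue protocol:
#' `U_crit = u_i + (t_i / t_ii) * u_ii`, where `u_i` is the highest velocity
#' maintained for a whole interval, `u_ii` the velocity increment (protocol
#' default 0.05 m/s), `t_i` the time swum into the fatigue interval and
#' `t_ii` the full interval length (protocol default 600 s).
#'
#' @param u_i Highest fully maintained velocity, m/s (>= 0).
#' @param u_ii Velocity increment, m/s (> 0).
#' @param t_i Time elapsed in the fatigue interval, s; `0 <= t_i <= t_ii`.
#' @param t_ii Interval length, s (> 0).
#' @return U_crit in m/s, bounded in `[u_i, u_i + u_ii]`. Vectorised.
#' @examples
#' compute_ucrit(u_i = 0.50, u_ii = 0.05, t_i = 300, t_ii = 600)  # 0.525
#' @export
compute_ucrit <- function(u_i, u_ii, t_i, t_ii) {
  if (any(u_ii <= 0) || any(t_ii <= 0)) {
    stop("'u_ii' and 't_ii' must be positive", call. = FALSE)
  }
  if (any(u_i < 0) || any(t_i < 0)) {
    stop("'u_i' and 't_i' must be non-negative", call. = FALSE)
  }
  if (any(t_i > t_ii)) {
    stop("protocol error: t_i exceeds the interval length t_ii", call. = FALSE)
  }
  u_i + (t_i / t_ii) * u_ii
}

#' U_crit for each fish in a trial table
#'
#' The protocol fatigues each fish repeatedly (three fatigue events per fish
#' in the reference protocol). `event = "first"` (default) uses the first
#' fatigue event per fish; `event = "mean"` averages the Brett estimate over
#' all recorded events.
#'
#' @param trials Data frame with columns
#'   `fish_id,u_i_ms,u_ii_ms,t_i_s,t_ii_s,fatigue_index`.
#' @param event `"first"` or `"mean"`.
#' @return Data frame with `fish_id` and `ucrit_ms`.
#' @export
ucrit_from_trials <- function(trials, event = c("first", "mean")) {
  event <- match.arg(event)
  required <- c("fish_id", "u_i_ms", "u_ii_ms", "t_i_s", "t_ii_s")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stop("trial table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  per_event <- compute_ucrit(trials$u_i_ms, trials$u_ii_ms,
                             trials$t_i_s, trials$t_ii_s)
  out <- lapply(split(seq_len(nrow(trials)), trials$fish_id), function(idx) {
    if (event == "first") {
      if ("fatigue_index" %in% names(trials)) {
        idx <- idx[order(trials$fatigue_index[idx])]
      }
      per_event[idx[1L]]
    } else {
      mean(per_event[idx])
    }
  })
  data.frame(fish_id = names(out), ucrit_ms = unname(unlist(out)),
             stringsAsFactors = FALSE)
}

#' Convert an absolute speed to body lengths per second
#'
#' Relative swimming speeds use the standard body length (BL, snout to caudal
#' peduncle), not total length, following the convention for swimming-fitness
#' reporting.
#'
#' @param speed_ms Speed in m/s.
#' @param standard_bl_cm Standard body length, cm (> 0).
#' @return Speed in standard body lengths per second (BL/s).
#' @examples
#' to_relative_speed(0.548, 3.05)  # ~18.0 BL/s
#' @export
to_relative_speed <- function(speed_ms, standard_bl_cm) {
  if (any(!is.finite(standard_bl_cm)) || any(standard_bl_cm <= 0)) {
    stop("standard body length missing or non-positive", call. = FALSE)
  }
  speed_ms / (standard_bl_cm / 100)
}

#' Convert a relative speed (BL/s) back to m/s
#'
#' Exact inverse of [to_relative_speed()].
#' @param speed_bls Speed in standard body lengths per second.
#' @inheritParams to_relative_speed
#' @return Speed in m/s.
#' @export
from_relative_speed <- function(speed_bls, standard_bl_cm) {
  if (any(!is.finite(standard_bl_cm)) || any(standard_bl_cm <= 0)) {
    stop("standard body length missing or non-positive", call. = FALSE)
  }
  speed_bls * (standard_bl_cm / 100)
}

#' Read the incremental-velocity trial CSV
#'
#' Dialect: `fish_id,u_i_ms,u_ii_ms,t_i_s,t_ii_s,fatigue_index`.
#' @param path Path to the CSV.
#' @return Data frame.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("fish_id", "u_i_ms", "u_ii_ms", "t_i_s", "t_ii_s")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("trial CSV ", path, " missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read the cohort morphometrics CSV
#'
#' Dialect: `fish_id,group,standard_bl_cm,total_tl_cm,body_weight_g,stage`
#' with `group` in `swimmer|rester|individual` and `stage` in `pre|post`.
#' @param path Path to the CSV.
#' @return Data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("fish_id", "group", "standard_bl_cm", "total_tl_cm",
                "body_weight_g", "stage")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cohort CSV ", path, " missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- !df$stage %in% c("pre", "post")
  if (any(bad)) {
    stop("cohort CSV ", path, ": invalid stage value(s) ",
         paste(unique(df$stage[bad]), collapse = ", "), call. = FALSE)
  }
  df
}
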