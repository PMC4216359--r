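#' Net fluid balance over one recording interval
#'
#' Fluid added (continuous crystalloid infusion plus replacement fluid given
#' for blood losses) minus fluid lost (urine plus whole blood lost) over one
#' interval of the measurement grid. The rate is normalised to body weight and
#' interval length.
#'
#' @param infusion_ml,replacement_ml fluid added during the interval, ml.
#' @param urine_ml,blood_loss_ml fluid lost during the interval, ml.
#' @param weight_kg body weight, kg.
#' @param dt_min interval length, min (30 on the standard grid).
#' @return `data.frame` with `nfb_ml` and `nfb_rate` (ml/kg/min).
#' @export
#' @examples
#' net_fluid_balance(210, 30, 60, 10, weight_kg = 42) # NFB 170 ml
net_fluid_balance <- function(infusion_ml, replacement_ml, urine_ml,
                              blood_loss_ml, weight_kg, dt_min = 30) {
  vols <- c(infusion_ml, replacement_ml, urine_ml, blood_loss_ml)
  stop_unless(is.numeric(vols) && all(is.finite(vols)) && all(vols >= 0),
              "all recorded volumes must be non-negative")
  stop_unless(is_number(weight_kg) && weight_kg > 0, "weight_kg must be positive")
  stop_unless(is_number(dt_min) && dt_min > 0, "dt_min must be positive")
  nfb <- (infusion_ml + replacement_ml) - (urine_ml + blood_loss_ml)
  data.frame(nfb_ml = nfb, nfb_rate = nfb / weight_kg / dt_min)
}

#' Fluid extravasation over one interval
#'
#' The central statistic of the analysis: fluid extravasation is net fluid
#' balance minus the change in plasma volume over the same interval,
#' `FE = NFB - dPV`. Positive FE is net fluid loss from plasma to the
#' interstitium; negative FE is net absorption and is returned unchanged.
#' The fluid extravasation rate FER is FE per kg body weight per minute.
#'
#' @param nfb_ml net fluid balance over the interval, ml.
#' @param pv_start,pv_end plasma volume at the interval endpoints, ml (> 0).
#' @param weight_kg body weight, kg.
#' @param dt_min interval length, min.
#' @return `data.frame` with `nfb_ml`, `dpv_ml`, `fe_ml` and `fer` (ml/kg/min).
#' @export
#' @examples
#' fluid_extravasation(239.4, 2558, 2457.2, weight_kg = 42, dt_min = 30)
fluid_extravasation <- function(nfb_ml, pv_start, pv_end, weight_kg,
                                dt_min = 30) {
  stop_unless(is.numeric(nfb_ml) && all(is.finite(nfb_ml)), "nfb_ml must be numeric")
  stop_unless(all(pv_start > 0) && all(pv_end > 0),
              "plasma volumes must be positive")
  stop_unless(is_number(weight_kg) && weight_kg > 0, "weight_kg must be positive")
  stop_unless(is_number(dt_min) && dt_min > 0, "dt_min must be positive")
  dpv <- pv_end - pv_start
  fe <- nfb_ml - dpv
  data.frame(nfb_ml = nfb_ml, dpv_ml = dpv, fe_ml = fe,
             fer = fe / weight_kg / dt_min)
}

#' Per-interval fluid balance and extravasation for one animal
#'
#' Walks the 30-min grid of one animal. By the recording convention, the row at
#' time `t` carries the fluid volumes accumulated over the interval
#' `(t - 30, t]`, so the first grid row contributes no interval. Plasma volume
#' at interval endpoints comes from the tracer-dilution volume series.
#'
#' @param tp `data.frame` of one animal's timepoints, ascending in `time`, with
#'   columns `time`, `infusion_ml`, `replacement_ml`, `urine_ml`,
#'   `blood_loss_ml`.
#' @param vs volume series for the same grid from [volume_series()] (columns
#'   `time`, `pv`).
#' @param weight_kg body weight, kg.
#' @param count_blood_loss whether measured blood loss enters the "lost" side
#'   of the NFB ledger (default) or only urine does; the source protocol is
#'   ambiguous on this ledger convention, so it is configurable.
#' @return `data.frame` with one row per interval: `t_start`, `t_end`, `t_mid`,
#'   `added_ml`, `lost_ml`, `nfb_ml`, `nfb_rate`, `dpv_ml`, `fe_ml`, `fer`.
#' @export
interval_balances <- function(tp, vs, weight_kg, count_blood_loss = TRUE) {
  stop_unless(all(c("time", "infusion_ml", "replacement_ml", "urine_ml",
                    "blood_loss_ml") %in% names(tp)),
              "tp is missing required fluid-ledger columns")
  stop_unless(!is.unsorted(tp$time, strictly = TRUE), "tp times must be ascending")
  stop_unless(identical(as.numeric(tp$time), as.numeric(vs$time)),
              "timepoint grid and volume-series grid differ")
  n <- nrow(tp)
  stop_unless(n >= 2, "need at least two grid points to form an interval")
  i <- 2:n
  bl <- if (count_blood_loss) tp$blood_loss_ml[i] else 0 * i
  nfb <- net_fluid_balance(tp$infusion_ml[i], tp$replacement_ml[i],
                           tp$urine_ml[i], bl,
                           weight_kg, dt_min = diff(tp$time)[1])
  fe <- fluid_extravasation(nfb$nfb_ml, vs$pv[i - 1], vs$pv[i], weight_kg,
                            dt_min = diff(tp$time)[1])
  data.frame(
    t_start = tp$time[i - 1], t_end = tp$time[i],
    t_mid = (tp$time[i - 1] + tp$time[i]) / 2,
    added_ml = tp$infusion_ml[i] + tp$replacement_ml[i],
    lost_ml = tp$urine_ml[i] + bl,
    nfb_ml = nfb$nfb_ml, nfb_rate = nfb$nfb_rate,
    dpv_ml = fe$dpv_ml, fe_ml = fe$fe_ml, fer = fe$fer,
    row.names = NULL
  )
}

#' Standard analysis windows
#'
#' Baseline (stabilisation, -60 to 0 min), early intervention (0-120 min) and
#' late intervention (120-240 min). Windows are half-open `(start, end]`.
#'
#' @return `data.frame` with columns `window`, `t_start`, `t_end`.
#' @export
analysis_windows <- function() {
  data.frame(window = c("baseline", "early", "late"),
             t_start = c(-60, 0, 120), t_end = c(0, 120, 240))
}

#' Average a series over an analysis window
#'
#' Means of the values whose time stamp falls in the half-open window
#' `(t_start, t_end]`. For interval-level series pass the interval midpoints as
#' `time`; for point series pass the grid times.
#'
#' @param time time stamps, min.
#' @param value values to average.
#' @param windows window table as from [analysis_windows()].
#' @return `data.frame` with `window`, `mean`, `n` (values averaged).
#' @export
#' @examples
#' window_average(c(135, 165, 195, 225), c(0.1, 0.2, 0.3, 0.4))
window_average <- function(time, value, windows = analysis_windows()) {
  stop_unless(length(time) == length(value), "time and value lengths differ")
  out <- lapply(seq_len(nrow(windows)), function(k) {
    inw <- time > windows$t_start[k] & time <= windows$t_end[k] & !is.na(value)
    if (!any(inw)) {
      stop("window '", windows$window[k], "' contains no values", call. = FALSE)
    }
    data.frame(window = windows$window[k], mean = mean(value[inw]),
               n = sum(inw))
  })
  do.call(rbind, out)
}

#' Group-level window summary
#'
#' Per-animal window means first, then group mean and SD of the per-animal
#' means — the convention in which the study's windowed group values are
#' reported.
#'
#' @param data long `data.frame` with columns `animal_id`, `group`, a time
#'   column and a value column.
#' @param value name of the value column.
#' @param time name of the time column (grid time or interval midpoint).
#' @param windows window table, see [analysis_windows()].
#' @return `data.frame` with `group`, `window`, `mean`, `sd`, `n` (animals).
#' @export
window_summary <- function(data, value, time = "time",
                           windows = analysis_windows()) {
  stop_unless(all(c("animal_id", "group", time, value) %in% names(data)),
              "data is missing required columns")
  per_animal <- do.call(rbind, lapply(split(data, data[c("animal_id", "group")],
                                            drop = TRUE), function(d) {
    wa <- window_average(d[[time]], d[[value]], windows)
    data.frame(animal_id = d$animal_id[1], group = d$group[1],
               window = wa$window, value = wa$mean)
  }))
  agg <- do.call(rbind, lapply(split(per_animal,
                                     per_animal[c("group", "window")],
                                     drop = TRUE), function(d) {
    data.frame(group = d$group[1], window = d$window[1],
               mean = mean(d$value), sd = stats::sd(d$value), n = nrow(d))
  }))
  agg <- agg[order(agg$group, match(agg$window, windows$window)), ]
  rownames(agg) <- NULL
  agg
}
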