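#' Write a dataset to CSV files
#'
#' Writes the four experiment tables (and, when present, the simulation truth
#' tables) in the documented external schemas. Fractions are written as
#' percent (`hct_pct`, `cohb_*_pct`); times as `time_min`.
#'
#' @param dataset a dataset list as returned by [simulate_cohort()] or
#'   [read_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tp <- dataset$timepoints
  tp_out <- data.frame(
    animal_id = tp$animal_id, group = tp$group, time_min = tp$time,
    hct_pct = tp$hct * 100, tp[, c("hb_g_dl", "s_protein_g_l",
                                   "s_albumin_g_l", "map", "mpap", "pcwp",
                                   "cvp_ra", "cvp_fv", "iap", "icp",
                                   "co_l_min", "urine_ml", "infusion_ml",
                                   "replacement_ml", "blood_loss_ml",
                                   "weight_kg")])
  utils::write.csv(tp_out, file.path(dir, "timepoints.csv"),
                   row.names = FALSE)
  cd <- dataset$co_dilution
  cd_out <- data.frame(animal_id = cd$animal_id, co_dose_ml = cd$co_dose_ml,
                       cohb_pre_pct = cd$cohb_pre * 100,
                       cohb_post_pct = cd$cohb_post * 100,
                       cthb_g_l = cd$cthb_g_l, hct_pct = cd$hct * 100)
  utils::write.csv(cd_out, file.path(dir, "co_dilution.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$microspheres, file.path(dir, "microspheres.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$tissue_water, file.path(dir, "tissue_water.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$truth_points)) {
    utils::write.csv(dataset$truth_points, file.path(dir, "truth_points.csv"),
                     row.names = FALSE)
    utils::write.csv(dataset$truth_intervals,
                     file.path(dir, "truth_intervals.csv"), row.names = FALSE)
  }
  invisible(dir)
}

required_tp_cols <- c("animal_id", "group", "time_min", "hct_pct", "hb_g_dl",
                      "s_protein_g_l", "s_albumin_g_l", "map", "mpap", "pcwp",
                      "cvp_ra", "cvp_fv", "iap", "icp", "co_l_min",
                      "urine_ml", "infusion_ml", "replacement_ml",
                      "blood_loss_ml", "weight_kg")

check_range <- function(x, lo, hi, col, file) {
  bad <- which(!is.na(x) & (x <= lo | x >= hi))
  if (length(bad)) {
    stop(sprintf("%s: column %s out of range (%g, %g) at row(s) %s", file,
                 col, lo, hi, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
}

check_nonneg <- function(x, col, file) {
  bad <- which(!is.na(x) & x < 0)
  if (length(bad)) {
    stop(sprintf("%s: column %s has negative value(s) at row(s) %s", file,
                 col, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
}

#' Read and validate a dataset from CSV files
#'
#' Reads `timepoints.csv`, `co_dilution.csv`, `microspheres.csv` and
#' `tissue_water.csv` (plus truth tables when present) from a directory,
#' checks the documented schemas — required columns, percentage and volume
#' ranges, duplicate animal-by-time records — reporting offending rows, and
#' converts external units to the internal conventions (percent to fraction,
#' `time_min` to `time`).
#'
#' @param dir directory containing the CSV files.
#' @return Dataset list of class `iah_dataset`.
#' @export
read_dataset <- function(dir) {
  path <- function(f) file.path(dir, f)
  need <- c("timepoints.csv", "co_dilution.csv")
  for (f in need) {
    stop_unless(file.exists(path(f)), "missing input file: ", path(f))
  }
  tp_raw <- utils::read.csv(path("timepoints.csv"))
  miss <- setdiff(required_tp_cols, names(tp_raw))
  if (length(miss)) {
    stop("timepoints.csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_range(tp_raw$hct_pct, 0, 100, "hct_pct", "timepoints.csv")
  for (cn in c("urine_ml", "infusion_ml", "replacement_ml", "blood_loss_ml")) {
    check_nonneg(tp_raw[[cn]], cn, "timepoints.csv")
  }
  dup <- duplicated(tp_raw[, c("animal_id", "time_min")])
  if (any(dup)) {
    stop("timepoints.csv: duplicate animal_id x time_min at row(s) ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  tp <- tp_raw
  tp$time <- tp$time_min
  tp$hct <- tp$hct_pct / 100
  tp$time_min <- NULL
  tp$hct_pct <- NULL

  cd_raw <- utils::read.csv(path("co_dilution.csv"))
  cd_need <- c("animal_id", "co_dose_ml", "cohb_pre_pct", "cohb_post_pct",
               "cthb_g_l", "hct_pct")
  miss <- setdiff(cd_need, names(cd_raw))
  if (length(miss)) {
    stop("co_dilution.csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_range(cd_raw$hct_pct, 0, 100, "hct_pct", "co_dilution.csv")
  cd <- data.frame(animal_id = cd_raw$animal_id,
                   co_dose_ml = cd_raw$co_dose_ml,
                   cohb_pre = cd_raw$cohb_pre_pct / 100,
                   cohb_post = cd_raw$cohb_post_pct / 100,
                   cthb_g_l = cd_raw$cthb_g_l, hct = cd_raw$hct_pct / 100)

  ms <- if (file.exists(path("microspheres.csv"))) {
    utils::read.csv(path("microspheres.csv"))
  }
  tw <- if (file.exists(path("tissue_water.csv"))) {
    utils::read.csv(path("tissue_water.csv"))
  }
  tpt <- if (file.exists(path("truth_points.csv"))) {
    utils::read.csv(path("truth_points.csv"))
  }
  tin <- if (file.exists(path("truth_intervals.csv"))) {
    utils::read.csv(path("truth_intervals.csv"))
  }
  out <- list(timepoints = tp, co_dilution = cd, microspheres = ms,
              tissue_water = tw, truth_points = tpt, truth_intervals = tin)
  class(out) <- c("iah_dataset", "list")
  out
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[iahfluid] ", fmt), ...))
}

#' Per-animal volume and balance tables
#'
#' For each animal: baseline red-cell volume from its CO-dilution record,
#' red-cell propagation through the blood-loss ledger, plasma volume from
#' hematocrit, and the per-interval NFB / dPV / FE / FER bookkeeping.
#'
#' @param dataset an `iah_dataset`.
#' @param hufner CO binding capacity used for the tracer estimate.
#' @param count_blood_loss see [interval_balances()].
#' @return List with `volumes` (per animal x grid time) and `intervals`
#'   (per animal x 30-min interval), both carrying `animal_id` and `group`.
#' @export
animal_volumes <- function(dataset, hufner = 1.39, count_blood_loss = TRUE) {
  tp_all <- dataset$timepoints
  cd <- dataset$co_dilution
  vol_list <- list(); int_list <- list()
  for (id in unique(tp_all$animal_id)) {
    tp <- tp_all[tp_all$animal_id == id, ]
    tp <- tp[order(tp$time), ]
    cdr <- cd[cd$animal_id == id, ]
    stop_unless(nrow(cdr) == 1, "need exactly one CO-dilution record for ",
                "animal ", id)
    rec <- co_dilution_record(cdr$co_dose_ml, cdr$cohb_pre, cdr$cohb_post,
                              cdr$cthb_g_l, cdr$hct)
    vrbc0 <- estimate_vrbc_co(rec, hufner)
    hct_filled <- fill_hct(tp$time, tp$hct)
    ev <- tp[tp$blood_loss_ml > 0,
             c("time", "blood_loss_ml")]
    events <- if (nrow(ev)) {
      data.frame(time = ev$time, volume = ev$blood_loss_ml,
                 hct = hct_filled[match(ev$time, tp$time)])
    }
    w <- tp$weight_kg[1]
    vs <- volume_series(vrbc0, tp$time, hct_filled, events, w)
    vs$animal_id <- id
    vs$group <- tp$group[1]
    ib <- interval_balances(tp, vs, w, count_blood_loss)
    ib$animal_id <- id
    ib$group <- tp$group[1]
    ib$weight_kg <- w
    vol_list[[id]] <- vs
    int_list[[id]] <- ib
  }
  list(volumes = do.call(rbind, c(vol_list, make.row.names = FALSE)),
       intervals = do.call(rbind, c(int_list, make.row.names = FALSE)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage over a validated dataset: tracer-dilution volume
#' series and interval balances per animal; group window summaries of
#' hematocrit, plasma volume, NFB rate and FER (the study's windowed
#' surface); derived hemodynamics; albumin and protein masses; microsphere
#' regional flows with the kidney percent-reduction statistic; tissue-water
#' summaries; and split-plot repeated-measures ANOVA with the post-hoc
#' battery for the windowed fluid variables and (when recorded) the
#' hemodynamic variables.
#'
#' @param dataset an `iah_dataset` from [read_dataset()] or
#'   [simulate_cohort()].
#' @param hufner CO binding capacity used for the tracer estimate.
#' @param verbose log each stage with input/output counts to stderr.
#' @return Named list of report tables; see Details in the package vignette.
#' @export
run_pipeline <- function(dataset, hufner = 1.39, verbose = TRUE) {
  tp <- dataset$timepoints
  n_animals <- length(unique(tp$animal_id))
  log_stage(verbose, "volumes: %d animals, %d timepoint rows", n_animals,
            nrow(tp))
  av <- animal_volumes(dataset, hufner)
  volumes <- av$volumes
  intervals <- av$intervals
  log_stage(verbose, "balance: %d intervals", nrow(intervals))

  # windowed group surface: Hct, PV, NFB, FER by analysis window
  win_fluid <- rbind(
    cbind(variable = "hct_pct",
          window_summary(transform(volumes, value = hct * 100), "value")),
    cbind(variable = "pv_ml_kg",
          window_summary(transform(volumes, value = pv_per_kg), "value")),
    cbind(variable = "nfb_ml_kg_min",
          window_summary(transform(intervals, value = nfb_rate,
                                   time = t_mid), "value")),
    cbind(variable = "fer_ml_kg_min",
          window_summary(transform(intervals, value = fer, time = t_mid),
                         "value"))
  )
  log_stage(verbose, "windows: %d group x window x variable summaries",
            nrow(win_fluid))

  # derived hemodynamics at the recorded timepoints
  hemo <- NULL; hemo_summary <- NULL
  if (!all(is.na(tp$map))) {
    ok <- stats::complete.cases(tp[, c("map", "cvp_ra", "mpap", "pcwp",
                                       "icp", "co_l_min")])
    h <- tp[ok, ]
    dh <- derived_hemodynamics(h$map, h$cvp_ra, h$mpap, h$pcwp, h$icp,
                               h$co_l_min)
    hemo <- cbind(h[, c("animal_id", "group", "time")], dh)
    hemo_summary <- do.call(rbind, lapply(
      split(hemo, hemo[c("group", "time")], drop = TRUE), function(d) {
        data.frame(group = d$group[1], time = d$time[1],
                   svr_mean = mean(d$svr), svr_sd = stats::sd(d$svr),
                   pvr_mean = mean(d$pvr), pvr_sd = stats::sd(d$pvr),
                   cpp_mean = mean(d$cpp), cpp_sd = stats::sd(d$cpp))
      }))
    rownames(hemo_summary) <- NULL
    log_stage(verbose, "hemodynamics: %d derived rows", nrow(hemo))
  }

  # solute masses
  solutes <- NULL
  if (!all(is.na(tp$s_protein_g_l))) {
    m <- merge(tp[, c("animal_id", "group", "time", "s_protein_g_l",
                      "s_albumin_g_l", "weight_kg")],
               volumes[, c("animal_id", "time", "pv")],
               by = c("animal_id", "time"))
    solutes <- data.frame(
      m[, c("animal_id", "group", "time")],
      protein_mass_g_kg = solute_mass(m$s_protein_g_l, m$pv, m$weight_kg),
      albumin_mass_g_kg = solute_mass(m$s_albumin_g_l, m$pv, m$weight_kg))
    log_stage(verbose, "solutes: %d mass rows", nrow(solutes))
  }

  # microsphere flows and the kidney percent-reduction statistic
  flows <- NULL; flow_pct <- NULL
  if (!is.null(dataset$microspheres) && nrow(dataset$microspheres)) {
    ms <- dataset$microspheres
    flows <- cbind(ms[, c("animal_id", "phase", "tissue")],
                   group = ms$group %||% substr(ms$animal_id, 1, 1),
                   flow_ml_min_100g = microsphere_flow(
                     ms$n_spheres, ms$sample_mass_g, ms$n_ref,
                     ms$q_ref_ml_min))
    wide <- merge(
      flows[flows$phase == "baseline",
            c("animal_id", "group", "tissue", "flow_ml_min_100g")],
      flows[flows$phase == "end",
            c("animal_id", "tissue", "flow_ml_min_100g")],
      by = c("animal_id", "tissue"), suffixes = c("_baseline", "_end"))
    wide <- wide[wide$flow_ml_min_100g_baseline > 0, ]
    wide$pct_reduction <- percent_change(wide$flow_ml_min_100g_baseline,
                                         wide$flow_ml_min_100g_end)
    flow_pct <- do.call(rbind, lapply(
      split(wide, wide[c("group", "tissue")], drop = TRUE), function(d) {
        data.frame(group = d$group[1], tissue = d$tissue[1],
                   pct_reduction_mean = mean(d$pct_reduction),
                   pct_reduction_sd = stats::sd(d$pct_reduction),
                   n = nrow(d))
      }))
    rownames(flow_pct) <- NULL
    log_stage(verbose, "microspheres: %d flow rows", nrow(flows))
  }

  # tissue water
  ttw <- NULL; ttw_summary <- NULL
  if (!is.null(dataset$tissue_water) && nrow(dataset$tissue_water)) {
    tw <- dataset$tissue_water
    tw$ttw <- tissue_water(tw$wet_mg, tw$dry_mg)
    ttw <- stats::aggregate(ttw ~ animal_id + group + tissue, tw, mean)
    ttw_summary <- do.call(rbind, lapply(
      split(ttw, ttw$tissue), function(d) {
        cg <- d$ttw[d$group == "C"]; pg <- d$ttw[d$group == "P"]
        p <- if (length(cg) >= 2 && length(pg) >= 2) welch_t(cg, pg)$p else NA
        data.frame(tissue = d$tissue[1], c_mean = mean(cg),
                   c_sd = stats::sd(cg), p_mean = mean(pg),
                   p_sd = stats::sd(pg), p_welch = p)
      }))
    rownames(ttw_summary) <- NULL
    log_stage(verbose, "tissue water: %d samples, %d tissues",
              nrow(tw), nrow(ttw_summary))
  }

  # repeated-measures statistics on the windowed fluid variables
  win_long <- function(data, value, time) {
    do.call(rbind, lapply(split(data, data$animal_id), function(d) {
      wa <- window_average(d[[time]], d[[value]])
      data.frame(animal_id = d$animal_id[1], group = d$group[1],
                 time = wa$window, value = wa$mean)
    }))
  }
  anova_in <- list(
    hct = win_long(transform(volumes, v = hct * 100), "v", "time"),
    pv_ml_kg = win_long(transform(volumes, v = pv_per_kg), "v", "time"),
    nfb = win_long(transform(intervals, v = nfb_rate), "v", "t_mid"),
    fer = win_long(transform(intervals, v = fer), "v", "t_mid")
  )
  anova_tables <- lapply(anova_in, mixed_anova)
  posthoc <- lapply(anova_in, function(d)
    posthoc_tests(d, baseline = "baseline"))
  log_stage(verbose, "stats: %d split-plot ANOVA tables", length(anova_tables))

  list(volumes = volumes, intervals = intervals, window_fluid = win_fluid,
       hemodynamics = hemo, hemo_summary = hemo_summary, solutes = solutes,
       flows = flows, flow_pct_change = flow_pct, ttw = ttw,
       ttw_summary = ttw_summary, anova = anova_tables, posthoc = posthoc)
}
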