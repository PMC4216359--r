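#' Simulator configuration
#'
#' Loads the default simulator configuration (cohort design, noise magnitudes,
#' trajectory presets per group, mechanistic Starling-model parameters,
#' microsphere and tissue-water generation settings) from the package's YAML
#' config file and applies any overrides.
#'
#' @param overrides named list merged recursively over the defaults.
#' @param file path to a YAML config; defaults to the packaged one.
#' @return Nested list of class `sim_params`.
#' @export
sim_params <- function(overrides = list(), file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "sim_defaults.yaml", package = "iahfluid")
  }
  stop_unless(nzchar(file) && file.exists(file), "config file not found")
  p <- yaml::read_yaml(file)
  p <- utils::modifyList(p, overrides)
  class(p) <- c("sim_params", "list")
  p
}

#' A noise specification with every magnitude set to zero
#'
#' Convenience for noise-free (oracle-equivalence) simulations.
#' @param noise a noise list, e.g. `sim_params()$noise`.
#' @return The list with all numeric entries set to 0.
#' @export
zero_noise <- function(noise = sim_params()$noise) {
  lapply(noise, function(x) 0)
}

#' Intra-abdominal pressure schedule
#'
#' Ordered step changes of the IAP target: the study protocol raises IAP to
#' 15 mmHg at t = 0 and to 30 mmHg at t = 120 min in the intervention group;
#' control animals stay at the resting baseline throughout.
#'
#' @param steps `data.frame` with columns `time_min` (ascending) and `level`
#'   (mmHg, >= 0); zero rows means no intervention.
#' @return Object of class `iap_schedule`.
#' @export
iap_schedule <- function(steps = data.frame(time_min = numeric(),
                                            level = numeric())) {
  stop_unless(all(c("time_min", "level") %in% names(steps)),
              "steps needs columns time_min and level")
  stop_unless(!is.unsorted(steps$time_min, strictly = TRUE),
              "step times must be strictly ascending")
  stop_unless(all(steps$level >= 0), "IAP levels must be non-negative")
  structure(list(steps = steps), class = "iap_schedule")
}

#' @rdname iap_schedule
#' @export
iap_schedule_p <- function() {
  iap_schedule(data.frame(time_min = c(0, 120), level = c(15, 30)))
}

#' @rdname iap_schedule
#' @export
iap_schedule_c <- function() iap_schedule()

#' IAP at a given time under a schedule
#'
#' @param schedule an [iap_schedule()].
#' @param t time, min (vectorised).
#' @param baseline resting IAP before the first step, mmHg.
#' @return IAP in mmHg.
#' @export
iap_at <- function(schedule, t, baseline = 0) {
  stopifnot(inherits(schedule, "iap_schedule"))
  st <- schedule$steps
  vapply(t, function(ti) {
    k <- which(st$time_min <= ti)
    if (length(k) == 0) baseline else st$level[max(k)]
  }, numeric(1))
}

standard_grid <- function(cohort) {
  seq(cohort$grid_start_min, cohort$grid_end_min, by = cohort$grid_step_min)
}

# piecewise-linear lookup that refuses extrapolation
knot_interp <- function(knots_time, knots_value, t, what = "trajectory") {
  stop_unless(min(t) >= min(knots_time) && max(t) <= max(knots_time),
              what, " knots do not cover the requested grid")
  stats::approx(knots_time, knots_value, xout = t, method = "linear")$y
}

window_of <- function(t_mid) {
  w <- analysis_windows()
  out <- rep(NA_character_, length(t_mid))
  for (k in seq_len(nrow(w))) {
    out[t_mid > w$t_start[k] & t_mid <= w$t_end[k]] <- w$window[k]
  }
  stop_unless(!anyNA(out), "interval midpoint outside the analysis windows")
  out
}

empty_timepoint_cols <- c("s_protein_g_l", "s_albumin_g_l", "map", "mpap",
                          "pcwp", "cvp_ra", "cvp_fv", "iap", "icp", "co_l_min")

#' Trajectory-driven synthetic animal
#'
#' Generates the observable record of one animal from a prescribed true
#' plasma-volume trajectory and a net-fluid-balance schedule — the round-trip
#' harness for the volume/balance pipeline. True PV is piecewise linear
#' through the knots; red-cell volume starts at `PV(t0) hct0 / (1 - hct0)` and
#' loses `blood_loss * hct` at each post-baseline grid draw (drawing whole
#' blood leaves the hematocrit itself unchanged). The fluid ledger (fixed
#' crystalloid infusion, 3x replacement of blood losses, residual urine) is
#' constructed so the realized NFB matches the schedule; a ledger that would
#' require negative urine is refused. Observed hematocrit is the true ratio
#' `V_RBC / (V_RBC + PV)` plus measurement noise. Deterministic given the
#' random state.
#'
#' @param pv_knots `data.frame` with `time` (min) and `pv_ml_kg`, covering the
#'   grid.
#' @param nfb_windows named numeric: target NFB rate (ml/kg/min) for windows
#'   `baseline`, `early`, `late`.
#' @param hct0 baseline hematocrit fraction in (0, 1).
#' @param weight_kg body weight, kg.
#' @param params [sim_params()] configuration (cohort block and noise used).
#' @param noise noise list; defaults to the configured magnitudes, use
#'   [zero_noise()] for exact round trips.
#' @param seed optional integer seed; `NULL` continues the current random
#'   stream.
#' @param animal_id,group identifiers stamped on the output.
#' @param decoration optional trajectory preset (protein/albumin/hemodynamic
#'   knots, as in the config's `trajectory` block) used to fill the remaining
#'   observable columns; left `NA` when absent.
#' @return List with `timepoints` (one row per grid time, internal units:
#'   hematocrit as fraction), `co_dilution` (one-row record), `truth_points`
#'   (true PV/V_RBC per grid time) and `truth_intervals` (realized NFB, dPV,
#'   FE, FER per 30-min interval).
#' @export
simulate_from_trajectory <- function(pv_knots, nfb_windows, hct0,
                                     weight_kg = 42, params = sim_params(),
                                     noise = params$noise, seed = NULL,
                                     animal_id = "A1", group = "C",
                                     decoration = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stop_unless(is_number(hct0) && hct0 > 0 && hct0 < 1, "hct0 must be in (0,1)")
  stop_unless(all(c("baseline", "early", "late") %in% names(nfb_windows)),
              "nfb_windows needs baseline, early and late rates")
  ch <- params$cohort
  grid <- standard_grid(ch)
  dt <- ch$grid_step_min
  n <- length(grid)
  pv_true <- knot_interp(pv_knots$time, pv_knots$pv_ml_kg, grid, "PV") *
    weight_kg

  bl <- ch$blood_loss_ml_per_interval
  vrbc_true <- numeric(n)
  hct_true <- numeric(n)
  vrbc_cur <- pv_true[1] * hct0 / (1 - hct0)
  for (i in seq_len(n)) {
    if (i == 1 || bl == 0) {
      hct_true[i] <- vrbc_cur / (vrbc_cur + pv_true[i])
    } else {
      # hematocrit measured after the draw, self-consistently: the draw at the
      # recorded hct h removes bl*h red cells, and h is the post-draw ratio
      # V_RBC/(V_RBC + PV); root in (0,1) of bl h^2 - (V+PV+bl) h + V = 0
      s <- vrbc_cur + pv_true[i] + bl
      hct_true[i] <- (s - sqrt(s^2 - 4 * bl * vrbc_cur)) / (2 * bl)
    }
    if (i > 1) vrbc_cur <- vrbc_cur - bl * hct_true[i]
    stop_unless(vrbc_cur > 0, "blood sampling exhausted red-cell volume")
    vrbc_true[i] <- vrbc_cur
  }

  # fluid ledger realizing the NFB schedule
  infusion <- weight_kg * ch$infusion_ml_kg_h / 60 * dt
  repl <- ch$replacement_factor * bl
  t_mid <- (grid[-n] + grid[-1]) / 2
  nfb_target <- nfb_windows[window_of(t_mid)] * weight_kg * dt
  urine_det <- infusion + repl - bl - nfb_target
  if (any(urine_det < -1e-9)) {
    stop("infeasible fluid ledger: the NFB schedule would require negative ",
         "urine output", call. = FALSE)
  }
  urine <- pmax(0, urine_det * (1 + stats::rnorm(n - 1, 0, noise$urine_frac_sd)))
  nfb_real <- infusion + repl - bl - urine

  hct_obs <- pmin(0.95, pmax(0.05, hct_true + stats::rnorm(n, 0, noise$hct_sd)))
  hb_obs <- hct_true * ch$mchc_g_l / 10 + stats::rnorm(n, 0, noise$hb_sd_g_dl)

  tp <- data.frame(
    animal_id = animal_id, group = group, time = grid,
    hct = hct_obs, hb_g_dl = hb_obs,
    urine_ml = c(0, urine), infusion_ml = c(0, rep(infusion, n - 1)),
    replacement_ml = c(0, rep(repl, n - 1)),
    blood_loss_ml = c(0, rep(bl, n - 1)),
    weight_kg = weight_kg
  )
  for (cn in empty_timepoint_cols) tp[[cn]] <- NA_real_
  if (!is.null(decoration)) {
    tp$s_protein_g_l <- knot_interp(decoration$protein_g_l$time,
                                    decoration$protein_g_l$value, grid,
                                    "protein") +
      stats::rnorm(n, 0, noise$protein_sd_g_l)
    tp$s_albumin_g_l <- knot_interp(decoration$albumin_g_l$time,
                                    decoration$albumin_g_l$value, grid,
                                    "albumin") +
      stats::rnorm(n, 0, noise$albumin_sd_g_l)
    for (v in names(decoration$hemo)) {
      kv <- decoration$hemo[[v]]
      base <- knot_interp(kv$time, kv$value, grid, v)
      fac <- 1 + stats::rnorm(1, 0, noise$hemo_animal_rel_sd)
      tp[[v]] <- base * fac * (1 + stats::rnorm(n, 0, noise$hemo_meas_rel_sd))
    }
  }
  tp <- tp[, c("animal_id", "group", "time", "hct", "hb_g_dl",
               "s_protein_g_l", "s_albumin_g_l", "map", "mpap", "pcwp",
               "cvp_ra", "cvp_fv", "iap", "icp", "co_l_min", "urine_ml",
               "infusion_ml", "replacement_ml", "blood_loss_ml", "weight_kg")]

  # CO-dilution record consistent with the true baseline red-cell volume; the
  # stored hematocrit/hemoglobin are the (noisy) measured values
  dF <- 0.05
  cthb_true <- hct_true[1] * ch$mchc_g_l
  co_dose <- vrbc_true[1] * ch$hufner_ml_per_g * dF * cthb_true /
    (1000 * hct_true[1])
  co_rec <- data.frame(animal_id = animal_id, co_dose_ml = co_dose,
                       cohb_pre = 0.01, cohb_post = 0.01 + dF,
                       cthb_g_l = hb_obs[1] * 10, hct = hct_obs[1])

  dpv <- diff(pv_true)
  fe <- nfb_real - dpv
  list(
    timepoints = tp,
    co_dilution = co_rec,
    truth_points = data.frame(animal_id = animal_id, time = grid,
                              pv_true_ml = pv_true, vrbc_true_ml = vrbc_true,
                              hct_true = hct_true),
    truth_intervals = data.frame(animal_id = animal_id,
                                 t_start = grid[-n], t_end = grid[-1],
                                 nfb_true_ml = nfb_real, dpv_true_ml = dpv,
                                 fe_true_ml = fe,
                                 fer_true = fe / weight_kg / dt)
  )
}

#' Analytic interstitial equilibrium of the mechanistic model
#'
#' With capillary pressure and both colloid-osmotic pressures held constant,
#' filtration `J_v = K_f [(P_c - P_i) - sigma (pi_c - pi_i)]` and lymph return
#' `L = (l0 + l1 (P_i - P_i0)) / (1 + f_iap IAP)` are both linear in the
#' interstitial pressure, so `J_v = L` has the closed-form solution
#' `P_i* = (K_f A - w l0 + w l1 P_i0) / (K_f + w l1)` with
#' `A = P_c - sigma (pi_c - pi_i)` and `w = 1 / (1 + f_iap IAP)`; the
#' equilibrium interstitial volume follows from the compliance relation.
#'
#' @param p mechanistic parameter block (`sim_params()$mechanistic`).
#' @param iap constant intra-abdominal pressure, mmHg.
#' @param pi_c,pi_i colloid-osmotic pressures held constant, mmHg; default
#'   from the baseline protein concentrations.
#' @return List with `p_i`, `v_int` (ml) and the common flow `j_v` (ml/min).
#' @export
equilibrium_interstitial <- function(p, iap = p$iap_baseline_mmhg,
                                     pi_c = p$a_cop_mmhg_g_l * p$protein_g_l,
                                     pi_i = p$a_cop_mmhg_g_l *
                                       p$interstitial_protein_g_l) {
  p_c <- p$p_v0_mmhg + p$cap_transmission * p$k_iap * iap + p$delta_fc_mmhg
  a <- p_c - p$sigma * (pi_c - pi_i)
  w <- 1 / (1 + p$lymph_iap_factor * iap)
  kf <- p$k_f_ml_min_mmhg
  p_i <- (kf * a - w * p$lymph_l0_ml_min +
            w * p$lymph_l1_ml_min_mmhg * p$p_i0_mmhg) /
    (kf + w * p$lymph_l1_ml_min_mmhg)
  v0 <- p$interstitial_volume_ml_kg * p$weight_kg
  list(p_i = p_i,
       v_int = v0 + p$c_int_ml_mmhg * (p_i - p$p_i0_mmhg),
       j_v = kf * (a - p_i))
}

#' Mechanistic Starling-model synthetic animal
#'
#' Two-compartment (plasma/interstitium) fluid and protein simulation driven
#' by an IAP schedule, integrated by explicit Euler at a fixed step. Venous
#' pressure couples to IAP (`P_v = p_v0 + k_iap IAP`), capillary pressure sits
#' a fixed offset above it (`P_c = P_v + delta_fc`), colloid-osmotic pressures
#' are linear in the compartment protein concentrations, interstitial pressure
#' follows a linear compliance, transcapillary filtration obeys the Starling
#' relation `J_v = K_f [(P_c - P_i) - sigma (pi_c - pi_i)]`, lymph return is
#' linear in interstitial pressure and attenuated under raised IAP, and
#' protein moves by sigma-filtered convection (upstream concentration).
#' Crystalloid infusion runs continuously; urine falls with plasma volume and
#' IAP; whole-blood sampling at each 30-min grid point is replaced threefold
#' with crystalloid. Fluid and protein ledgers are audited every step.
#'
#' @param params mechanistic parameter block (`sim_params()$mechanistic`).
#' @param schedule an [iap_schedule()].
#' @param t_start,t_end simulation horizon, min (observables are emitted on
#'   the 30-min grid).
#' @param noise noise list as in `sim_params()$noise`; [zero_noise()] for
#'   exact output.
#' @param seed optional integer seed.
#' @param animal_id,group identifiers stamped on the output.
#' @return List with `timepoints`, `co_dilution`, `truth_points` (true PV,
#'   V_RBC, interstitial volume, pressures per grid time), `truth_intervals`
#'   (per-interval realized NFB, dPV, FE and the `J_v - L` integral) and
#'   `audit` (max per-step fluid and protein conservation error, ml / g).
#' @export
simulate_mechanistic <- function(params = sim_params()$mechanistic,
                                 schedule = iap_schedule_c(),
                                 t_start = -60, t_end = 240,
                                 noise = zero_noise(), seed = NULL,
                                 animal_id = "A1", group = "C") {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  dt <- p$dt_min
  w <- p$weight_kg
  vpl <- p$pv0_ml_kg * w
  vint <- p$interstitial_volume_ml_kg * w
  vint0 <- vint
  vrbc <- vpl * p$hct0 / (1 - p$hct0)
  mpl <- p$protein_g_l * vpl / 1000
  mint <- p$interstitial_protein_g_l * vint / 1000
  infusion_rate <- w * p$infusion_ml_kg_h / 60
  draw_ml <- p$sample_ml_per_30min + p$bleed_ml_per_30min

  grid_step <- 30
  times <- seq(t_start, t_end, by = dt)
  is_grid <- abs((times - t_start) %% grid_step) < 1e-9

  # accumulators for the current 30-min interval
  acc <- c(inf = 0, repl = 0, urine = 0, blood = 0, jvl = 0)
  max_fluid_err <- 0
  max_prot_err <- 0

  pts <- list(); ints <- list()
  pv_at_last_grid <- NA_real_

  for (k in seq_along(times)) {
    t <- times[k]
    if (is_grid[k]) {
      hct_now <- vrbc / (vrbc + vpl)
      cp_now <- mpl / vpl * 1000
      iap_now <- iap_at(schedule, t, p$iap_baseline_mmhg)
      p_v <- p$p_v0_mmhg + p$k_iap * iap_now
      p_i <- p$p_i0_mmhg + (vint - vint0) / p$c_int_ml_mmhg
      pts[[length(pts) + 1L]] <- data.frame(
        time = t, pv_true_ml = vpl, vrbc_true_ml = vrbc, vint_true_ml = vint,
        hct_true = hct_now, cp_true_g_l = cp_now, p_v = p_v, p_i = p_i,
        iap = iap_now,
        urine_acc = acc[["urine"]], inf_acc = acc[["inf"]],
        repl_acc = acc[["repl"]], blood_acc = acc[["blood"]],
        jvl_acc = acc[["jvl"]])
      if (t > t_start) {
        nfb <- acc[["inf"]] + acc[["repl"]] - acc[["urine"]] - acc[["blood"]]
        dpv <- vpl - pv_at_last_grid
        ints[[length(ints) + 1L]] <- data.frame(
          t_start = t - grid_step, t_end = t, nfb_true_ml = nfb,
          dpv_true_ml = dpv, fe_true_ml = nfb - dpv,
          jv_minus_l_ml = acc[["jvl"]])
        # sampling event: draw whole blood, replace threefold
        if (draw_ml > 0) {
          plasma_part <- draw_ml * (1 - hct_now)
          rbc_part <- draw_ml * hct_now
          prot_part <- cp_now * plasma_part / 1000
          repl_ml <- 3 * draw_ml
          v_before <- vpl + vint
          m_before <- mpl + mint
          vpl <- vpl - plasma_part + repl_ml
          vrbc <- vrbc - rbc_part
          mpl <- mpl - prot_part
          max_fluid_err <- max(max_fluid_err,
                               abs((vpl + vint) - v_before -
                                     (repl_ml - plasma_part)))
          max_prot_err <- max(max_prot_err,
                              abs((mpl + mint) - m_before - (-prot_part)))
          acc[["blood"]] <- draw_ml
          acc[["repl"]] <- repl_ml
        } else {
          acc[["blood"]] <- 0; acc[["repl"]] <- 0
        }
        acc[["inf"]] <- 0; acc[["urine"]] <- 0; acc[["jvl"]] <- 0
      }
      pv_at_last_grid <- pts[[length(pts)]]$pv_true_ml
    }
    if (k == length(times)) break

    # Euler step t -> t + dt
    iap_now <- iap_at(schedule, t, p$iap_baseline_mmhg)
    p_v <- p$p_v0_mmhg + p$k_iap * iap_now
    # only a fraction of the venous pressure rise is transmitted to the
    # capillaries: pre-capillary (myogenic) constriction under raised IAP
    p_c <- p$p_v0_mmhg + p$cap_transmission * p$k_iap * iap_now +
      p$delta_fc_mmhg
    cp <- mpl / vpl * 1000
    ci <- mint / vint * 1000
    pi_c <- p$a_cop_mmhg_g_l * cp
    pi_i <- p$a_cop_mmhg_g_l * ci
    p_i <- p$p_i0_mmhg + (vint - vint0) / p$c_int_ml_mmhg
    j_v <- p$k_f_ml_min_mmhg * ((p_c - p_i) - p$sigma * (pi_c - pi_i))
    lymph <- max(0, (p$lymph_l0_ml_min +
                       p$lymph_l1_ml_min_mmhg * (p_i - p$p_i0_mmhg)) /
                   (1 + p$lymph_iap_factor * iap_now))
    urine <- p$urine_u0_ml_min * (vpl / (p$pv0_ml_kg * w))^p$urine_pv_exp /
      (1 + p$urine_iap_coef * max(0, iap_now - p$iap_baseline_mmhg))
    j_s <- j_v * (1 - p$sigma) * (if (j_v >= 0) cp else ci) / 1000
    l_s <- lymph * ci / 1000

    v_before <- vpl + vint
    m_before <- mpl + mint
    d_vpl <- (infusion_rate - urine - (j_v - lymph)) * dt
    d_vint <- (j_v - lymph) * dt
    vpl <- vpl + d_vpl
    vint <- vint + d_vint
    mpl <- mpl + (-j_s + l_s) * dt
    mint <- mint + (j_s - l_s) * dt
    if (vpl <= 0 || vint <= 0 || vrbc <= 0) {
      stop(sprintf(paste0("integration instability at t = %g min: ",
                          "non-positive compartment volume (plasma %.1f ml, ",
                          "interstitium %.1f ml); reduce the step or check ",
                          "parameters"), t + dt, vpl, vint), call. = FALSE)
    }
    max_fluid_err <- max(max_fluid_err,
                         abs((vpl + vint) - v_before -
                               (infusion_rate - urine) * dt))
    max_prot_err <- max(max_prot_err, abs((mpl + mint) - m_before))
    acc[["inf"]] <- acc[["inf"]] + infusion_rate * dt
    acc[["urine"]] <- acc[["urine"]] + urine * dt
    acc[["jvl"]] <- acc[["jvl"]] + (j_v - lymph) * dt
  }

  truth_points <- do.call(rbind, pts)
  truth_intervals <- do.call(rbind, ints)
  truth_points$animal_id <- animal_id
  truth_intervals$animal_id <- animal_id
  truth_intervals$fer_true <- truth_intervals$fe_true_ml / w / grid_step

  n <- nrow(truth_points)
  hct_obs <- pmin(0.95, pmax(0.05, truth_points$hct_true +
                               stats::rnorm(n, 0, noise$hct_sd)))
  bv0 <- truth_points$pv_true_ml[1] + truth_points$vrbc_true_ml[1]
  tp <- data.frame(
    animal_id = animal_id, group = group, time = truth_points$time,
    hct = hct_obs,
    hb_g_dl = truth_points$hct_true * 310 / 10 +
      stats::rnorm(n, 0, noise$hb_sd_g_dl),
    s_protein_g_l = truth_points$cp_true_g_l +
      stats::rnorm(n, 0, noise$protein_sd_g_l),
    s_albumin_g_l = truth_points$cp_true_g_l * 0.66 +
      stats::rnorm(n, 0, noise$albumin_sd_g_l),
    map = p$map0_mmhg, mpap = p$mpap0_mmhg, pcwp = p$pcwp0_mmhg,
    cvp_ra = truth_points$p_v - 1, cvp_fv = truth_points$p_v,
    iap = truth_points$iap, icp = p$icp0_mmhg,
    co_l_min = p$co0_l_min *
      (truth_points$pv_true_ml + truth_points$vrbc_true_ml) / bv0,
    urine_ml = truth_points$urine_acc,
    inf_acc = truth_points$inf_acc, repl_acc = truth_points$repl_acc,
    blood_acc = truth_points$blood_acc,
    weight_kg = w
  )
  names(tp)[names(tp) == "inf_acc"] <- "infusion_ml"
  names(tp)[names(tp) == "repl_acc"] <- "replacement_ml"
  names(tp)[names(tp) == "blood_acc"] <- "blood_loss_ml"

  dF <- 0.05
  cthb_true <- truth_points$hct_true[1] * 310
  co_rec <- data.frame(
    animal_id = animal_id,
    co_dose_ml = truth_points$vrbc_true_ml[1] * 1.39 * dF *
      cthb_true / (1000 * truth_points$hct_true[1]),
    cohb_pre = 0.01, cohb_post = 0.01 + dF,
    cthb_g_l = tp$hb_g_dl[1] * 10, hct = hct_obs[1])

  keep <- c("time", "pv_true_ml", "vrbc_true_ml", "vint_true_ml", "hct_true",
            "cp_true_g_l", "p_v", "p_i", "iap", "animal_id")
  list(timepoints = tp, co_dilution = co_rec,
       truth_points = truth_points[, keep],
       truth_intervals = truth_intervals,
       audit = list(max_fluid_err_ml = max_fluid_err,
                    max_protein_err_g = max_prot_err))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

child_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 100003 + i * 1009) %% 2147483629)
}

#' Synthetic two-group cohort
#'
#' Generates a full synthetic experiment — 30-min timepoint records,
#' CO-dilution records, microsphere count tables and wet/dry tissue weights —
#' for `n_c` control and `n_p` intervention animals, together with the hidden
#' truth. In `"trajectory"` mode each animal follows the group's configured
#' PV/NFB preset with between-animal variation (PV shift, baseline hematocrit,
#' NFB offset, weight); in `"mechanistic"` mode each animal is integrated from
#' the Starling model under the group's IAP schedule. Per-animal seeds are
#' derived from the master seed by a fixed offset, so any animal can be
#' regenerated independently.
#'
#' Microsphere counts are drawn multinomially: each tissue aliquot captures
#' spheres with probability `flow x mass / 100 / CO`, the reference withdrawal
#' with probability `q_ref / CO`. Tissue-water samples draw a per-animal true
#' water content per tissue and convert it to wet/dry weights.
#'
#' @param n_c,n_p animals per group (>= 1).
#' @param mode `"trajectory"` or `"mechanistic"`.
#' @param params [sim_params()] configuration.
#' @param master_seed integer master seed.
#' @param noise noise list; [zero_noise()] disables all randomness except the
#'   between-animal effects (which are part of the noise list here via
#'   `between_animal = FALSE`).
#' @param between_animal draw between-animal effects (trajectory mode).
#' @return List of class `iah_dataset` with elements `timepoints`,
#'   `co_dilution`, `microspheres`, `tissue_water`, `truth_points`,
#'   `truth_intervals`, `truth_flows`, `truth_ttw`.
#' @export
simulate_cohort <- function(n_c = 8, n_p = 8,
                            mode = c("trajectory", "mechanistic"),
                            params = sim_params(), master_seed = 1,
                            noise = params$noise, between_animal = TRUE) {
  mode <- match.arg(mode)
  stop_unless(n_c >= 1 && n_p >= 1, "need at least one animal per group")
  ids <- c(sprintf("C%02d", seq_len(n_c)), sprintf("P%02d", seq_len(n_p)))
  groups <- c(rep("C", n_c), rep("P", n_p))
  ba <- params$between_animal
  ch <- params$cohort

  parts <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    set.seed(child_seed(master_seed, i))
    gr <- groups[i]
    if (mode == "trajectory") {
      preset <- params$trajectory[[gr]]
      pv_shift <- if (between_animal) stats::rnorm(1, 0, ba$pv_ml_kg_sd) else 0
      hct0 <- preset$hct0 +
        if (between_animal) stats::rnorm(1, 0, ba$hct0_sd) else 0
      nfb_shift <- if (between_animal)
        stats::rnorm(1, 0, ba$nfb_ml_kg_min_sd) else 0
      weight <- ch$weight_kg +
        if (between_animal) stats::rnorm(1, 0, ba$weight_kg_sd) else 0
      knots <- data.frame(time = preset$pv_knots$time,
                          pv_ml_kg = preset$pv_knots$pv_ml_kg + pv_shift)
      # an animal cannot balance more than it is given: NFB is capped by the
      # ledger ceiling (infusion + replacement - blood loss), the oliguric
      # limit at which urine output is zero
      dt <- ch$grid_step_min
      ceiling_rate <- (weight * ch$infusion_ml_kg_h / 60 * dt +
                         (ch$replacement_factor - 1) *
                           ch$blood_loss_ml_per_interval) / weight / dt
      nfbw <- pmin(unlist(preset$nfb_ml_kg_min) + nfb_shift, ceiling_rate)
      sim <- simulate_from_trajectory(knots, nfbw, hct0, weight, params,
                                      noise, seed = NULL, animal_id = ids[i],
                                      group = gr, decoration = preset)
    } else {
      schedule <- if (gr == "P") iap_schedule_p() else iap_schedule_c()
      sim <- simulate_mechanistic(params$mechanistic, schedule,
                                  t_start = ch$grid_start_min,
                                  t_end = ch$grid_end_min,
                                  noise = noise, seed = NULL,
                                  animal_id = ids[i], group = gr)
      sim$truth_points <- sim$truth_points[, c("animal_id", "time",
                                               "pv_true_ml", "vrbc_true_ml",
                                               "hct_true")]
      sim$truth_intervals <- sim$truth_intervals[
        , c("animal_id", "t_start", "t_end", "nfb_true_ml", "dpv_true_ml",
            "fe_true_ml", "fer_true")]
    }
    ms <- simulate_microspheres(params$microspheres, ids[i], gr)
    tw <- simulate_tissue_water(params$tissue_water, ids[i], gr)
    parts[[i]] <- list(sim = sim, ms = ms, tw = tw)
  }

  bind <- function(get) do.call(rbind, lapply(parts, get))
  out <- list(
    timepoints = bind(function(x) x$sim$timepoints),
    co_dilution = bind(function(x) x$sim$co_dilution),
    microspheres = bind(function(x) x$ms$counts),
    tissue_water = bind(function(x) x$tw$samples),
    truth_points = bind(function(x) x$sim$truth_points),
    truth_intervals = bind(function(x) x$sim$truth_intervals),
    truth_flows = bind(function(x) x$ms$truth),
    truth_ttw = bind(function(x) x$tw$truth)
  )
  class(out) <- c("iah_dataset", "list")
  out
}

# multinomial microsphere counts for one animal, both phases
simulate_microspheres <- function(cfg, animal_id, group) {
  tiss <- do.call(rbind, lapply(cfg$tissues, as.data.frame))
  a_fac <- exp(stats::rnorm(nrow(tiss), 0, cfg$animal_rel_sd))
  counts <- list(); truth <- list()
  for (phase in c("baseline", "end")) {
    mean_flow <- tiss[[paste0(tolower(group), "_", phase)]]
    flow <- mean_flow * a_fac * exp(stats::rnorm(nrow(tiss), 0, cfg$phase_rel_sd))
    p_tiss <- flow * tiss$sample_mass_g / 100 / cfg$cardiac_output_ml_min
    p_ref <- cfg$q_ref_ml_min / cfg$cardiac_output_ml_min
    p_rest <- 1 - sum(p_tiss) - p_ref
    stop_unless(p_rest > 0, "flow partition exceeds cardiac output")
    draw <- stats::rmultinom(1, cfg$n_total, c(p_tiss, p_ref, p_rest))
    n_ref <- draw[length(p_tiss) + 1L]
    counts[[phase]] <- data.frame(
      animal_id = animal_id, group = group, phase = phase,
      tissue = tiss$tissue, n_spheres = draw[seq_along(p_tiss)],
      sample_mass_g = tiss$sample_mass_g, n_ref = n_ref,
      q_ref_ml_min = cfg$q_ref_ml_min)
    truth[[phase]] <- data.frame(animal_id = animal_id, group = group,
                                 phase = phase, tissue = tiss$tissue,
                                 flow_true = flow)
  }
  list(counts = rbind(counts$baseline, counts$end),
       truth = rbind(truth$baseline, truth$end))
}

# wet/dry gravimetry samples for one animal
simulate_tissue_water <- function(cfg, animal_id, group) {
  tiss <- do.call(rbind, lapply(cfg$tissues, as.data.frame))
  mu <- tiss[[paste0(tolower(group), "_mean")]]
  sdv <- tiss[[paste0(tolower(group), "_sd")]]
  ttw_animal <- pmax(0.2, stats::rnorm(nrow(tiss), mu, sdv))
  samples <- list(); k <- 0
  for (r in seq_len(cfg$replicates)) {
    ttw_rep <- pmax(0.1, ttw_animal + stats::rnorm(nrow(tiss), 0, 0.05))
    dry <- pmax(50, stats::rnorm(nrow(tiss), cfg$dry_mg_mean, cfg$dry_mg_sd))
    k <- k + 1
    samples[[k]] <- data.frame(
      animal_id = animal_id, group = group, tissue = tiss$tissue,
      replicate = r, wet_mg = dry * (1 + ttw_rep), dry_mg = dry)
  }
  list(samples = do.call(rbind, samples),
       truth = data.frame(animal_id = animal_id, group = group,
                          tissue = tiss$tissue, ttw_true = ttw_animal))
}
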