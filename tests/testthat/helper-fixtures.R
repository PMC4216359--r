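# shared fixtures built in code

# one noise-free trajectory animal with the given PV knots / NFB schedule
traj_animal <- function(pv_knots, nfb = c(baseline = 0.18, early = 0.18,
                                          late = 0.18),
                        hct0 = 0.277, weight = 42, seed = 1, noise = NULL,
                        params = sim_params()) {
  if (is.null(noise)) noise <- zero_noise(params$noise)
  simulate_from_trajectory(pv_knots, nfb, hct0, weight, params, noise,
                           seed = seed, animal_id = "A1", group = "P")
}

# wrap one simulated animal as a dataset the pipeline accepts
as_dataset <- function(sim) {
  structure(list(timepoints = sim$timepoints, co_dilution = sim$co_dilution),
            class = c("iah_dataset", "list"))
}

# random balanced split-plot dataset
random_split_plot <- function(n_per_group = 4, n_time = 5, effect = 0) {
  d <- expand.grid(animal_id = seq_len(2 * n_per_group),
                   time = seq_len(n_time))
  d$group <- ifelse(d$animal_id <= n_per_group, "C", "P")
  subj_eff <- rnorm(2 * n_per_group)
  d$value <- rnorm(nrow(d)) + subj_eff[d$animal_id] +
    effect * (d$group == "P") * d$time
  d
}

# independent sums-of-squares oracle for the split-plot decomposition:
# sequential (Type I) least-squares fits via lm/anova, a different numerical
# route (QR on dummy-coded factors) from the cell-means formulas
split_plot_oracle <- function(d) {
  d$animal_id <- factor(d$animal_id)
  d$group <- factor(d$group)
  d$time <- factor(d$time)
  a <- stats::anova(stats::lm(value ~ group + animal_id + time + group:time,
                              data = d))
  ss <- a[["Sum Sq"]]
  names(ss) <- rownames(a)
  c(group = ss[["group"]], subj = ss[["animal_id"]], time = ss[["time"]],
    gt = ss[["group:time"]], resid = ss[["Residuals"]])
}

ss_of <- function(tab) {
  stats::setNames(tab$ss[match(c("group", "animal:group", "time",
                                 "group:time", "residual"), tab$effect)],
                  c("group", "subj", "time", "gt", "resid"))
}

# pooled per-animal window means of the four fluid variables for one
# trajectory-mode cohort
recovered_windows <- function(master_seed, n_c = 8, n_p = 8,
                              params = sim_params()) {
  ds <- simulate_cohort(n_c, n_p, "trajectory", params,
                        master_seed = master_seed)
  av <- animal_volumes(ds)
  per_animal <- function(df, value, time) {
    do.call(rbind, lapply(split(df, df$animal_id), function(d) {
      wa <- window_average(d[[time]], d[[value]])
      data.frame(animal_id = d$animal_id[1], group = d$group[1],
                 window = wa$window, value = wa$mean)
    }))
  }
  rbind(
    cbind(variable = "hct",
          per_animal(transform(av$volumes, v = hct * 100), "v", "time")),
    cbind(variable = "pv",
          per_animal(transform(av$volumes, v = pv_per_kg), "v", "time")),
    cbind(variable = "nfb",
          per_animal(transform(av$intervals, v = nfb_rate), "v", "t_mid")),
    cbind(variable = "fer",
          per_animal(transform(av$intervals, v = fer), "v", "t_mid"))
  )
}

window_mean_over_seeds <- function(seeds, variable, group, window,
                                   n_c = 8, n_p = 8) {
  vals <- unlist(lapply(seeds, function(s) {
    w <- recovered_windows(s, n_c, n_p)
    w$value[w$variable == variable & w$group == group & w$window == window]
  }))
  mean(vals)
}
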