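#' Split-plot (mixed-design) repeated-measures ANOVA
#'
#' Classical univariate decomposition for one between-subjects factor (group)
#' and one within-subjects factor (time), with subjects nested in groups and
#' crossed with time. Sums of squares are computed from cell, subject, group
#' and time means:
#' between-subject variation splits into the group effect (tested against
#' subject-within-group) and subject-within-group; within-subject variation
#' splits into time, group x time (both tested against the residual
#' subject x time stratum) and the residual. No sphericity adjustment is
#' applied by default; the Greenhouse-Geisser epsilon correction of the
#' within-subject degrees of freedom is available via `gg_correction = TRUE`.
#'
#' Every subject must be observed at every time level (missing cells are an
#' error, no imputation); unequal group sizes are accepted with a warning.
#' Effects with zero variance return F = 0 and p = 1.
#'
#' @param data long `data.frame`, one row per subject x time.
#' @param value,animal,group,time names of the value, subject-id,
#'   between-factor and within-factor columns.
#' @param gg_correction apply the Greenhouse-Geisser epsilon to the
#'   within-subject tests.
#' @return `data.frame` of class `anova_split_plot` with one row per effect
#'   (`group`, `animal:group`, `time`, `group:time`, `residual`, `total`) and
#'   columns `df`, `ss`, `ms`, `f`, `p`.
#' @export
#' @examples
#' d <- expand.grid(animal_id = 1:6, time = c(0, 60, 120))
#' d$group <- ifelse(d$animal_id <= 3, "C", "P")
#' set.seed(1); d$value <- rnorm(nrow(d)) + (d$group == "P") * d$time / 100
#' mixed_anova(d)
mixed_anova <- function(data, value = "value", animal = "animal_id",
                        group = "group", time = "time",
                        gg_correction = FALSE) {
  stop_unless(all(c(value, animal, group, time) %in% names(data)),
              "data is missing required columns")
  y <- data[[value]]
  stop_unless(is.numeric(y) && !anyNA(y), "values must be numeric without NA")
  a <- factor(data[[animal]])
  g <- factor(data[[group]])
  t <- factor(data[[time]])
  stop_unless(nlevels(t) >= 2, "need at least two time levels")
  stop_unless(nlevels(g) >= 2, "need at least two groups")

  # each animal belongs to exactly one group and has each time exactly once
  tab <- table(a, t)
  if (any(tab != 1)) {
    stop("unbalanced design: every animal must have exactly one value per ",
         "time level (no imputation is performed)", call. = FALSE)
  }
  ag <- table(a, g)
  if (any(rowSums(ag > 0) != 1)) {
    stop("each animal must belong to exactly one group", call. = FALSE)
  }
  n_per_group <- table(factor(tapply(as.character(g), a, `[`, 1),
                              levels = levels(g)))
  if (length(unique(as.integer(n_per_group))) > 1) {
    warning("unequal group sizes; proceeding with the unweighted-cell-means ",
            "decomposition")
  }
  if (any(n_per_group < 2)) {
    stop("need at least 2 animals per group", call. = FALSE)
  }

  n_t <- nlevels(t)
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)

  subj_mean <- tapply(y, a, mean)
  subj_group <- factor(tapply(as.character(g), a, `[`, 1), levels = levels(g))
  group_mean <- tapply(subj_mean, subj_group, mean)   # unweighted over animals
  time_mean <- tapply(y, t, mean)
  cell_mean <- tapply(y, list(g, t), mean)

  n_subj <- nlevels(a)
  ss_between <- n_t * sum((subj_mean - grand)^2)
  ss_group <- n_t * sum(as.integer(n_per_group) * (group_mean - grand)^2)
  ss_subj <- ss_between - ss_group
  ss_time <- n_subj * sum((time_mean - grand)^2)
  ss_cells <- sum(rep(as.integer(n_per_group), times = n_t) *
                    (as.vector(cell_mean) - grand)^2)
  ss_gt <- ss_cells - ss_group - ss_time
  ss_resid <- ss_total - ss_cells - ss_subj

  df_group <- nlevels(g) - 1L
  df_subj <- n_subj - nlevels(g)
  df_time <- n_t - 1L
  df_gt <- df_group * df_time
  df_resid <- df_subj * df_time

  # numerical guard: tiny negative SS from cancellation
  clamp0 <- function(x) if (x < 0 && x > -1e-8 * max(ss_total, 1)) 0 else x
  ss_gt <- clamp0(ss_gt); ss_resid <- clamp0(ss_resid); ss_subj <- clamp0(ss_subj)
  stop_unless(ss_gt >= 0 && ss_resid >= 0 && ss_subj >= 0,
              "negative sum of squares: inconsistent input")

  eps <- 1
  if (gg_correction) eps <- gg_epsilon(y, a, t)

  f_test <- function(ss_num, df_num, ss_den, df_den, e = 1) {
    ms_num <- ss_num / df_num
    ms_den <- ss_den / df_den
    if (ms_den <= 0) {
      if (ms_num <= 0) return(c(f = 0, p = 1))
      return(c(f = Inf, p = 0))
    }
    f <- ms_num / ms_den
    if (ss_num <= 0) return(c(f = 0, p = 1))
    c(f = f, p = stats::pf(f, e * df_num, e * df_den, lower.tail = FALSE))
  }

  tg <- f_test(ss_group, df_group, ss_subj, df_subj)
  tt <- f_test(ss_time, df_time, ss_resid, df_resid, eps)
  ti <- f_test(ss_gt, df_gt, ss_resid, df_resid, eps)

  out <- data.frame(
    effect = c("group", "animal:group", "time", "group:time", "residual",
               "total"),
    df = c(df_group, df_subj, df_time, df_gt, df_resid, length(y) - 1L),
    ss = c(ss_group, ss_subj, ss_time, ss_gt, ss_resid, ss_total),
    ms = c(ss_group / df_group, ss_subj / df_subj, ss_time / df_time,
           ss_gt / df_gt, ss_resid / df_resid, NA),
    f = c(tg["f"], NA, tt["f"], ti["f"], NA, NA),
    p = c(tg["p"], NA, tt["p"], ti["p"], NA, NA)
  )
  attr(out, "gg_epsilon") <- if (gg_correction) eps else NA_real_
  class(out) <- c("anova_split_plot", "data.frame")
  out
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# subject x time matrix
gg_epsilon <- function(y, a, t, g = NULL) {
  m <- tapply(y, list(a, t), mean)
  s <- stats::cov(m)
  k <- ncol(s)
  dbar <- mean(diag(s))
  sbar <- mean(s)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(s^2) - 2 * k * mean(rowMeans(s)^2) + k^2 * sbar^2)
  if (den <= 0) return(1)
  max(1 / (k - 1), min(1, num / den))
}

#' @export
print.anova_split_plot <- function(x, ...) {
  cat("Split-plot repeated-measures ANOVA",
      if (!is.na(attr(x, "gg_epsilon")))
        sprintf(" (Greenhouse-Geisser eps = %.3f)", attr(x, "gg_epsilon")),
      "\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}

#' Paired t-test (first principles)
#'
#' Two-sided paired t-test on the differences `x - y`. When the differences
#' have zero variance the statistic is degenerate: all-zero differences give
#' t = 0, p = 1; constant non-zero differences are reported with p = 0 and
#' flagged.
#'
#' @param x,y paired numeric vectors (n >= 2).
#' @return `data.frame` with `statistic`, `df`, `p`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  stop_unless(length(x) == length(y), "x and y must be paired")
  d <- x - y
  n <- length(d)
  stop_unless(n >= 2, "need at least 2 pairs")
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      return(data.frame(statistic = 0, df = n - 1, p = 1, degenerate = TRUE))
    }
    return(data.frame(statistic = sign(mean(d)) * Inf, df = n - 1, p = 0,
                      degenerate = TRUE))
  }
  tstat <- mean(d) / (s / sqrt(n))
  data.frame(statistic = tstat, df = n - 1,
             p = 2 * stats::pt(abs(tstat), n - 1, lower.tail = FALSE),
             degenerate = FALSE)
}

#' Welch's independent-samples t-test (first principles)
#'
#' Two-sided t-test for a difference in means without assuming equal
#' variances, with Welch-Satterthwaite degrees of freedom.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @return `data.frame` with `statistic`, `df`, `p`, `degenerate`.
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stop_unless(nx >= 2 && ny >= 2, "need at least 2 observations per group")
  vx <- stats::var(x) / nx
  vy <- stats::var(y) / ny
  if (vx + vy == 0) {
    if (mean(x) == mean(y)) {
      return(data.frame(statistic = 0, df = nx + ny - 2, p = 1,
                        degenerate = TRUE))
    }
    return(data.frame(statistic = sign(mean(x) - mean(y)) * Inf,
                      df = nx + ny - 2, p = 0, degenerate = TRUE))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  data.frame(statistic = tstat, df = df,
             p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
             degenerate = FALSE)
}

#' Mann-Whitney U test (first principles)
#'
#' Rank-sum test for a location difference between two independent samples.
#' `U` counts pairs `(x_i, y_j)` with `x_i > y_j` (ties count 1/2). For small
#' samples (both n <= `exact_max`) without ties the two-sided p-value is exact,
#' from complete enumeration of the permutation distribution of U; otherwise
#' the tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y numeric vectors (each n >= 1, combined n >= 3).
#' @param exact_max largest per-group n for the exact enumeration.
#' @return `data.frame` with `u`, `p`, `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
mann_whitney <- function(x, y, exact_max = 8) {
  nx <- length(x); ny <- length(y)
  stop_unless(nx >= 1 && ny >= 1 && nx + ny >= 3, "samples too small")
  r <- rank(c(x, y))
  rx <- sum(r[seq_len(nx)])
  u <- rx - nx * (nx + 1) / 2          # pairs with x > y (+ 1/2 per tie)
  ties <- any(duplicated(c(x, y)))
  if (!ties && nx <= exact_max && ny <= exact_max) {
    # exact permutation distribution of U by enumeration of rank subsets
    idx <- utils::combn(nx + ny, nx)
    us <- colSums(matrix(seq_len(nx + ny)[idx], nrow = nx)) -
      nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    return(data.frame(u = u, p = p, method = "exact"))
  }
  mu <- nx * ny / 2
  tie_tab <- table(c(x, y))
  n <- nx + ny
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(data.frame(u = u, p = 1, method = "normal"))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  data.frame(u = u, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Post-hoc test battery for the split-plot design
#'
#' The follow-up comparisons used after a significant omnibus result: within
#' each group, paired t-tests of every post-baseline time level against
#' baseline; between groups at every time level, Welch's t-test and the
#' Mann-Whitney U test. Two-sided, unadjusted p-values.
#'
#' @inheritParams mixed_anova
#' @param baseline first (reference) time level; defaults to the first level
#'   in sort order.
#' @return Tidy `data.frame`: `comparison` (`"vs_baseline"` or
#'   `"between_groups"`), `test`, `group` (for within-group tests), `time`,
#'   `statistic`, `p`, `degenerate`.
#' @export
posthoc_tests <- function(data, value = "value", animal = "animal_id",
                          group = "group", time = "time", baseline = NULL) {
  stop_unless(all(c(value, animal, group, time) %in% names(data)),
              "data is missing required columns")
  t_lev <- sort(unique(data[[time]]))
  if (is.null(baseline)) baseline <- t_lev[1]
  g_lev <- sort(unique(as.character(data[[group]])))
  stop_unless(length(g_lev) == 2, "post-hoc battery expects exactly 2 groups")

  pull <- function(gr, tl) {
    d <- data[data[[group]] == gr & data[[time]] == tl, ]
    d <- d[order(d[[animal]]), ]
    stats::setNames(d[[value]], d[[animal]])
  }
  rows <- list()
  for (gr in g_lev) {
    base <- pull(gr, baseline)
    for (tl in setdiff(t_lev, baseline)) {
      cur <- pull(gr, tl)
      shared <- intersect(names(base), names(cur))
      stop_unless(length(shared) >= 2, "need >= 2 paired animals")
      r <- paired_t(cur[shared], base[shared])
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = "vs_baseline", test = "paired_t", group = gr, time = tl,
        statistic = r$statistic, p = r$p, degenerate = r$degenerate)
    }
  }
  for (tl in t_lev) {
    xa <- pull(g_lev[1], tl); xb <- pull(g_lev[2], tl)
    stop_unless(length(xa) >= 2 && length(xb) >= 2,
                "need >= 2 animals per group")
    rw <- welch_t(xa, xb)
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = "between_groups", test = "welch_t", group = NA, time = tl,
      statistic = rw$statistic, p = rw$p, degenerate = rw$degenerate)
    rm_ <- mann_whitney(xa, xb)
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = "between_groups", test = "mann_whitney", group = NA,
      time = tl, statistic = rm_$u, p = rm_$p, degenerate = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
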