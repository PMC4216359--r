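test_that("all-identical data give zero F and p = 1 for every effect", {
  d <- expand.grid(animal_id = 1:4, time = 1:3)
  d$group <- ifelse(d$animal_id <= 2, "C", "P")
  d$value <- 7
  tab <- mixed_anova(d)
  expect_equal(tab$f[!is.na(tab$f)], c(0, 0, 0))
  expect_equal(tab$p[!is.na(tab$p)], c(1, 1, 1))
})

test_that("the 2x2x2 toy decomposition matches the least-squares oracle", {
  d <- expand.grid(animal_id = 1:4, time = 1:2)
  d$group <- ifelse(d$animal_id <= 2, "C", "P")
  d$value <- c(1, 2, 5, 7, 2, 4, 9, 12)
  expect_equal(ss_of(mixed_anova(d)), split_plot_oracle(d), tolerance = 1e-10)
})

test_that("sums of squares agree with the independent oracle on random designs", {
  set.seed(101)
  for (k in 1:50) {
    d <- random_split_plot(n_per_group = sample(2:6, 1),
                           n_time = sample(2:6, 1),
                           effect = runif(1, 0, 0.5))
    tab <- mixed_anova(d)
    expect_equal(ss_of(tab), split_plot_oracle(d), tolerance = 1e-8)
    expect_equal(sum(ss_of(tab)), tab$ss[tab$effect == "total"],
                 tolerance = 1e-8)
  }
})

test_that("the decomposition agrees with aov's Error-stratum table", {
  set.seed(7)
  d <- random_split_plot(4, 5, effect = 0.3)
  d$animal_id <- factor(d$animal_id); d$group <- factor(d$group)
  d$time <- factor(d$time)
  a <- summary(aov(value ~ group * time + Error(animal_id), data = d))
  between <- a[["Error: animal_id"]][[1]]
  within <- a[["Error: Within"]][[1]]
  tab <- mixed_anova(d)
  expect_equal(tab$ss[tab$effect == "group"], between["group", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "animal:group"],
               between["Residuals", "Sum Sq"], tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "time"], within["time", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "group:time"],
               within["group:time", "Sum Sq"], tolerance = 1e-10)
  expect_equal(tab$f[tab$effect == "time"], within["time", "F value"],
               tolerance = 1e-10)
})

test_that("swapping group labels leaves the time effect untouched", {
  set.seed(3)
  d <- random_split_plot(3, 4, effect = 0.2)
  d2 <- d
  d2$group <- ifelse(d$group == "C", "P", "C")
  expect_equal(mixed_anova(d)$ss[3], mixed_anova(d2)$ss[3])
})

test_that("missing cells and singleton groups are refused, unequal sizes warned", {
  d <- random_split_plot(3, 3)
  expect_error(mixed_anova(d[-1, ]), "unbalanced")
  d1 <- d[d$animal_id != 4, ]
  expect_warning(mixed_anova(d1), "unequal group sizes")
  d2 <- d[d$animal_id %in% c(1, 4, 5, 6), ]
  expect_error(suppressWarnings(mixed_anova(d2)), "at least 2 animals")
})

test_that("paired and Welch t match the reference implementations", {
  set.seed(13)
  for (k in 1:20) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(length(x)) + runif(1, -1, 1)
    r <- paired_t(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
    z <- rnorm(sample(3:10, 1), sd = runif(1, 0.5, 2))
    rw <- welch_t(x, z)
    refw <- t.test(x, z)
    expect_equal(rw$statistic, unname(refw$statistic), tolerance = 1e-12)
    expect_equal(rw$p, refw$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate paired differences are flagged", {
  r0 <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  r1 <- paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4)) # differences all 1
  expect_true(r1$degenerate)
  expect_equal(r1$p, 0)
})

test_that("Mann-Whitney U is exact by enumeration for small samples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p, 0.1) # 2/20 orderings as extreme, two-sided
  expect_equal(r$method, "exact")
  set.seed(29)
  for (k in 1:15) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1))
    r <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(r$u, unname(ref$statistic))
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("ties fall back to the corrected normal approximation", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  r <- mann_whitney(x, y)
  expect_equal(r$method, "normal")
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)
})

test_that("the post-hoc battery covers both directions of the design", {
  set.seed(17)
  d <- random_split_plot(4, 3, effect = 0.4)
  d$time <- c("baseline", "60", "120")[d$time]
  ph <- posthoc_tests(d, baseline = "baseline")
  expect_equal(sum(ph$comparison == "vs_baseline"), 2 * 2) # 2 groups x 2 times
  expect_equal(sum(ph$test == "welch_t"), 3)
  expect_equal(sum(ph$test == "mann_whitney"), 3)
  expect_true(all(ph$p >= 0 & ph$p <= 1))
})
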