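# Statistics battery: mixed ANOVA/ANCOVA, post hocs, Mann-Whitney,
# chi-square, Spearman + FDR, bootstrap regression, power simulation.

test_that("between-only mixed ANOVA reduces to the pooled-variance t test", {
  for (i in 1:20) {
    set.seed(100 + i)
    n1 <- sample(4:9, 1); n2 <- sample(4:9, 1)
    d <- data.frame(participant = paste0("P", seq_len(n1 + n2)),
                    group = rep(c("A", "B"), c(n1, n2)),
                    y = c(rnorm(n1, 10, 2), rnorm(n2, 12, 2)))
    tab <- mixed_anova(d, "y", between = "group")
    tt <- t.test(y ~ group, data = d, var.equal = TRUE)
    expect_equal(tab$f, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(tab$p, tt$p.value, tolerance = 1e-8)
    expect_identical(tab$df2, n1 + n2 - 2)
  }
})

test_that("balanced split-plot ANOVA matches the aov() error-stratum oracle", {
  set.seed(7)
  n <- 8
  d <- expand.grid(participant = sprintf("S%d", 1:n), eye = c("yes", "no"),
                   attr = c("self", "other"), stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("S", "", d$participant)) <= n / 2, "A", "B")
  d$y <- rnorm(nrow(d), 100, 15) + ifelse(d$eye == "yes", 6, 0) +
    ifelse(d$group == "A", 9, 0)
  mine <- mixed_anova(d, "y", between = "group", within = c("eye", "attr"))

  oracle <- summary(aov(y ~ group * eye * attr + Error(participant / (eye * attr)),
                        data = d))
  pull <- function(stratum, term) {
    tab <- oracle[[stratum]][[1]]
    i <- match(term, trimws(rownames(tab)))
    c(f = tab$`F value`[i], p = tab$`Pr(>F)`[i])
  }
  cases <- list(
    group = pull("Error: participant", "group"),
    eye = pull("Error: participant:eye", "eye"),
    `eye:group` = pull("Error: participant:eye", "group:eye"),
    attr = pull("Error: participant:attr", "attr"),
    `attr:group` = pull("Error: participant:attr", "group:attr"),
    `eye:attr` = pull("Error: participant:eye:attr", "eye:attr"),
    `eye:attr:group` = pull("Error: participant:eye:attr", "group:eye:attr"))
  for (eff in names(cases)) {
    row <- mine[mine$effect == eff, ]
    expect_equal(row$f, unname(cases[[eff]]["f"]), tolerance = 1e-10,
                 label = paste("F of", eff))
    expect_equal(row$p, unname(cases[[eff]]["p"]), tolerance = 1e-10,
                 label = paste("p of", eff))
  }
})

test_that("every emitted partial eta squared satisfies its identity", {
  set.seed(8)
  d <- expand.grid(participant = sprintf("S%d", 1:11), eye = c("yes", "no"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("S", "", d$participant)) <= 6, "A", "B")
  d$y <- rnorm(nrow(d), 50, 10)
  tab <- mixed_anova(d, "y", between = "group", within = "eye")
  expect_equal(tab$partial_eta_sq,
               (tab$f * tab$df1) / (tab$f * tab$df1 + tab$df2),
               tolerance = 1e-10)
})

test_that("covariates enter the between stratum only (ANCOVA)", {
  set.seed(9)
  d <- expand.grid(participant = sprintf("S%d", 1:12), eye = c("yes", "no"),
                   stringsAsFactors = FALSE)
  idx <- as.integer(sub("S", "", d$participant))
  d$group <- ifelse(idx <= 6, "A", "B")
  d$age <- 20 + idx
  d$y <- rnorm(nrow(d), 50, 10) + 0.5 * d$age
  plain <- mixed_anova(d, "y", between = "group", within = "eye")
  adj <- mixed_anova(d, "y", between = "group", within = "eye",
                     covariates = "age")
  g <- function(t, e) t[t$effect == e, ]
  expect_identical(g(adj, "group")$df2, g(plain, "group")$df2 - 1)
  expect_identical(g(adj, "eye")$df2, g(plain, "eye")$df2)
  expect_equal(g(adj, "eye")$f, g(plain, "eye")$f)

  # oracle: ANCOVA F for group = squared t of group in lm on subject means
  means <- aggregate(y ~ participant + group + age, d, mean)
  means$gs <- ifelse(means$group == "A", 1, -1)
  fit <- summary(lm(y ~ gs + age, means))
  expect_equal(g(adj, "group")$f, fit$coefficients["gs", "t value"]^2,
               tolerance = 1e-10)
})

test_that("unsupported designs are rejected with clear errors", {
  d <- data.frame(participant = c("a", "b", "c"), group = c("A", "B", "C"),
                  y = 1:3)
  expect_error(mixed_anova(d, "y", between = "group"), "2-level")
  d2 <- data.frame(participant = c("a", "b", "c"), group = c("A", "A", "B"),
                   y = 1:3)
  expect_error(mixed_anova(d2, "y", between = "group"), "at least 2")
  expect_error(mixed_anova(d2, "z", between = "group"), "lacks column")
})

test_that("participants with incomplete within cells are dropped listwise", {
  set.seed(10)
  d <- expand.grid(participant = sprintf("S%d", 1:10), eye = c("yes", "no"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("S", "", d$participant)) <= 5, "A", "B")
  d$y <- rnorm(nrow(d), 100, 10)
  d_miss <- d[!(d$participant == "S3" & d$eye == "no"), ]
  expect_message(tab <- mixed_anova(d_miss, "y", between = "group",
                                    within = "eye"), "S3")
  expect_identical(attr(tab, "dropped"), "S3")
  manual <- suppressMessages(
    mixed_anova(d[d$participant != "S3", ], "y", between = "group",
                within = "eye"))
  expect_equal(tab$f, manual$f)
})

test_that("Bonferroni post hocs multiply by the family size and cap at 1", {
  set.seed(11)
  d <- expand.grid(participant = sprintf("S%d", 1:12),
                   time = c("baseline", "task"), stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d), 50, 8) + ifelse(d$time == "task", 6, 0)
  ph <- bonferroni_posthoc(d, "y", "time", family_size = 2)
  expect_true(ph$paired)
  expect_equal(ph$p_adj, min(1, ph$p_raw * 2))
  ref <- t.test(d$y[d$time == "baseline"], d$y[d$time == "task"], paired = TRUE)
  expect_equal(ph$p_raw, ref$p.value)

  d$y <- rnorm(nrow(d))  # null-ish: check the cap with a big family
  ph2 <- bonferroni_posthoc(d, "y", "time", family_size = 40)
  expect_lte(ph2$p_adj, 1)
  expect_equal(ph2$p_adj, min(1, ph2$p_raw * 40))

  expect_error(bonferroni_posthoc(d[d$time == "task", ], "y", "time"),
               "family is empty")
})

test_that("post hoc false-positive rate under the null stays near alpha", {
  set.seed(12)
  hits <- vapply(1:200, function(i) {
    d <- expand.grid(participant = sprintf("S%d", 1:14),
                     cond = c("a", "b"), stringsAsFactors = FALSE)
    d$y <- rnorm(nrow(d))
    bonferroni_posthoc(d, "y", "cond", family_size = 2)$p_adj < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("Mann-Whitney U equals brute-force pair counting (with ties)", {
  for (i in 1:100) {
    set.seed(200 + i)
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(1:6, n1, replace = TRUE)  # integer pool forces ties
    y <- sample(1:6, n2, replace = TRUE)
    res <- mann_whitney_rb(x, y)
    expect_equal(res$U, brute_u(x, y), tolerance = 1e-12)
    expect_equal(res$rank_biserial_r, 1 - 2 * res$U / (n1 * n2),
                 tolerance = 1e-12)
  }
})

test_that("complete separation gives the extreme effect size", {
  res <- mann_whitney_rb(c(1, 2, 3, 4), c(10, 11, 12))
  expect_identical(res$U, 0)
  expect_identical(res$rank_biserial_r, 1)
  res2 <- mann_whitney_rb(c(10, 11, 12), c(1, 2, 3, 4))
  expect_identical(res2$rank_biserial_r, -1)
})

test_that("exact and approximate p values agree with wilcox.test", {
  # exact path, no ties
  for (i in 1:20) {
    set.seed(300 + i)
    x <- rnorm(sample(3:7, 1)); y <- rnorm(sample(3:7, 1))
    res <- mann_whitney_rb(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_match(res$method, "exact")
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  }
  # tie-corrected normal path on larger samples
  set.seed(321)
  x <- sample(seq(0, 50, by = 2), 30, replace = TRUE)
  y <- sample(seq(1, 61, by = 2), 28, replace = TRUE) - 0.5
  res <- mann_whitney_rb(x, y, exact_max = 10)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_match(res$method, "normal")
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)

  expect_error(mann_whitney_rb(numeric(0), 1:3), "non-empty")
})

test_that("chi-square follows the uncorrected Pearson convention", {
  prop <- matrix(c(10, 20, 30, 60), 2)  # perfectly proportional
  expect_equal(chi_square_test(prop)$statistic, 0, tolerance = 1e-12)

  tab <- matrix(c(18, 14, 4, 7), 2)
  res <- chi_square_test(tab)
  expect_equal(round(res$statistic, 3), 1.296)
  expect_equal(res$statistic, chi_square_test(tab[2:1, ])$statistic)
  expect_lt(chi_square_test(tab, correct = TRUE)$statistic, res$statistic)

  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "expected cell")
  expect_error(chi_square_test(matrix(1:3, 1)), "2x2")
})

test_that("Spearman report: invariance, BH oracle, masks and flags", {
  set.seed(13)
  x <- rnorm(30)
  d <- data.frame(a = x, b = exp(x), c = rnorm(30), k = rep(1, 30))
  rep <- spearman_fdr(d)
  expect_equal(rep$rho["a", "b"], 1)
  expect_identical(rep$flagged_constant, "k")
  expect_true(all(is.na(rep$rho["k", c("a", "b", "c")])))

  lower <- lower.tri(rep$p) & !is.na(rep$p)
  expect_equal(rep$q[lower], bh_oracle(rep$p[lower]))
  expect_true(all(rep$q[lower] >= rep$p[lower]))
  o <- order(rep$p[lower])
  expect_true(!is.unsorted(rep$q[lower][o]))
  expect_identical(rep$significant["a", "b"], TRUE)
})

test_that("BH screening controls false discoveries under a permuted null", {
  set.seed(14)
  any_hit <- vapply(1:100, function(i) {
    d <- as.data.frame(matrix(rnorm(40 * 5), 40))
    any(spearman_fdr(d, level = 0.05)$significant)
  }, logical(1))
  expect_lte(mean(any_hit), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("bootstrap regression: exact fits, identities, determinism", {
  x <- seq(1, 10, length.out = 25)
  fit <- bootstrap_regression(2 * x, data.frame(x = x), n_boot = 200, seed = 3)
  expect_equal(fit$coefficients$estimate, c(0, 2), tolerance = 1e-10)
  expect_lt(max(fit$coefficients$bootstrap_se), 1e-10)

  set.seed(15)
  y <- 3 + 1.5 * x + rnorm(25)
  f2 <- bootstrap_regression(y, data.frame(x = x), n_boot = 300, seed = 4)
  m <- f2$model
  expect_equal(m$r_squared, (m$f_statistic * m$df1) /
                 (m$f_statistic * m$df1 + m$df2), tolerance = 1e-10)
  f3 <- bootstrap_regression(y, data.frame(x = x), n_boot = 300, seed = 4)
  expect_identical(f2$coefficients, f3$coefficients)

  X_bad <- data.frame(x = x, x2 = 2 * x)
  expect_error(bootstrap_regression(y, X_bad, n_boot = 10), "x2")
})

test_that("power simulation is monotone in sample size", {
  gp <- function(n) list(n1 = n, mean1 = 0, sd1 = 1, n2 = n, mean2 = 0.6,
                         sd2 = 1)
  p1 <- power_simulation(gp(15), n_reps = 400, seed = 5)$power
  p2 <- power_simulation(gp(30), n_reps = 400, seed = 6)$power
  expect_gte(p2, p1 - 0.05)
  expect_error(power_simulation(gp(10), n_reps = 50), "at least 100")
  expect_error(power_simulation(list(n1 = 5), n_reps = 100), "group_params")
})

test_that("significant group effects at the design presets all point ASD > CP", {
  set.seed(16)
  n_sig <- 0
  for (i in 1:200) {
    mu <- c(rnorm(22, 103.670, 47.322), rnorm(21, 67.690, 28.589))
    d <- expand.grid(participant = sprintf("S%d", 1:43),
                     eye_contact = c("yes", "no"),
                     attribution = c("self", "other"),
                     stringsAsFactors = FALSE)
    idx <- as.integer(sub("S", "", d$participant))
    d$group <- ifelse(idx <= 22, "ASD", "CP")
    d$distance_cm <- mu[idx] + rnorm(nrow(d), 0, 5)
    tab <- mixed_anova(d, "distance_cm", between = "group",
                       within = c("eye_contact", "attribution"))
    row <- tab[tab$effect == "group", ]
    if (row$p < 0.05) {
      n_sig <- n_sig + 1
      expect_gt(mean(mu[1:22]), mean(mu[23:43]))
      means <- tapply(d$distance_cm, d$group, mean)
      expect_gt(means["ASD"], means["CP"])
    }
  }
  expect_gt(n_sig, 100)  # the preset effect is large; most replicates detect it
})
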