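test_that("change scores are signed proportions of the reference", {
  expect_equal(change_score(110, 100), 0.10)
  expect_equal(change_score(7, 7), 0)
  expect_error(change_score(5, 0), "undefined")
  expect_warning(na <- change_score(5, 0, na_undefined = TRUE), "undefined")
  expect_true(is.na(na))

  # scale invariance
  set.seed(61)
  for (rep in 1:10) {
    xi <- runif(1, 1, 10); xj <- runif(1, 1, 10); c_ <- runif(1, 0.1, 10)
    expect_equal(change_score(c_ * xi, c_ * xj), change_score(xi, xj))
  }
})

test_that("degenerate ANOVA inputs give zero F and effect size", {
  dat <- expand.grid(unit = paste0("u", 1:6), within = c("t1", "t2", "t3"),
                     stringsAsFactors = FALSE)
  dat$between <- rep(c("a", "b"), each = 3)[match(dat$unit,
                                                  paste0("u", 1:6))]
  dat$value <- 5
  res <- mixed_anova(dat, between = "between")
  expect_equal(res$F, c(0, 0, 0))
  expect_equal(res$partial_eta_sq, c(0, 0, 0))
  expect_equal(res$p, c(1, 1, 1))
})

test_that("sphericity is vacuous with two within levels", {
  set.seed(62)
  dat <- random_mixed_data(n_per_group = 5, t = 2)
  res <- mixed_anova(dat, between = "between")
  expect_equal(attr(res, "epsilon"), 1)
  expect_false(attr(res, "gg_applied"))
})

test_that("the split-plot ANOVA matches the general-linear-model oracle", {
  set.seed(63)
  for (rep in 1:12) {
    t_n <- sample(3:5, 1)
    dat <- random_mixed_data(n_per_group = sample(4:7, 1), t = t_n,
                             g = sample(2:3, 1),
                             effect = runif(1, 0, 2))
    res <- mixed_anova(dat, between = "between")
    orc <- oracle_mixed_anova(dat)
    expect_equal(res$F[res$effect == "within"], orc$F_within,
                 tolerance = 1e-8)
    expect_equal(res$F[res$effect == "between"], orc$F_between,
                 tolerance = 1e-8)
    expect_equal(res$F[res$effect == "within:between"], orc$F_inter,
                 tolerance = 1e-8)
    expect_equal(res$p[res$effect == "within"], orc$p_within,
                 tolerance = 1e-8)
    expect_equal(attr(res, "epsilon"), orc$epsilon, tolerance = 1e-3)
    expect_equal(attr(res, "mauchly_W"), orc$mauchly_W, tolerance = 1e-8)
    # second-order approximations differ between references in the
    # third-order term; agreement to ~1e-3 in the p-value is the honest bound
    expect_equal(attr(res, "mauchly_p"), orc$mauchly_p, tolerance = 1e-3)
    # partial eta^2 against the oracle's sums of squares
    expect_equal(res$partial_eta_sq[res$effect == "within"],
                 orc$SS_within / (orc$SS_within + orc$SS_err_w),
                 tolerance = 1e-8)
    expect_equal(res$partial_eta_sq[res$effect == "between"],
                 orc$SS_between / (orc$SS_between + orc$SS_err_b),
                 tolerance = 1e-8)
  }
})

test_that("GG-corrected p-values match the mlm reference when triggered", {
  set.seed(64)
  found <- 0
  for (rep in 1:40) {
    # correlated repeated measures to provoke sphericity violations
    n <- 10; t_n <- 4
    base <- rnorm(n)
    Y <- sapply(1:t_n, function(k) base * k + rnorm(n, 0, 0.2 * k^2))
    dat <- data.frame(unit = rep(paste0("u", 1:n), t_n),
                      within = rep(paste0("t", 1:t_n), each = n),
                      between = rep(rep(c("a", "b"), each = n / 2), t_n),
                      value = as.vector(Y))
    res <- mixed_anova(dat, between = "between")
    if (!attr(res, "gg_applied")) next
    found <- found + 1
    orc <- oracle_mixed_anova(dat)
    expect_equal(res$p_gg[res$effect == "within"], orc$p_gg_within,
                 tolerance = 1e-6)
    expect_equal(res$p_gg[res$effect == "within:between"], orc$p_gg_inter,
                 tolerance = 1e-6)
    if (found >= 5) break
  }
  expect_gte(found, 3)
})

test_that("one-way repeated measures reduces to the paired t-test", {
  set.seed(65)
  x1 <- rnorm(8); x2 <- x1 + rnorm(8, 0.5)
  dat <- data.frame(unit = rep(paste0("u", 1:8), 2),
                    within = rep(c("t1", "t2"), each = 8),
                    value = c(x1, x2))
  res <- mixed_anova(dat, between = NULL)
  tt <- t.test(x2, x1, paired = TRUE)
  expect_equal(res$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p[1], tt$p.value, tolerance = 1e-10)
})

test_that("unbalanced or underpowered designs are rejected", {
  dat <- random_mixed_data(n_per_group = 3, t = 3)
  expect_error(mixed_anova(dat[-1, ], between = "between"), "unbalanced")
  dat1 <- dat[dat$unit != "u1", ]
  dat1$between[dat1$unit == "u2"] <- "solo"
  expect_error(mixed_anova(dat1, between = "between"), "2 units")
})

test_that("Holm adjustment matches hand enumeration and its bounds", {
  expect_equal(holm_adjust(0.04), 0.04)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(66)
  for (rep in 1:20) {
    p <- runif(sample(1:8, 1))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))                    # never below raw
    expect_true(all(adj <= pmin(1, length(p) * p) |
                    adj <= cummax(pmin(1, length(p) * sort(p)))[rank(p)]))
    perm <- sample(length(p))
    expect_equal(holm_adjust(p[perm]), adj[perm]) # permutation invariance
  }
})

test_that("time post hocs enumerate labeled paired contrasts", {
  set.seed(67)
  n <- 7
  dat <- data.frame(unit = rep(paste0("u", 1:n), 3),
                    within = rep(c("t1", "t2", "t3"), each = n),
                    value = rnorm(3 * n))
  ph <- posthoc_time_contrasts(dat)
  expect_equal(ph$contrast, c("2vs1", "3vs1", "3vs2"))
  expect_equal(ph$p_holm, holm_adjust(ph$p_raw))

  # two time points: single contrast equals the closed-form paired t
  d2 <- dat[dat$within != "t3", ]
  ph2 <- posthoc_time_contrasts(d2)
  tt <- t.test(d2$value[d2$within == "t2"], d2$value[d2$within == "t1"],
               paired = TRUE)
  expect_equal(ph2$t, unname(tt$statistic))
  expect_equal(ph2$p_raw, tt$p.value)
  expect_equal(ph2$p_holm, tt$p.value)

  # identical paired values: t = 0, p = 1
  flat <- dat; flat$value <- rep(rnorm(n), 3)
  phf <- posthoc_time_contrasts(flat)
  expect_equal(phf$t, c(0, 0, 0))
  expect_equal(phf$p_raw, c(1, 1, 1))

  # restricted family adjusts within the family only
  phr <- posthoc_time_contrasts(dat, family = c("2vs1", "3vs1"))
  expect_equal(nrow(phr), 2)
  expect_error(posthoc_time_contrasts(dat, family = "4vs1"), "unknown")
})

test_that("rank-collapsed correlation ranks within groups before pooling", {
  # perfectly concordant within both groups
  x <- c(1, 2, 3, 4, 10, 20, 30)
  y <- c(2, 4, 6, 8, 1, 2, 3)
  g <- c(rep("a", 4), rep("b", 3))
  expect_equal(rank_collapse_correlation(x, y, g)$r, 1)

  # invariant under strictly increasing within-group transforms
  res <- rank_collapse_correlation(exp(x), y, g)
  expect_equal(res$r, 1)

  # hand-computed two groups of 4 against rank-then-Pearson by hand
  x2 <- c(5, 1, 3, 2, 40, 10, 20, 30)
  y2 <- c(2, 9, 4, 6, 1, 8, 6, 3)
  g2 <- rep(c("a", "b"), each = 4)
  rx <- c(rank(x2[1:4]), rank(x2[5:8]))
  ry <- c(rank(y2[1:4]), rank(y2[5:8]))
  hand_r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  res2 <- rank_collapse_correlation(x2, y2, g2)
  expect_equal(res2$r, hand_r)
  expect_equal(res2$n, 8)

  # single group, no ties: identical to Spearman's rho
  set.seed(68)
  x3 <- rnorm(12); y3 <- rnorm(12)
  expect_equal(rank_collapse_correlation(x3, y3)$r,
               cor(x3, y3, method = "spearman"))

  expect_error(rank_collapse_correlation(rep(1, 6), y2[1:6],
                                         rep(c("a", "b"), each = 3)),
               "constant")
  expect_error(rank_collapse_correlation(1:3, 1:3, rep("a", 3)),
               "n < 4")
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(69)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    res <- partial_correlation(x, y, z)
    rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
    expect_equal(res$r, cor(rx, ry), tolerance = 1e-10)
    # p from the t-transform with n - 3 df
    tstat <- res$r * sqrt((n - 3) / (1 - res$r^2))
    expect_equal(res$p, 2 * pt(-abs(tstat), n - 3))
  }

  # a control collinear with x makes the coefficient indeterminate (0/0)
  set.seed(70)
  x <- rnorm(10); y <- 0.8 * x + rnorm(10, 0, 0.3)
  expect_error(partial_correlation(x, y, x), "degenerate control")
  expect_error(partial_correlation(x, y, 2 * x + 1), "degenerate control")
})

test_that("orthogonal controls leave the Pearson correlation unchanged", {
  # construct z exactly uncorrelated with x and y
  set.seed(71)
  x <- rnorm(20); y <- rnorm(20); z0 <- rnorm(20)
  z <- resid(lm(z0 ~ x + y))
  res <- partial_correlation(x, y, z)
  expect_equal(res$r, cor(x, y), tolerance = 1e-10)
})
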