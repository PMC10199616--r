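make_2x2 <- function(mu, n = 3, sd = 0, seed = 1) {
  set.seed(seed)
  g <- expand.grid(factor1 = c("control", "mutant"),
                   factor2 = c("young", "old"))
  do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    data.frame(subject = paste0(g$factor1[i], g$factor2[i], seq_len(n)),
               factor1 = g$factor1[i], factor2 = g$factor2[i],
               value = mu[i] + rnorm(n, 0, sd))
  }))
}

test_that("two-way ANOVA matches explicit sums of squares on balanced data", {
  # hand-computable balanced 2x2, n = 3 per cell
  tbl <- make_2x2(c(10, 12, 14, 20), n = 3, sd = 1, seed = 2)
  res <- two_way_anova(tbl)
  # oracle: classical balanced two-way SS by explicit summation
  y <- tbl$value
  f1 <- tbl$factor1; f2 <- tbl$factor2
  gm <- mean(y)
  ss_a <- sum(tapply(y, f1, function(v) length(v) * (mean(v) - gm)^2))
  ss_b <- sum(tapply(y, f2, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, list(f1, f2), mean)
  ss_cells <- 3 * sum((cellm - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- sum((y - ave(y, f1, f2))^2)
  f_a <- (ss_a / 1) / (ss_e / 8)
  f_b <- (ss_b / 1) / (ss_e / 8)
  f_ab <- (ss_ab / 1) / (ss_e / 8)
  expect_equal(res$statistic, c(f_a, f_b, f_ab), tolerance = 1e-10)
  expect_equal(res$df, c(1, 1, 1))
})

test_that("two-way ANOVA flags empty cells and identical means give F ~ 0", {
  # identical cell means with within-cell spread: every effect SS is 0
  g <- expand.grid(factor1 = c("control", "mutant"),
                   factor2 = c("young", "old"))
  tbl <- do.call(rbind, lapply(seq_len(4), function(i) {
    data.frame(factor1 = g$factor1[i], factor2 = g$factor2[i],
               value = 10 + c(-1, 0, 1))
  }))
  res <- two_way_anova(tbl)
  expect_true(all(res$statistic < 1e-20))
  expect_true(all(res$p > 1 - 1e-10))
  tbl2 <- tbl[!(tbl$factor1 == "mutant" & tbl$factor2 == "old"), ]
  expect_error(two_way_anova(tbl2), "empty design cell")
})

test_that("ANOVA detects a strong main effect", {
  hits <- 0
  for (s in 1:50) {
    tbl <- make_2x2(c(0, 2, 0, 2), n = 10, sd = 1, seed = 100 + s)
    res <- two_way_anova(tbl)
    if (res$p[res$effect == "factor1"] < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 48)  # ~100% power at d = 2, n = 10/cell
})

test_that("Mann-Whitney exact p matches full enumeration", {
  tbl <- data.frame(subject = 1:6,
                    factor1 = rep(c("control", "mutant"), each = 3),
                    factor2 = "all",
                    value = c(1, 2, 3, 4, 5, 6))
  res <- pairwise_tests(tbl, method = "mann_whitney", adjust = "none")
  # U = 0; two-sided exact p = 2 * (1 / choose(6, 3)) = 0.1
  expect_equal(res$p, 0.1)
  expect_equal(as.numeric(res$statistic), 0)
})

test_that("Holm-Sidak follows the step-down formula and is monotone", {
  p <- c(0.01, 0.04, 0.20)
  adj <- ephyr:::holm_sidak(p)
  expect_equal(adj[1], 1 - (1 - 0.01)^3)
  expect_equal(adj[2], max(1 - (1 - 0.01)^3, 1 - (1 - 0.04)^2))
  expect_equal(adj[3], max(adj[2], 1 - (1 - 0.20)^1))
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  # scrambled input keeps pairing
  p2 <- c(0.20, 0.01, 0.04)
  expect_equal(ephyr:::holm_sidak(p2), adj[c(3, 1, 2)])
})

test_that("paired tests demand matched subjects and flag degeneracy", {
  tbl <- data.frame(subject = c(1:4, 1:4),
                    factor1 = rep(c("baseline", "drug"), each = 4),
                    factor2 = "all",
                    value = c(1, 2, 3, 4, 1, 2, 3, 4))
  res <- pairwise_tests(tbl, method = "wilcoxon", adjust = "none")
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
  tbl_bad <- tbl
  tbl_bad$subject[5:8] <- 5:8
  expect_error(pairwise_tests(tbl_bad, method = "t_paired"), "unmatched")
})

test_that("null calibration of the pairwise tests", {
  # label-permutation null: rejection rate compatible with alpha = 0.05
  set.seed(77)
  rej <- c(mw = 0, tt = 0)
  n_sim <- 400
  for (i in seq_len(n_sim)) {
    tbl <- data.frame(subject = 1:24,
                      factor1 = sample(rep(c("a", "b"), 12)),
                      factor2 = "all", value = rnorm(24))
    r1 <- pairwise_tests(tbl, method = "mann_whitney", adjust = "none")
    r2 <- pairwise_tests(tbl, method = "t_unpaired", adjust = "none")
    rej["mw"] <- rej["mw"] + (r1$p < 0.05)
    rej["tt"] <- rej["tt"] + (r2$p < 0.05)
  }
  for (k in names(rej)) {
    expect_gt(binom.test(rej[[k]], n_sim, 0.05)$p.value, 0.001)
  }
})

test_that("slope comparison: exact arithmetic and discrimination", {
  # slope of (1,4),(2,3),(3,2),(4,1) is exactly -1
  tbl <- data.frame(subject = "s1", group = "a",
                    trial = 1:4, value = c(4, 3, 2, 1))
  tbl <- rbind(tbl, data.frame(subject = "s2", group = "b",
                               trial = 1:4, value = c(4, 3, 2, 1)))
  res <- slope_compare(tbl)
  expect_equal(res$slopes$slope, c(-1, -1))
  expect_true(res$test$degenerate)

  set.seed(8)
  mk <- function(subj, grp, slope) {
    do.call(rbind, lapply(subj, function(s) {
      data.frame(subject = s, group = grp, trial = 9:12,
                 value = 50 + slope * (9:12) + rnorm(4, 0, 0.01))
    }))
  }
  tbl2 <- rbind(mk(paste0("a", 1:3), "ctl", -1), mk(paste0("b", 1:3), "mut", -3))
  res2 <- slope_compare(tbl2, trials = 9:12)
  expect_lt(res2$test$p, 0.01)
  expect_equal(res2$test$mean_1, -1, tolerance = 0.05)
  # subject with < 2 trials is excluded with a warning
  tbl3 <- rbind(tbl2, data.frame(subject = "c1", group = "ctl",
                                 trial = 9, value = 50))
  expect_warning(slope_compare(tbl3, trials = 9:12), "excluded")
})
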