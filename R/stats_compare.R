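#' Two-way ANOVA on a long-format comparison table
#'
#' Fits `value ~ factor1 * factor2` and reports F and p per effect
#' (factor1, factor2, interaction). Sums of squares are Type II by
#' default, appropriate for the mildly unbalanced designs typical of
#' per-animal electrophysiology and behavior tables; Type III is
#' available via `type` (fitted with sum-to-zero contrasts).
#'
#' @param tbl data frame with columns `factor1`, `factor2`, `value`
#'   (e.g. genotype x age group with one value per cell/animal).
#' @param type `"II"` or `"III"`.
#' @return data frame (`effect`, `df`, `statistic`, `p`), rows
#'   `factor1`, `factor2`, `factor1:factor2`.
#' @export
two_way_anova <- function(tbl, type = c("II", "III")) {
  type <- match.arg(type)
  need <- c("factor1", "factor2", "value")
  if (!all(need %in% names(tbl))) {
    stop("table needs columns factor1, factor2, value")
  }
  tbl$factor1 <- factor(tbl$factor1)
  tbl$factor2 <- factor(tbl$factor2)
  if (nlevels(tbl$factor1) < 2L || nlevels(tbl$factor2) < 2L) {
    stop("need at least 2 levels per factor")
  }
  counts <- table(tbl$factor1, tbl$factor2)
  if (any(counts == 0L)) {
    i <- which(counts == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: factor1=%s, factor2=%s",
                 rownames(counts)[i[1]], colnames(counts)[i[2]]))
  }
  if (type == "III") {
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old))
  }
  fit <- stats::lm(value ~ factor1 * factor2, data = tbl)
  a <- car::Anova(fit, type = type)
  rows <- c("factor1", "factor2", "factor1:factor2")
  data.frame(
    effect = rows,
    df = a[rows, "Df"],
    statistic = a[rows, "F value"],
    p = a[rows, "Pr(>F)"])
}

# Holm-Sidak step-down adjustment: sort p ascending, adjust
# p_(i) -> 1 - (1 - p_(i))^(m - i + 1), enforce monotonicity, unsort.
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(pmax(adj, p[o]), 1)  # never below raw p (exact ties included)
  out
}

#' Pairwise two-group tests with optional Holm-Sidak adjustment
#'
#' Runs one two-sample test per stratum of `factor2`, comparing the two
#' levels of `factor1` (e.g. genotype within each age group), as the
#' post-hoc family after an omnibus ANOVA. Rank tests use exact p-values
#' for small samples without ties (the default behaviour of the
#' underlying tests) and the normal approximation with tie correction
#' otherwise. Paired methods match subjects by `subject`.
#'
#' @param tbl data frame with columns `subject`, `factor1` (2 levels),
#'   `factor2` (strata), `value`.
#' @param method `"mann_whitney"`, `"t_unpaired"`, `"t_paired"` or
#'   `"wilcoxon"` (matched-pairs signed-rank).
#' @param adjust `"holm_sidak"` or `"none"`.
#' @return data frame (`stratum`, `test`, `statistic`, `df`, `p`,
#'   `adjusted_p`, `direction`, `degenerate`); `direction` is the sign of
#'   (first level minus second level); `degenerate` flags strata with no
#'   usable variation (p reported as 1).
#' @export
pairwise_tests <- function(tbl, method = c("mann_whitney", "t_unpaired",
                                           "t_paired", "wilcoxon"),
                           adjust = c("holm_sidak", "none")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  need <- c("factor1", "factor2", "value")
  if (!all(need %in% names(tbl))) {
    stop("table needs columns factor1, factor2, value (and subject for paired tests)")
  }
  tbl$factor1 <- factor(tbl$factor1)
  if (nlevels(tbl$factor1) != 2L) stop("factor1 must have exactly 2 levels")
  lv <- levels(tbl$factor1)
  paired <- method %in% c("t_paired", "wilcoxon")
  if (paired && !"subject" %in% names(tbl)) {
    stop("paired tests need a subject column")
  }
  strata <- unique(as.character(tbl$factor2))
  rows <- list()
  for (s in strata) {
    d <- tbl[tbl$factor2 == s, , drop = FALSE]
    x <- d$value[d$factor1 == lv[1]]
    y <- d$value[d$factor1 == lv[2]]
    if (paired) {
      sx <- d$subject[d$factor1 == lv[1]]
      sy <- d$subject[d$factor1 == lv[2]]
      if (!setequal(sx, sy) || anyDuplicated(sx) || anyDuplicated(sy)) {
        stop("paired test with unmatched subjects in stratum ", s)
      }
      y <- y[match(sx, sy)]
    }
    degenerate <- FALSE
    res <- switch(method,
      mann_whitney = {
        if (length(unique(c(x, y))) == 1L) {
          degenerate <- TRUE
          list(statistic = NA_real_, parameter = NA_real_, p.value = 1)
        } else {
          suppressWarnings(stats::wilcox.test(x, y))
        }
      },
      t_unpaired = {
        if (stats::sd(c(x, y)) == 0) {
          degenerate <- TRUE
          list(statistic = NA_real_, parameter = NA_real_, p.value = 1)
        } else {
          stats::t.test(x, y)
        }
      },
      t_paired = {
        if (stats::sd(x - y) == 0) {
          degenerate <- TRUE
          list(statistic = NA_real_, parameter = NA_real_, p.value = 1)
        } else {
          stats::t.test(x, y, paired = TRUE)
        }
      },
      wilcoxon = {
        if (all(x == y)) {
          degenerate <- TRUE
          list(statistic = NA_real_, parameter = NA_real_, p.value = 1)
        } else {
          suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
        }
      })
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = s, test = method,
      statistic = as.numeric(res$statistic %||% NA_real_),
      df = as.numeric(res$parameter %||% NA_real_),
      p = res$p.value,
      direction = sign(mean(x) - mean(y)),
      degenerate = degenerate)
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- if (adjust == "holm_sidak") holm_sidak(out$p) else out$p
  out[, c("stratum", "test", "statistic", "df", "p", "adjusted_p",
          "direction", "degenerate")]
}

#' Compare per-subject learning-curve slopes between two groups
#'
#' For each subject, a least-squares slope is fitted over the designated
#' trials (e.g. the relearning trials after a goal relocation); the two
#' groups' slope sets are compared by a two-tailed unpaired t test.
#' Subjects with fewer than 2 usable trials are excluded with a warning.
#'
#' @param tbl data frame with columns `subject`, `group` (2 levels),
#'   `trial`, `value` (e.g. latency).
#' @param trials trial numbers entering the slope (default all present).
#' @return list with `slopes` (per-subject data frame) and `test`
#'   (one-row data frame: `statistic`, `df`, `p`, `mean_1`, `mean_2`,
#'   `degenerate`).
#' @export
slope_compare <- function(tbl, trials = NULL) {
  need <- c("subject", "group", "trial", "value")
  if (!all(need %in% names(tbl))) {
    stop("table needs columns subject, group, trial, value")
  }
  if (!is.null(trials)) tbl <- tbl[tbl$trial %in% trials, , drop = FALSE]
  tbl$group <- factor(tbl$group)
  if (nlevels(tbl$group) != 2L) stop("group must have exactly 2 levels")
  subj <- unique(tbl$subject)
  rows <- list()
  for (s in subj) {
    d <- tbl[tbl$subject == s, , drop = FALSE]
    if (nrow(d) < 2L || length(unique(d$trial)) < 2L) {
      warning("subject ", s, " has fewer than 2 trials; excluded")
      next
    }
    sl <- stats::coef(stats::lm(value ~ trial, data = d))[["trial"]]
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, group = as.character(d$group[1]), slope = sl)
  }
  slopes <- do.call(rbind, rows)
  lv <- levels(tbl$group)
  a <- slopes$slope[slopes$group == lv[1]]
  b <- slopes$slope[slopes$group == lv[2]]
  degenerate <- stats::sd(c(a, b)) == 0
  if (degenerate) {
    test <- data.frame(statistic = NA_real_, df = NA_real_, p = 1,
                       mean_1 = mean(a), mean_2 = mean(b),
                       degenerate = TRUE)
  } else {
    tt <- stats::t.test(a, b)
    test <- data.frame(statistic = as.numeric(tt$statistic),
                       df = as.numeric(tt$parameter), p = tt$p.value,
                       mean_1 = mean(a), mean_2 = mean(b),
                       degenerate = FALSE)
  }
  list(slopes = slopes, test = test)
}
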