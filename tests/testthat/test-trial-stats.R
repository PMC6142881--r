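make_factorial <- function(levels_list, reps, effects_fun, sd = 1,
                           seed = 1) {
  set.seed(seed)
  d <- expand.grid(c(levels_list, list(rep = seq_len(reps))),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$y <- effects_fun(d) + stats::rnorm(nrow(d), 0, sd)
  d
}

test_that("factorial ANOVA matches the brute-force SS decomposition", {
  for (seed in 1:5) {
    d <- make_factorial(list(landrace = c("P", "F"),
                             inoc = c("minus", "plus"),
                             site = c("N", "S")),
                        reps = 3,
                        function(d) 10 + 2 * (d$landrace == "P") -
                          1.5 * (d$inoc == "plus") +
                          0.8 * (d$landrace == "P") * (d$site == "S"),
                        seed = seed)
    tab <- factorial_anova(d, "y", c("landrace", "inoc", "site"))
    orc <- oracle_factorial_ss(d, "y", c("landrace", "inoc", "site"))
    for (nm in names(orc$ss)) {
      row <- tab[tab$term == nm, ]
      expect_equal(row$sumsq, unname(orc$ss[nm]), tolerance = 1e-10)
      expect_equal(row$df, unname(orc$df[nm]))
    }
    res <- tab[tab$term == "Residuals", ]
    expect_equal(res$sumsq, orc$ss_residual, tolerance = 1e-10)
    expect_equal(res$df, orc$df_residual)
    # decomposition is exact under balance
    expect_equal(sum(tab$sumsq), orc$ss_total, tolerance = 1e-8)
    expect_equal(sum(tab$df), nrow(d) - 1L)
  }
})

test_that("statistics are invariant to observation order", {
  d <- make_factorial(list(a = c("x", "y", "z"), b = c("u", "v")),
                      reps = 4, function(d) 3 * (d$a == "x"), seed = 9)
  t1 <- factorial_anova(d, "y", c("a", "b"))
  t2 <- factorial_anova(d[sample(nrow(d)), ], "y", c("a", "b"))
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("noise-free responses give infinite F with p = 0", {
  d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:3,
                   stringsAsFactors = FALSE)
  d$y <- 2 * (d$a == "x") + 5 * (d$b == "v")  # exact cell means
  tab <- factorial_anova(d, "y", c("a", "b"))
  expect_equal(tab$statistic[tab$term == "a"], Inf)
  expect_equal(tab$p.value[tab$term == "a"], 0)
  expect_equal(tab$sumsq[tab$term == "Residuals"], 0)
})

test_that("unbalanced or degenerate designs are rejected", {
  d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:3,
                   stringsAsFactors = FALSE)
  d$y <- stats::rnorm(nrow(d))
  expect_error(factorial_anova(d[-1, ], "y", c("a", "b")), "unbalanced")
  d1 <- d[d$rep == 1, ]
  expect_error(factorial_anova(d1, "y", c("a", "b")), "replicates")
  d$a2 <- "x"
  expect_error(factorial_anova(d, "y", c("a2", "b")), "levels")
})

test_that("an additive block factor is accepted and absorbs block SS", {
  d <- make_factorial(list(a = c("x", "y"), b = c("u", "v")),
                      reps = 4, function(d) 2 * (d$a == "x"), seed = 4)
  d$block <- d$rep
  tab <- factorial_anova(d, "y", c("a", "b"), block = "block")
  expect_true("block" %in% tab$term)
  expect_equal(sum(tab$df), nrow(d) - 1L)
})

test_that("Duncan ranges use protected studentized-range quantiles", {
  # frozen from an independent numerical oracle for alpha = 0.05
  # (scipy.stats.studentized_range at levels (1 - 0.05)^(p - 1))
  frozen <- data.frame(p = c(2, 3, 4, 5, 3, 5),
                       df = c(10, 10, 10, 10, 30, 30),
                       q = c(3.1511, 3.2928, 3.3763, 3.4297,
                             3.0352, 3.1985))
  for (i in seq_len(nrow(frozen))) {
    got <- duncan_critical_range(frozen$p[i], frozen$df[i],
                                 ms_error = 1, n = 1)
    expect_equal(got, frozen$q[i], tolerance = 1e-4)
  }
  # scale: ranges are proportional to sqrt(ms/n)
  expect_equal(duncan_critical_range(3, 10, ms_error = 4, n = 4),
               duncan_critical_range(3, 10, ms_error = 1, n = 1))
})

test_that("Duncan letters handle degenerate separations", {
  all_same <- duncan_mrt(c(a = 5, b = 5, c = 5), n = 4,
                         ms_error = 0, df_error = 9)
  expect_equal(unique(all_same$letters), "a")

  far <- duncan_mrt(c(hi = 100, lo = 0), n = 4, ms_error = 1,
                    df_error = 9)
  expect_equal(far$letters, c("a", "b"))

  zero_ms <- duncan_mrt(c(a = 3, b = 2, c = 2, d = 1), n = 4,
                        ms_error = 0, df_error = 9)
  expect_equal(zero_ms$letters, c("a", "b", "b", "c"))
})

test_that("Duncan letters match the exhaustive all-spans oracle", {
  set.seed(21)
  for (rep in 1:30) {
    k <- sample(3:8, 1)
    means <- round(stats::rnorm(k, 10, sample(c(0.3, 1, 3), 1)), 2)
    names(means) <- paste0("L", seq_len(k))
    ms <- stats::runif(1, 0.05, 2)
    n <- sample(2:6, 1)
    df <- sample(5:40, 1)
    got <- duncan_mrt(means, n = n, ms_error = ms, df_error = df)
    want <- oracle_duncan_letters(means, n = n, ms_error = ms,
                                  df_error = df)
    expect_equal(got$letters, unname(want), info = paste("rep", rep))
    expect_equal(got$level, names(want))

    # transitive consistency: shared letters cover contiguous ranks
    for (ch in unique(unlist(strsplit(got$letters, "")))) {
      idx <- grep(ch, got$letters, fixed = TRUE)
      expect_equal(idx, seq(min(idx), max(idx)))
    }
  }
})

test_that("correlation and regression match their definitions", {
  x <- c(1.2, 2.3, 3.1, 4.8, 5.5, 6.1, 7.9, 8.2, 9.4, 10.0)
  y <- c(2.0, 2.9, 3.8, 5.1, 5.0, 7.2, 7.7, 8.9, 9.1, 11.2)
  ct <- pearson_correlation(x, y)
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$r, r_def, tolerance = 1e-12)
  tt <- r_def * sqrt(8 / (1 - r_def^2))
  expect_equal(ct$p.value, 2 * stats::pt(-abs(tt), 8), tolerance = 1e-12)

  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -2 * x + 3)$r, -1)
  expect_error(pearson_correlation(x, rep(1, 10)), "zero variance")

  # normal-equations oracle on a fixed 8-point set
  x8 <- c(0.5, 1, 2, 3.5, 4, 6, 7, 9); y8 <- c(1, 3, 2, 5, 6, 7, 6, 10)
  fit <- linear_regression(x8, y8)
  sxx <- sum((x8 - mean(x8))^2)
  slope <- sum((x8 - mean(x8)) * (y8 - mean(y8))) / sxx
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y8) - slope * mean(x8),
               tolerance = 1e-12)
  expect_equal(fit$r_squared, pearson_correlation(x8, y8)$r^2,
               tolerance = 1e-12)

  exact <- linear_regression(1:5, 2 * (1:5) + 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)
})

test_that("protected reporting gates mean separation on the omnibus F", {
  # no landrace effect: all levels must share one letter
  d <- make_factorial(list(landrace = c("A", "B", "C"),
                           inoc = c("m", "p")),
                      reps = 4, function(d) 0, sd = 1, seed = 12)
  rep_null <- trial_stats_report(d, "y", c("landrace", "inoc"))
  if (rep_null$anova$p.value[rep_null$anova$term == "landrace"] > 0.05) {
    expect_equal(unique(rep_null$letters$landrace$letters), "a")
  }
  # strong effect: top and bottom levels must differ
  d2 <- make_factorial(list(landrace = c("A", "B", "C"),
                            inoc = c("m", "p")),
                       reps = 4,
                       function(d) 10 * (d$landrace == "A"),
                       sd = 0.5, seed = 13)
  rep_eff <- trial_stats_report(d2, "y", c("landrace", "inoc"))
  lg <- rep_eff$letters$landrace
  top <- lg$letters[1]; bottom <- lg$letters[nrow(lg)]
  expect_false(any(strsplit(top, "")[[1]] %in%
                     strsplit(bottom, "")[[1]]))
})
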