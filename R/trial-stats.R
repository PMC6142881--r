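# Statistics for balanced factorial field trials: fixed-effects ANOVA,
# Duncan's multiple range test with letter grouping, and simple
# correlation/regression summaries.

#' Balanced factorial analysis of variance
#'
#' Fits a fixed-effects factorial model (all main effects and, by
#' default, all interactions) to a balanced dataset and returns the
#' classical ANOVA decomposition. Under balance the Type I and Type III
#' sums of squares coincide, so the table is unambiguous. An optional
#' block factor enters additively (no block interactions), matching a
#' randomized-complete-block layout.
#'
#' Unbalanced designs are rejected outright: with unequal replication
#' the SS decomposition is no longer unique and silently picking one
#' convention would be misleading.
#'
#' When the residual mean square is zero (noise-free responses) the F
#' statistics are reported as `Inf` with p-values of 0 rather than
#' failing.
#'
#' @param data Data frame holding the response and factor columns.
#' @param response Name of the numeric response column.
#' @param factors Character vector of treatment factor column names
#'   (each with >= 2 levels, crossed and equally replicated).
#' @param block Optional name of a block/replicate column, fitted as an
#'   additive factor.
#' @param interactions Include all factor interactions (default TRUE)?
#' @return Data frame of class `"anova_table"` with columns `term`,
#'   `df`, `sumsq`, `meansq`, `statistic`, `p.value`; the last row is
#'   the residual. Attribute `"ms_error"` and `"df_error"` carry the
#'   residual mean square and df for downstream mean separation.
#' @examples
#' d <- expand.grid(landrace = c("A", "B"), inoc = c("minus", "plus"),
#'                  rep = 1:4)
#' d$y <- rnorm(nrow(d), mean = ifelse(d$landrace == "A", 10, 12))
#' factorial_anova(d, "y", c("landrace", "inoc"))
#' @export
factorial_anova <- function(data, response, factors, block = NULL,
                            interactions = TRUE) {
  stopifnot(is.data.frame(data), is.character(response),
            length(response) == 1L, is.character(factors),
            length(factors) >= 1L)
  cols <- c(response, factors, block)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- data[[response]]
  if (!is.numeric(y) || anyNA(y)) {
    stop("response must be numeric with no missing values", call. = FALSE)
  }
  for (f in c(factors, block)) data[[f]] <- factor(data[[f]])
  for (f in factors) {
    if (nlevels(data[[f]]) < 2L) {
      stop("factor '", f, "' needs at least 2 levels", call. = FALSE)
    }
  }
  counts <- table(data[factors])
  if (length(unique(c(counts))) != 1L || any(counts == 0L)) {
    stop("unbalanced design: all factor-level combinations must have ",
         "equal replication", call. = FALSE)
  }
  if (c(counts)[1] < 2L && is.null(block) && interactions) {
    stop("at least 2 replicates per cell are required", call. = FALSE)
  }

  op <- paste(factors, collapse = if (interactions) " * " else " + ")
  rhs <- if (is.null(block)) op else paste(block, "+", op)
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::aov(fml, data = data)
  tab <- summary(fit)[[1]]
  term <- trimws(rownames(tab))
  df <- tab[["Df"]]
  ss <- tab[["Sum Sq"]]
  ms <- ss / df
  n_terms <- length(term)
  if (df[n_terms] < 1L) {
    stop("zero residual degrees of freedom: add replication or drop terms",
         call. = FALSE)
  }
  ms_err <- ms[n_terms]
  # a residual SS that is numerically negligible against the model SS
  # means a noise-free response: report the F sentinel, not overflow
  if (ss[n_terms] <= 1e-10 * sum(ss[-n_terms])) ms_err <- 0
  fstat <- c(if (ms_err > 0) ms[-n_terms] / ms_err else
               ifelse(ms[-n_terms] > 1e-10 * sum(ss), Inf, NaN), NA)
  pval <- c(stats::pf(fstat[-n_terms], df[-n_terms], df[n_terms],
                      lower.tail = FALSE), NA)
  out <- data.frame(term = c(term[-n_terms], "Residuals"),
                    df = df, sumsq = ss, meansq = ms,
                    statistic = fstat, p.value = pval,
                    stringsAsFactors = FALSE)
  attr(out, "ms_error") <- ms_err
  attr(out, "df_error") <- df[n_terms]
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Duncan's multiple range test with letter grouping
#'
#' Separates a set of treatment means using Duncan's multiple range
#' test. Means are ranked in descending order; the extremes of a span
#' of `p` consecutive means are significantly different when their
#' difference exceeds the critical range
#' \deqn{R_p = q(1 - \alpha_p, p, df) \sqrt{MS_{error} / n}}
#' with the protection level `alpha_p = 1 - (1 - alpha)^(p - 1)` and
#' `q` the studentized-range quantile. A span whose extremes are not
#' significantly different is declared homogeneous and, per the
#' test's protection rule, so is every span inside it. Letters are
#' assigned one per maximal homogeneous span: levels that share any
#' letter are not significantly different.
#'
#' Duncan's test is conventionally run only after a significant
#' omnibus F test ("protected" usage); this function performs the mean
#' separation itself and leaves that gate to the caller (see
#' [trial_stats_report()], which applies it).
#'
#' @param means Named numeric vector of level means.
#' @param n Common replication per level.
#' @param ms_error Residual mean square from the ANOVA (>= 0).
#' @param df_error Residual degrees of freedom (>= 1).
#' @param alpha Significance level, default 0.05.
#' @return Data frame of class `"letter_grouping"` with columns
#'   `level`, `mean`, `se` (standard error of a level mean,
#'   `sqrt(ms_error/n)`) and `letters`, ordered by descending mean.
#' @examples
#' duncan_mrt(c(a = 10, b = 9.8, c = 5), n = 4, ms_error = 0.5,
#'            df_error = 9)
#' @export
duncan_mrt <- function(means, n, ms_error, df_error, alpha = 0.05) {
  stopifnot(is.numeric(means), length(means) >= 1L,
            is.numeric(n), length(n) == 1L, n >= 1,
            is.numeric(ms_error), ms_error >= 0,
            is.numeric(df_error), df_error >= 1,
            is.numeric(alpha), alpha > 0, alpha < 1)
  if (is.null(names(means))) {
    names(means) <- paste0("level", seq_along(means))
  }
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  se_mean <- sqrt(ms_error / n)

  crit <- duncan_critical_range(seq_len(k), df_error, ms_error, n, alpha)

  # span i..j (in rank order) is homogeneous by its own test when the
  # extreme difference does not exceed the critical range for its width
  homog <- function(i, j) (m[i] - m[j]) <= crit[j - i + 1]

  # maximal homogeneous spans; protection: subspans of a homogeneous
  # span are never re-tested
  spans <- list()
  j_max <- 0L
  for (i in seq_len(k)) {
    j <- i
    while (j < k && homog(i, j + 1L)) j <- j + 1L
    if (j > j_max) {            # not contained in a previous span
      spans[[length(spans) + 1L]] <- c(i, j)
      j_max <- j
    }
  }
  letters_by_level <- rep("", k)
  for (s in seq_along(spans)) {
    idx <- spans[[s]][1]:spans[[s]][2]
    letters_by_level[idx] <- paste0(letters_by_level[idx],
                                    make_group_letter(s))
  }
  out <- data.frame(level = names(m), mean = unname(m),
                    se = se_mean, letters = letters_by_level,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("letter_grouping", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Duncan critical ranges
#'
#' Critical range for comparing the extremes of a span of `p` ranked
#' means under Duncan's protection levels. Exposed mainly for
#' inspection and testing.
#'
#' @param p Integer vector of span widths (>= 1; width 1 gives 0).
#' @param df_error,ms_error,n,alpha As in [duncan_mrt()].
#' @return Numeric vector of critical ranges, same length as `p`.
#' @export
duncan_critical_range <- function(p, df_error, ms_error, n, alpha = 0.05) {
  se <- sqrt(ms_error / n)
  vapply(p, function(pp) {
    if (pp < 2L) return(0)
    alpha_p <- 1 - (1 - alpha)^(pp - 1)
    stats::qtukey(1 - alpha_p, nmeans = pp, df = df_error) * se
  }, numeric(1))
}

# letter labels a, b, ..., z, aa, ab, ... for group indices
make_group_letter <- function(i) {
  out <- ""
  i <- i - 1L
  repeat {
    out <- paste0(letters[(i %% 26L) + 1L], out)
    i <- i %/% 26L - 1L
    if (i < 0L) break
  }
  out
}

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation between two numeric vectors with the
#' two-sided p-value from the t transform on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @return A list with elements `r`, `p.value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("'x' and 'y' differ in length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' Simple linear regression
#'
#' Ordinary least-squares fit of `y` on `x` with slope, intercept and
#' coefficient of determination (which equals the squared Pearson
#' correlation).
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` must vary.
#' @return A list with elements `slope`, `intercept`, `r_squared`,
#'   `p.value` (two-sided, for the slope) and `n`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("'x' and 'y' differ in length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate 'x': zero variance",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       r_squared = sm$r.squared,
       p.value = sm$coefficients[2, 4], n = length(x))
}

#' ANOVA plus protected Duncan letters for one response
#'
#' Runs [factorial_anova()] for a response and, for each treatment
#' factor, attaches Duncan letter groupings. Following protected usage,
#' letters are separated only when the factor's F test is significant
#' at `alpha`; otherwise all levels share the letter "a". Set
#' `protected = FALSE` to separate means regardless of the omnibus
#' test.
#'
#' @inheritParams factorial_anova
#' @param alpha Significance level for both the omnibus gate and the
#'   range test.
#' @param protected Gate mean separation on a significant F?
#' @return A list with elements `anova` (the [factorial_anova()] table)
#'   and `letters` (a named list of [duncan_mrt()] groupings, one per
#'   factor).
#' @export
trial_stats_report <- function(data, response, factors, block = NULL,
                               alpha = 0.05, protected = TRUE) {
  tab <- factorial_anova(data, response, factors, block = block)
  ms_err <- attr(tab, "ms_error")
  df_err <- attr(tab, "df_error")
  groups <- lapply(factors, function(f) {
    mns <- tapply(data[[response]], data[[f]], mean)
    n_per <- length(data[[response]]) / length(mns)
    pv <- tab$p.value[tab$term == f]
    if (protected && length(pv) == 1L && !is.na(pv) && pv > alpha) {
      g <- data.frame(level = names(sort(mns, decreasing = TRUE)),
                      mean = unname(sort(mns, decreasing = TRUE)),
                      se = sqrt(ms_err / n_per), letters = "a",
                      stringsAsFactors = FALSE)
      class(g) <- c("letter_grouping", "data.frame")
      attr(g, "alpha") <- alpha
      g
    } else {
      duncan_mrt(mns, n = n_per, ms_error = ms_err, df_error = df_err,
                 alpha = alpha)
    }
  })
  names(groups) <- factors
  list(anova = tab, letters = groups)
}
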