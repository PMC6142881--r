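# Independent brute-force oracles used across the suite. These are
# deliberately naive re-derivations from definitions, kept separate
# from the package's own code paths.

# Balanced factorial sums of squares by direct mean decomposition:
# each term's SS is computed from marginal means of the raw data, and
# the residual by subtraction from the total.
oracle_factorial_ss <- function(data, response, factors) {
  y <- data[[response]]
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  terms <- list()
  for (k in seq_along(factors)) {
    combos <- utils::combn(factors, k, simplify = FALSE)
    for (cmb in combos) terms[[paste(cmb, collapse = ":")]] <- cmb
  }
  ss <- numeric(length(terms))
  df <- numeric(length(terms))
  names(ss) <- names(df) <- names(terms)
  # effect of a term = cell mean of its factors minus sum of all
  # lower-order effects (inclusion-exclusion via recursion)
  effect_of <- function(cmb) {
    key <- interaction(data[cmb], drop = FALSE, lex.order = TRUE)
    cell_mean <- stats::ave(y, key)
    eff <- cell_mean - grand
    if (length(cmb) > 1L) {
      for (k in seq_len(length(cmb) - 1L)) {
        for (sub in utils::combn(cmb, k, simplify = FALSE)) {
          eff <- eff - effect_of(sub)
        }
      }
    }
    eff
  }
  for (nm in names(terms)) {
    cmb <- terms[[nm]]
    eff <- effect_of(cmb)
    ss[nm] <- sum(eff^2)
    df[nm] <- prod(vapply(cmb, function(f) {
      length(unique(data[[f]])) - 1L
    }, numeric(1)))
  }
  ss_res <- ss_total - sum(ss)
  df_res <- length(y) - 1L - sum(df)
  list(ss = ss, df = df, ss_residual = ss_res, df_residual = df_res,
       ss_total = ss_total)
}

# All-spans Duncan oracle: tests every contiguous span of the ranked
# means against its own critical range, then assigns one letter per
# maximal homogeneous span (protection: subspans of a homogeneous span
# are homogeneous).
oracle_duncan_letters <- function(means, n, ms_error, df_error,
                                  alpha = 0.05) {
  k <- length(means)
  m <- sort(means, decreasing = TRUE)
  pass <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      p <- j - i + 1L
      crit <- if (p < 2L) 0 else {
        ap <- 1 - (1 - alpha)^(p - 1)
        stats::qtukey(1 - ap, p, df_error) * sqrt(ms_error / n)
      }
      pass[i, j] <- (m[i] - m[j]) <= crit
    }
  }
  maximal <- list()
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (!pass[i, j]) next
      contained <- FALSE
      for (a in seq_len(k)) {
        for (b in a:k) {
          if (pass[a, b] && (a < i || b > j) && a <= i && b >= j) {
            contained <- TRUE
          }
        }
      }
      if (!contained) maximal[[length(maximal) + 1L]] <- c(i, j)
    }
  }
  lab <- rep("", k)
  ord <- order(vapply(maximal, `[`, numeric(1), 1L))
  for (s in seq_along(ord)) {
    idx <- maximal[[ord[s]]][1]:maximal[[ord[s]]][2]
    lab[idx] <- paste0(lab[idx], letters[s])
  }
  names(lab) <- names(m)
  lab
}

# Exhaustive SSR oracle: for every start and unit length, extend the
# tandem run copy by copy with direct substring comparison; keep
# maximal, primitive-motif, threshold-passing runs; then apply
# longest-run-wins overlap suppression.
oracle_scan_ssrs <- function(seq, min_unit = 1L, max_unit = 6L,
                             min_repeats = c(8L, 5L, 4L, 4L, 4L, 4L)) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  is_primitive <- function(motif) {
    u <- nchar(motif)
    for (p in seq_len(u - 1L)) {
      if (u %% p == 0L &&
          paste(rep(substr(motif, 1L, p), u / p), collapse = "") == motif)
        return(FALSE)
    }
    TRUE
  }
  hits <- list()
  for (u in min_unit:max_unit) {
    start <- 1L
    while (start + 2L * u - 1L <= n) {
      motif <- paste(chars[start:(start + u - 1L)], collapse = "")
      if (grepl("[^ACGT]", motif) || !is_primitive(motif)) {
        start <- start + 1L
        next
      }
      count <- 1L
      while (start + (count + 1L) * u - 1L <= n &&
             paste(chars[(start + count * u):(start + (count + 1L) * u - 1L)],
                   collapse = "") == motif) {
        count <- count + 1L
      }
      # keep only true run starts: position start-1 must not continue
      # the period (otherwise this is the suffix of a longer run)
      left_ext <- start > 1L && chars[start - 1L] == chars[start + u - 1L]
      right_end <- start + count * u - 1L
      if (count >= min_repeats[u] && !left_ext) {
        hits[[length(hits) + 1L]] <- data.frame(
          motif = motif, repeat_count = count, start = start,
          end = right_end, stringsAsFactors = FALSE)
      }
      start <- start + 1L
    }
  }
  if (!length(hits)) {
    return(data.frame(motif = character(), repeat_count = integer(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  # longest run wins on overlap (ties: earlier start, shorter unit)
  out <- out[order(-(out$end - out$start + 1L), out$start,
                   nchar(out$motif)), , drop = FALSE]
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    ov <- keep & !(out$end[i] < out$start | out$start[i] > out$end)
    keep[i] <- !any(ov)
  }
  out <- out[keep, c("motif", "repeat_count", "start", "end")]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

reverse_complement <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# small noise-free trial for exactness checks
zero_noise_config <- function(seed = 7L, replicates = 4L) {
  trial_sim_config(replicates = replicates,
                   sd = c(shoot_dm = 0, nodule_dm = 0, n_pct = 0,
                          c_pct = 0, delta15n = 0),
                   reference = data.frame(
                     site = c("SiteA", "SiteB"),
                     mean = c(3.95, 3.04), sd = c(0, 0), n = 9L),
                   bvalue = data.frame(
                     landrace = rep(c("GlasshouseA", "GlasshouseB"),
                                    each = 2L),
                     organ = rep(c("shoot", "root"), 2L),
                     delta15n = c(-3.68, -2.60, -3.99, -3.31),
                     sd = 0, n_content_mg = c(100, 50, 100, 50)),
                   seed = seed)
}

# lexicographically smallest rotation, for comparing motif classes
oracle_rotation <- function(motif) {
  m <- strsplit(motif, "")[[1]]
  min(vapply(seq_along(m), function(i) {
    paste(c(m[i:length(m)], if (i > 1) m[seq_len(i - 1L)]),
          collapse = "")
  }, character(1)))
}
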