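# Synthetic study generator: factorial field trials with planted
# treatment effects, reference-plant delta-15N draws, glasshouse
# B-value measurements, and SSR sequences with planted tandem arrays.
# Every draw is Gaussian around a configured true mean, so recovering
# the configured values through the analysis pipeline is a well-posed
# check at any noise level and exact at SD = 0.

#' Configuration for a synthetic field trial
#'
#' Builds the configuration object consumed by [generate_trial()]. The
#' default configuration emulates a two-site trial of five landraces
#' with and without inoculant, four replicate plots per treatment cell,
#' with cell means and within-cell standard deviations on the scale of
#' a West African groundnut landrace trial: shoot dry matter around
#' 15-27 g/plant, shoot N near 3%, legume delta-15N between +1.0 and
#' +1.9 permil, site reference means of +3.95 and +3.04 permil, and a
#' B value near -3.8 permil. Within-cell SDs default to twice the
#' reported cell standard errors of such trials (SE x sqrt(4 reps)).
#'
#' @param sites Character vector of site labels.
#' @param landraces Character vector of landrace labels.
#' @param inoculation Character vector of inoculation levels.
#' @param replicates Replicate plots per treatment cell (>= 2).
#' @param cell_means Data frame with one row per site x landrace x
#'   inoculation cell and numeric columns `shoot_dm`, `nodule_dm`,
#'   `n_pct`, `c_pct`, `delta15n` giving the true cell means. When
#'   `NULL`, a default table on the scale described above is built,
#'   with planted landrace, inoculation and interaction effects.
#' @param sd Named numeric vector of within-cell SDs for the same five
#'   measurements (>= 0; zero gives noise-free data).
#' @param reference Data frame with columns `site`, `mean`, `sd`, `n`
#'   describing per-site reference-plant delta-15N draws.
#' @param bvalue Data frame with columns `landrace`, `organ`,
#'   `delta15n`, `sd`, `n_content_mg` describing the glasshouse
#'   B-value plants (true organ means; `n` replicate pots are drawn
#'   via `bvalue_reps`).
#' @param bvalue_reps Replicate pots per glasshouse landrace.
#' @param seed Integer random seed; fixes the full dataset.
#' @return A list of class `"trial_sim_config"`.
#' @export
trial_sim_config <- function(sites = c("SiteA", "SiteB"),
                             landraces = c("Puffeun", "Dowie", "Funsi",
                                           "Sigiri", "Boli"),
                             inoculation = c("uninoculated", "inoculated"),
                             replicates = 4L,
                             cell_means = NULL,
                             sd = c(shoot_dm = 2.0, nodule_dm = 1.6,
                                    n_pct = 0.25, c_pct = 1.5,
                                    delta15n = 0.25),
                             reference = NULL,
                             bvalue = NULL,
                             bvalue_reps = 3L,
                             seed = 1L) {
  stopifnot(length(sites) >= 1L, length(landraces) >= 1L,
            length(inoculation) >= 1L, replicates >= 2L,
            all(sd >= 0), bvalue_reps >= 1L)
  if (is.null(cell_means)) {
    cell_means <- default_cell_means(sites, landraces, inoculation)
  }
  need <- c("site", "landrace", "inoculation", "shoot_dm", "nodule_dm",
            "n_pct", "c_pct", "delta15n")
  if (!all(need %in% names(cell_means))) {
    stop("'cell_means' needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n_cells <- length(sites) * length(landraces) * length(inoculation)
  if (nrow(cell_means) != n_cells) {
    stop("'cell_means' must have one row per factorial cell (",
         n_cells, ")", call. = FALSE)
  }
  if (is.null(reference)) {
    reference <- data.frame(site = sites,
                            mean = rep_len(c(3.95, 3.04), length(sites)),
                            sd = rep_len(c(0.63, 0.88), length(sites)),
                            n = 9L)
  }
  if (is.null(bvalue)) {
    bvalue <- data.frame(
      landrace = rep(c("GlasshouseA", "GlasshouseB"), each = 2L),
      organ = rep(c("shoot", "root"), 2L),
      delta15n = c(-3.68, -2.60, -3.99, -3.31),
      sd = c(0.49, 0.30, 0.10, 0.08),
      n_content_mg = c(100, 50, 100, 50))
  }
  structure(list(sites = sites, landraces = landraces,
                 inoculation = inoculation,
                 replicates = as.integer(replicates),
                 cell_means = cell_means, sd = sd,
                 reference = reference, bvalue = bvalue,
                 bvalue_reps = as.integer(bvalue_reps),
                 seed = as.integer(seed)),
            class = "trial_sim_config")
}

# default true cell means: additive site/landrace/inoculation effects
# plus a landrace x inoculation interaction on delta15n, scaled to a
# typical low-fixing groundnut trial
default_cell_means <- function(sites, landraces, inoculation) {
  grid <- expand.grid(site = sites, landrace = landraces,
                      inoculation = inoculation,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ns <- length(sites); nl <- length(landraces); ni <- length(inoculation)
  site_shift <- rep_len(c(0, -6), ns)[match(grid$site, sites)]
  lr_dm <- rep_len(c(20.4, 22.6, 27.0, 26.4, 22.8), nl)
  lr_d15 <- rep_len(c(1.03, 1.21, 1.07, 1.65, 1.39), nl)
  lr_nod <- rep_len(c(6.0, 7.0, 7.4, 6.0, 8.9), nl)
  inoc_dm <- rep_len(c(-1.7, 1.7), ni)
  inoc_d15 <- rep_len(c(0.03, -0.03), ni)
  li <- match(grid$landrace, landraces)
  ii <- match(grid$inoculation, inoculation)
  # alternating-sign interaction so inoculation helps some landraces
  # and not others, as observed in real trials
  inter <- 0.15 * ifelse(li %% 2L == 0L, 1, -1) * ifelse(ii == 1L, 1, -1)
  grid$shoot_dm <- lr_dm[li] + inoc_dm[ii] + site_shift
  grid$nodule_dm <- lr_nod[li] + rep_len(c(-1.5, 1.5), ni)[ii]
  grid$n_pct <- rep_len(c(2.8, 2.9, 2.9, 2.9, 3.0), nl)[li]
  grid$c_pct <- 40 + site_shift / 2
  grid$delta15n <- lr_d15[li] + inoc_d15[ii] + inter +
    ifelse(grid$site == sites[1], 0, 0.4)
  grid
}

#' Generate a synthetic field trial
#'
#' Draws a complete synthetic study from a [trial_sim_config()]: the
#' per-plant samples table, the reference-plant table and the
#' glasshouse B-value table, in exactly the CSV schemas the analysis
#' functions consume. Every measurement is its configured true mean
#' plus independent Gaussian noise; with all SDs zero the data equal
#' the configured truths. The same config (including its seed) always
#' reproduces the same tables.
#'
#' @param config A [trial_sim_config()] object.
#' @param seed Optional integer overriding `config$seed`.
#' @return A list with data frames `samples`, `references`, `bvalue`
#'   and the numeric element `seed` actually used.
#' @export
generate_trial <- function(config = trial_sim_config(), seed = NULL) {
  stopifnot(inherits(config, "trial_sim_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  cm <- config$cell_means
  reps <- config$replicates
  idx <- rep(seq_len(nrow(cm)), each = reps)
  samples <- data.frame(site = cm$site[idx],
                        landrace = cm$landrace[idx],
                        inoculation = cm$inoculation[idx],
                        replicate = rep(seq_len(reps), nrow(cm)),
                        stringsAsFactors = FALSE)
  n <- nrow(samples)
  sd <- config$sd
  samples$shoot_dm_g <- pmax(0, cm$shoot_dm[idx] +
                               stats::rnorm(n, 0, sd[["shoot_dm"]]))
  samples$nodule_dm_mg <- pmax(0, cm$nodule_dm[idx] +
                                 stats::rnorm(n, 0, sd[["nodule_dm"]]))
  samples$n_pct <- pmax(0, cm$n_pct[idx] +
                          stats::rnorm(n, 0, sd[["n_pct"]]))
  samples$c_pct <- pmax(0, cm$c_pct[idx] +
                          stats::rnorm(n, 0, sd[["c_pct"]]))
  samples$delta15n <- cm$delta15n[idx] +
    stats::rnorm(n, 0, sd[["delta15n"]])

  ref_cfg <- config$reference
  references <- do.call(rbind, lapply(seq_len(nrow(ref_cfg)), function(i) {
    k <- ref_cfg$n[i]
    data.frame(site = ref_cfg$site[i],
               species = paste0("reference_sp", seq_len(k)),
               delta15n = ref_cfg$mean[i] + stats::rnorm(k, 0, ref_cfg$sd[i]),
               stringsAsFactors = FALSE)
  }))

  bv_cfg <- config$bvalue
  bvalue <- do.call(rbind, lapply(seq_len(nrow(bv_cfg)), function(i) {
    k <- config$bvalue_reps
    data.frame(landrace = bv_cfg$landrace[i],
               organ = bv_cfg$organ[i],
               delta15n = bv_cfg$delta15n[i] +
                 stats::rnorm(k, 0, bv_cfg$sd[i]),
               n_content_mg = bv_cfg$n_content_mg[i],
               stringsAsFactors = FALSE)
  }))
  rownames(references) <- rownames(bvalue) <- NULL
  list(samples = samples, references = references, bvalue = bvalue,
       seed = seed)
}

#' Generate random sequences with planted SSR arrays
#'
#' Draws uniform-random A/C/G/T background sequences and overwrites
#' given positions with exact tandem repeat arrays. The bases flanking
#' each array are resampled if necessary so the planted run cannot be
#' extended by chance, guaranteeing that [scan_ssrs()] recovers each
#' planted array at its exact coordinates.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp (> 0).
#' @param planted List of `list(motif =, repeats =, position =)`
#'   entries (1-based start positions), all applied to every sequence.
#'   Arrays must fit within `length` and must not overlap.
#' @param seed Integer random seed.
#' @return A `Biostrings::DNAStringSet` named `seq1..seqn`.
#' @examples
#' s <- generate_ssr_sequences(1, 300,
#'        planted = list(list(motif = "CT", repeats = 10, position = 50)))
#' scan_ssrs(as.character(s[[1]]))
#' @export
generate_ssr_sequences <- function(n, length, planted = list(), seed = 1L) {
  stopifnot(n >= 1L)
  if (length <= 0) stop("'length' must be positive", call. = FALSE)
  spans <- lapply(planted, function(p) {
    stopifnot(all(c("motif", "repeats", "position") %in% names(p)))
    motif <- toupper(p$motif)
    if (!grepl("^[ACGT]{1,6}$", motif)) {
      stop("planted motif must be 1-6 bases over A/C/G/T", call. = FALSE)
    }
    w <- nchar(motif) * p$repeats
    if (p$position < 1L || p$position + w - 1L > length) {
      stop("planted array does not fit within the sequence", call. = FALSE)
    }
    c(p$position, p$position + w - 1L)
  })
  if (length(spans) > 1L) {
    ord <- order(vapply(spans, `[`, numeric(1), 1L))
    for (i in seq_along(ord)[-1L]) {
      if (spans[[ord[i]]][1] <= spans[[ord[i - 1L]]][2]) {
        stop("planted arrays overlap", call. = FALSE)
      }
    }
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i) {
    chars <- sample(bases, length, replace = TRUE)
    for (p in planted) {
      motif <- strsplit(toupper(p$motif), "")[[1]]
      u <- base::length(motif)
      start <- p$position
      end <- start + u * p$repeats - 1L
      chars[start:end] <- rep(motif, p$repeats)
      # block chance extension: left flank must not continue the period,
      # right flank must not start another copy
      if (start > 1L && chars[start - 1L] == motif[u]) {
        chars[start - 1L] <- sample(setdiff(bases, motif[u]), 1L)
      }
      if (end < length && chars[end + 1L] == motif[1L]) {
        chars[end + 1L] <- sample(setdiff(bases, motif[1L]), 1L)
      }
    }
    paste(chars, collapse = "")
  }, character(1))
  names(seqs) <- paste0("seq", seq_len(n))
  Biostrings::DNAStringSet(seqs)
}
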