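# End-to-end orchestration: CSV readers with schema validation, the
# full analysis (reference means -> B value -> per-plant budgets ->
# treatment-cell summaries -> ANOVA + Duncan letters -> correlations),
# and report writers.

SAMPLES_COLS <- c("site", "landrace", "inoculation", "replicate",
                  "shoot_dm_g", "nodule_dm_mg", "n_pct", "c_pct",
                  "delta15n")

read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(d))) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad)) {
        stop(path, ": non-numeric value in '", col, "' at data row(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
      d[[col]] <- as.numeric(v)
    }
  }
  d
}

#' Read a per-plant samples table
#'
#' Expects columns `site`, `landrace`, `inoculation`, `replicate`,
#' `shoot_dm_g`, `nodule_dm_mg`, `n_pct`, `c_pct`, `delta15n` (header
#' required, UTF-8, '.' decimal). Rows with negative biomass or %N
#' outside [0, 100] are reported with their row numbers.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_samples_csv <- function(path) {
  d <- read_checked_csv(path, SAMPLES_COLS,
                        c("replicate", "shoot_dm_g", "nodule_dm_mg",
                          "n_pct", "c_pct", "delta15n"))
  bad <- which(d$shoot_dm_g < 0 | d$nodule_dm_mg < 0 |
                 d$n_pct < 0 | d$n_pct > 100 |
                 d$c_pct < 0 | d$c_pct > 100)
  if (length(bad)) {
    stop(path, ": invalid measurement(s) at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (negative biomass or %N/%C outside [0, 100])", call. = FALSE)
  }
  d
}

#' Read a reference-plant delta-15N table
#'
#' Expects columns `site`, `species`, `delta15n`.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_references_csv <- function(path) {
  read_checked_csv(path, c("site", "species", "delta15n"), "delta15n")
}

#' Read a glasshouse B-value organ table
#'
#' Expects columns `landrace`, `organ` (`shoot`/`root`), `delta15n`,
#' `n_content_mg` (the latter may be empty where organ N contents were
#' not recorded; whole-plant delta-15N is then unavailable but the
#' shoot-based B value is unaffected).
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_bvalue_csv <- function(path) {
  d <- read_checked_csv(path, c("landrace", "organ", "delta15n"),
                        c("delta15n", "n_content_mg"))
  bad <- which(!d$organ %in% c("shoot", "root"))
  if (length(bad)) {
    stop(path, ": 'organ' must be 'shoot' or 'root' at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  d
}

#' Treatment-cell summary of symbiosis results
#'
#' Computes per-plant symbiosis budgets (see [symbiosis_budget()]) and
#' aggregates them as mean and standard error over replicates for each
#' grouping cell. Per-plant values are computed first and averaged
#' after, so cell summaries reflect the replicate-level spread.
#'
#' @param samples Samples data frame (see [read_samples_csv()]).
#' @param ref_means Named per-site reference delta-15N means, permil
#'   (names must cover all sites present in `samples`).
#' @param b B value, permil.
#' @param density Plant density, plants per hectare.
#' @param group_by Columns defining a treatment cell.
#' @param clamp Passed to [ndfa_percent()].
#' @return Data frame with one row per cell: grouping columns, `n_reps`
#'   and `<var>_mean`/`<var>_se` for shoot DM, nodule DM, %N, N
#'   content, C/N, delta-15N, %Ndfa, total N, N-fixed and soil N
#'   uptake. Attribute `"ndfa_out_of_range"` gives the number of
#'   per-plant estimates outside [0, 100].
#' @export
summarise_symbiosis <- function(samples, ref_means, b,
                                density = plant_density(),
                                group_by = c("site", "landrace",
                                             "inoculation"),
                                clamp = FALSE) {
  stopifnot(is.data.frame(samples))
  sites <- unique(samples$site)
  missing_sites <- setdiff(sites, names(ref_means))
  if (length(missing_sites)) {
    stop("no reference mean for site(s): ",
         paste(missing_sites, collapse = ", "), call. = FALSE)
  }
  per_plant <- samples
  n_out <- 0L
  budg <- do.call(rbind, lapply(sites, function(s) {
    rows <- samples$site == s
    withCallingHandlers(
      {
        b_ <- symbiosis_budget(samples$delta15n[rows],
                               samples$shoot_dm_g[rows],
                               samples$n_pct[rows],
                               samples$c_pct[rows],
                               delta_ref = ref_means[[s]], b = b,
                               density = density, clamp = clamp)
        n_out <<- n_out + sum(attr(b_, "ndfa_out_of_range"))
        cbind(which_row = which(rows), b_)
      },
      warning = function(w) invokeRestart("muffleWarning"))
  }))
  budg <- budg[order(budg$which_row), , drop = FALSE]
  per_plant <- cbind(per_plant, budg[, -1, drop = FALSE])

  vars <- c(shoot_dm = "shoot_dm_g", nodule_dm = "nodule_dm_mg",
            n_pct = "n_pct", n_content = "n_content_mg",
            cn = "cn_ratio", delta15n = "delta15n", ndfa = "ndfa_pct",
            total_n = "total_n_kg_ha", n_fixed = "n_fixed_kg_ha",
            soil_n = "soil_n_kg_ha")
  key <- interaction(per_plant[group_by], drop = TRUE, lex.order = TRUE)
  cells <- unique(per_plant[group_by])
  cells <- cells[order(interaction(cells, drop = TRUE, lex.order = TRUE)), ,
                 drop = FALSE]
  out <- cells
  out$n_reps <- as.integer(table(key)[as.character(
    interaction(cells, drop = TRUE, lex.order = TRUE))])
  for (nm in names(vars)) {
    v <- per_plant[[vars[[nm]]]]
    out[[paste0(nm, "_mean")]] <- as.numeric(tapply(v, key, mean))
    out[[paste0(nm, "_se")]] <- as.numeric(
      tapply(v, key, function(z) stats::sd(z) / sqrt(length(z))))
  }
  rownames(out) <- NULL
  attr(out, "per_plant") <- per_plant
  attr(out, "ndfa_out_of_range") <- n_out
  out
}

#' Run the full 15N natural-abundance analysis
#'
#' Orchestrates the whole pipeline on per-plant records: per-site
#' reference-plant means, the shoot-based B value, per-plant %Ndfa and
#' N budgets, treatment-cell summaries (mean +/- SE), per-site
#' two-way ANOVA with protected Duncan letters for each response, a
#' cross-site three-way ANOVA, and a correlation panel among the
#' symbiotic variables. Inputs can be supplied as file paths or as
#' already-loaded data frames.
#'
#' @param samples Samples data frame or CSV path.
#' @param references Reference-plant data frame or CSV path (ignored
#'   when `ref_means` is given).
#' @param bvalue B-value organ data frame or CSV path (ignored when
#'   `b` is given).
#' @param ref_means Optional named per-site reference means, permil.
#' @param b Optional explicit B value, permil.
#' @param density Plant density, plants per hectare.
#' @param alpha Significance level for ANOVA gating and Duncan's test.
#' @param clamp Clamp %Ndfa to [0, 100]?
#' @param out_dir Optional directory; when given, the cell summary,
#'   ANOVA tables, letter groupings, correlations and a JSON summary
#'   are written there.
#' @return A list of class `"isofix_report"` with elements
#'   `reference_means`, `b_value`, `cells`, `per_plant`, `anova`
#'   (per site per response), `anova_three_way`, `letters`,
#'   `correlations`, `warnings`, and `params`.
#' @export
run_full_analysis <- function(samples, references = NULL, bvalue = NULL,
                              ref_means = NULL, b = NULL,
                              density = plant_density(), alpha = 0.05,
                              clamp = FALSE, out_dir = NULL) {
  if (is.character(samples)) samples <- read_samples_csv(samples)
  if (is.null(ref_means)) {
    if (is.null(references)) {
      stop("supply either 'references' or 'ref_means'", call. = FALSE)
    }
    if (is.character(references)) {
      references <- read_references_csv(references)
    }
    ref_means <- reference_means(references)
  }
  bv <- NULL
  if (is.null(b)) {
    if (is.null(bvalue)) {
      stop("supply either 'bvalue' or an explicit 'b'", call. = FALSE)
    }
    if (is.character(bvalue)) bvalue <- read_bvalue_csv(bvalue)
    bv <- b_value(bvalue)
    b <- bv$b
  }
  for (s in unique(samples$site)) {
    if (s %in% names(ref_means) && ref_means[[s]] == b) {
      stop("site '", s, "': reference mean equals the B value; ",
           "%Ndfa is undefined (isotope-dilution denominator is zero)",
           call. = FALSE)
    }
  }

  cells <- summarise_symbiosis(samples, ref_means, b, density = density,
                               clamp = clamp)
  per_plant <- attr(cells, "per_plant")
  warnings <- character()
  n_out <- attr(cells, "ndfa_out_of_range")
  if (n_out > 0L) {
    warnings <- c(warnings, sprintf(
      "%d per-plant %%Ndfa estimate(s) outside [0, 100] (raw values kept)",
      n_out))
  }
  # conservation check, logged per cell
  closure <- abs(cells$n_fixed_mean + cells$soil_n_mean -
                   cells$total_n_mean)
  if (any(closure > 1e-8 * pmax(1, abs(cells$total_n_mean)))) {
    warnings <- c(warnings, "N budget failed to close in some cells")
  }

  responses <- c("shoot_dm_g", "nodule_dm_mg", "n_pct", "n_content_mg",
                 "cn_ratio", "delta15n", "ndfa_pct", "n_fixed_kg_ha",
                 "soil_n_kg_ha")
  balanced <- is_balanced(per_plant,
                          c("site", "landrace", "inoculation"))
  anova_by_site <- list()
  letters_by_site <- list()
  anova3 <- NULL
  if (balanced) {
    for (s in unique(per_plant$site)) {
      d <- per_plant[per_plant$site == s, , drop = FALSE]
      reports <- lapply(responses, function(r) {
        trial_stats_report(d, r, c("landrace", "inoculation"),
                           alpha = alpha)
      })
      names(reports) <- responses
      anova_by_site[[s]] <- lapply(reports, `[[`, "anova")
      letters_by_site[[s]] <- lapply(reports, `[[`, "letters")
    }
    if (length(unique(per_plant$site)) >= 2L) {
      anova3 <- lapply(responses, function(r) {
        factorial_anova(per_plant, r,
                        c("site", "landrace", "inoculation"))
      })
      names(anova3) <- responses
    }
  } else {
    warnings <- c(warnings,
                  "design is unbalanced: ANOVA and mean separation skipped")
  }

  corr_pairs <- list(c("ndfa_pct", "soil_n_kg_ha"),
                     c("shoot_dm_g", "n_content_mg"),
                     c("shoot_dm_g", "n_fixed_kg_ha"),
                     c("delta15n", "ndfa_pct"))
  correlations <- do.call(rbind, lapply(unique(per_plant$site), function(s) {
    d <- per_plant[per_plant$site == s, , drop = FALSE]
    do.call(rbind, lapply(corr_pairs, function(pr) {
      ct <- pearson_correlation(d[[pr[1]]], d[[pr[2]]])
      lr <- linear_regression(d[[pr[1]]], d[[pr[2]]])
      data.frame(site = s, x = pr[1], y = pr[2], r = ct$r,
                 p.value = ct$p.value, slope = lr$slope,
                 intercept = lr$intercept, r_squared = lr$r_squared,
                 stringsAsFactors = FALSE)
    }))
  }))

  report <- structure(list(
    reference_means = ref_means,
    b_value = if (is.null(bv)) b else bv,
    cells = cells,
    per_plant = per_plant,
    anova = anova_by_site,
    anova_three_way = anova3,
    letters = letters_by_site,
    correlations = correlations,
    warnings = warnings,
    params = list(density = density, alpha = alpha, clamp = clamp,
                  b = b)), class = "isofix_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

is_balanced <- function(data, factors) {
  counts <- table(data[factors])
  length(unique(c(counts))) == 1L && all(counts > 0L)
}

#' @export
print.isofix_report <- function(x, ...) {
  cat("15N natural-abundance symbiosis report\n")
  cat("Reference means (permil):\n")
  print(round(unclass(x$reference_means), 2))
  cat("B value:", format(round(x$params$b, 3)), "permil\n")
  cat("Treatment cells:", nrow(x$cells), " plants:",
      nrow(x$per_plant), "\n")
  if (length(x$warnings)) {
    cat("Warnings:\n"); for (w in x$warnings) cat(" -", w, "\n")
  }
  invisible(x)
}

#' Write an analysis report bundle to disk
#'
#' Emits the treatment-cell summary, per-plant table, correlations and
#' letter groupings as CSV, plus a machine-readable `summary.json`
#' capturing reference means, the B value, parameters and warnings.
#' Output is deterministic: identical inputs give byte-identical files.
#'
#' @param report An `"isofix_report"` from [run_full_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "isofix_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                        row.names = FALSE)
  wr(report$cells, "cells.csv")
  wr(report$per_plant, "per_plant.csv")
  wr(report$correlations, "correlations.csv")
  for (s in names(report$anova)) {
    tabs <- do.call(rbind, lapply(names(report$anova[[s]]), function(r) {
      cbind(response = r, as.data.frame(report$anova[[s]][[r]]))
    }))
    wr(tabs, paste0("anova_", gsub("[^A-Za-z0-9]", "_", s), ".csv"))
    lets <- do.call(rbind, lapply(names(report$letters[[s]]), function(r) {
      do.call(rbind, lapply(names(report$letters[[s]][[r]]), function(f) {
        cbind(response = r, factor = f,
              as.data.frame(report$letters[[s]][[r]][[f]]))
      }))
    }))
    wr(lets, paste0("letters_", gsub("[^A-Za-z0-9]", "_", s), ".csv"))
  }
  b <- report$b_value
  summary <- list(
    reference_means = as.list(unclass(report$reference_means)),
    b_value = if (inherits(b, "b_value")) b$b else b,
    b_shoot_means = if (inherits(b, "b_value")) as.list(b$shoot_means),
    params = report$params,
    n_cells = nrow(report$cells),
    n_plants = nrow(report$per_plant),
    warnings = report$warnings)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' Packaged transcriptions of the study tables
#'
#' Loads the plain-text fixtures shipped with the package: the
#' reference-plant delta-15N table (nine species per site at two Ghana
#' sites), the glasshouse B-value organ table, and the
#' treatment-cell means of the field trial. These are transcriptions
#' of published summary tables; organ N contents in the B-value table
#' were not published and are left `NA`, and two legume delta-15N cell
#' means lost in transcription of the source were reconstructed by
#' inverting the %Ndfa relation (flagged by `delta15n_reconstructed`).
#'
#' @param which One of `"references"`, `"bvalue"`, `"cells"`.
#' @return The corresponding data frame.
#' @export
isofix_example_data <- function(which = c("references", "bvalue",
                                          "cells")) {
  which <- match.arg(which)
  f <- switch(which,
              references = "table_reference_delta15n.csv",
              bvalue = "table_bvalue_organs.csv",
              cells = "table_trial_cell_means.csv")
  path <- system.file("extdata", f, package = "isofix", mustWork = TRUE)
  switch(which,
         references = read_references_csv(path),
         bvalue = read_bvalue_csv(path),
         cells = utils::read.csv(path, stringsAsFactors = FALSE))
}
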