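# Isotope arithmetic and per-hectare N budgeting for the 15N
# natural-abundance method. All delta values are in per mil (permil),
# N contents in mg N per plant, area-scaled quantities in kg per ha.

#' Atmospheric 15N/14N abundance ratio
#'
#' The 15N/14N abundance ratio of atmospheric N2, the reference against
#' which delta-15N is expressed. Air is the international standard for
#' nitrogen isotope ratios, so this value is a physical constant rather
#' than a tunable parameter; it can nevertheless be overridden in
#' [delta15n()] and [delta15n_to_ratio()] for sensitivity checks.
#'
#' @format A length-one numeric, dimensionless.
#' @export
R_ATMOSPHERE <- 0.0036765

#' Convert a 15N/14N abundance ratio to delta-15N
#'
#' delta-15N expresses the relative deviation of a sample's 15N/14N
#' abundance ratio from that of atmospheric N2, in parts per thousand:
#' delta-15N = (R_sample - R_atm) / R_atm * 1000.
#'
#' @param r_sample Numeric vector of 15N/14N abundance ratios (> 0).
#' @param r_atm Atmospheric 15N/14N ratio (> 0); defaults to
#'   [R_ATMOSPHERE].
#' @return Numeric vector of delta-15N values in per mil. Samples
#'   depleted in 15N relative to air give negative values.
#' @seealso [delta15n_to_ratio()] for the inverse transform.
#' @examples
#' delta15n(0.0036765)          # air itself: 0 permil
#' delta15n(1.001 * 0.0036765)  # 1 permil enrichment
#' @export
delta15n <- function(r_sample, r_atm = R_ATMOSPHERE) {
  stopifnot(is.numeric(r_sample), is.numeric(r_atm), length(r_atm) == 1L)
  if (any(!is.finite(r_sample)) || any(r_sample <= 0)) {
    stop("'r_sample' must be finite and strictly positive", call. = FALSE)
  }
  if (!is.finite(r_atm) || r_atm <= 0) {
    stop("'r_atm' must be finite and strictly positive", call. = FALSE)
  }
  (r_sample - r_atm) / r_atm * 1000
}

#' Recover an abundance ratio from delta-15N
#'
#' Inverse of [delta15n()]: R_sample = R_atm * (1 + delta/1000).
#'
#' @param delta Numeric vector of delta-15N values in per mil.
#' @param r_atm Atmospheric 15N/14N ratio (> 0).
#' @return Numeric vector of 15N/14N abundance ratios.
#' @export
delta15n_to_ratio <- function(delta, r_atm = R_ATMOSPHERE) {
  stopifnot(is.numeric(delta), is.numeric(r_atm), length(r_atm) == 1L)
  if (!is.finite(r_atm) || r_atm <= 0) {
    stop("'r_atm' must be finite and strictly positive", call. = FALSE)
  }
  r_atm * (1 + delta / 1000)
}

#' N-content-weighted whole-plant delta-15N
#'
#' Combines shoot and root delta-15N into a whole-plant value by
#' weighting each organ's delta by its N content (organ dry mass times
#' %N). The result always lies between the two organ values.
#'
#' @param delta_shoot,delta_root Organ delta-15N in per mil.
#' @param n_shoot,n_root Organ N contents in mg N (>= 0, not both zero).
#' @return Whole-plant delta-15N in per mil.
#' @examples
#' whole_plant_delta15n(-4, -2, n_shoot = 100, n_root = 50)
#' @export
whole_plant_delta15n <- function(delta_shoot, delta_root, n_shoot, n_root) {
  stopifnot(is.numeric(delta_shoot), is.numeric(delta_root),
            is.numeric(n_shoot), is.numeric(n_root))
  if (any(n_shoot < 0) || any(n_root < 0)) {
    stop("organ N contents must be non-negative", call. = FALSE)
  }
  total <- n_shoot + n_root
  if (any(total <= 0)) {
    stop("total organ N content must be positive", call. = FALSE)
  }
  (delta_shoot * n_shoot + delta_root * n_root) / total
}

#' B value from glasshouse plants grown solely on atmospheric N2
#'
#' The B value calibrates the isotopic fractionation associated with N2
#' fixation: it is the delta-15N a legume attains when all of its N
#' comes from the atmosphere. Following the shoot-based convention for
#' shoot-sampled field material, the B value is the arithmetic mean of
#' the shoot delta-15N values across the glasshouse landraces;
#' whole-plant values (see [whole_plant_delta15n()]) are reported
#' alongside for completeness but are never used as B.
#'
#' @param bvalue_data Data frame with columns `landrace`, `organ`
#'   (`"shoot"`/`"root"`), `delta15n` (permil) and optionally
#'   `n_content_mg`, as read by [read_bvalue_csv()].
#' @return A list of class `"b_value"` with elements `b` (the shoot-mean
#'   B value, permil), `shoot_means` (named per-landrace shoot means)
#'   and `whole_plant` (named per-landrace N-weighted whole-plant
#'   delta-15N, `NA` where organ N contents are unavailable).
#' @examples
#' d <- data.frame(landrace = c("Puffeun", "Funsi"),
#'                 organ = "shoot", delta15n = c(-3.68, -3.99))
#' b_value(d)$b   # -3.835
#' @export
b_value <- function(bvalue_data) {
  stopifnot(is.data.frame(bvalue_data))
  need <- c("landrace", "organ", "delta15n")
  if (!all(need %in% names(bvalue_data))) {
    stop("'bvalue_data' needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  shoots <- bvalue_data[bvalue_data$organ == "shoot", , drop = FALSE]
  if (nrow(shoots) == 0L) {
    stop("no shoot measurements: cannot form a B value", call. = FALSE)
  }
  shoot_means <- tapply(shoots$delta15n, shoots$landrace, mean)
  whole <- vapply(names(shoot_means), function(lr) {
    sub <- bvalue_data[bvalue_data$landrace == lr, , drop = FALSE]
    s <- sub[sub$organ == "shoot", , drop = FALSE]
    r <- sub[sub$organ == "root", , drop = FALSE]
    if (nrow(s) == 0L || nrow(r) == 0L || is.null(sub$n_content_mg) ||
        anyNA(sub$n_content_mg)) {
      return(NA_real_)
    }
    whole_plant_delta15n(mean(s$delta15n), mean(r$delta15n),
                         sum(s$n_content_mg), sum(r$n_content_mg))
  }, numeric(1))
  structure(list(b = mean(shoot_means),
                 shoot_means = shoot_means,
                 whole_plant = whole),
            class = "b_value")
}

#' @export
print.b_value <- function(x, ...) {
  cat("B value (mean shoot delta-15N):", format(x$b), "permil\n")
  cat("Per-landrace shoot means:\n")
  print(x$shoot_means)
  invisible(x)
}

#' Percent N derived from atmospheric fixation (%Ndfa)
#'
#' Isotope-dilution estimate of the percentage of legume N derived from
#' symbiotic N2 fixation:
#' \deqn{\%Ndfa = 100 (\delta_{ref} - \delta_{leg}) / (\delta_{ref} - B)}
#' where `delta_ref` is the mean delta-15N of non-fixing reference
#' plants (a proxy for plant-available soil N), `delta_leg` the legume
#' shoot delta-15N, and `b` the B value.
#'
#' Measurement noise can push the estimate outside [0, 100]. By default
#' the raw value is returned and an `"ndfa_out_of_range"` attribute
#' flags offending elements (with a warning); `clamp = TRUE` instead
#' truncates to [0, 100].
#'
#' @param delta_ref Reference-plant mean delta-15N, permil.
#' @param delta_leg Legume delta-15N, permil (vectorised).
#' @param b B value, permil; must differ from `delta_ref`.
#' @param clamp Logical; truncate estimates to [0, 100]?
#' @return Numeric vector of %Ndfa values. When `clamp = FALSE` and any
#'   value falls outside [0, 100], the vector carries a logical
#'   attribute `"ndfa_out_of_range"`.
#' @examples
#' ndfa_percent(3.95, 1.03, -3.835)   # about 37.5 %
#' @export
ndfa_percent <- function(delta_ref, delta_leg, b, clamp = FALSE) {
  stopifnot(is.numeric(delta_ref), is.numeric(delta_leg), is.numeric(b),
            length(delta_ref) == 1L, length(b) == 1L)
  if (isTRUE(all.equal(delta_ref, b)) || delta_ref == b) {
    stop("delta_ref equals the B value: the isotope-dilution ",
         "denominator is zero and %Ndfa is undefined", call. = FALSE)
  }
  out <- 100 * (delta_ref - delta_leg) / (delta_ref - b)
  bad <- out < 0 | out > 100
  if (clamp) {
    out <- pmin(pmax(out, 0), 100)
  } else if (any(bad, na.rm = TRUE)) {
    warning(sum(bad, na.rm = TRUE),
            " %Ndfa estimate(s) outside [0, 100]; returning raw values",
            call. = FALSE)
    attr(out, "ndfa_out_of_range") <- bad
  }
  out
}

#' Shoot N content per plant
#'
#' N content is the product of shoot dry matter and %N, expressed in
#' mg N per plant: `shoot_dm` g x 1000 mg/g x `n_pct`/100.
#'
#' @param shoot_dm Shoot dry matter, g per plant (>= 0).
#' @param n_pct Shoot N concentration, percent of dry matter (>= 0).
#' @return N content in mg N per plant.
#' @export
shoot_n_content <- function(shoot_dm, n_pct) {
  stopifnot(is.numeric(shoot_dm), is.numeric(n_pct))
  if (any(shoot_dm < 0, na.rm = TRUE) || any(n_pct < 0, na.rm = TRUE)) {
    stop("'shoot_dm' and 'n_pct' must be non-negative", call. = FALSE)
  }
  shoot_dm * 1000 * n_pct / 100
}

#' Plant density from trial spacing
#'
#' Plants per hectare implied by planting-hole spacing:
#' `plants_per_hole / (within x between)` holes per m2, scaled by
#' 10 000 m2/ha. The default arguments encode 20 cm within-row by 60 cm
#' between-row spacing with two plants per hole, i.e. 166 666.7
#' plants/ha.
#'
#' @param within_row_spacing Distance between holes within a row, m.
#' @param between_row_spacing Distance between rows, m.
#' @param plants_per_hole Plants established per hole (>= 1).
#' @return Plant density in plants per hectare.
#' @examples
#' plant_density()                 # 166666.7
#' plant_density(1, 1, 1)          # 10000
#' @export
plant_density <- function(within_row_spacing = 0.20,
                          between_row_spacing = 0.60,
                          plants_per_hole = 2) {
  stopifnot(is.numeric(within_row_spacing), is.numeric(between_row_spacing))
  if (any(within_row_spacing <= 0) || any(between_row_spacing <= 0)) {
    stop("spacings must be strictly positive", call. = FALSE)
  }
  if (any(plants_per_hole < 1)) {
    stop("'plants_per_hole' must be at least 1", call. = FALSE)
  }
  plants_per_hole / (within_row_spacing * between_row_spacing) * 10000
}

#' Amount of N-fixed per hectare
#'
#' Scales the fixed fraction of per-plant shoot N to area basis:
#' `(ndfa_pct/100) x n_content mg/plant x density plants/ha`, converted
#' mg to kg (x 1e-6).
#'
#' @param ndfa_pct Percent N derived from fixation.
#' @param n_content Shoot N content, mg N per plant.
#' @param density Plant density, plants per hectare (> 0).
#' @return N-fixed in kg N per hectare.
#' @examples
#' n_fixed(37.46, 567.09, plant_density())   # about 35.4 kg/ha
#' @export
n_fixed <- function(ndfa_pct, n_content, density = plant_density()) {
  stopifnot(is.numeric(ndfa_pct), is.numeric(n_content), is.numeric(density))
  if (any(density <= 0)) {
    stop("'density' must be strictly positive", call. = FALSE)
  }
  (ndfa_pct / 100) * n_content * density * 1e-6
}

#' Soil N uptake by difference
#'
#' Shoot N not attributable to symbiotic fixation: total shoot N per
#' hectare minus N-fixed. Both arguments in kg N per hectare.
#'
#' @param total_n Total shoot N, kg N per hectare.
#' @param n_fixed N-fixed, kg N per hectare.
#' @return Soil N uptake in kg N per hectare.
#' @export
soil_n_uptake <- function(total_n, n_fixed) {
  stopifnot(is.numeric(total_n), is.numeric(n_fixed))
  total_n - n_fixed
}

#' Shoot C/N ratio
#'
#' @param c_pct Shoot C concentration, percent of dry matter.
#' @param n_pct Shoot N concentration, percent of dry matter (> 0).
#' @return C/N mass ratio, g C per g N.
#' @export
cn_ratio <- function(c_pct, n_pct) {
  stopifnot(is.numeric(c_pct), is.numeric(n_pct))
  if (any(n_pct == 0)) {
    stop("'n_pct' must be non-zero to form a C/N ratio", call. = FALSE)
  }
  c_pct / n_pct
}

#' Grain yield scaled to per-hectare basis
#'
#' Mean grain mass per sampled plant multiplied by plant density,
#' converted g to kg.
#'
#' @param total_seed_mass Total grain mass of the sampled plants, g.
#' @param n_plants_sampled Number of plants sampled (>= 1).
#' @param density Plant density, plants per hectare.
#' @return Grain yield in kg per hectare.
#' @export
grain_yield_per_ha <- function(total_seed_mass, n_plants_sampled,
                               density = plant_density()) {
  stopifnot(is.numeric(total_seed_mass), is.numeric(n_plants_sampled))
  if (any(n_plants_sampled < 1)) {
    stop("'n_plants_sampled' must be at least 1", call. = FALSE)
  }
  if (any(total_seed_mass < 0)) {
    stop("'total_seed_mass' must be non-negative", call. = FALSE)
  }
  (total_seed_mass / n_plants_sampled) * density / 1000
}

#' Per-plant symbiosis budget
#'
#' Computes the full chain %Ndfa -> N content -> total N, N-fixed and
#' soil N uptake for vectors of per-plant measurements. This is the
#' per-plot computation step: treatment-level summaries should average
#' these per-plant results, not recompute from cell means.
#'
#' @param delta_leg Legume shoot delta-15N, permil (vector).
#' @param shoot_dm Shoot dry matter, g per plant (vector).
#' @param n_pct Shoot N concentration, percent (vector).
#' @param c_pct Shoot C concentration, percent (vector, optional).
#' @param delta_ref Site reference-plant mean delta-15N, permil.
#' @param b B value, permil.
#' @param density Plant density, plants per hectare.
#' @param clamp Passed to [ndfa_percent()].
#' @return Data frame with columns `ndfa_pct`, `n_content_mg`,
#'   `total_n_kg_ha`, `n_fixed_kg_ha`, `soil_n_kg_ha` and (when `c_pct`
#'   is supplied) `cn_ratio`. `n_fixed_kg_ha + soil_n_kg_ha` equals
#'   `total_n_kg_ha` exactly, by construction.
#' @export
symbiosis_budget <- function(delta_leg, shoot_dm, n_pct, c_pct = NULL,
                             delta_ref, b, density = plant_density(),
                             clamp = FALSE) {
  ndfa <- ndfa_percent(delta_ref, delta_leg, b, clamp = clamp)
  flag <- attr(ndfa, "ndfa_out_of_range")
  ndfa <- as.numeric(ndfa)
  ncont <- shoot_n_content(shoot_dm, n_pct)
  total <- ncont * density * 1e-6
  fixed <- n_fixed(ndfa, ncont, density)
  soil <- soil_n_uptake(total, fixed)
  out <- data.frame(ndfa_pct = ndfa,
                    n_content_mg = ncont,
                    # total re-derived from its parts so the budget
                    # closes bit-for-bit per plant
                    total_n_kg_ha = fixed + soil,
                    n_fixed_kg_ha = fixed,
                    soil_n_kg_ha = soil)
  if (!is.null(c_pct)) out$cn_ratio <- cn_ratio(c_pct, n_pct)
  if (!is.null(flag)) attr(out, "ndfa_out_of_range") <- flag
  out
}

#' Site mean delta-15N of non-fixing reference plants
#'
#' Arithmetic mean over all reference-plant entries of a site; this
#' mean stands in for the delta-15N of plant-available soil N in the
#' %Ndfa calculation.
#'
#' @param references Data frame with columns `site`, `species`,
#'   `delta15n`, as read by [read_references_csv()].
#' @return Named numeric vector of per-site means (permil), plus
#'   attributes `sd` and `n` with the per-site spread and counts.
#' @export
reference_means <- function(references) {
  stopifnot(is.data.frame(references))
  if (!all(c("site", "delta15n") %in% names(references))) {
    stop("'references' needs columns 'site' and 'delta15n'", call. = FALSE)
  }
  if (nrow(references) == 0L) {
    stop("'references' has no entries", call. = FALSE)
  }
  m <- tapply(references$delta15n, references$site, mean)
  structure(c(m),
            sd = c(tapply(references$delta15n, references$site, stats::sd)),
            n = c(tapply(references$delta15n, references$site, length)))
}
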