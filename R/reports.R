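# Research-synthesis reports: per-function broadness (vs the total-biomass
# reference, with observation-count and nutrient filters) and per-class
# response-diversity / biomass-scaling estimates and rankings.

#' Default nutrient-exclusion mapping
#'
#' Broadness estimates need perturbations with collectively random effects,
#' so perturbations of a nutrient are not used for functions tied to that
#' nutrient (their effects are systematic, not random). The mapping is
#' configuration, not code; this shipped default links N addition to
#' N-cycling properties and P addition to phosphatase under the property
#' and factor labels used by the synthetic-data generator. Supply your own
#' mapping for other label schemes.
#'
#' @return Named list: property -> character vector of factors to drop.
#' @export
default_nutrient_exclusions <- function() {
  list(
    nag = "N",
    n_mineralization = "N",
    phosphatase = "P"
  )
}

#' Default diversity-metric property names
#'
#' Property labels treated as diversity metrics (rather than ecosystem
#' functions) by the reports, under both the synthetic generator's naming
#' and the common empirical column names.
#'
#' @return Character vector.
#' @export
default_diversity_metrics <- function() {
  c("richness", "shannon", "simpson", "chao")
}

# shared mismatch tally for one property pair on a record subset
pair_tally <- function(records, prop_a, prop_b, zero_tolerance = 0) {
  a <- records[records$property == prop_a, c("perturbation_id", "rr", "factor")]
  b <- records[records$property == prop_b, c("perturbation_id", "rr")]
  m <- merge(a, b, by = "perturbation_id", suffixes = c("_a", "_b"))
  sa <- observed_sign(m$rr_a, zero_tolerance)
  sb <- observed_sign(m$rr_b, zero_tolerance)
  ok <- sa != 0 & sb != 0
  list(n_pairs = sum(ok),
       n_mismatches = sum(sa[ok] * sb[ok] < 0),
       factors = unique(m$factor[ok]))
}

#' Per-function broadness report
#'
#' For each function (non-diversity property other than the reference),
#' tallies mismatches with the reference (total biomass by default) after
#' dropping perturbations whose factor is nutrient-matched to the
#' function, applies the observation filters -- at least
#' `min_perturbations` valid shared perturbations spanning at least
#' `min_factor_types` factor types -- and estimates broadness with
#' [estimate_broadness()] for eligible rows. Ineligible rows are reported
#' with a reason, never dropped silently. Weakening the filters only adds
#' rows; retained proportions are unchanged (filters are pure row
#' selections).
#'
#' @param records effect-size table ([as_effect_sizes()]).
#' @param reference the broadest reference property, default `"biomass"`.
#' @param min_perturbations,min_factor_types eligibility filters, defaults
#'   20 and 5.
#' @param nutrient_exclusions property -> factors map, see
#'   [default_nutrient_exclusions()].
#' @param diversity_metrics property labels to skip, see
#'   [default_diversity_metrics()].
#' @param biome optional biome filter.
#' @param zero_tolerance tolerance for [observed_sign()].
#' @return data.frame: property, n_pairs, n_mismatches, proportion,
#'   n_factors, eligible, reason, broadness, lower, upper.
#' @export
broadness_report <- function(records, reference = "biomass",
                             min_perturbations = 20, min_factor_types = 5,
                             nutrient_exclusions = default_nutrient_exclusions(),
                             diversity_metrics = default_diversity_metrics(),
                             biome = NULL, zero_tolerance = 0) {
  records <- as_effect_sizes(records)
  if (!is.null(biome)) records <- records[records$biome %in% biome, ]
  if (!reference %in% records$property) {
    stop(sprintf("configuration error: reference property '%s' not present",
                 reference), call. = FALSE)
  }
  funs <- setdiff(sort(unique(records$property)),
                  c(reference, diversity_metrics))
  rows <- lapply(funs, function(f) {
    sub <- records
    excl <- nutrient_exclusions[[f]]
    if (!is.null(excl)) sub <- sub[!sub$factor %in% excl, ]
    t <- pair_tally(sub, f, reference, zero_tolerance)
    n_factors <- length(t$factors)
    eligible <- t$n_pairs >= min_perturbations &&
      n_factors >= min_factor_types
    reason <- if (eligible) {
      ""
    } else if (t$n_pairs < min_perturbations) {
      sprintf("only %d shared perturbations (need %d)",
              t$n_pairs, min_perturbations)
    } else {
      sprintf("only %d factor types (need %d)", n_factors, min_factor_types)
    }
    est <- if (eligible) {
      estimate_broadness(t$n_mismatches, t$n_pairs)
    } else {
      list(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
    }
    data.frame(property = f, n_pairs = t$n_pairs,
               n_mismatches = t$n_mismatches,
               proportion = if (t$n_pairs > 0) {
                 t$n_mismatches / t$n_pairs
               } else NA_real_,
               n_factors = n_factors, eligible = eligible, reason = reason,
               broadness = est$estimate, lower = est$lower,
               upper = est$upper, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-class response-diversity / biomass-scaling report
#'
#' For a fixed property pair, tallies mismatches separately per
#' perturbation class (factor, within biome) and ranks the classes: for
#' two ecosystem functions (`mode = "response-diversity"`) a lower
#' mismatch proportion means lower response diversity; for a function and
#' a diversity metric (`mode = "biomass-scaling"`) a higher proportion
#' means stronger biomass scaling. Classes with fewer than `min_shared`
#' valid shared observations are excluded (reported with reason). With a
#' matching calibration curve the report also carries parameter estimates
#' ([estimate_response_consistency()] needs a baseline `theta`;
#' [estimate_biomass_scaling()] needs only the curve).
#'
#' @param records effect-size table.
#' @param pair character vector of two property labels.
#' @param mode `"response-diversity"` (two functions) or
#'   `"biomass-scaling"` (one function, one diversity metric); checked
#'   against `diversity_metrics`.
#' @param min_shared class-eligibility cutoff, default 5.
#' @param biome optional biome filter (recommended: pooling biomes breaks
#'   the shared-phase-space assumption).
#' @param curve optional [build_calibration_curve()] object of the
#'   matching parameter.
#' @param theta baseline collinearity angle for response-diversity
#'   estimates (e.g. from `acos(cos_from_broadness(...))`).
#' @param diversity_metrics see [default_diversity_metrics()].
#' @param zero_tolerance tolerance for [observed_sign()].
#' @return data.frame: factor, biome, n_pairs, n_mismatches, proportion,
#'   lower, upper, eligible, rank, and (when a curve is supplied)
#'   `estimate` (mu_hat or alpha_hat) and `extrapolated`.
#' @export
perturbation_report <- function(records, pair,
                                mode = c("response-diversity",
                                         "biomass-scaling"),
                                min_shared = 5, biome = NULL, curve = NULL,
                                theta = NULL,
                                diversity_metrics = default_diversity_metrics(),
                                zero_tolerance = 0) {
  mode <- match.arg(mode)
  records <- as_effect_sizes(records)
  if (!is.null(biome)) records <- records[records$biome %in% biome, ]
  stopifnot(length(pair) == 2L)
  is_div <- pair %in% diversity_metrics
  if (mode == "response-diversity" && any(is_div)) {
    stop("type error: response-diversity mode needs two ecosystem functions",
         call. = FALSE)
  }
  if (mode == "biomass-scaling" && sum(is_div) != 1L) {
    stop("type error: biomass-scaling mode needs one function and one diversity metric",
         call. = FALSE)
  }
  classes <- unique(records[, c("factor", "biome")])
  rows <- lapply(seq_len(nrow(classes)), function(k) {
    sub <- records[records$factor == classes$factor[k] &
                     records$biome == classes$biome[k], ]
    t <- pair_tally(sub, pair[1], pair[2], zero_tolerance)
    ci <- if (t$n_pairs >= 1) {
      wilson_interval(t$n_mismatches, t$n_pairs)
    } else c(lower = NA_real_, upper = NA_real_)
    data.frame(factor = classes$factor[k], biome = classes$biome[k],
               n_pairs = t$n_pairs, n_mismatches = t$n_mismatches,
               proportion = if (t$n_pairs > 0) {
                 t$n_mismatches / t$n_pairs
               } else NA_real_,
               lower = unname(ci["lower"]), upper = unname(ci["upper"]),
               eligible = t$n_pairs >= min_shared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank <- NA_real_
  el <- out$eligible
  out$rank[el] <- rank(out$proportion[el])
  if (!is.null(curve)) {
    out$estimate <- NA_real_
    out$extrapolated <- NA
    for (k in which(el)) {
      est <- if (mode == "biomass-scaling") {
        estimate_biomass_scaling(out$n_mismatches[k], out$n_pairs[k], curve)
      } else {
        estimate_response_consistency(out$n_mismatches[k], out$n_pairs[k],
                                      theta, curve)
      }
      out$estimate[k] <- if (mode == "biomass-scaling") {
        est$alpha_hat
      } else est$mu_hat
      out$extrapolated[k] <- est$extrapolated
    }
  }
  out
}
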