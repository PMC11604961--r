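# Synthetic effect-size tables with the full statistical structure the
# analysis assumes: planted contribution directions per property shared
# within a biome, per-factor response bias mu and biomass scaling alpha,
# and missing-at-random dropout -- plus ground-truth bookkeeping so every
# pipeline stage has a recovery test with no external data.

#' Default synthetic study design
#'
#' Two scales. `"smoke"` (seconds, < 10,000 rows): 2 biomes x 1 study,
#' 3 factor classes x 50 perturbations, 7 properties. `"paper_like"`
#' (minutes): 2 biomes x 2 studies, 6 factor classes x 80 perturbations
#' per study (~1,000 perturbations per biome), 13 properties (3 diversity
#' metrics, 2 broad and 8 narrow functions) and 20% observation dropout,
#' mirroring the magnitudes of the soil global-change synthesis the
#' pipeline is built for. Factor-class (mu, alpha) defaults encode the
#' qualitative empirical pattern that land-use conversion has consistent,
#' biomass-scaled effects while warming and nutrient enrichment have
#' diverse, weakly scaled effects; intensities are drawn from [0, 0.1].
#' Per-biome contribution directions are drawn at design time (seeded), so
#' a design carries its own ground-truth directions.
#'
#' @param scale `"smoke"` or `"paper_like"`.
#' @param seed integer seed for the direction draws, default 1.
#' @return Object of class `"synthetic_design"`.
#' @examples
#' d <- default_design("smoke")
#' names(d$biomes)
#' @export
default_design <- function(scale = c("smoke", "paper_like"), seed = 1L) {
  scale <- match.arg(scale)
  set.seed(seed)
  narrow <- c("phosphatase", "nag", "beta_xylosidase", "cellobiohydrolase",
              "beta_glucosidase", "alpha_glucosidase", "peroxidase",
              "phenol_oxidase")
  if (scale == "smoke") {
    fun_sds <- c(biomass = 0, respiration = 0.3,
                 phosphatase = 1.2, nag = 1.2)
    hills <- list(shannon = hill_order(1), simpson = hill_order(2))
    richness <- 40L
    n_studies <- 1L
    factors <- list(
      warming = list(mu = 0.05, alpha = 0.2, n_perturbations = 50L),
      N = list(mu = -0.15, alpha = 0.3, n_perturbations = 50L),
      NEtoAgr = list(mu = -0.3, alpha = 0.9, n_perturbations = 50L)
    )
    dropout <- 0
  } else {
    fun_sds <- c(biomass = 0, respiration = 0.3,
                 setNames(rep(1.2, length(narrow)), narrow))
    hills <- list(richness = hill_order(0), shannon = hill_order(1),
                  simpson = hill_order(2))
    richness <- 60L
    n_studies <- 2L
    factors <- list(
      warming = list(mu = 0.05, alpha = 0.2, n_perturbations = 80L),
      eCO2 = list(mu = 0.1, alpha = 0.2, n_perturbations = 80L),
      N = list(mu = -0.15, alpha = 0.3, n_perturbations = 80L),
      P = list(mu = -0.1, alpha = 0.4, n_perturbations = 80L),
      PPT = list(mu = 0.05, alpha = 0.5, n_perturbations = 80L),
      NEtoAgr = list(mu = -0.3, alpha = 0.9, n_perturbations = 80L)
    )
    dropout <- 0.2
  }
  factors <- lapply(factors, function(f) {
    f$intensity_range <- c(0, 0.1)
    f
  })
  biomes <- lapply(c(grassland = "grassland", forest = "forest"), function(b) {
    dirs <- lapply(names(fun_sds), function(nm) {
      generate_function(richness, fun_sds[[nm]])
    })
    names(dirs) <- names(fun_sds)
    list(richness = richness, lognormal_sd = 1.0, n_studies = n_studies,
         properties = c(dirs, hills))
  })
  structure(list(biomes = biomes, factors = factors, dropout = dropout,
                 scale = scale, seed = seed),
            class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf("<synthetic_design '%s': %d biomes, %d factor classes, dropout %.2f>\n",
              x$scale, length(x$biomes), length(x$factors), x$dropout))
  invisible(x)
}

#' Generate a synthetic effect-size table with ground truth
#'
#' For each biome x study a community is drawn; each factor class then
#' applies its perturbations (displacements from the simulation protocol
#' with the class's mu and alpha). Per property,
#' rr = ln(f(N + dN) / f(N)) for linear functions and
#' rr = ln(qD(N + dN) / qD(N)) for diversity columns, both evaluated on
#' the zero-clipped perturbed state (as a real study would measure them).
#' Records whose property evaluates to zero at either state are skipped
#' and counted in attribute `n_skipped`. Observations are then dropped
#' missing-at-random at the design's dropout rate.
#'
#' @param design a [default_design()] (or hand-built) design.
#' @param seed optional integer seed; fixing it makes the table
#'   byte-identical across calls.
#' @return List with `records` (effect-size table, [as_effect_sizes()]
#'   schema) and `truth`: `broadness` (biome x property), `theta`
#'   (biome-level angles between linear property pairs), `factors`
#'   (planted mu, alpha), `perturbations` (realized bias, intensity per
#'   perturbation), `communities` (biome, study, richness).
#' @export
generate_dataset <- function(design, seed = NULL) {
  stopifnot(inherits(design, "synthetic_design"))
  if (!is.null(seed)) set.seed(seed)
  recs <- list()
  pert_truth <- list()
  comm_truth <- list()
  n_skipped <- 0L
  for (b in names(design$biomes)) {
    bio <- design$biomes[[b]]
    props <- bio$properties
    linear <- !vapply(props, is_hill_order, logical(1))
    for (s in seq_len(bio$n_studies)) {
      study_id <- sprintf("%s_study%02d", b, s)
      N <- exp(stats::rnorm(bio$richness, 0, bio$lognormal_sd))
      comm_truth[[study_id]] <- data.frame(biome = b, study_id = study_id,
                                           richness = bio$richness)
      for (fac in names(design$factors)) {
        fc <- design$factors[[fac]]
        n <- fc$n_perturbations
        if (n < 1L) stop("every factor class needs n_perturbations >= 1",
                         call. = FALSE)
        intensity <- stats::runif(n, fc$intensity_range[1],
                                  fc$intensity_range[2])
        D <- simulate_displacements(N, n, fc$mu, fc$alpha, intensity)
        clipped <- pmax(N + D, 0)
        pert_ids <- sprintf("%s_%s_%03d", study_id, fac, seq_len(n))
        pert_truth[[paste(study_id, fac)]] <- data.frame(
          perturbation_id = pert_ids, biome = b, study_id = study_id,
          factor = fac, bias = abs(0.5 - colMeans(D < 0)),
          intensity = intensity, stringsAsFactors = FALSE)
        for (pn in names(props)) {
          pr <- props[[pn]]
          if (is_hill_order(pr)) {
            base <- drop(hill_cols(matrix(N / sum(N), ncol = 1), pr$q))
            tot <- colSums(clipped)
            after <- hill_cols(clipped / rep(tot, each = length(N)), pr$q)
          } else {
            base <- sum(pr * N)
            after <- colSums(pr * clipped)
          }
          okv <- after > 0 & base > 0
          n_skipped <- n_skipped + sum(!okv)
          if (!any(okv)) next
          recs[[length(recs) + 1L]] <- data.frame(
            study_id = study_id, perturbation_id = pert_ids[okv],
            factor = fac, biome = b, property = pn,
            rr = log(after[okv] / base), variance = NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  if (design$dropout > 0) {
    keep <- stats::rbinom(nrow(records), 1L, 1 - design$dropout) == 1L
    records <- records[keep, ]
    rownames(records) <- NULL
  }
  records <- as_effect_sizes(records)
  attr(records, "n_skipped") <- n_skipped

  broad <- do.call(rbind, lapply(names(design$biomes), function(b) {
    props <- design$biomes[[b]]$properties
    lin <- props[!vapply(props, is_hill_order, logical(1))]
    data.frame(biome = b, property = names(lin),
               broadness = vapply(lin, broadness, numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  theta <- do.call(rbind, lapply(names(design$biomes), function(b) {
    props <- design$biomes[[b]]$properties
    lin <- props[!vapply(props, is_hill_order, logical(1))]
    if (length(lin) < 2L) return(NULL)
    idx <- utils::combn(length(lin), 2)
    data.frame(biome = b,
               property_a = names(lin)[idx[1, ]],
               property_b = names(lin)[idx[2, ]],
               theta = apply(idx, 2, function(ij) {
                 angle_between(lin[[ij[1]]], lin[[ij[2]]])
               }),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  truth <- list(
    broadness = broad,
    theta = theta,
    factors = data.frame(factor = names(design$factors),
                         mu = vapply(design$factors, `[[`, numeric(1), "mu"),
                         alpha = vapply(design$factors, `[[`, numeric(1),
                                        "alpha"),
                         stringsAsFactors = FALSE, row.names = NULL),
    perturbations = do.call(rbind, c(pert_truth, make.row.names = FALSE)),
    communities = do.call(rbind, c(comm_truth, make.row.names = FALSE))
  )
  list(records = records, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Records as CSV (the same schema [read_effect_sizes()] ingests) and the
#' ground truth as a JSON companion.
#'
#' @param dataset a [generate_dataset()] result.
#' @param records_path CSV path for the effect-size table.
#' @param truth_path optional JSON path for the ground truth.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, records_path, truth_path = NULL) {
  utils::write.csv(dataset$records, records_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    jsonlite::write_json(dataset$truth, truth_path, auto_unbox = TRUE,
                         digits = I(17), dataframe = "columns")
  }
  invisible(c(records_path, truth_path))
}
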