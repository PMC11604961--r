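# Effect-size ingestion and the mismatch matrix: one row per (study,
# perturbation, aggregate property) carrying a log response ratio, and the
# property x property table of opposite-sign proportions with supporting
# counts.

#' Log response ratio
#'
#' RR = ln(X_t / X_c), the effect size used per aggregate property per
#' perturbation; X_t and X_c are treatment and control group means.
#'
#' @param x_treatment,x_control strictly positive means (vectorized).
#' @return Signed log ratio.
#' @examples
#' log_response_ratio(2, 4) # -log(2)
#' @export
log_response_ratio <- function(x_treatment, x_control) {
  if (any(x_treatment <= 0) || any(x_control <= 0)) {
    stop("treatment and control means must be strictly positive", call. = FALSE)
  }
  log(x_treatment / x_control)
}

#' Validate a long-format effect-size table
#'
#' Canonical columns: `study_id`, `perturbation_id`, `factor`, `biome`,
#' `property`, `rr`, and optionally `variance` (carried but never used:
#' no statistical-significance filtering of effect sizes is performed).
#' `(perturbation_id, property)` must be unique and `rr` finite.
#'
#' @param df data.frame.
#' @param mapping optional named list/vector mapping canonical names to the
#'   data's column names, e.g. `list(rr = "log_ratio")`.
#' @return The validated data.frame with canonical column names.
#' @export
as_effect_sizes <- function(df, mapping = NULL) {
  stopifnot(is.data.frame(df))
  canonical <- c("study_id", "perturbation_id", "factor", "biome",
                 "property", "rr")
  if (!is.null(mapping)) {
    mapping <- unlist(mapping)
    for (nm in names(mapping)) {
      if (!mapping[[nm]] %in% names(df)) {
        stop(sprintf("mapped column '%s' not found", mapping[[nm]]),
             call. = FALSE)
      }
      names(df)[names(df) == mapping[[nm]]] <- nm
    }
  }
  missing_cols <- setdiff(canonical, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  if (!"variance" %in% names(df)) df$variance <- NA_real_
  df <- df[, c(canonical, "variance")]
  for (col in c("study_id", "perturbation_id", "factor", "biome", "property")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$rr <- as.numeric(df$rr)
  if (any(!is.finite(df$rr))) {
    stop("all `rr` values must be finite", call. = FALSE)
  }
  key <- paste(df$perturbation_id, df$property, sep = "\r")
  if (anyDuplicated(key)) {
    stop("(perturbation_id, property) pairs must be unique", call. = FALSE)
  }
  df
}

#' Read a long-format effect-size table from CSV/TSV
#'
#' @param path file path; tab-separated when the extension is `.tsv` or
#'   `.txt`, comma-separated otherwise.
#' @param mapping optional column mapping, see [as_effect_sizes()].
#' @return Validated effect-size data.frame.
#' @export
read_effect_sizes <- function(path, mapping = NULL) {
  tabbed <- grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)
  df <- if (tabbed) {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  as_effect_sizes(df, mapping)
}

#' Build the property-by-property mismatch matrix
#'
#' For every unordered property pair, over the perturbations where both
#' were measured with a nonzero response sign, the proportion of
#' opposite-sign pairs. Pairs with fewer than `min_pairs` valid shared
#' perturbations are masked (`NA` proportion; the count is kept), never
#' zero-filled. Rows with a zero sign (per [observed_sign()]) are excluded
#' from that pair's tally.
#'
#' @param records effect-size table (see [as_effect_sizes()]).
#' @param min_pairs observation cutoff, default 10.
#' @param biome,factor optional filters (records are subset first).
#' @param zero_tolerance tolerance for [observed_sign()], default 0.
#' @return Object of class `"mismatch_matrix"`: list with `proportion`,
#'   `counts`, `mismatches` (symmetric matrices over `properties`),
#'   `min_pairs`, `group` and `n_perturbations`.
#' @export
build_mismatch_matrix <- function(records, min_pairs = 10, biome = NULL,
                                  factor = NULL, zero_tolerance = 0) {
  records <- as_effect_sizes(records)
  if (min_pairs < 1L) stop("`min_pairs` must be >= 1", call. = FALSE)
  if (!is.null(biome)) records <- records[records$biome %in% biome, ]
  if (!is.null(factor)) records <- records[records$factor %in% factor, ]
  props <- sort(unique(records$property))
  perts <- unique(records$perturbation_id)
  P <- length(props)
  wide <- matrix(NA_real_, length(perts), P,
                 dimnames = list(perts, props))
  wide[cbind(match(records$perturbation_id, perts),
             match(records$property, props))] <- records$rr
  sgn <- observed_sign(wide, zero_tolerance)

  counts <- mism <- matrix(0L, P, P, dimnames = list(props, props))
  prop <- matrix(NA_real_, P, P, dimnames = list(props, props))
  diag(prop) <- 0
  any_pair <- FALSE
  if (P >= 2L) {
    for (i in seq_len(P - 1L)) {
      for (j in seq.int(i + 1L, P)) {
        ok <- !is.na(sgn[, i]) & !is.na(sgn[, j]) &
          sgn[, i] != 0 & sgn[, j] != 0
        n <- sum(ok)
        counts[i, j] <- counts[j, i] <- n
        m <- sum(sgn[ok, i] * sgn[ok, j] < 0)
        mism[i, j] <- mism[j, i] <- m
        if (n > 0L) any_pair <- TRUE
        if (n >= min_pairs) prop[i, j] <- prop[j, i] <- m / n
      }
    }
  }
  if (!any_pair) {
    warning("no property pair shares any perturbation; matrix is empty",
            call. = FALSE)
  }
  structure(list(proportion = prop, counts = counts, mismatches = mism,
                 properties = props, min_pairs = min_pairs,
                 group = list(biome = biome, factor = factor),
                 n_perturbations = length(perts)),
            class = "mismatch_matrix")
}

#' @export
print.mismatch_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<mismatch_matrix: %d properties, %d perturbations, cutoff %d>\n",
              length(x$properties), x$n_perturbations, x$min_pairs))
  print(round(x$proportion, digits))
  invisible(x)
}

#' Write a mismatch matrix (proportions and counts) to CSV
#'
#' @param matrix a [build_mismatch_matrix()] object.
#' @param path base path; writes `<path>_proportions.csv` and
#'   `<path>_counts.csv`.
#' @return Invisibly, the two paths written.
#' @export
write_mismatch_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "mismatch_matrix"))
  p1 <- paste0(path, "_proportions.csv")
  p2 <- paste0(path, "_counts.csv")
  utils::write.csv(matrix$proportion, p1)
  utils::write.csv(matrix$counts, p2)
  invisible(c(p1, p2))
}
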