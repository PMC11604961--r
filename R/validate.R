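# Angular-consistency validation test: leave one property pair out and
# predict its mismatch proportion from all remaining pairs through a
# low-rank Gram-matrix embedding. A strong predicted-vs-observed
# correlation supports treating the properties as directions in a shared
# phase space; an inconclusive result does not by itself invalidate it,
# since the matrix completion can introduce artefacts.

# Alternating-projection completion of a unit-diagonal cosine matrix.
# G has NA at unknown entries. Repeats: project onto rank-`rank` PSD
# matrices (truncated eigendecomposition), renormalize to unit diagonal,
# re-impose known entries. The rank constraint makes the problem
# nonconvex, so the iteration is restarted from several initial values of
# the unknown entries and the completion that best reproduces the known
# cosines is kept. Returns the completed normalized matrix.
complete_gram <- function(G, rank, max_iter = 2000, tol = 1e-13,
                          starts = c(0.9, 0.5, 0, -0.5)) {
  known <- !is.na(G)
  diag(known) <- TRUE
  best <- NULL
  best_err <- Inf
  for (s0 in starts) {
    cur <- G
    cur[!known] <- s0
    diag(cur) <- 1
    norm <- cur
    for (it in seq_len(max_iter)) {
      eg <- eigen((cur + t(cur)) / 2, symmetric = TRUE)
      vals <- pmax(eg$values, 0)
      if (rank < length(vals)) vals[-seq_len(rank)] <- 0
      low <- eg$vectors %*% (vals * t(eg$vectors))
      d <- sqrt(pmax(diag(low), 1e-300))
      norm <- low / outer(d, d)
      nxt <- norm
      nxt[known] <- G[known]
      diag(nxt) <- 1
      delta <- max(abs(nxt - cur))
      cur <- nxt
      if (delta < tol) break
    }
    err <- max(abs(norm[known] - G[known]))
    if (err < best_err) {
      best_err <- err
      best <- norm
    }
  }
  best
}

# is the graph over properties connected, using `mask` as the edge set?
edges_connected <- function(mask) {
  diag(mask) <- FALSE
  if (!any(mask)) return(FALSE)
  g <- igraph::graph_from_adjacency_matrix(mask, mode = "undirected")
  igraph::is_connected(g)
}

#' Validation test: leave-pair-out prediction of mismatch proportions
#'
#' Converts the mismatch matrix to cosines G_ij = cos(pi P_ij), and for
#' each unmasked property pair (i, j) holds that entry out, completes the
#' remaining cosine matrix with a rank-`rank` positive-semidefinite
#' embedding (unit vectors whose Gram matrix best matches the known
#' cosines), and predicts P_ij = arccos(G_ij) / pi from the completed
#' entry. Pairs whose removal disconnects the known-entry graph are
#' skipped with a flag.
#'
#' @param matrix a [build_mismatch_matrix()] object.
#' @param rank embedding rank; default `min(P - 1, 5)` where P is the
#'   number of properties. The true phase-space dimension is unknown, so a
#'   sensitivity check over ranks ([validation_rank_sweep()]) is
#'   recommended.
#' @param max_iter,tol completion iteration controls.
#' @return Object of class `"validation_test"`: list with `table`
#'   (property_a, property_b, observed, predicted, n), `correlation`
#'   (Pearson, predicted vs observed), `rank`, `n_skipped`.
#' @export
validation_test <- function(matrix, rank = NULL, max_iter = 2000,
                            tol = 1e-13) {
  stopifnot(inherits(matrix, "mismatch_matrix"))
  P <- matrix$proportion
  # properties with no unmasked pair at all cannot be embedded; drop them
  off <- P
  diag(off) <- NA
  keep <- rowSums(!is.na(off)) > 0
  if (!all(keep)) {
    warning(sprintf("dropping properties with no unmasked pair: %s",
                    paste(matrix$properties[!keep], collapse = ", ")),
            call. = FALSE)
    P <- P[keep, keep, drop = FALSE]
    matrix$counts <- matrix$counts[keep, keep, drop = FALSE]
    matrix$properties <- matrix$properties[keep]
  }
  np <- nrow(P)
  if (np < 3L) {
    stop("insufficient matrix: fewer than 3 embeddable properties",
         call. = FALSE)
  }
  if (is.null(rank)) rank <- max(1L, min(np - 1L, 5L))
  if (rank < 1L) stop("`rank` must be >= 1", call. = FALSE)
  G <- cos(pi * P)
  diag(G) <- 1
  known <- !is.na(G)
  out <- list()
  n_skipped <- 0L
  for (i in seq_len(np - 1L)) {
    for (j in seq.int(i + 1L, np)) {
      if (is.na(P[i, j])) next
      mask <- known
      mask[i, j] <- mask[j, i] <- FALSE
      if (!edges_connected(mask)) {
        n_skipped <- n_skipped + 1L
        next
      }
      Gho <- G
      Gho[i, j] <- Gho[j, i] <- NA
      comp <- complete_gram(Gho, rank, max_iter, tol)
      pred <- acos(clamp(comp[i, j], -1, 1)) / pi
      out[[length(out) + 1L]] <- data.frame(
        property_a = matrix$properties[i],
        property_b = matrix$properties[j],
        observed = P[i, j], predicted = pred,
        n = matrix$counts[i, j], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    stop("insufficient matrix: every pair was masked or skipped",
         call. = FALSE)
  }
  tab <- do.call(rbind, out)
  correlation <- if (nrow(tab) >= 3 && stats::sd(tab$observed) > 0 &&
                     stats::sd(tab$predicted) > 0) {
    stats::cor(tab$observed, tab$predicted)
  } else NA_real_
  structure(list(table = tab, correlation = correlation, rank = rank,
                 n_skipped = n_skipped),
            class = "validation_test")
}

#' @export
print.validation_test <- function(x, ...) {
  cat(sprintf("<validation_test: %d pairs, rank %d, r = %.3f, %d skipped>\n",
              nrow(x$table), x$rank,
              if (is.na(x$correlation)) NA else x$correlation, x$n_skipped))
  invisible(x)
}

#' Rank-sensitivity sweep of the validation test
#'
#' @param matrix a [build_mismatch_matrix()] object.
#' @param ranks integer ranks to try; default `1:min(P - 1, 6)`.
#' @param ... passed to [validation_test()].
#' @return data.frame with columns `rank`, `correlation`, `n_pairs`.
#' @export
validation_rank_sweep <- function(matrix, ranks = NULL, ...) {
  stopifnot(inherits(matrix, "mismatch_matrix"))
  np <- length(matrix$properties)
  if (is.null(ranks)) ranks <- seq_len(max(1L, min(np - 1L, 6L)))
  res <- lapply(ranks, function(r) {
    vt <- validation_test(matrix, rank = r, ...)
    data.frame(rank = r, correlation = vt$correlation,
               n_pairs = nrow(vt$table))
  })
  do.call(rbind, res)
}
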