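# Shared fixtures, all generated in code.

# Two nonnegative unit directions in S dimensions at an exact angle theta
# (theta in [0, pi/2]): e1 and cos(theta) e1 + sin(theta) e2, padded.
directions_with_angle <- function(theta, S) {
  u <- c(1, rep(0, S - 1))
  v <- c(cos(theta), sin(theta), rep(0, S - 2))
  list(u = u, v = v)
}

# A two-level contribution vector with a prescribed broadness b in (1/S, 1]:
# m entries equal 1, the rest equal t solved by root finding.
direction_with_broadness <- function(b, S) {
  stopifnot(b > 1 / S, b <= 1)
  m <- max(1L, floor(b * S / 2))
  f <- function(t) broadness(c(rep(1, m), rep(t, S - m))) - b
  t <- stats::uniroot(f, c(1e-9, 1), tol = 1e-12)$root
  c(rep(1, m), rep(t, S - m))
}

# Minimal effect-size table builder.
make_records <- function(perturbation_id, property, rr,
                         factor = "warming", biome = "grassland",
                         study_id = "s1") {
  data.frame(study_id = study_id, perturbation_id = perturbation_id,
             factor = factor, biome = biome, property = property, rr = rr,
             stringsAsFactors = FALSE)
}

# A mismatch_matrix built exactly from a set of directions (P = theta/pi,
# no sampling noise), as produced by an idealized infinite experiment.
gram_consistent_matrix <- function(dirs, counts = 100L) {
  P <- length(dirs)
  prop <- matrix(0, P, P)
  for (i in seq_len(P - 1)) {
    for (j in seq.int(i + 1, P)) {
      prop[i, j] <- prop[j, i] <- angle_between(dirs[[i]], dirs[[j]]) / pi
    }
  }
  nm <- paste0("f", seq_len(P))
  dimnames(prop) <- list(nm, nm)
  structure(list(proportion = prop,
                 counts = matrix(counts, P, P, dimnames = dimnames(prop)),
                 mismatches = round(prop * counts),
                 properties = nm, min_pairs = 1L,
                 group = list(biome = NULL, factor = NULL),
                 n_perturbations = counts),
            class = "mismatch_matrix")
}

# Directions spanning a rank-r positive cone (so the Gram matrix of any
# subset has rank at most r).
cone_directions <- function(n, S, r, seed = 1) {
  set.seed(seed)
  base <- matrix(stats::rexp(S * r), S, r)
  W <- matrix(stats::runif(n * r), n, r)
  lapply(seq_len(n), function(i) as.vector(base %*% W[i, ]))
}
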