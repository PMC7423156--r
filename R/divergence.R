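# Cross-brain comparison of connectivity blueprints by Kullback-Leibler
# divergence: minimum-divergence maps, best-match fingerprints, tract-swap
# difference maps, divergence distributions and their Kolmogorov-Smirnov
# comparison.

.KL_EPS <- 1e-8

#' Kullback-Leibler divergence between two fingerprints
#'
#' `sum_i p_i * ln((p_i + eps) / (q_i + eps))` in nats with a symmetric
#' regularizer `eps = 1e-8`; terms with `p_i = 0` contribute nothing.  Both
#' fingerprints must be normalized probability distributions over the same
#' tract space.
#'
#' @param p,q numeric fingerprints of equal length summing to 1 (1e-6).
#' @return Non-negative divergence (up to the eps-induced error of order
#'   1e-6 near zero).
#' @export
klDivergence <- function(p, q) {
  if (length(p) != length(q)) .stopf("fingerprints differ in length")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    .stopf("fingerprints must be normalized to sum 1")
  nz <- p > 0
  sum(p[nz] * (log(p[nz] + .KL_EPS) - log(q[nz] + .KL_EPS)))
}

# Full KL matrix between rows of P (na x T) and rows of Q (nb x T):
# KL[i, j] = sum_t P[i,t] (log(P[i,t]+eps) - log(Q[j,t]+eps)); zero P terms
# vanish because they are multiplied by P.
.klCross <- function(P, Q) {
  self <- rowSums(P * log(P + .KL_EPS))
  cross <- P %*% t(log(Q + .KL_EPS))
  kl <- self - cross
  kl[kl < 0] <- 0  # clip the eps-induced negative dust near identity
  kl
}

# Align Q's tract columns with P's; identical tract name sets required.
.alignTracts <- function(bpA, bpB) {
  if (!length(intersect(bpA@tractNames, bpB@tractNames)))
    .stopf("blueprints share no tract names")
  if (!setequal(bpA@tractNames, bpB@tractNames))
    .stopf("blueprints must be built over the same tract space")
  match(bpA@tractNames, bpB@tractNames)
}

#' Minimum-KL divergence map between two blueprints
#'
#' For every defined vertex of `bpA` (non-zero fingerprint), the minimum KL
#' divergence over all defined vertices of `bpB`, with the best-matching
#' vertex recorded; ties go to the lowest vertex id.  Zero-fingerprint
#' vertices on either side are excluded from the matching pool and map to
#' `NA`.
#'
#' @param bpA,bpB [Blueprint-class] over the same tract space.
#' @return A [DivergenceMap-class] in direction `"A->B"` (`bpA` rows,
#'   matched into `bpB`).
#' @export
minKlMap <- function(bpA, bpB) {
  ord <- .alignTracts(bpA, bpB)
  defA <- which(!bpA@zeroRows)
  defB <- which(!bpB@zeroRows)
  nA <- nrow(bpA@matrix)
  minKl <- rep(NA_real_, nA)
  best <- rep(NA_integer_, nA)
  if (length(defA) && length(defB)) {
    P <- bpA@matrix[defA, , drop = FALSE]
    Q <- bpB@matrix[defB, ord, drop = FALSE]
    kl <- .klCross(P, Q)
    j <- apply(kl, 1L, which.min)   # first minimum = lowest vertex id
    minKl[defA] <- kl[cbind(seq_along(defA), j)]
    best[defA] <- bpB@vertexIds[defB][j]
  }
  new("DivergenceMap", minKl = minKl, bestMatch = best,
      vertexIds = bpA@vertexIds, direction = "A->B")
}

#' Mean fingerprint of the n best-matching vertices
#'
#' @param vertex vertex id in `bpA`.
#' @param bpA,bpB [Blueprint-class] over the same tract space.
#' @param n number of lowest-KL matches to average (default 10).
#' @return Named numeric fingerprint (a probability distribution).
#' @export
bestMatchFingerprint <- function(vertex, bpA, bpB, n = 10L) {
  ord <- .alignTracts(bpA, bpB)
  i <- match(vertex, bpA@vertexIds)
  if (is.na(i)) .stopf("vertex %s not in blueprint A", vertex)
  if (bpA@zeroRows[i]) .stopf("vertex %s has a zero fingerprint", vertex)
  defB <- which(!bpB@zeroRows)
  if (length(defB) < n)
    .stopf("blueprint B has only %d defined vertices (< n = %d)", length(defB), n)
  P <- bpA@matrix[i, , drop = FALSE]
  Q <- bpB@matrix[defB, ord, drop = FALSE]
  kl <- as.vector(.klCross(P, Q))
  pick <- order(kl)[seq_len(n)]
  fp <- colMeans(bpB@matrix[defB[pick], ord, drop = FALSE])
  setNames(fp, bpA@tractNames)
}

#' Divergence difference map between two blueprint variants
#'
#' Computes the per-vertex difference `minKl(bpA vs variant1) - minKl(bpA vs
#' variant2)`: positive values mean variant 2 provides the better match for
#' that vertex.  Used to compare which subcomponent of a split bundle
#' better predicts the unsplit bundle of the other brain.
#'
#' @param bpA reference [Blueprint-class].
#' @param bpVariant1,bpVariant2 variant blueprints of the other brain over
#'   the same tract space (the swapped tract occupying the same column slot).
#' @return Named numeric per-vertex difference (`NA` where undefined).
#' @export
swapVariantMaps <- function(bpA, bpVariant1, bpVariant2) {
  if (!identical(bpVariant1@tractNames, bpVariant2@tractNames))
    .stopf("variant blueprints must share the same tract column slots")
  m1 <- minKlMap(bpA, bpVariant1)
  m2 <- minKlMap(bpA, bpVariant2)
  setNames(m1@minKl - m2@minKl, bpA@vertexIds)
}

#' Distribution of strictly positive minimum divergences
#'
#' The vertices entering the distribution are those with a defined, strictly
#' positive minimum divergence — vertices whose fingerprints differ at all
#' from their best match — optionally restricted to a vertex mask such as a
#' tract territory.
#'
#' @param divmap a [DivergenceMap-class].
#' @param vertexMask logical over the map's vertices, or `NULL` for all.
#' @return Numeric sample (possibly empty, with a warning).
#' @export
klDistribution <- function(divmap, vertexMask = NULL) {
  v <- divmap@minKl
  if (!is.null(vertexMask)) {
    if (length(vertexMask) != length(v)) .stopf("mask length mismatch")
    v <- v[vertexMask]
  }
  out <- v[!is.na(v) & v > 0]
  if (!length(out)) .warnf("no positive divergence values after filtering")
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test with the asymptotic p-value, comparing two
#' distributions of minimum divergence scores.
#'
#' @param sampleA,sampleB non-empty numeric samples.
#' @return List with `D` (the supremum ECDF distance) and `p`.
#' @export
ksCompare <- function(sampleA, sampleB) {
  if (!length(sampleA) || !length(sampleB)) .stopf("samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(sampleA, sampleB, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}
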