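#' Correlation between estimated and reference connectivity
#'
#' Pearson correlation over all strictly off-diagonal entry pairs (zeros
#' included). With `mirrored = TRUE` the estimate is symmetrized with
#' [mirror_network()] first, for comparison against symmetric references.
#'
#' @param est,truth equal-sized square numeric matrices.
#' @param mirrored symmetrize `est` before comparing.
#' @return Pearson r, or `NA` (with a warning) if either side has zero
#'   variance.
#' @export
weight_correlation <- function(est, truth, mirrored = FALSE) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  if (!all(dim(est) == dim(truth))) stop("matrices must have equal shapes")
  if (mirrored) est <- mirror_network(est)
  a <- offdiag_values(est); b <- offdiag_values(truth)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in off-diagonal weights: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Area under the ROC curve for edge detection
#'
#' Rank-based AUC over the strictly off-diagonal entries, using the score
#' magnitude `|score|` as the ranking statistic (ties get averaged ranks).
#' Equals the probability that a randomly chosen true edge outranks a
#' randomly chosen non-edge.
#'
#' @param scores square numeric (or complex) score matrix.
#' @param truth_adjacency square matrix; nonzero (or `TRUE`) off-diagonal
#'   entries are the true edges.
#' @param use_magnitude rank by `|score|` (default) rather than the signed
#'   score.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth_adjacency, use_magnitude = TRUE) {
  scores <- as.matrix(scores); truth_adjacency <- as.matrix(truth_adjacency)
  if (!all(dim(scores) == dim(truth_adjacency)))
    stop("matrices must have equal shapes")
  s <- offdiag_values(scores)
  s <- if (use_magnitude) Mod(s) else Re(s)
  y <- offdiag_values(truth_adjacency) != 0
  ok <- is.finite(s)
  s <- s[ok]; y <- y[ok]
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop("truth must contain at least one edge and one non-edge")
  r <- rank(s)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Correlation between connectivity estimates at different frequencies
#'
#' Pairwise [weight_correlation()] between the signed-weight slices of the
#' estimate; the resulting `F x F` matrix (symmetric, unit diagonal) shows
#' which frequencies carry the same network and is the basis for choosing
#' frequency bands.
#'
#' @param est a `connectivity_estimate` with at least 2 frequencies.
#' @return `F x F` correlation matrix (degenerate slices give `NA`
#'   rows/columns).
#' @export
interfrequency_similarity <- function(est) {
  stopifnot(inherits(est, "connectivity_estimate"))
  F <- length(est$frequencies)
  if (F < 2L) stop("need at least 2 frequencies")
  out <- diag(1, F)
  for (i in seq_len(F - 1)) for (j in (i + 1):F) {
    r <- suppressWarnings(
      weight_correlation(est$signed_weights[, , i], est$signed_weights[, , j]))
    out[i, j] <- out[j, i] <- r
  }
  dimnames(out) <- list(format(est$frequencies), format(est$frequencies))
  out
}

#' Threshold matched to a target false-positive rate
#'
#' Finds the smallest magnitude threshold such that the fraction of
#' reference-negative off-diagonal entries with `|est|` above it does not
#' exceed `target_fpr`.
#'
#' @param est square numeric matrix of estimated weights.
#' @param reference square matrix; nonzero off-diagonal entries are reference
#'   positives.
#' @param target_fpr target false-positive rate in (0, 1] .
#' @return List with `threshold` and `achieved_fpr`.
#' @export
fpr_matched_threshold <- function(est, reference, target_fpr) {
  est <- as.matrix(est); reference <- as.matrix(reference)
  if (!all(dim(est) == dim(reference))) stop("matrices must have equal shapes")
  if (target_fpr <= 0 || target_fpr > 1)
    stop("`target_fpr` must be in (0, 1]")
  neg <- offdiag_values(reference) == 0
  if (!any(neg)) stop("reference has no negative (absent) connections")
  vals <- Mod(offdiag_values(est))[neg]
  cand <- sort(unique(c(0, vals)))
  for (t in cand) {
    fpr <- mean(vals > t)
    if (fpr <= target_fpr) return(list(threshold = t, achieved_fpr = fpr))
  }
  list(threshold = max(vals), achieved_fpr = 0)
}

#' Agreement summary between an estimated and a reference network
#'
#' Classifies each off-diagonal connection present in either network as
#' present in both, estimate-only, or reference-only, and reports the three
#' percentages relative to the union of present connections, plus the edge
#' densities of both networks.
#'
#' @param est square matrix (thresholded estimate; symmetrize with
#'   [mirror_network()] first when the reference is symmetric).
#' @param reference square matrix; nonzero entries are reference edges.
#' @return List with `pct_both`, `pct_est_only`, `pct_ref_only` (sum to
#'   100), `density_est`, `density_ref`.
#' @export
coincidence_summary <- function(est, reference) {
  est <- as.matrix(est); reference <- as.matrix(reference)
  if (!all(dim(est) == dim(reference))) stop("matrices must have equal shapes")
  e <- offdiag_values(est) != 0
  s <- offdiag_values(reference) != 0
  union_n <- sum(e | s)
  if (union_n == 0) stop("no connections present in either network")
  list(pct_both = 100 * sum(e & s) / union_n,
       pct_est_only = 100 * sum(e & !s) / union_n,
       pct_ref_only = 100 * sum(!e & s) / union_n,
       density_est = mean(e),
       density_ref = mean(s))
}
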