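# exhaustive minimal-cost one-to-one assignment (small n only)
best_assignment <- function(dmat) {
  nt <- nrow(dmat); ne <- ncol(dmat)
  if (nt > ne) stop("more true sources than estimates to match")
  best <- NULL; best_cost <- Inf
  recurse <- function(row, used, cost, asg) {
    if (cost >= best_cost) return()
    if (row > nt) { best_cost <<- cost; best <<- asg; return() }
    for (c in seq_len(ne)) {
      if (used[c]) next
      used[c] <- TRUE
      recurse(row + 1, used, cost + dmat[row, c], c(asg, c))
      used[c] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, ne), 0, integer(0))
  best
}

#' Source localization error with optimal matching
#'
#' Pairs every true source with a distinct estimated source by the
#' one-to-one assignment minimizing the total Euclidean distance (exhaustive
#' over the at most 5! candidate assignments); extra estimated sources
#' remain unmatched.
#'
#' @param true_locs `n_true x 3` matrix of true locations (m).
#' @param est_locs `n_est x 3` matrix of estimated locations
#'   (`n_est >= n_true`).
#' @return list with `distances` (per true source, m), `mean`, `max`,
#'   `assignment` (estimated index matched to each true source).
#' @export
source_localization_error <- function(true_locs, est_locs) {
  true_locs <- rbind(true_locs); est_locs <- rbind(est_locs)
  if (nrow(true_locs) == 0 || nrow(est_locs) == 0)
    stop("empty location sets")
  d <- outer(seq_len(nrow(true_locs)), seq_len(nrow(est_locs)),
             Vectorize(function(i, j)
               sqrt(sum((true_locs[i, ] - est_locs[j, ])^2))))
  asg <- best_assignment(d)
  dist <- d[cbind(seq_len(nrow(true_locs)), asg)]
  list(distances = dist, mean = mean(dist), max = max(dist),
       assignment = asg)
}

#' Correct-hit (NOC) rate
#'
#' Percentage of realizations whose maximum source localization error falls
#' below `threshold` (default 10 mm).
#'
#' @param max_sles numeric vector of per-realization maximum SLEs (m).
#' @param threshold distance threshold (m, > 0).
#' @return percentage in `[0, 100]`.
#' @export
noc_rate <- function(max_sles, threshold = 0.010) {
  if (length(max_sles) == 0) stop("empty SLE list")
  if (threshold <= 0) stop("`threshold` must be > 0")
  100 * mean(max_sles < threshold)
}

#' Relative error between gPDC spectra
#'
#' Frobenius norm of the difference over the Frobenius norm of the truth,
#' stacked over all frequencies.
#'
#' @param est_gpdc,true_gpdc [gpdc()] objects on the same frequency grid.
#' @return scalar relative error (0 for identical spectra, 1 for a zero
#'   estimate).
#' @export
relative_error <- function(est_gpdc, true_gpdc) {
  stopifnot(inherits(est_gpdc, "gpdc_spectrum"),
            inherits(true_gpdc, "gpdc_spectrum"))
  if (length(est_gpdc$freqs) != length(true_gpdc$freqs) ||
      max(abs(est_gpdc$freqs - true_gpdc$freqs)) > 1e-12 ||
      !all(dim(est_gpdc$values) == dim(true_gpdc$values)))
    stop("frequency grids/dimensions do not match")
  sqrt(sum((est_gpdc$values - true_gpdc$values)^2)) /
    sqrt(sum(true_gpdc$values^2))
}

#' True- and false-positive rates for directed links
#'
#' Off-diagonal comparison of binary connectivity matrices:
#' `TPR = #TP / (#TP + #FN)`, `FPR = #FP / (#FP + #TN)`. The estimated
#' matrix may involve extra sources beyond `n_true_sources` (rows/columns
#' `1..n_true_sources` must already be matched to the truth); any estimated
#' link touching an extra source counts as a false positive, and quiet
#' extra-source pairs count as true negatives.
#'
#' @param est_binary `K x K` logical/0-1 matrix (`K >= n_true_sources`).
#' @param true_binary `n_true x n_true` logical/0-1 matrix.
#' @param n_true_sources number of true sources (default `nrow(true_binary)`).
#' @return list with `tpr`, `fpr`, and `counts` (`tp`, `fn`, `fp`, `tn`);
#'   `tpr` is `NA` (flagged via `tpr_defined`) when the truth has no links.
#' @export
tpr_fpr <- function(est_binary, true_binary,
                    n_true_sources = nrow(true_binary)) {
  est <- as.matrix(est_binary) != 0
  tru <- as.matrix(true_binary) != 0
  K <- nrow(est)
  if (ncol(est) != K) stop("estimated matrix must be square")
  if (nrow(tru) != n_true_sources) stop("truth dimension mismatch")
  full_true <- matrix(FALSE, K, K)
  full_true[seq_len(n_true_sources), seq_len(n_true_sources)] <- tru
  off <- !diag(K)
  tp <- sum(est & full_true & off)
  fn <- sum(!est & full_true & off)
  fp <- sum(est & !full_true & off)
  tn <- sum(!est & !full_true & off)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  list(tpr = tpr, fpr = fp / (fp + tn),
       counts = c(tp = tp, fn = fn, fp = fp, tn = tn),
       tpr_defined = tp + fn > 0)
}

#' Two-level bootstrap mean and standard deviation
#'
#' Draws `B` bootstrap samples of size `S` with replacement, takes the mean
#' of each sample, and reports the mean and SD of those `B` sample means.
#'
#' @param values numeric vector of per-realization metric values.
#' @param B number of bootstrap sets (default 100).
#' @param S bootstrap sample size (default 50).
#' @return list with `mean`, `sd` (0 and flagged when `B = 1`), `B`, `S`.
#' @export
bootstrap_summary <- function(values, B = 100L, S = 50L) {
  if (length(values) == 0) stop("empty value vector")
  if (B < 1 || S < 1) stop("B and S must be >= 1")
  means <- vapply(seq_len(B), function(b)
    mean(values[sample.int(length(values), S, replace = TRUE)]), numeric(1))
  list(mean = mean(means),
       sd = if (B == 1) 0 else sd(means),
       degenerate = B == 1, B = B, S = S)
}
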