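# Accuracy of the dimer-likelihood score against observed dimer reads.
#
# The evaluation universe is all (2N)^2 ordered primer pairs, self-pairs
# included. A pair is an observed dimer when its dimer read count exceeds a
# reads threshold (conventionally the mean on-target read depth), and a
# predicted dimer when its badness exceeds a badness threshold. Sweeping
# the badness threshold yields an ROC curve; the trapezoidal area under it
# summarizes how well the score discriminates real dimers.

#' Flatten score and count matrices into ordered pair observations
#'
#' @param badness 2N x 2N badness matrix (symmetric).
#' @param dimer_reads 2N x 2N observed dimer read-count matrix. Counts are
#'   symmetrized (both orderings of a pair share the summed count) so each
#'   ordered pair carries one badness and one read value.
#' @return data.frame with columns `a`, `b` (1-based primer indices),
#'   `badness`, `dimer_reads`; `(2N)^2` rows.
#' @export
pair_observations <- function(badness, dimer_reads) {
  stopifnot(is.matrix(badness), is.matrix(dimer_reads),
            all(dim(badness) == dim(dimer_reads)),
            nrow(badness) == ncol(badness))
  n <- nrow(badness)
  reads_sym <- dimer_reads + t(dimer_reads)
  diag(reads_sym) <- diag(dimer_reads)
  grid <- expand.grid(a = seq_len(n), b = seq_len(n))
  data.frame(a = grid$a, b = grid$b,
             badness = badness[cbind(grid$a, grid$b)],
             dimer_reads = reads_sym[cbind(grid$a, grid$b)])
}

#' Label observed dimers
#'
#' A pair is positive when its dimer read count strictly exceeds the reads
#' threshold.
#'
#' @param obs data.frame with a `dimer_reads` column.
#' @param reads_threshold non-negative threshold (typically the mean
#'   on-target read depth).
#' @return logical vector.
#' @export
label_observed <- function(obs, reads_threshold) {
  stopifnot(reads_threshold >= 0)
  obs$dimer_reads > reads_threshold
}

#' Sensitivity and specificity at fixed thresholds
#'
#' Predicted positives are pairs with badness strictly above
#' `badness_threshold`; observed positives come from [label_observed()].
#'
#' @param obs pair observations ([pair_observations()]).
#' @param reads_threshold observed-dimer threshold.
#' @param badness_threshold predicted-dimer threshold.
#' @return named numeric `c(sensitivity, specificity)`; sensitivity is
#'   `NaN` (with a warning) when there are no observed positives.
#' @export
sens_spec <- function(obs, reads_threshold, badness_threshold) {
  truth <- label_observed(obs, reads_threshold)
  pred <- obs$badness > badness_threshold
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L) {
    warning("no observed positives; sensitivity is undefined", call. = FALSE)
    sens <- NaN
  } else sens <- sum(pred & truth) / n_pos
  spec <- if (n_neg == 0L) NaN else sum(!pred & !truth) / n_neg
  c(sensitivity = sens, specificity = spec)
}

#' ROC curve and AUROC of the badness score
#'
#' Sweeps the badness threshold over all unique score values and computes
#' the trapezoidal area under the resulting sensitivity / (1 - specificity)
#' staircase. Invariant under strictly monotone transforms of the score.
#'
#' @param obs pair observations.
#' @param reads_threshold observed-dimer threshold.
#' @return list of class `badness_roc`: `points` (data.frame
#'   `badness_threshold`, `sensitivity`, `specificity`), `auroc`,
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(obs, reads_threshold) {
  truth <- label_observed(obs, reads_threshold)
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs at least one positive and one negative pair",
         call. = FALSE)
  thr <- sort(unique(obs$badness), decreasing = TRUE)
  ord <- order(obs$badness, decreasing = TRUE)
  bad_sorted <- obs$badness[ord]
  truth_sorted <- truth[ord]
  cum_tp <- cumsum(truth_sorted)
  cum_fp <- cumsum(!truth_sorted)
  # predicted positive means badness > t: count scores strictly above t
  last_gt <- vapply(thr, function(t) sum(bad_sorted > t), integer(1L))
  tp <- c(0L, cum_tp[pmax(last_gt, 1L)] * (last_gt > 0L))
  fp <- c(0L, cum_fp[pmax(last_gt, 1L)] * (last_gt > 0L))
  sens <- tp / n_pos
  fpr <- fp / n_neg
  # ensure the staircase ends at (1, 1): threshold below the minimum score
  sens <- c(sens, 1)
  fpr <- c(fpr, 1)
  auroc <- sum(diff(fpr) * (head(sens, -1) + sens[-1]) / 2)
  points <- data.frame(badness_threshold = c(Inf, thr, -Inf),
                       sensitivity = sens, specificity = 1 - fpr)
  structure(list(points = points, auroc = auroc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "badness_roc")
}

#' Badness threshold maximizing sensitivity + specificity
#'
#' @param obs pair observations.
#' @param reads_threshold observed-dimer threshold.
#' @return list: `badness_threshold`, `sensitivity`, `specificity`.
#' @export
best_threshold <- function(obs, reads_threshold) {
  roc <- roc_auc(obs, reads_threshold)
  j <- roc$points$sensitivity + roc$points$specificity
  i <- which.max(j)
  list(badness_threshold = roc$points$badness_threshold[i],
       sensitivity = roc$points$sensitivity[i],
       specificity = roc$points$specificity[i])
}

#' Top-k observed and predicted dimer species
#'
#' Ranks ordered pairs by observed dimer reads and by predicted badness
#' (ties broken by the other score, then by index) and reports the overlap
#' between the two top-k lists. Each unordered pair is reported once.
#'
#' @param obs pair observations.
#' @param k list length.
#' @return list of class `top_k_report`: `observed`, `predicted` (ranked
#'   data.frames) and `overlap` (count of shared pairs).
#' @export
top_k_report <- function(obs, k = 5L) {
  un <- obs[obs$a <= obs$b, , drop = FALSE]
  key <- paste(un$a, un$b, sep = ":")
  by_obs <- un[order(-un$dimer_reads, -un$badness, un$a, un$b), ][seq_len(k), ]
  by_pred <- un[order(-un$badness, -un$dimer_reads, un$a, un$b), ][seq_len(k), ]
  overlap <- length(intersect(paste(by_obs$a, by_obs$b, sep = ":"),
                              paste(by_pred$a, by_pred$b, sep = ":")))
  structure(list(observed = by_obs, predicted = by_pred, overlap = overlap),
            class = "top_k_report")
}
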