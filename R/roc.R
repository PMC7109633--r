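checkTwoClasses <- function(labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be binary (0/1 or logical)")
  if (all(labels) || !any(labels))
    stop("undefined-AUC error: both classes must be present")
  labels
}

#' Area under the ROC curve (rank statistic)
#'
#' `AUC = P(score_pos > score_neg) + 1/2 P(tie)`, computed from the
#' Mann-Whitney rank statistic; identical to the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores numeric classifier scores (here: aspect ratios).
#' @param labels binary outcomes (1 = divided).
#' @return AUC in `[0, 1]`.
#' @examples
#' aucRank(c(0.2, 0.8, 0.4, 0.6), c(0, 1, 1, 0))  # 0.75
#' @export
aucRank <- function(scores, labels) {
  labels <- checkTwoClasses(labels)
  stopifnot(length(scores) == length(labels))
  r <- rank(scores, ties.method = "average")
  nPos <- sum(labels); nNeg <- sum(!labels)
  U <- sum(r[labels]) - nPos * (nPos + 1) / 2
  U / (nPos * nNeg)
}

#' Empirical ROC curve points
#'
#' One operating point per distinct threshold (ties grouped), ordered from
#' (0, 0) to (1, 1), using the rule `score > threshold` => predicted
#' positive.
#'
#' @inheritParams aucRank
#' @return data.frame (threshold, fpr, tpr); the first row is threshold
#'   `Inf` at (0, 0), the last `-Inf` at (1, 1).
#' @export
rocPoints <- function(scores, labels) {
  labels <- checkTwoClasses(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  keep <- c(diff(s) != 0, TRUE)          # last index of each tie group
  tp <- cumsum(l)[keep]
  fp <- cumsum(!l)[keep]
  pts <- data.frame(threshold = c(Inf, s[keep]),
                    fpr = c(0, fp / sum(!labels)),
                    tpr = c(0, tp / sum(labels)))
  last <- nrow(pts)
  if (pts$fpr[last] < 1 || pts$tpr[last] < 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  pts
}

trapezoidArea <- function(points) {
  sum(diff(points$fpr) * (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
}

#' Youden-optimal score threshold
#'
#' Scans all cuts between consecutive distinct scores and returns the
#' midpoint maximizing Youden's J = TPR - FPR (rule `score > cut`). Ties are
#' broken toward the widest score gap. For perfectly separated classes this
#' is the midpoint between the largest negative and the smallest positive
#' score.
#'
#' @inheritParams aucRank
#' @return estimated threshold (same units as the scores).
#' @export
thresholdEstimate <- function(scores, labels) {
  labels <- checkTwoClasses(labels)
  s <- sort(unique(scores))
  if (length(s) < 2L) stop("need at least two distinct scores")
  cuts <- (s[-length(s)] + s[-1]) / 2
  gaps <- diff(s)
  J <- vapply(cuts, function(c) {
    mean(scores[labels] > c) - mean(scores[!labels] > c)
  }, numeric(1))
  best <- which(J == max(J))
  cuts[best[which.max(gaps[best])]]
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples positives and negatives separately (class sizes preserved) and
#' returns the percentile 2.5/97.5 interval of the AUC over the replicates.
#' Seeded and reproducible; R's global RNG state is restored on exit.
#'
#' @inheritParams aucRank
#' @param n number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return numeric `c(lower, upper)`.
#' @export
bootstrapCI <- function(scores, labels, n = 2000L, seed = 1L) {
  labels <- checkTwoClasses(labels)
  stopifnot(n >= 100L)
  pos <- which(labels); neg <- which(!labels)
  withSeed(seed, {
    reps <- vapply(seq_len(n), function(i) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      aucRank(scores[idx], labels[idx])
    }, numeric(1))
    unname(quantile(reps, c(0.025, 0.975)))
  })
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Normal approximation with tie correction (no continuity correction, so
#' identical samples give p = 1).
#'
#' @param a,b numeric samples (both non-empty).
#' @return list(statistic = U, p).
#' @export
rankSumTest <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = FALSE, correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Full ROC analysis of division scores
#'
#' @inheritParams aucRank
#' @param nBoot bootstrap replicates for the CI.
#' @param seed seed for the bootstrap.
#' @return a [RocResult-class].
#' @export
rocAnalysis <- function(scores, labels, nBoot = 2000L, seed = 1L) {
  labels <- checkTwoClasses(labels)
  new("RocResult",
      points = rocPoints(scores, labels),
      auc = aucRank(scores, labels),
      ci = bootstrapCI(scores, labels, n = nBoot, seed = seed),
      threshold = thresholdEstimate(scores, labels),
      n = c(negative = sum(!labels), positive = sum(labels)))
}
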