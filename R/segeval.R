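#' @include AllClasses.R labeling.R
NULL

#' Dice overlap between two masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}. When both masks are empty the score is
#' defined as 1.0 and flagged degenerate (attribute `degenerate`), which
#' keeps cohort means defined while letting callers exclude such cases.
#'
#' @param gt,pred [BinaryMask-class] on the same lattice.
#' @return Dice in \[0, 1\], with attribute `degenerate` (logical).
#' @export
diceScore <- function(gt, pred) {
  stopifnot(is(gt, "BinaryMask"), is(pred, "BinaryMask"))
  stopIfLatticeMismatch(gt, pred, "ground truth and prediction")
  a <- sum(gt@values); b <- sum(pred@values)
  if (a + b == 0) return(structure(1.0, degenerate = TRUE))
  structure(2 * sum(gt@values & pred@values) / (a + b), degenerate = FALSE)
}

#' Mean and global Dice over a set of acquisitions
#'
#' The mean Dice averages per-acquisition scores (each acquisition weighs
#' equally, so it is most hurt by errors on acquisitions with few/small
#' lesions); the global Dice pools all voxels as one acquisition
#' (\eqn{2\sum|A_i \cap B_i| / \sum(|A_i|+|B_i|)}), so it is most hurt by
#' errors on large lesions.
#'
#' @param pairs list of list(gt = [BinaryMask-class],
#'   pred = [BinaryMask-class]).
#' @return list(per_acquisition, mean, sd, global_dice, n_degenerate).
#' @export
diceSummary <- function(pairs) {
  if (length(pairs) == 0) stop("empty acquisition list", call. = FALSE)
  per <- numeric(length(pairs))
  degen <- logical(length(pairs))
  inter <- 0; tot <- 0
  for (i in seq_along(pairs)) {
    gt <- pairs[[i]]$gt; pred <- pairs[[i]]$pred
    d <- diceScore(gt, pred)
    per[i] <- as.numeric(d)
    degen[i] <- attr(d, "degenerate")
    inter <- inter + sum(gt@values & pred@values)
    tot <- tot + sum(gt@values) + sum(pred@values)
  }
  list(per_acquisition = per,
       mean = mean(per),
       sd = if (length(per) > 1) stats::sd(per) else NA_real_,
       global_dice = if (tot > 0) 2 * inter / tot else 1.0,
       n_degenerate = sum(degen))
}

#' Lesion-wise detection counts at an overlap threshold
#'
#' Ground-truth lesions (connected components) are compared against the
#' pooled predicted segmentation: a GT lesion with
#' \eqn{|component \cap pred| / |component| \ge threshold} is a true
#' positive, otherwise a false negative. Symmetrically, a predicted
#' component whose overlap with the pooled ground truth is *strictly below*
#' the threshold is a false positive (a predicted component at exactly the
#' threshold is not FP). The overlap denominator is always the component's
#' own volume.
#'
#' @param gt,pred [BinaryMask-class] on the same lattice.
#' @param threshold overlap fraction (default 0.5, the 50 percent rule).
#' @param connectivity component connectivity (default 26, consistent with
#'   lesion labeling).
#' @return list(tp, fn, fp, recall, precision); recall/precision are NA
#'   when their denominator is 0.
#' @export
detectionCounts <- function(gt, pred, threshold = 0.5, connectivity = 26L) {
  stopifnot(is(gt, "BinaryMask"), is(pred, "BinaryMask"))
  stopIfLatticeMismatch(gt, pred, "ground truth and prediction")
  gtl <- labelLesions(gt, connectivity)
  prl <- labelLesions(pred, connectivity)
  overlapFractions <- function(lm, other) {
    K <- nLesions(lm)
    if (K == 0) return(numeric(0))
    inl <- lm@labels > 0L
    lab <- lm@labels[inl]
    n <- tabulate(lab, nbins = K)
    o <- tabulate(lab[other@values[inl]], nbins = K)
    o / n
  }
  fGT <- overlapFractions(gtl, pred)
  fPR <- overlapFractions(prl, gt)
  tp <- sum(fGT >= threshold)
  fn <- sum(fGT < threshold)
  fp <- sum(fPR < threshold)
  list(tp = tp, fn = fn, fp = fp,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Segmentation evaluation table for a set of acquisitions
#'
#' Per-acquisition Dice and detection counts plus a pooled summary row
#' (mean Dice with sd, global Dice, pooled recall/precision from summed
#' TP/FN/FP).
#'
#' @inheritParams diceSummary
#' @param threshold detection overlap threshold.
#' @param connectivity component connectivity.
#' @param ids optional character vector of acquisition identifiers.
#' @return data.frame; the last row (`id == "ALL"`) is the summary.
#' @export
segEvalTable <- function(pairs, threshold = 0.5, connectivity = 26L,
                         ids = NULL) {
  if (is.null(ids)) ids <- sprintf("acq%03d", seq_along(pairs))
  ds <- diceSummary(pairs)
  rows <- lapply(seq_along(pairs), function(i) {
    dc <- detectionCounts(pairs[[i]]$gt, pairs[[i]]$pred, threshold,
                          connectivity)
    data.frame(id = ids[i], dice = ds$per_acquisition[i], dice_sd = NA_real_,
               tp = dc$tp, fn = dc$fn, fp = dc$fp, recall = dc$recall,
               precision = dc$precision)
  })
  tab <- do.call(rbind, rows)
  tp <- sum(tab$tp); fn <- sum(tab$fn); fp <- sum(tab$fp)
  summary <- data.frame(id = "ALL", dice = ds$mean, dice_sd = ds$sd,
                        tp = tp, fn = fn, fp = fp,
                        recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                        precision = if (tp + fp > 0) tp / (tp + fp)
                                    else NA_real_)
  summary$global_dice <- ds$global_dice
  tab$global_dice <- NA_real_
  rbind(tab, summary)
}
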