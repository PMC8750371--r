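#' @include AllClasses.R
NULL

#' Relative biomarker change between baseline and follow-up
#'
#' \eqn{\Delta = 100 (FU - BL) / BL} in percent. Baselines of exactly 0
#' (possible for PBI/PLI) follow a declared policy: 0 -> 0 gives 0 percent
#' (no disease at either timepoint), 0 -> positive gives +Inf (new-lesion
#' appearance, later classified non-responder). Both cases are flagged in
#' the `undefined` attribute.
#'
#' @param bl,fu baseline and follow-up biomarker values (>= 0), vectorised.
#' @return numeric vector of percent changes with logical attribute
#'   `undefined` marking zero-baseline entries.
#' @examples
#' deltaBiomarker(5, 3.4)   # -32 percent
#' @export
deltaBiomarker <- function(bl, fu) {
  if (any(bl < 0 | fu < 0, na.rm = TRUE))
    stop("biomarker values must be non-negative", call. = FALSE)
  d <- 100 * (fu - bl) / bl
  undef <- !is.na(bl) & bl == 0
  d[undef & fu == 0] <- 0
  d[undef & fu > 0] <- Inf
  structure(d, undefined = undef)
}

#' Binarize a PERCIST category into responder / non-responder
#'
#' CR and PR are responders; SD and PD are non-responders.
#'
#' @param label character vector of "CR", "PR", "SD", "PD".
#' @return logical vector, TRUE for responders.
#' @export
binarizePercist <- function(label) {
  bad <- !label %in% PERCIST_CATEGORIES
  if (any(bad))
    stop(sprintf("unknown PERCIST label(s): %s",
                 paste(unique(label[bad]), collapse = ", ")), call. = FALSE)
  label %in% c("CR", "PR")
}

#' ROC analysis of a biomarker change
#'
#' Responders are the positive class and a *decrease* signals response:
#' a subject is called responder when its delta is less than or equal to
#' the threshold. Every observed delta serves as a candidate threshold
#' (no midpoint interpolation), with a -Inf sentinel closing the curve at
#' (0, 0). The AUC is the trapezoidal area, which on this construction
#' equals the Mann-Whitney probability estimate (ties counted 1/2).
#'
#' @param deltas numeric vector of percent changes (+Inf sentinels allowed).
#' @param responder logical vector, TRUE = responder (positive class).
#' @return object of class `rocResult`: list(thresholds, tpr, fpr, auc,
#'   n_pos, n_neg).
#' @export
rocCurve <- function(deltas, responder) {
  stopifnot(length(deltas) == length(responder))
  keep <- !is.na(deltas) & !is.na(responder)
  deltas <- deltas[keep]; responder <- as.logical(responder[keep])
  n1 <- sum(responder); n0 <- sum(!responder)
  if (n1 == 0 || n0 == 0)
    stop("both responders and non-responders must be present", call. = FALSE)
  th <- c(-Inf, sort(unique(deltas)))
  tpr <- vapply(th, function(t) mean(deltas[responder] <= t), numeric(1))
  fpr <- vapply(th, function(t) mean(deltas[!responder] <= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc,
                 n_pos = n1, n_neg = n0, deltas = deltas,
                 responder = responder),
            class = "rocResult")
}

#' @export
print.rocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f  (%d responders vs %d non-responders, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds) - 1))
  invisible(x)
}

#' Youden-optimal cutoff of an ROC curve
#'
#' Maximises \eqn{J = sensitivity + specificity - 1} over the observed
#' thresholds. Ties are broken toward the most negative delta, i.e. the
#' most conservative responder call.
#'
#' @param roc an `rocResult` from [rocCurve()].
#' @return list(cutoff, sensitivity, specificity, j).
#' @export
youdenCutoff <- function(roc) {
  stopifnot(inherits(roc, "rocResult"))
  obs <- roc$thresholds != -Inf
  j <- roc$tpr - roc$fpr
  jobs <- j[obs]; tobs <- roc$thresholds[obs]
  best <- which(jobs == max(jobs))[1]  # thresholds ascending: first = most negative
  list(cutoff = tobs[best],
       sensitivity = roc$tpr[obs][best],
       specificity = 1 - roc$fpr[obs][best],
       j = jobs[best])
}

#' Classify a subject from its biomarker change and a cutoff
#'
#' Responder iff delta <= cutoff (boundary inclusive); a +Inf delta
#' (new-lesion appearance on a zero baseline) is always a non-responder.
#'
#' @param delta percent change(s).
#' @param cutoff percent cutoff (e.g. from [youdenCutoff()]).
#' @return logical vector, TRUE = responder.
#' @export
classifyResponse <- function(delta, cutoff) {
  !is.na(delta) & delta <= cutoff
}

delongPlacements <- function(scores, responder) {
  x <- scores[responder]; y <- scores[!responder]
  m <- length(x); n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  V10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  V01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
  list(V10 = V10, V01 = V01, auc = mean(V10), m = m, n = n)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two biomarker deltas measured on the same subjects
#' with the same responder labels, using placement values (structural
#' components) for the covariance of the paired AUC estimates and a normal
#' approximation for the two-sided p-value. Deltas are internally negated
#' so that larger scores indicate response, matching [rocCurve()]'s
#' orientation; AUC estimates are identical to [rocCurve()]'s.
#'
#' @param deltasA,deltasB percent changes of the two biomarkers, same
#'   subjects in the same order.
#' @param responder logical vector of responder labels.
#' @return list(aucA, aucB, z, p).
#' @export
delongTest <- function(deltasA, deltasB, responder) {
  if (length(deltasA) != length(deltasB) ||
      length(deltasA) != length(responder))
    stop("deltasA, deltasB and responder must have equal length",
         call. = FALSE)
  responder <- as.logical(responder)
  if (sum(responder) == 0 || sum(!responder) == 0)
    stop("both classes must be present", call. = FALSE)
  pa <- delongPlacements(-deltasA, responder)
  pb <- delongPlacements(-deltasB, responder)
  s10 <- stats::cov(cbind(pa$V10, pb$V10))
  s01 <- stats::cov(cbind(pa$V01, pb$V01))
  S <- s10 / pa$m + s01 / pa$n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  dauc <- pa$auc - pb$auc
  if (abs(dauc) < .Machine$double.eps) {
    z <- 0; p <- 1
  } else if (v <= 0) {
    z <- sign(dauc) * Inf; p <- 0
  } else {
    z <- dauc / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(aucA = pa$auc, aucB = pb$auc, z = z, p = p)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements with the identity line:
#' \deqn{CCC = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)}
#' with population (biased, 1/n) moments, following Lin's original
#' estimator; `moments = "sample"` uses 1/(n-1) moments instead. When both
#' variables are constant and equal, 1 is returned by continuity with a
#' `degenerate` attribute.
#'
#' @param x,y paired measurements, n >= 2.
#' @param moments "population" (default) or "sample".
#' @return CCC in \[-1, 1\].
#' @export
linCCC <- function(x, y, moments = c("population", "sample")) {
  moments <- match.arg(moments)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  den <- if (moments == "population") n else n - 1
  vx <- sum((x - mx)^2) / den
  vy <- sum((y - my)^2) / den
  cxy <- sum((x - mx) * (y - my)) / den
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(structure(1.0, degenerate = TRUE))
  structure(2 * cxy / denom, degenerate = FALSE)
}

#' Spearman rank correlation (midranks for ties)
#'
#' @param x,y paired measurements.
#' @return rho.
#' @export
spearmanRho <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  stats::cor(x[keep], y[keep], method = "spearman")
}

#' Wilcoxon signed-rank test on paired measurements
#'
#' Zero differences are dropped (the standard treatment); if all
#' differences are zero the test is degenerate and p = NA is returned with
#' a flag.
#'
#' @param x,y paired measurements.
#' @return list(p, statistic, degenerate).
#' @export
wilcoxonSignedRank <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (all(x == y))
    return(list(p = NA_real_, statistic = NA_real_, degenerate = TRUE))
  w <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  list(p = w$p.value, statistic = unname(w$statistic), degenerate = FALSE)
}

#' Mann-Whitney U test between two groups
#'
#' @param a,b samples from the two groups.
#' @return list(p, statistic).
#' @export
mannWhitneyU <- function(a, b) {
  w <- suppressWarnings(stats::wilcox.test(a, b))
  list(p = w$p.value, statistic = unname(w$statistic))
}

#' Kolmogorov-Smirnov normality check
#'
#' KS distance of the sample against a normal with the sample's own mean
#' and standard deviation (as commonly reported; parameters are not
#' corrected for estimation).
#'
#' @param x sample.
#' @return list(p, statistic).
#' @export
ksNormality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || stats::sd(x) == 0)
    return(list(p = NA_real_, statistic = NA_real_))
  k <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(p = k$p.value, statistic = unname(k$statistic))
}

#' Per-biomarker response assessment (ROC, Youden cutoff, group test)
#'
#' For each biomarker delta column: ROC AUC against the binarized PERCIST
#' labels, Youden-optimal cutoff with its sensitivity and specificity
#' (responders are the positive class), and a Mann-Whitney U test between
#' the responder and non-responder groups' deltas. Pairwise DeLong
#' comparisons between all biomarker AUCs are included.
#'
#' @param deltas data.frame of per-follow-up percent changes, one column
#'   per biomarker.
#' @param responder logical vector of binarized PERCIST labels, one per
#'   row of `deltas`.
#' @param alpha significance level applied at the reporting layer
#'   (default 0.001).
#' @return list(table, delong, roc): `table` has one row per biomarker
#'   with auc, cutoff, sensitivity, specificity, j, p_value, significant;
#'   `delong` has one row per biomarker pair; `roc` holds the rocResult
#'   objects.
#' @export
assessResponse <- function(deltas, responder, alpha = 0.001) {
  stopifnot(is.data.frame(deltas), nrow(deltas) == length(responder))
  responder <- as.logical(responder)
  rocs <- list()
  rows <- lapply(names(deltas), function(bm) {
    d <- deltas[[bm]]
    r <- rocCurve(d, responder)
    rocs[[bm]] <<- r
    yc <- youdenCutoff(r)
    mw <- mannWhitneyU(d[responder], d[!responder])
    data.frame(biomarker = bm, auc = r$auc, cutoff = yc$cutoff,
               sensitivity = yc$sensitivity, specificity = yc$specificity,
               j = yc$j, p_value = mw$p,
               significant = !is.na(mw$p) & mw$p <= alpha)
  })
  tab <- do.call(rbind, rows)
  pairsIdx <- if (ncol(deltas) >= 2) utils::combn(names(deltas), 2) else NULL
  dl <- if (!is.null(pairsIdx)) {
    do.call(rbind, lapply(seq_len(ncol(pairsIdx)), function(k) {
      a <- pairsIdx[1, k]; b <- pairsIdx[2, k]
      keep <- !is.na(deltas[[a]]) & !is.na(deltas[[b]])
      t <- delongTest(deltas[[a]][keep], deltas[[b]][keep], responder[keep])
      data.frame(biomarker_a = a, biomarker_b = b, auc_a = t$aucA,
                 auc_b = t$aucB, z = t$z, p_value = t$p)
    }))
  } else NULL
  list(table = tab, delong = dl, roc = rocs)
}

#' Agreement between two measurement routes of the same biomarkers
#'
#' For each shared biomarker column (e.g. computed on manual vs automatic
#' segmentations): Lin's CCC, Spearman rho, Wilcoxon signed-rank p and the
#' KS normality p of the pooled values.
#'
#' @param manual,auto data.frames with identical biomarker columns, rows
#'   paired by acquisition.
#' @return data.frame with one row per biomarker.
#' @export
concordancePanel <- function(manual, auto) {
  common <- intersect(names(manual), names(auto))
  if (length(common) == 0) stop("no shared biomarker columns", call. = FALSE)
  do.call(rbind, lapply(common, function(bm) {
    x <- manual[[bm]]; y <- auto[[bm]]
    keep <- stats::complete.cases(x, y) & is.finite(x) & is.finite(y)
    w <- wilcoxonSignedRank(x[keep], y[keep])
    data.frame(biomarker = bm,
               ccc = as.numeric(linCCC(x[keep], y[keep])),
               spearman = spearmanRho(x[keep], y[keep]),
               wilcoxon_p = w$p,
               ks_normality_p = ksNormality(c(x[keep], y[keep]))$p,
               n = sum(keep))
  }))
}
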