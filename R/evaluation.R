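# Normalize class labels to logical (TRUE = positive = intolerant/DV).
.asLabel <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  if (is.character(labels) || is.factor(labels)) {
    l <- tolower(as.character(labels))
    pos <- l %in% c("positive", "intolerant", "dv", "1", "true")
    neg <- l %in% c("negative", "tolerant", "cv", "0", "false")
    if (!all(pos | neg)) stop("unrecognized label value(s)")
    return(pos)
  }
  stop("labels must be logical, 0/1, or positive/negative strings")
}

#' Label variants by relative activity
#'
#' A variant is intolerant (positive class) when its measured activity is
#' strictly below \code{cutoff} times the wild-type activity; the default
#' cutoff is 0.5, i.e. <50\% of wild-type activity.
#'
#' @param activity numeric vector of activities relative to wild type
#'   (1 = wild-type level); must be non-negative.
#' @param cutoff strict threshold (default 0.5).
#' @return logical vector, TRUE = intolerant.
#' @export
labelByActivity <- function(activity, cutoff = 0.5) {
  if (any(activity < 0)) stop("activity must be non-negative")
  activity < cutoff
}

#' Confusion counts at a score threshold
#'
#' Predicts the positive (intolerant) class when the score meets the
#' threshold: \code{score >= threshold} by default (configurable to strict
#' \code{>}).
#'
#' @param scores numeric scores (higher = more likely intolerant).
#' @param labels true classes (logical, 0/1, or intolerant/tolerant strings).
#' @param threshold decision threshold.
#' @param rule \code{">="} (default) or \code{">"}.
#' @return named integer vector with TP, FP, TN, FN.
#' @export
confusionAtThreshold <- function(scores, labels, threshold, rule = c(">=", ">")) {
  rule <- match.arg(rule)
  labels <- .asLabel(labels)
  if (length(scores) == 0L) stop("empty input")
  if (length(scores) != length(labels)) stop("length mismatch")
  pred <- if (rule == ">=") scores >= threshold else scores > threshold
  c(TP = sum(pred & labels), FP = sum(pred & !labels),
    TN = sum(!pred & !labels), FN = sum(!pred & labels))
}

#' Classifier metrics from a confusion table
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
#' accuracy (TP+TN)/n, balanced accuracy (sensitivity+specificity)/2, Matthews
#' correlation coefficient, and F1. Ratios with zero denominators are 0 by
#' convention (including MCC when any marginal is empty).
#'
#' @param conf named vector with TP, FP, TN, FN (see [confusionAtThreshold()]).
#' @param auc optional AUC to carry along in the result.
#' @return named numeric vector of metrics.
#' @export
metricSet <- function(conf, auc = NULL) {
  tp <- as.numeric(conf[["TP"]]); fp <- as.numeric(conf[["FP"]])
  tn <- as.numeric(conf[["TN"]]); fn <- as.numeric(conf[["FN"]])
  n <- tp + fp + tn + fn
  if (n < 1L) stop("empty confusion table")
  div <- function(num, den) if (den == 0) 0 else num / den
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  acc <- (tp + tn) / n
  bacc <- (sens + spec) / 2
  mccDen <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mccDen == 0) 0 else (tp * tn - fp * fn) / mccDen
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  out <- c(sensitivity = sens, specificity = spec, precision = prec,
           accuracy = acc, balanced_accuracy = bacc, MCC = mcc, F1 = f1)
  if (!is.null(auc)) out <- c(out, AUC = auc)
  out
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability (ties counted 1/2),
#' which equals trapezoidal integration of the ROC curve over all thresholds.
#'
#' @inheritParams confusionAtThreshold
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  labels <- .asLabel(labels)
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Accuracy-maximizing decision threshold
#'
#' Scans every observed score value (plus one value above the maximum, i.e.
#' "predict nothing positive") as a candidate threshold under the
#' \code{score >= threshold} rule and returns the one maximizing accuracy;
#' ties go to the smallest such threshold.
#'
#' @inheritParams confusionAtThreshold
#' @return the selected threshold.
#' @export
bestThreshold <- function(scores, labels) {
  labels <- .asLabel(labels)
  if (length(scores) == 0L) stop("empty input")
  cand <- sort(unique(c(scores, max(scores) + 1)))
  acc <- vapply(cand, function(thr)
    metricSet(confusionAtThreshold(scores, labels, thr))[["accuracy"]],
    numeric(1L))
  cand[which.max(acc)]  # which.max takes the first (smallest) maximizer
}

#' Union-rule integration of two scores
#'
#' Classifies a variant as intolerant when at least one of the two scores
#' meets its threshold: \code{a >= thrA | b >= thrB}.
#'
#' @param scoreA,scoreB aligned numeric score vectors.
#' @param thrA,thrB per-score thresholds.
#' @return logical predictions.
#' @export
integratedClassify <- function(scoreA, thrA, scoreB, thrB) {
  if (length(scoreA) != length(scoreB)) stop("score length mismatch")
  scoreA >= thrA | scoreB >= thrB
}

#' Monte-Carlo cross-validation of threshold classifiers
#'
#' Repeatedly splits the labeled set into training (default 90\%) and test
#' (10\%) subsets; per repeat, fits the accuracy-maximizing threshold of each
#' score on the training split and evaluates on the test split. With one score
#' the prediction is \code{score >= threshold}; with two scores the union rule
#' of [integratedClassify()] is used. Splits in which either subset lacks one
#' of the classes are redrawn (continuing the seeded RNG stream). AUC is
#' reported for single-score schemes.
#'
#' @param data data.frame holding the label column and score columns.
#' @param scoreCols one (single scheme) or two (integrated scheme) column
#'   names.
#' @param labelCol name of the label column (default \code{"label"}).
#' @param nRepeats number of random splits (default 100).
#' @param trainFraction training fraction (default 0.9).
#' @param seed integer seed; all randomness derives from it and the global
#'   RNG state is left untouched.
#' @return list of class \code{cvReport}: \code{perRepeat} (metrics per
#'   repeat), \code{mean}, \code{se} (sample SD / sqrt(nRepeats)),
#'   \code{nRepeats}, \code{trainFraction}, \code{seed}, \code{scheme},
#'   \code{redraws}.
#' @export
monteCarloCV <- function(data, scoreCols, labelCol = "label",
                         nRepeats = 100, trainFraction = 0.9, seed) {
  stopifnot(is.data.frame(data), labelCol %in% names(data),
            all(scoreCols %in% names(data)),
            length(scoreCols) %in% 1:2)
  labels <- .asLabel(data[[labelCol]])
  n <- nrow(data)
  if (n < 10L) stop("need at least 10 labeled variants")
  if (sum(labels) == 0L || sum(!labels) == 0L)
    stop("both classes must be present")
  nTrain <- round(trainFraction * n)
  if (nTrain < 1L || nTrain >= n)
    stop("trainFraction leaves an empty split")
  scheme <- if (length(scoreCols) == 1L) "single" else "integrated"
  redraws <- 0L
  rows <- withr::with_seed(seed, {
    lapply(seq_len(nRepeats), function(rep) {
      repeat {
        tr <- sample.int(n, nTrain)
        te <- setdiff(seq_len(n), tr)
        okTr <- any(labels[tr]) && any(!labels[tr])
        okTe <- any(labels[te]) && any(!labels[te])
        if (okTr && okTe) break
        redraws <<- redraws + 1L
      }
      thr <- vapply(scoreCols, function(sc)
        bestThreshold(data[[sc]][tr], labels[tr]), numeric(1L))
      pred <- if (scheme == "single") {
        data[[scoreCols]][te] >= thr[[1L]]
      } else {
        integratedClassify(data[[scoreCols[1L]]][te], thr[[1L]],
                           data[[scoreCols[2L]]][te], thr[[2L]])
      }
      conf <- c(TP = sum(pred & labels[te]), FP = sum(pred & !labels[te]),
                TN = sum(!pred & !labels[te]), FN = sum(!pred & labels[te]))
      auc <- if (scheme == "single")
        rocAuc(data[[scoreCols]][te], labels[te]) else NA_real_
      metricSet(conf, auc = auc)
    })
  })
  perRepeat <- as.data.frame(do.call(rbind, rows))
  means <- colMeans(perRepeat)
  ses <- apply(perRepeat, 2L, stats::sd) / sqrt(nRepeats)
  structure(list(perRepeat = perRepeat, mean = means, se = ses,
                 nRepeats = nRepeats, trainFraction = trainFraction,
                 seed = seed, scheme = scheme, scoreCols = scoreCols,
                 redraws = redraws),
            class = "cvReport")
}

#' @export
print.cvReport <- function(x, ...) {
  cat(sprintf("Monte-Carlo CV: %d repeats, train fraction %g, seed %s (%s: %s)\n",
              x$nRepeats, x$trainFraction, format(x$seed), x$scheme,
              paste(x$scoreCols, collapse = " + ")))
  for (m in names(x$mean))
    cat(sprintf("  %-17s %.4f +/- %.4f\n", m, x$mean[[m]], x$se[[m]]))
  invisible(x)
}

#' Variants per residue
#'
#' Mutational coverage of a saturation-mutagenesis set: the number of variants
#' divided by the protein sequence length, reported to 2 decimals.
#'
#' @param nVariants variant count.
#' @param length protein length (>= 1).
#' @return the ratio, rounded to 2 decimals.
#' @export
variantsPerResidue <- function(nVariants, length) {
  if (any(length < 1)) stop("length must be >= 1")
  round(nVariants / length, 2)
}

#' Identification coverage percentage
#'
#' Share of known positives identified by a method: 100 x identified / total,
#' reported to 2 decimals.
#'
#' @param nIdentified identified count (0 <= nIdentified <= nTotal).
#' @param nTotal total count (>= 1).
#' @return the percentage, rounded to 2 decimals.
#' @export
identificationCoverage <- function(nIdentified, nTotal) {
  if (any(nTotal < 1)) stop("nTotal must be >= 1")
  if (any(nIdentified < 0 | nIdentified > nTotal))
    stop("nIdentified must lie in [0, nTotal]")
  round(100 * nIdentified / nTotal, 2)
}
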