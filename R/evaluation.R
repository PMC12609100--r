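## Regression and threshold-swept detection metrics for severity estimates,
## ROC / precision-recall construction, and multi-model aggregation.

#' Severity regression metrics
#'
#' Pearson correlation, mean absolute error and root mean squared error of
#' predicted vs reference VSI, plus per-bin mean predictions over the
#' true-severity bins 5-15%, 15-25%, ..., 85-95%.
#'
#' @param predictions,references paired numeric vectors (VSI, %)
#' @return list with \code{rho}, \code{mae}, \code{rmse} and a
#'   \code{bins} data.frame (\code{mid}, \code{meanPrediction}, \code{n})
#' @export
regressionMetrics <- function(predictions, references) {
    ok <- is.finite(predictions) & is.finite(references)
    if (sum(ok) < 2) stop("need at least two paired finite values")
    p <- predictions[ok]; r <- references[ok]
    mids <- seq(10, 90, by = 10)
    bins <- data.frame(
        mid = mids,
        meanPrediction = vapply(mids, function(m) {
            i <- r >= m - 5 & r < m + 5
            if (any(i)) mean(p[i]) else NA_real_
        }, numeric(1)),
        n = vapply(mids, function(m) sum(r >= m - 5 & r < m + 5),
                   numeric(1)))
    list(rho = cor(p, r), mae = mean(abs(p - r)),
         rmse = sqrt(mean((p - r)^2)), bins = bins)
}

#' Detection metrics at fixed thresholds
#'
#' Ground truth is positive where the reference VSI strictly exceeds the
#' labeling threshold; the call is positive where the predicted VSI
#' strictly exceeds the decision threshold (by default equal to the
#' labeling threshold).
#'
#' @param predictions,references paired numeric vectors (VSI, %)
#' @param labelingThreshold VSI cutoff defining the positive class
#' @param decisionThreshold classifier cutoff on the predictions
#' @return list with the confusion counts and \code{sensitivity},
#'   \code{specificity}, \code{accuracy}, \code{ppv}, \code{npv}, \code{f1}
#' @export
detectionMetrics <- function(predictions, references, labelingThreshold,
                             decisionThreshold = labelingThreshold) {
    truth <- references > labelingThreshold
    call <- predictions > decisionThreshold
    tp <- sum(truth & call); fn <- sum(truth & !call)
    fp <- sum(!truth & call); tn <- sum(!truth & !call)
    sens <- if (tp + fn) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp) tn / (tn + fp) else NA_real_
    ppv <- if (tp + fp) tp / (tp + fp) else NA_real_
    npv <- if (tn + fn) tn / (tn + fn) else NA_real_
    f1 <- if (is.na(ppv) || is.na(sens) || ppv + sens == 0) NA_real_
          else 2 * ppv * sens / (ppv + sens)
    list(labelingThreshold = labelingThreshold,
         decisionThreshold = decisionThreshold,
         tp = tp, fn = fn, fp = fp, tn = tn,
         sensitivity = sens, specificity = spec,
         accuracy = (tp + tn) / (tp + tn + fp + fn),
         ppv = ppv, npv = npv, f1 = f1)
}

#' Detection metrics swept over labeling thresholds
#'
#' One row per labeling cutoff (default 20%, 30%, ..., 80% VSI), with the
#' decision threshold set equal to the labeling threshold.
#'
#' @param predictions,references paired numeric vectors
#' @param thresholds labeling cutoffs (%)
#' @return \code{data.frame} of [detectionMetrics()] rows
#' @export
thresholdSweep <- function(predictions, references,
                           thresholds = seq(20, 80, by = 10)) {
    do.call(rbind, lapply(thresholds, function(th) {
        m <- detectionMetrics(predictions, references, th)
        as.data.frame(m[c("labelingThreshold", "sensitivity",
                          "specificity", "accuracy", "ppv", "npv", "f1")])
    }))
}

#' ROC and precision-recall curves
#'
#' The ground truth is fixed by the labeling threshold; the classifier
#' decision threshold is swept over the predicted values.  AUCs are
#' trapezoidal; the precision-recall baseline equals the positive
#' prevalence.
#'
#' @param predictions,references paired numeric vectors
#' @param labelingThreshold VSI cutoff defining the positive class
#' @return list with \code{roc} (data.frame \code{fpr}, \code{tpr}),
#'   \code{prc} (data.frame \code{recall}, \code{precision}),
#'   \code{aucRoc}, \code{aucPrc}, \code{prevalence}
#' @export
rocPrc <- function(predictions, references, labelingThreshold) {
    truth <- references > labelingThreshold
    nP <- sum(truth); nN <- sum(!truth)
    if (nP == 0 || nN == 0)
        stop("both classes must be present for ROC/PRC")
    ord <- order(predictions, decreasing = TRUE)
    t_ <- truth[ord]; p_ <- predictions[ord]
    tp <- cumsum(t_); fp <- cumsum(!t_)
    ## collapse tied prediction values to their final counts
    last <- c(p_[-1] != p_[-length(p_)], TRUE)
    tp <- tp[last]; fp <- fp[last]
    tpr <- c(0, tp / nP); fpr <- c(0, fp / nN)
    aucRoc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    prec <- tp / (tp + fp)
    rec <- tp / nP
    recall <- c(0, rec); precision <- c(prec[1], prec)
    aucPrc <- sum(diff(recall) * (head(precision, -1) +
                                  tail(precision, -1)) / 2)
    list(roc = data.frame(fpr = fpr, tpr = tpr),
         prc = data.frame(recall = recall, precision = precision),
         aucRoc = aucRoc, aucPrc = aucPrc, prevalence = nP / (nP + nN))
}

#' Aggregate reports over an ensemble of models
#'
#' Element-wise mean and sample standard deviation (n - 1) of numeric
#' metrics across per-model reports, the convention used for
#' "mean +/- SD over independently trained models" summaries.  Per-bin
#' calibration curves are averaged bin-wise.
#'
#' @param reports list of per-model metric lists (all with the same
#'   numeric fields, e.g. from [regressionMetrics()])
#' @return list with \code{mean} and \code{sd} components
#' @export
aggregateModels <- function(reports) {
    if (!length(reports)) stop("no reports to aggregate")
    fields <- names(reports[[1]])
    num <- fields[vapply(reports[[1]], is.numeric, logical(1))]
    mats <- lapply(num, function(f)
        vapply(reports, function(r) r[[f]], numeric(length(reports[[1]][[f]]))))
    names(mats) <- num
    res <- list(
        mean = lapply(mats, function(m)
            if (is.matrix(m)) rowMeans(m) else mean(m)),
        sd = lapply(mats, function(m)
            if (is.matrix(m)) apply(m, 1, sd)
            else if (length(reports) > 1) sd(m) else 0))
    if ("bins" %in% fields) {
        bm <- vapply(reports, function(r) r$bins$meanPrediction,
                     numeric(nrow(reports[[1]]$bins)))
        bm <- matrix(bm, nrow = nrow(reports[[1]]$bins))
        res$bins <- data.frame(
            mid = reports[[1]]$bins$mid,
            meanPrediction = rowMeans(bm, na.rm = TRUE),
            sdPrediction = apply(bm, 1, sd, na.rm = TRUE))
    }
    res
}

#' Full evaluation of a severity estimator on a test cohort
#'
#' Convenience wrapper: regression metrics, the 20-80% threshold sweep and
#' ROC/PRC at the 30/50/70% labeling thresholds.
#'
#' @param predictions,references paired numeric vectors (VSI, %)
#' @return list with \code{regression}, \code{sweep} and \code{curves}
#'   (one [rocPrc()] result per threshold)
#' @export
evaluateSeverity <- function(predictions, references) {
    curves <- lapply(c(30, 50, 70), function(th)
        rocPrc(predictions, references, th))
    names(curves) <- paste0("t", c(30, 50, 70))
    list(regression = regressionMetrics(predictions, references),
         sweep = thresholdSweep(predictions, references),
         curves = curves)
}
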