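test_that("regression metrics match hand arithmetic", {
    r <- regressionMetrics(c(0, 60, 90), c(0, 50, 100))
    expect_equal(r$mae, 20 / 3)
    expect_equal(r$rmse, sqrt(200 / 3))
    perfect <- regressionMetrics(1:10 * 10 - 5, 1:10 * 10 - 5)
    expect_equal(perfect$rho, 1)
    expect_equal(perfect$mae, 0)
    expect_equal(perfect$rmse, 0)
    off <- regressionMetrics(1:20 + 5, 1:20)
    expect_equal(off$mae, 5)
    expect_equal(off$rho, 1)
    expect_lte(off$mae, off$rmse)
    expect_equal(r$bins$mid, seq(10, 90, 10))
    expect_error(regressionMetrics(1, 1), "two")
})

test_that("detection metrics reproduce the confusion-matrix arithmetic", {
    ## 90 TP, 10 FN, 12 FP, 88 TN at a 50% threshold
    refs <- c(rep(60, 100), rep(40, 100))
    preds <- c(rep(70, 90), rep(30, 10), rep(70, 12), rep(30, 88))
    m <- detectionMetrics(preds, refs, 50)
    expect_equal(m$tp, 90); expect_equal(m$fn, 10)
    expect_equal(m$fp, 12); expect_equal(m$tn, 88)
    expect_equal(m$sensitivity, 0.90)
    expect_equal(m$specificity, 0.88)
    expect_equal(m$ppv, 90 / 102, tolerance = 1e-12)
    expect_equal(m$accuracy, 0.89)
    ## swapping the class definition swaps the paired metrics
    sw <- detectionMetrics(-preds, -refs, -50.0001,
                           decisionThreshold = -50.0001)
    expect_equal(sw$sensitivity, m$specificity)
    expect_equal(sw$ppv, m$npv, tolerance = 1e-12)
    perfect <- detectionMetrics(refs, refs, 50)
    for (f in c("sensitivity", "specificity", "accuracy", "ppv", "npv",
                "f1"))
        expect_equal(perfect[[f]], 1)
})

test_that("threshold sweep walks the 20-80% cutoffs", {
    set.seed(1)
    refs <- runif(4000, 0, 100)
    preds <- pmin(pmax(refs + rnorm(4000, 0, 15), 0), 100)
    sw <- thresholdSweep(preds, refs)
    expect_equal(nrow(sw), 7)
    expect_equal(sw$labelingThreshold, seq(20, 80, 10))
    ## single-point metrics are reproduced exactly at each cutoff
    m50 <- detectionMetrics(preds, refs, 50)
    expect_equal(sw$accuracy[sw$labelingThreshold == 50], m50$accuracy)
    ## a prediction-free classifier tracks class prevalence
    rnd <- runif(4000, 0, 100)
    sw2 <- thresholdSweep(rnd, refs)
    for (th in c(20, 50, 80)) {
        prev <- mean(refs > th)
        expAcc <- prev * (1 - th / 100) + (1 - prev) * th / 100
        expect_equal(sw2$accuracy[sw2$labelingThreshold == th], expAcc,
                     tolerance = 0.05)
    }
})

test_that("ROC equals the pairwise concordance statistic", {
    set.seed(2)
    refs <- runif(200, 0, 100)
    preds <- refs + rnorm(200, 0, 25)
    r <- rocPrc(preds, refs, 40)
    truth <- refs > 40
    pos <- preds[truth]; neg <- preds[!truth]
    conc <- mean(outer(pos, neg, function(a, b)
        (a > b) + 0.5 * (a == b)))
    expect_equal(r$aucRoc, conc, tolerance = 1e-6)
    expect_equal(r$prevalence, mean(truth))
    ## perfect separation
    p2 <- ifelse(truth, 90, 10)
    r2 <- rocPrc(p2, refs, 40)
    expect_equal(r2$aucRoc, 1)
    expect_equal(r2$aucPrc, 1)
    ## uninformative predictor
    set.seed(3)
    r3 <- rocPrc(runif(5000), runif(5000, 0, 100), 50)
    expect_equal(r3$aucRoc, 0.5, tolerance = 0.05)
    ## rank-based AUC is invariant to monotone transforms of the score,
    ## thresholded accuracy is not
    r4 <- rocPrc(exp(preds / 30), refs, 40)
    expect_equal(r4$aucRoc, r$aucRoc, tolerance = 1e-12)
    accRaw <- detectionMetrics(preds, refs, 40)$accuracy
    accMono <- detectionMetrics(exp(preds / 30), refs, 40)$accuracy
    expect_false(isTRUE(all.equal(accRaw, accMono)))
    expect_error(rocPrc(preds, rep(10, 200), 40), "classes")
})

test_that("ROC agrees with an established implementation", {
    skip_if_not_installed("pROC")
    set.seed(4)
    refs <- runif(300, 0, 100)
    preds <- refs + rnorm(300, 0, 30)
    r <- rocPrc(preds, refs, 50)
    ref <- suppressMessages(as.numeric(
        pROC::auc(pROC::roc(refs > 50, preds, quiet = TRUE))))
    expect_equal(r$aucRoc, ref, tolerance = 1e-9)
})

test_that("model aggregation uses mean and sample SD", {
    reps <- list(list(rho = 0.8, mae = 10), list(rho = 0.9, mae = 14))
    ag <- aggregateModels(reps)
    expect_equal(ag$mean$mae, 12)
    expect_equal(ag$sd$mae, sd(c(10, 14)))
    single <- aggregateModels(reps[1])
    expect_equal(single$sd$mae, 0)
    ## permutation invariance
    ag2 <- aggregateModels(rev(reps))
    expect_equal(ag$mean$rho, ag2$mean$rho)
    expect_equal(ag$sd$rho, ag2$sd$rho)
})
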