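test_that("default architecture has the published parameter budget", {
    m <- buildNetwork(seed = 1)
    n <- cparParameterCount(m)
    expect_equal(unname(n["vsiHead"]), 266433)
    expect_equal(unname(n["heightHead"]), 266433)
    expect_equal(unname(n["ageHead"]), 266433)
    expect_lt(abs(n[["featureExtractor"]] - 810000) / 810000, 0.10)
})

test_that("forward pass yields the latent shape and row independence", {
    cfg <- networkConfig()
    expect_equal(cfg$latentDim, 32 * 2 * 64)
    m <- buildNetwork(cfg, seed = 2)
    set.seed(3)
    X <- matrix(rnorm(2 * 256), 2, 256)
    fw <- PulseAAA:::.trunkForward(m@thetaF, X, cfg, train = FALSE)
    expect_equal(dim(fw$Z), c(4096L, 1L))
    ## altering only the tibial row leaves the brachial half of the
    ## latent untouched (convolutions act along width, per row)
    X2 <- X; X2[2, ] <- rnorm(256)
    fw2 <- PulseAAA:::.trunkForward(m@thetaF, X2, cfg, train = FALSE)
    expect_equal(fw$Z[1:2048, 1], fw2$Z[1:2048, 1])
    expect_false(isTRUE(all.equal(fw$Z[2049:4096, 1], fw2$Z[2049:4096, 1])))
    ## invalid skip configuration fails at construction
    expect_error(networkConfig(channels = c(8L, 12L, 8L, 16L, 8L)), "skip")
})

test_that("input preprocessing standardizes rows and is scale invariant", {
    set.seed(4)
    b <- runif(256, 80, 120); ti <- runif(256, 0, 3)
    pp <- inputPreprocess(b, ti)
    expect_equal(dim(pp), c(2L, 256L))
    expect_equal(mean(pp[1, ]), 0, tolerance = 1e-12)
    expect_equal(sd(pp[2, ]), 1, tolerance = 1e-12)
    expect_equal(inputPreprocess(10 * b, ti)[1, ], pp[1, ],
                 tolerance = 1e-12)
    expect_equal(inputPreprocess(rep(5, 256), ti)[1, ], rep(0, 256))
    expect_error(inputPreprocess(b, ti[-1]), "length")
})

test_that("losses match their closed forms", {
    expect_equal(labelLoss(c(60, 20), c(80, 20)), 200)
    expect_equal(labelLoss(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(labelLoss(c(6, 7), c(1, 2)), 25)
    expect_equal(disturbanceLoss(0, 0), 0)
    expect_equal(disturbanceLoss(5, 0), disturbanceLoss(-5, 0))
    expect_equal(disturbanceLoss(0, 5), 2 * 5 - log(2), tolerance = 0.01)
    expect_error(labelLoss(numeric(), numeric()), "empty")
})

test_that("hand-derived backpropagation matches finite differences", {
    cfg <- tinyNetConfig(width = 32L)
    set.seed(1)
    thetaF <- PulseAAA:::.initTrunk(cfg)
    thetaL <- PulseAAA:::.initHead(cfg)
    ## move biases off the ReLU kinks so central differences are two-sided
    thetaF$comp$b <- rnorm(length(thetaF$comp$b), 0, 0.1)
    for (i in 1:5)
        thetaF$conv[[i]]$be <- rnorm(length(thetaF$conv[[i]]$be), 0, 0.1)
    X <- matrix(rnorm(4 * 32), 4, 32)
    y <- c(30, 70)
    fw <- PulseAAA:::.trunkForward(thetaF, X, cfg, train = TRUE)
    hl <- PulseAAA:::.headForward(thetaL, fw$Z)
    bl <- PulseAAA:::.headBackward(thetaL, 2 * (hl$y - y) / 2, hl)
    gF <- PulseAAA:::.trunkBackward(thetaF, bl$dZ, fw$cache, cfg)
    lossAt <- function(th)
        labelLoss(PulseAAA:::.headForward(
            thetaL, PulseAAA:::.trunkForward(th, X, cfg, train = TRUE)$Z)$y, y)
    h <- 1e-6
    probe <- function(path, i) {
        th1 <- thetaF; th2 <- thetaF
        th1[[path]][i] <- th1[[path]][i] + h
        th2[[path]][i] <- th2[[path]][i] - h
        fd <- (lossAt(th1) - lossAt(th2)) / (2 * h)
        an <- gF[[path]][i]
        expect_equal(an, fd, tolerance = 1e-3)
    }
    probe(c("conv", "C1", "W"), 2)
    probe(c("conv", "C2", "g"), 3)
    probe(c("conv", "C3", "W"), 11)
    probe(c("conv", "C4", "be"), 1)
    probe(c("conv", "C5", "W"), 30)
    probe(c("cbam", "L3", "Wc1"), 2)
    probe(c("cbam", "L3", "Wc2"), 4)
    probe(c("cbam", "L5", "Ws"), 5)
    probe(c("cbam", "L5", "bs"), 1)
    probe(c("comp", "W"), 6)
    probe(c("comp", "b"), 2)
    ## head gradients
    gd <- bl$grads
    for (nm in c("W1", "W3", "b2")) {
        i <- 2
        t1 <- thetaL; t2 <- thetaL
        t1[[nm]][i] <- t1[[nm]][i] + h
        t2[[nm]][i] <- t2[[nm]][i] - h
        f1 <- labelLoss(PulseAAA:::.headForward(t1, fw$Z)$y, y)
        f2 <- labelLoss(PulseAAA:::.headForward(t2, fw$Z)$y, y)
        expect_equal(gd[[nm]][i], (f1 - f2) / (2 * h), tolerance = 1e-3)
    }
})

test_that("update laws keep the parameter sets disjoint", {
    cfg <- tinyNetConfig()
    m <- buildNetwork(cfg, training = trainingConfig("pvr"), seed = 5)
    set.seed(6)
    batch <- list(X = matrix(rnorm(8 * 64), 8, 64), y = runif(4, 0, 100),
                  height = rnorm(4), age = rnorm(4))
    ubatch <- list(X = matrix(rnorm(8 * 64), 8, 64),
                   height = rnorm(4), age = rnorm(4))
    ## an adversarial-head-only step (unlabeled batch alone) leaves the
    ## feature extractor and the VSI head untouched
    r <- trainingStep(m, batch = NULL, ubatch = ubatch)
    expect_identical(r$model@thetaF, m@thetaF)
    expect_identical(r$model@thetaL, m@thetaL)
    expect_false(identical(r$model@thetaH, m@thetaH))
    ## a full step changes all four sets
    r2 <- trainingStep(m, batch)
    expect_false(identical(r2$model@thetaF$conv$C1$W, m@thetaF$conv$C1$W))
    expect_false(identical(r2$model@thetaL$W1, m@thetaL$W1))
})

test_that("lambda = 0 training equals plain supervised training exactly", {
    pc <- generateCohort(8, 2, seed = 61)
    val <- generateCohort(4, 1, seed = 62)
    cfg <- tinyNetConfig(width = 256L)
    run <- function(freeze) trainCpar(
        pc, val, unlabeled = NULL, config = cfg,
        training = trainingConfig("pvr", lambda = 0, maxEpochs = 3L,
                                  freezeAdversarial = freeze),
        seed = 77)
    a <- run(FALSE); b <- run(TRUE)
    expect_identical(a@thetaF$conv$C3$W, b@thetaF$conv$C3$W)
    expect_identical(a@thetaL$W1, b@thetaL$W1)
    expect_identical(trainingHistory(a)$val, trainingHistory(b)$val)
})

test_that("repeated steps on one batch drive the label loss down", {
    cfg <- tinyNetConfig()
    m <- buildNetwork(cfg, training = trainingConfig("pvr", lrF = 1e-3,
                                                     lrL = 1e-3), seed = 8)
    set.seed(9)
    batch <- list(X = matrix(rnorm(16 * 64), 16, 64), y = runif(8, 0, 100),
                  height = rnorm(8), age = rnorm(8))
    r <- trainingStep(m, batch)
    losses <- numeric(100)
    for (i in 1:100) {
        r <- trainingStep(r$model, batch, state = r$state)
        losses[i] <- r$losses[["label"]]
    }
    expect_lt(losses[100], losses[10] / 4)
})

test_that("prediction is deterministic and ignores the adversarial heads", {
    pc <- generateCohort(8, 2, seed = 63)
    val <- generateCohort(4, 1, seed = 64)
    cfg <- tinyNetConfig(width = 256L)
    m <- trainCpar(pc, val, config = cfg,
                   training = trainingConfig("pvr", maxEpochs = 2L),
                   seed = 5)
    b <- SummarizedExperiment::assay(pc, "pvr_brachial")[, 1]
    ti <- SummarizedExperiment::assay(pc, "pvr_tibial")[, 1]
    p1 <- predictVsi(m, b, ti)
    p2 <- predictVsi(m, b, ti)
    expect_identical(p1, p2)
    ## scrambling the adversarial heads cannot change inference
    m2 <- m
    m2@thetaH$W1[] <- 0
    expect_identical(predictVsi(m2, b, ti), p1)
    ## predictions feed back into the training loss consistently
    p <- predictCohort(m, pc)
    expect_equal(labelLoss(p, vsiLabels(pc)),
                 mean((vsiLabels(pc) - p)^2))
    expect_error(predictVsi(buildNetwork(cfg), b, ti), "trained")
})

test_that("early stopping respects the patience and epoch caps", {
    pc <- generateCohort(6, 2, seed = 65)
    val <- generateCohort(3, 1, seed = 66)
    cfg <- tinyNetConfig(width = 256L)
    m <- trainCpar(pc, val, config = cfg,
                   training = trainingConfig("pvr", maxEpochs = 4L,
                                             patience = 2L), seed = 5)
    h <- trainingHistory(m)
    expect_lte(nrow(h), 4)
    best <- which.min(h$val)
    expect_lte(nrow(h) - best, 2)
})
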