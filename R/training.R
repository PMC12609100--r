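#' Training configuration
#'
#' Hyperparameters of the joint CPAR optimization.  The defaults per
#' modality are the selected values used for the PVR- and arterial-BP-based
#' variants: batch size 16; Adam momentum coefficients (beta1, beta2) of
#' (0.95, 0.95) for PVR and (0.989, 0.970) for ABP; CPAR weight lambda of
#' 6.5e-4 (PVR) or 7.3e-4 (ABP); learning rates (feature extractor, VSI
#' head, adversarial heads) of (1.2e-3, 1.1e-3, 7.0e-4) for PVR and
#' (2.2e-4, 3.6e-5, 5.5e-6) for ABP; early stopping with patience 25 and at
#' most 100 epochs.
#'
#' @param modality \code{"pvr"} or \code{"abp"} (selects the default
#'   hyperparameter set)
#' @param batchSize records per batch
#' @param beta1,beta2 Adam momentum coefficients
#' @param lambda CPAR regularization weight
#' @param lrF,lrL,lrEta learning rates for the feature extractor, the VSI
#'   head and the two adversarial heads
#' @param patience early-stopping patience (epochs without validation
#'   improvement)
#' @param maxEpochs maximum training epochs
#' @param adversarial if \code{TRUE} (default) the feature extractor
#'   ascends the disturbance losses (gradient reversal), making the latent
#'   features uninformative about height and age; \code{FALSE} descends
#'   them jointly instead
#' @param freezeAdversarial if \code{TRUE} the adversarial heads are never
#'   updated (plain supervised training; used with \code{lambda = 0})
#' @return configuration list
#' @export
trainingConfig <- function(modality = c("pvr", "abp"), batchSize = 16L,
                           beta1 = NULL, beta2 = NULL, lambda = NULL,
                           lrF = NULL, lrL = NULL, lrEta = NULL,
                           patience = 25L, maxEpochs = 100L,
                           adversarial = TRUE,
                           freezeAdversarial = FALSE) {
    modality <- match.arg(modality)
    def <- if (modality == "pvr")
        list(beta1 = 0.95, beta2 = 0.95, lambda = 6.5e-4,
             lrF = 1.2e-3, lrL = 1.1e-3, lrEta = 7.0e-4)
    else
        list(beta1 = 0.989, beta2 = 0.970, lambda = 7.3e-4,
             lrF = 2.2e-4, lrL = 3.6e-5, lrEta = 5.5e-6)
    list(modality = modality, batchSize = as.integer(batchSize),
         beta1 = if (is.null(beta1)) def$beta1 else beta1,
         beta2 = if (is.null(beta2)) def$beta2 else beta2,
         lambda = if (is.null(lambda)) def$lambda else lambda,
         lrF = if (is.null(lrF)) def$lrF else lrF,
         lrL = if (is.null(lrL)) def$lrL else lrL,
         lrEta = if (is.null(lrEta)) def$lrEta else lrEta,
         patience = as.integer(patience),
         maxEpochs = as.integer(maxEpochs),
         adversarial = adversarial,
         freezeAdversarial = freezeAdversarial)
}

## extract network-ready data from a PulseCohort
.cohortToData <- function(cohort, modality) {
    an <- SummarizedExperiment::assayNames(cohort)
    pick <- function(site) {
        nm <- paste0(if (modality == "pvr") "pvr_" else "bp_", site)
        if (!nm %in% an) stop("cohort lacks assay ", nm)
        SummarizedExperiment::assay(cohort, nm)
    }
    cd <- SummarizedExperiment::colData(cohort)
    list(X = .stackInputs(pick("brachial"), pick("tibial")),
         y = if ("vsi" %in% names(cd)) as.numeric(cd$vsi) else NULL,
         height = as.numeric(cd$height),
         age = as.numeric(cd$age))
}

## one joint CPAR update; batches carry standardized height/age targets
.cparStep <- function(theta, batch, ubatch, cfg, tcfg, opt) {
    lossL <- lossH <- lossA <- NA_real_
    if (is.null(batch)) {
        ## adversarial-head-only step on the unlabeled batch
        if (!is.null(ubatch) && !tcfg$freezeAdversarial) {
            fu <- .trunkForward(theta$F, ubatch$X, cfg, train = FALSE)
            hu <- .headForward(theta$H, fu$Z)
            au <- .headForward(theta$A, fu$Z)
            lossH <- disturbanceLoss(hu$y, ubatch$height)
            lossA <- disturbanceLoss(au$y, ubatch$age)
            buH <- .headBackward(theta$H, .disturbanceGrad(hu$y, ubatch$height), hu)
            buA <- .headBackward(theta$A, .disturbanceGrad(au$y, ubatch$age), au)
            opt$tH <- opt$tH + 1L
            rH <- .adamStep(theta$H, buH$grads, opt$sH, tcfg$lrEta,
                            tcfg$beta1, tcfg$beta2, opt$tH)
            theta$H <- rH$p; opt$sH <- rH$s
            opt$tA <- opt$tA + 1L
            rA <- .adamStep(theta$A, buA$grads, opt$sA, tcfg$lrEta,
                            tcfg$beta1, tcfg$beta2, opt$tA)
            theta$A <- rA$p; opt$sA <- rA$s
        }
        return(list(theta = theta, opt = opt,
                    losses = c(label = lossL, distH = lossH,
                               distA = lossA)))
    }
    fw <- .trunkForward(theta$F, batch$X, cfg, train = TRUE)
    ## update BN running statistics (labeled batches only)
    for (i in seq_along(theta$F$conv)) {
        bn <- fw$cache$layers[[i]]$bn
        theta$F$conv[[i]]$rm <- 0.9 * theta$F$conv[[i]]$rm + 0.1 * bn$mu
        theta$F$conv[[i]]$rv <- 0.9 * theta$F$conv[[i]]$rv + 0.1 * bn$v
    }
    hl <- .headForward(theta$L, fw$Z)
    hh <- .headForward(theta$H, fw$Z)
    ha <- .headForward(theta$A, fw$Z)
    n <- length(batch$y)
    lossL <- labelLoss(hl$y, batch$y)
    lossH <- disturbanceLoss(hh$y, batch$height)
    lossA <- disturbanceLoss(ha$y, batch$age)
    dyL <- 2 * (hl$y - batch$y) / n
    dyH <- .disturbanceGrad(hh$y, batch$height)
    dyA <- .disturbanceGrad(ha$y, batch$age)
    bl <- .headBackward(theta$L, dyL, hl)
    bh <- .headBackward(theta$H, dyH, hh)
    ba <- .headBackward(theta$A, dyA, ha)
    sgn <- if (tcfg$adversarial) -1 else 1
    dZf <- bl$dZ + sgn * tcfg$lambda * (bh$dZ + ba$dZ)
    gF <- .trunkBackward(theta$F, dZf, fw$cache, cfg)
    ## updates: disjoint parameter sets, separate optimizers
    opt$tF <- opt$tF + 1L
    rF <- .adamStep(theta$F, gF, opt$sF, tcfg$lrF, tcfg$beta1, tcfg$beta2,
                    opt$tF)
    theta$F <- rF$p; opt$sF <- rF$s
    opt$tL <- opt$tL + 1L
    rL <- .adamStep(theta$L, bl$grads, opt$sL, tcfg$lrL, tcfg$beta1,
                    tcfg$beta2, opt$tL)
    theta$L <- rL$p; opt$sL <- rL$s
    if (!tcfg$freezeAdversarial) {
        opt$tH <- opt$tH + 1L
        rH <- .adamStep(theta$H, bh$grads, opt$sH, tcfg$lrEta, tcfg$beta1,
                        tcfg$beta2, opt$tH)
        theta$H <- rH$p; opt$sH <- rH$s
        opt$tA <- opt$tA + 1L
        rA <- .adamStep(theta$A, ba$grads, opt$sA, tcfg$lrEta, tcfg$beta1,
                        tcfg$beta2, opt$tA)
        theta$A <- rA$p; opt$sA <- rA$s
    }
    ## unlabeled batch: adversarial heads only
    if (!is.null(ubatch) && !tcfg$freezeAdversarial) {
        fu <- .trunkForward(theta$F, ubatch$X, cfg, train = TRUE)
        hu <- .headForward(theta$H, fu$Z)
        au <- .headForward(theta$A, fu$Z)
        duH <- .disturbanceGrad(hu$y, ubatch$height)
        duA <- .disturbanceGrad(au$y, ubatch$age)
        buH <- .headBackward(theta$H, duH, hu)
        buA <- .headBackward(theta$A, duA, au)
        opt$tH <- opt$tH + 1L
        rH <- .adamStep(theta$H, buH$grads, opt$sH, tcfg$lrEta, tcfg$beta1,
                        tcfg$beta2, opt$tH)
        theta$H <- rH$p; opt$sH <- rH$s
        opt$tA <- opt$tA + 1L
        rA <- .adamStep(theta$A, buA$grads, opt$sA, tcfg$lrEta, tcfg$beta1,
                        tcfg$beta2, opt$tA)
        theta$A <- rA$p; opt$sA <- rA$s
    }
    list(theta = theta, opt = opt,
         losses = c(label = lossL, distH = lossH, distA = lossA))
}

#' One CPAR training step
#'
#' Applies the joint update to a model: the VSI head descends the label
#' loss on the labeled batch, the adversarial heads descend their
#' disturbance losses on the labeled (and, if given, unlabeled) batch, and
#' the feature extractor descends \code{L_L - lambda (L_DH + L_DA)}
#' (gradient reversal; the printed joint-descent sign is available via
#' \code{trainingConfig(adversarial = FALSE)}).  Each parameter set has its
#' own Adam optimizer; no optimizer touches parameters outside its set.
#'
#' @param model a [CparModel-class]
#' @param batch list with \code{X} (row-stacked input matrix from
#'   [inputPreprocess()]/two rows per record), \code{y} (VSI, %),
#'   \code{height}, \code{age} (standardized targets)
#' @param ubatch optional unlabeled batch (no \code{y})
#' @param state optional optimizer state from a previous call
#' @return list with the updated \code{model}, the optimizer \code{state}
#'   and the batch \code{losses}
#' @export
trainingStep <- function(model, batch, ubatch = NULL, state = NULL) {
    ## detach from the caller's model: the optimizer updates in place
    theta <- list(F = .deepCopy(model@thetaF), L = .deepCopy(model@thetaL),
                  H = .deepCopy(model@thetaH), A = .deepCopy(model@thetaA))
    if (is.null(state))
        state <- list(sF = .adamInit(theta$F), sL = .adamInit(theta$L),
                      sH = .adamInit(theta$H), sA = .adamInit(theta$A),
                      tF = 0L, tL = 0L, tH = 0L, tA = 0L)
    r <- .cparStep(theta, batch, ubatch, model@config, model@training,
                   state)
    model@thetaF <- r$theta$F; model@thetaL <- r$theta$L
    model@thetaH <- r$theta$H; model@thetaA <- r$theta$A
    list(model = model, state = r$opt, losses = r$losses)
}

## inference-mode VSI predictions for a stacked input matrix
.predictX <- function(thetaF, thetaL, X, cfg, chunk = 256L) {
    N <- nrow(X) %/% 2L
    out <- numeric(N)
    i <- 1L
    while (i <= N) {
        j <- min(N, i + chunk - 1L)
        rows <- (2L * i - 1L):(2L * j)
        fw <- .trunkForward(thetaF, X[rows, , drop = FALSE], cfg,
                            train = FALSE)
        out[i:j] <- .headForward(thetaL, fw$Z)$y
        i <- j + 1L
    }
    out
}

#' Train a CPAR model
#'
#' Full training driver: standardizes the adversarial targets (height, age)
#' over the labeled + unlabeled training records, iterates mini-batches
#' with the labeled/unlabeled batches interleaved 1:1, monitors the
#' validation label loss each epoch, and returns the
#' best-validation-checkpoint model with the per-epoch loss history.  A
#' master seed governs initialization and data order.
#'
#' @param labeled labeled training [PulseCohort-class]
#' @param validation validation [PulseCohort-class] (labeled)
#' @param unlabeled optional unlabeled [PulseCohort-class]
#' @param config a [networkConfig()] list
#' @param training a [trainingConfig()] list
#' @param seed master seed
#' @param verbose print per-epoch losses
#' @return a trained [CparModel-class]
#' @export
trainCpar <- function(labeled, validation, unlabeled = NULL,
                      config = networkConfig(),
                      training = trainingConfig(), seed = 1,
                      verbose = FALSE) {
    set.seed(seed)
    mod <- training$modality
    dl <- .cohortToData(labeled, mod)
    dv <- .cohortToData(validation, mod)
    du <- if (!is.null(unlabeled)) .cohortToData(unlabeled, mod) else NULL
    if (is.null(dl$y)) stop("labeled cohort carries no vsi labels")
    ## standardize adversarial targets over the training pool
    hAll <- c(dl$height, du$height)
    aAll <- c(dl$age, du$age)
    norm <- list(hMu = mean(hAll), hSd = max(sd(hAll), 1e-9),
                 aMu = mean(aAll), aSd = max(sd(aAll), 1e-9))
    dl$heightS <- (dl$height - norm$hMu) / norm$hSd
    dl$ageS <- (dl$age - norm$aMu) / norm$aSd
    if (!is.null(du)) {
        du$heightS <- (du$height - norm$hMu) / norm$hSd
        du$ageS <- (du$age - norm$aMu) / norm$aSd
    }
    theta <- list(F = .initTrunk(config), L = .initHead(config),
                  H = .initHead(config), A = .initHead(config))
    opt <- list(sF = .adamInit(theta$F), sL = .adamInit(theta$L),
                sH = .adamInit(theta$H), sA = .adamInit(theta$A),
                tF = 0L, tL = 0L, tH = 0L, tA = 0L)
    nL <- length(dl$y)
    nU <- if (!is.null(du)) length(du$height) else 0L
    bs <- training$batchSize
    nBatch <- max(1L, nL %/% bs)
    best <- list(val = Inf, thetaF = theta$F, thetaL = theta$L, epoch = 0L)
    hist <- NULL
    wait <- 0L
    for (epoch in seq_len(training$maxEpochs)) {
        perm <- sample.int(nL)
        ## drawn unconditionally so RNG use matches across configurations
        permU <- if (nU) sample.int(nU) else integer()
        eps <- c(label = 0, distH = 0, distA = 0)
        for (b in seq_len(nBatch)) {
            sel <- perm[((b - 1L) * bs + 1L):min(nL, b * bs)]
            rows <- as.vector(rbind(2L * sel - 1L, 2L * sel))
            batch <- list(X = dl$X[rows, , drop = FALSE], y = dl$y[sel],
                          height = dl$heightS[sel], age = dl$ageS[sel])
            ubatch <- NULL
            if (nU) {
                us <- permU[(((b - 1L) * bs) %% nU + 1L):
                            min(nU, ((b - 1L) * bs) %% nU + bs)]
                urows <- as.vector(rbind(2L * us - 1L, 2L * us))
                ubatch <- list(X = du$X[urows, , drop = FALSE],
                               height = du$heightS[us], age = du$ageS[us])
            }
            r <- .cparStep(theta, batch, ubatch, config, training, opt)
            theta <- r$theta; opt <- r$opt
            eps <- eps + r$losses / nBatch
        }
        valPred <- .predictX(theta$F, theta$L, dv$X, config)
        valLoss <- labelLoss(valPred, dv$y)
        if (!is.finite(valLoss)) stop("validation loss is not finite")
        hist <- rbind(hist, data.frame(epoch = epoch,
                                       label = eps[["label"]],
                                       distH = eps[["distH"]],
                                       distA = eps[["distA"]],
                                       val = valLoss))
        if (verbose)
            message(sprintf(
                "epoch %3d  L %8.2f  DH %6.3f  DA %6.3f  val %8.2f",
                epoch, eps[["label"]], eps[["distH"]], eps[["distA"]],
                valLoss))
        if (valLoss < best$val - 1e-12) {
            best <- list(val = valLoss, thetaF = .deepCopy(theta$F),
                         thetaL = .deepCopy(theta$L), epoch = epoch)
            wait <- 0L
        } else {
            wait <- wait + 1L
            if (wait >= training$patience) break
        }
    }
    if (!is.finite(best$val))
        warning("validation never improved; returning initial parameters")
    new("CparModel", thetaF = best$thetaF, thetaL = best$thetaL,
        thetaH = .deepCopy(theta$H), thetaA = .deepCopy(theta$A),
        config = config, training = training, norm = norm,
        history = hist, trained = TRUE)
}

#' Train an ensemble of independently seeded CPAR models
#'
#' @inheritParams trainCpar
#' @param seeds integer seeds, one per ensemble member
#' @return list of trained [CparModel-class] objects
#' @export
trainCparEnsemble <- function(labeled, validation, unlabeled = NULL,
                              config = networkConfig(),
                              training = trainingConfig(),
                              seeds = 1:10, verbose = FALSE) {
    lapply(seeds, function(s)
        trainCpar(labeled, validation, unlabeled, config, training,
                  seed = s, verbose = verbose))
}

#' Predict VSI from brachial and tibial waveforms
#'
#' Inference uses only the feature extractor and the VSI head; the
#' adversarial heads are not evaluated.
#'
#' @param model a trained [CparModel-class]
#' @param brachial,tibial waveform vectors (or matrices with one record
#'   per column)
#' @return predicted VSI (%), one value per record
#' @export
predictVsi <- function(model, brachial, tibial) {
    if (!model@trained) stop("model is not trained")
    if (is.null(dim(brachial))) brachial <- matrix(brachial, ncol = 1)
    if (is.null(dim(tibial))) tibial <- matrix(tibial, ncol = 1)
    X <- .stackInputs(brachial, tibial)
    .predictX(model@thetaF, model@thetaL, X, model@config)
}

#' Predict VSI for every record of a cohort
#'
#' @param model a trained [CparModel-class]
#' @param cohort a [PulseCohort-class]
#' @return numeric vector of predicted VSI (%)
#' @export
predictCohort <- function(model, cohort) {
    if (!model@trained) stop("model is not trained")
    d <- .cohortToData(cohort, model@training$modality)
    .predictX(model@thetaF, model@thetaL, d$X, model@config)
}
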