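## 1-D CNN with CBAM attention, a skip connection and three regressor heads,
## trained with continuous property-adversarial regularization (CPAR).
## The whole engine (dilated convolutions, batch normalization, channel and
## spatial attention, Adam, adversarial updates) is implemented on plain
## matrices: activations live in a (channels x width*batch) matrix whose
## columns are sample-major, so a convolution is an im2col gather followed
## by one matrix product.  Backward passes are hand-derived and verified
## against finite differences in the test suite.

#' Network architecture configuration
#'
#' The feature extractor processes each input row (brachial, tibial)
#' independently: five dilated 1-D convolutions (kernel 5 then 3,3,3,3,
#' stride 1, dilation 3, length-preserving padding) with batch
#' normalization and ReLU, a skip connection from layer 2 to layer 4,
#' CBAM attention after layers 3 and 5, then a 1x1 compression convolution
#' to \code{latentChannels} channels and average pooling by
#' \code{poolFactor}, yielding a latent tensor of shape
#' (\code{latentChannels}, 2, \code{width/poolFactor}).  Three parallel
#' fully connected heads (64, 64, 1 neurons) map the flattened latent to
#' the VSI estimate and the two adversarial targets.
#'
#' @param channels convolution output channels per layer; the default is
#'   sized so the feature extractor holds approximately 810,000 trainable
#'   parameters.  Layers 2 and 4 must match for the skip connection.
#' @param kernel kernel width per layer (odd)
#' @param dilation dilation of all convolution layers
#' @param width input record length (samples)
#' @param latentChannels channels after the compression convolution
#' @param poolFactor average-pooling factor (width 256 -> 64)
#' @param reduction CBAM channel-attention reduction factor
#' @param spatialKernel CBAM spatial-attention kernel width
#' @param cbamAfter layers followed by a CBAM block
#' @param skip \code{c(from, to)} skip connection between conv layers
#' @param headWidths fully connected widths of each regressor head
#' @return configuration list
#' @export
networkConfig <- function(channels = c(128L, 256L, 256L, 256L, 320L),
                          kernel = c(5L, 3L, 3L, 3L, 3L),
                          dilation = 3L, width = 256L,
                          latentChannels = 32L, poolFactor = 4L,
                          reduction = 16L, spatialKernel = 7L,
                          cbamAfter = c(3L, 5L), skip = c(2L, 4L),
                          headWidths = c(64L, 64L, 1L)) {
    stopifnot(length(channels) == length(kernel),
              all(kernel %% 2 == 1), width %% poolFactor == 0)
    if (channels[skip[1]] != channels[skip[2]])
        stop("skip connection requires matching channel widths at layers ",
             skip[1], " and ", skip[2])
    list(channels = channels, kernel = kernel, dilation = dilation,
         width = width, latentChannels = latentChannels,
         poolFactor = poolFactor, reduction = reduction,
         spatialKernel = spatialKernel, cbamAfter = cbamAfter, skip = skip,
         headWidths = headWidths,
         latentDim = latentChannels * 2L * (width %/% poolFactor))
}

## ---- initialization --------------------------------------------------

.heInit <- function(nout, nin) {
    matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

.initTrunk <- function(cfg) {
    ch <- c(1L, cfg$channels)
    conv <- lapply(seq_along(cfg$channels), function(i) {
        fanin <- ch[i] * cfg$kernel[i]
        ## no conv bias: batch normalization directly follows, making a
        ## bias redundant (its gradient is identically zero)
        list(W = .heInit(ch[i + 1], fanin),
             g = rep(1, ch[i + 1]), be = numeric(ch[i + 1]),
             rm = numeric(ch[i + 1]), rv = rep(1, ch[i + 1]))
    })
    names(conv) <- paste0("C", seq_along(conv))
    cbam <- lapply(cfg$cbamAfter, function(i) {
        C <- cfg$channels[i]
        r <- max(1L, C %/% cfg$reduction)
        ## bs must be freshly allocated (never a shared literal): the
        ## Adam kernel updates parameter buffers in place
        list(Wc1 = .heInit(r, C), Wc2 = .heInit(C, r),
             Ws = .heInit(1, 2 * cfg$spatialKernel), bs = numeric(1))
    })
    names(cbam) <- paste0("L", cfg$cbamAfter)
    comp <- list(W = .heInit(cfg$latentChannels, tail(cfg$channels, 1)),
                 b = numeric(cfg$latentChannels))
    list(conv = conv, cbam = cbam, comp = comp)
}

.initHead <- function(cfg) {
    w <- cfg$headWidths
    d <- cfg$latentDim
    list(W1 = .heInit(w[1], d), b1 = numeric(w[1]),
         W2 = .heInit(w[2], w[1]), b2 = numeric(w[2]),
         W3 = .heInit(w[3], w[2]), b3 = numeric(w[3]))
}

#' Build an initialized CPAR network
#'
#' @param config a [networkConfig()] list
#' @param training a [trainingConfig()] list stored with the model
#' @param seed integer seed for parameter initialization
#' @return an untrained [CparModel-class]
#' @examples
#' m <- buildNetwork(networkConfig(channels = c(8, 8, 8, 8, 8)), seed = 1)
#' cparParameterCount(m)
#' @export
buildNetwork <- function(config = networkConfig(),
                         training = trainingConfig(), seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    new("CparModel",
        thetaF = .initTrunk(config),
        thetaL = .initHead(config),
        thetaH = .initHead(config),
        thetaA = .initHead(config),
        config = config, training = training,
        norm = list(), history = data.frame(), trained = FALSE)
}

#' Parameter counts of a CPAR model
#'
#' @param model a [CparModel-class]
#' @return named vector: trainable parameters in the feature extractor and
#'   in each regressor head (batch-normalization running statistics are
#'   state, not parameters, and are excluded)
#' @export
cparParameterCount <- function(model) {
    countT <- function(l) {
        n <- 0
        for (cv in l$conv) n <- n + length(cv$W) +
            length(cv$g) + length(cv$be)
        for (cb in l$cbam) n <- n + length(cb$Wc1) + length(cb$Wc2) +
            length(cb$Ws) + length(cb$bs)
        n + length(l$comp$W) + length(l$comp$b)
    }
    countH <- function(h) sum(vapply(h, length, 1L))
    c(featureExtractor = countT(model@thetaF),
      vsiHead = countH(model@thetaL),
      heightHead = countH(model@thetaH),
      ageHead = countH(model@thetaA))
}

## ---- convolution as im2col -------------------------------------------

.convIndexCache <- new.env(parent = emptyenv())

## gather indices (k x W*B): column c feeds from columns idx[j, c] of the
## activation matrix (0 = zero padding); samples are independent
.convIndex <- function(W, B, k, d) {
    key <- paste(W, B, k, d, sep = "_")
    hit <- .convIndexCache[[key]]
    if (!is.null(hit)) return(hit)
    off <- d * (seq_len(k) - (k + 1) / 2)
    w <- rep(seq_len(W), B)
    base <- rep((seq_len(B) - 1L) * W, each = W)
    idx <- vapply(off, function(o) {
        ww <- w + o
        as.integer(ifelse(ww >= 1 & ww <= W, base + ww, 0L))
    }, integer(W * B))
    idx <- t(idx)                       # k x W*B
    .convIndexCache[[key]] <- idx
    idx
}

.im2col <- function(A, idx) im2col_cpp(A, idx)

.col2im <- function(dXcol, idx, C) col2im_cpp(dXcol, idx, as.integer(C))

.poolMatCache <- new.env(parent = emptyenv())
.poolMat <- function(C, pf) {
    key <- paste(C, pf)
    hit <- .poolMatCache[[key]]
    if (!is.null(hit)) return(hit)
    E <- do.call(cbind, rep(list(diag(C)), pf))
    .poolMatCache[[key]] <- E
    E
}

## ---- layers -----------------------------------------------------------

.bnForward <- function(x, g, be, rm, rv, train, eps = 1e-5) {
    if (train) {
        mu <- rowMeans(x)
        v <- rowMeans((x - mu)^2)
    } else {
        mu <- rm; v <- rv
    }
    istd <- 1 / sqrt(v + eps)
    xhat <- (x - mu) * istd
    list(y = xhat * g + be, xhat = xhat, istd = istd, mu = mu, v = v)
}

.bnBackward <- function(dy, cache, g) {
    xhat <- cache$xhat
    dg <- rowSums(dy * xhat)
    dbe <- rowSums(dy)
    m <- ncol(dy)
    dx <- (g * cache$istd) *
        (dy - dbe / m - xhat * (dg / m))
    list(dx = dx, dg = dg, dbe = dbe)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

## CBAM forward: channel attention then spatial attention.
.cbamForward <- function(A, p, W, B, cfg) {
    C <- nrow(A)
    cols <- matrix(seq_len(W * B), W, B)
    A3 <- matrix(A, C * W, B)            # per-sample stacked columns
    savg <- matrix(.poolMat(C, W) %*% A3 / W, C, B)
    amaxIdx <- matrix(0L, C, B)
    smax <- matrix(0, C, B)
    for (b in seq_len(B)) {
        Ab <- A[, cols[, b], drop = FALSE]
        mi <- max.col(Ab, ties.method = "first")
        amaxIdx[, b] <- mi
        smax[, b] <- Ab[cbind(seq_len(C), mi)]
    }
    m1a <- p$Wc1 %*% savg; h1a <- pmax(m1a, 0)
    m1m <- p$Wc1 %*% smax; h1m <- pmax(m1m, 0)
    z <- p$Wc2 %*% h1a + p$Wc2 %*% h1m
    att <- .sigmoid(z)                       # C x B
    attX <- att[, rep(seq_len(B), each = W), drop = FALSE]
    Ac <- A * attX
    ## spatial attention
    pavg <- colMeans(Ac)
    pmaxIdx <- max.col(t(Ac), ties.method = "first")
    pmaxV <- Ac[cbind(pmaxIdx, seq_len(W * B))]
    S <- rbind(pavg, pmaxV)                  # 2 x W*B
    idxS <- .convIndex(W, B, cfg$spatialKernel, 1L)
    Scol <- .im2col(S, idxS)
    ys <- as.numeric(p$Ws %*% Scol + p$bs)   # 1 x W*B
    satt <- .sigmoid(ys)
    out <- Ac * rep(satt, each = C)
    list(out = out, A = A, att = att, attX = attX, Ac = Ac,
         savg = savg, smax = smax, amaxIdx = amaxIdx,
         m1a = m1a, h1a = h1a, m1m = m1m, h1m = h1m,
         pavg = pavg, pmaxIdx = pmaxIdx, S = S, Scol = Scol,
         satt = satt, idxS = idxS, cols = cols)
}

.cbamBackward <- function(dOut, cc, p, W, B) {
    C <- nrow(dOut)
    ## spatial attention
    dAc <- dOut * rep(cc$satt, each = C)
    dsatt <- colSums(dOut * cc$Ac)
    dys <- dsatt * cc$satt * (1 - cc$satt)
    dWs <- tcrossprod(matrix(dys, 1), cc$Scol)
    dbs <- sum(dys)
    dScol <- crossprod(p$Ws, matrix(dys, 1))
    dS <- .col2im(dScol, cc$idxS, 2L)
    dAc <- dAc + matrix(dS[1, ] / C, C, W * B, byrow = TRUE)
    ix <- cbind(cc$pmaxIdx, seq_len(W * B))
    dAc[ix] <- dAc[ix] + dS[2, ]
    ## channel attention
    dA <- dAc * cc$attX
    P <- dAc * cc$A
    datt <- matrix(.poolMat(C, W) %*% matrix(P, C * W, B), C, B)
    dz <- datt * cc$att * (1 - cc$att)
    dh1a <- crossprod(p$Wc2, dz); dh1m <- dh1a
    dWc2 <- tcrossprod(dz, cc$h1a) + tcrossprod(dz, cc$h1m)
    dm1a <- dh1a * (cc$m1a > 0); dm1m <- dh1m * (cc$m1m > 0)
    dWc1 <- tcrossprod(dm1a, cc$savg) + tcrossprod(dm1m, cc$smax)
    dsavg <- crossprod(p$Wc1, dm1a)
    dsmax <- crossprod(p$Wc1, dm1m)
    dA <- dA + (dsavg / W)[, rep(seq_len(B), each = W), drop = FALSE]
    ix2 <- cbind(rep(seq_len(C), B),
                 rep((seq_len(B) - 1L) * W, each = C) +
                     as.vector(cc$amaxIdx))
    dA[ix2] <- dA[ix2] + as.vector(dsmax)
    list(dA = dA, grads = list(Wc1 = dWc1, Wc2 = dWc2, Ws = dWs, bs = dbs))
}

## ---- trunk forward / backward ----------------------------------------

## X: matrix (B x width) of row-sequences (2 consecutive rows per record)
.trunkForward <- function(theta, X, cfg, train = TRUE) {
    B <- nrow(X); W <- cfg$width
    A <- matrix(t(X), nrow = 1)          # 1 x W*B, sample-major columns
    layers <- vector("list", length(cfg$channels))
    acts <- list()
    for (i in seq_along(cfg$channels)) {
        p <- theta$conv[[i]]
        idx <- .convIndex(W, B, cfg$kernel[i], cfg$dilation)
        Xcol <- .im2col(A, idx)
        Y <- p$W %*% Xcol
        bn <- .bnForward(Y, p$g, p$be, p$rm, p$rv, train)
        Z <- bn$y
        if (i == cfg$skip[2]) Z <- Z + acts[[cfg$skip[1]]]
        relu <- pmax(Z, 0)
        cc <- NULL
        out <- relu
        key <- paste0("L", i)
        if (i %in% cfg$cbamAfter) {
            cc <- .cbamForward(relu, theta$cbam[[key]], W, B, cfg)
            out <- cc$out
        }
        layers[[i]] <- list(Ain = A, Xcol = Xcol, bn = bn, Z = Z,
                            relu = relu, cbam = cc, idx = idx)
        acts[[i]] <- out
        A <- out
    }
    cache <- list(layers = layers)
    ## compression 1x1 conv + ReLU
    Yc <- theta$comp$W %*% A + theta$comp$b
    Rc <- pmax(Yc, 0)
    ## average pooling along width by poolFactor: consecutive column
    ## blocks of pf stack under a reshape, so pooling is one matmul with
    ## pf horizontally tiled identity blocks
    pf <- cfg$poolFactor
    Wp <- W %/% pf
    LC <- cfg$latentChannels
    E <- .poolMat(LC, pf)
    pooled <- (E %*% matrix(Rc, LC * pf, Wp * B)) / pf
    ## flatten per record: two consecutive row-samples
    N <- B %/% 2L
    Zl <- matrix(pooled, LC * Wp * 2L, N)
    cache$comp <- list(Ain = A, Yc = Yc, Rc = Rc)
    cache$dims <- c(W = W, B = B, Wp = Wp, LC = LC, N = N)
    list(Z = Zl, cache = cache)
}

.trunkBackward <- function(theta, dZ, cache, cfg) {
    d <- cache$dims
    W <- d[["W"]]; B <- d[["B"]]; Wp <- d[["Wp"]]; LC <- d[["LC"]]
    layers <- cache$layers
    pooled <- matrix(dZ, LC, Wp * (2L * d[["N"]]))
    ## un-pool (distribute evenly)
    pf <- cfg$poolFactor
    dRc <- matrix(crossprod(.poolMat(LC, pf), pooled) / pf, LC, W * B)
    dYc <- dRc * (cache$comp$Yc > 0)
    grads <- list(conv = vector("list", length(cfg$channels)),
                  cbam = list(),
                  comp = list(W = dYc %*% t(cache$comp$Ain),
                              b = rowSums(dYc)))
    dA <- t(theta$comp$W) %*% dYc
    dSkip <- NULL
    for (i in rev(seq_along(cfg$channels))) {
        lc <- layers[[i]]
        key <- paste0("L", i)
        ## the skip taps the full layer output (post-ReLU/CBAM)
        if (i == cfg$skip[1] && !is.null(dSkip)) dA <- dA + dSkip
        if (!is.null(lc$cbam)) {
            cb <- .cbamBackward(dA, lc$cbam, theta$cbam[[key]], W, B)
            grads$cbam[[key]] <- cb$grads
            dA <- cb$dA
        }
        dZl <- dA * (lc$Z > 0)
        p <- theta$conv[[i]]
        bb <- .bnBackward(dZl, lc$bn, p$g)
        if (i == cfg$skip[2]) dSkip <- dZl    # routed to the skip source
        dY <- bb$dx
        grads$conv[[i]] <- list(W = tcrossprod(dY, lc$Xcol),
                                g = bb$dg, be = bb$dbe)
        Cin <- nrow(lc$Ain)
        dXcol <- crossprod(p$W, dY)
        dA <- .col2im(dXcol, lc$idx, Cin)
    }
    names(grads$conv) <- paste0("C", seq_along(grads$conv))
    grads
}

## ---- head forward / backward -----------------------------------------

.headForward <- function(h, Z) {
    a1 <- h$W1 %*% Z + h$b1; r1 <- pmax(a1, 0)
    a2 <- h$W2 %*% r1 + h$b2; r2 <- pmax(a2, 0)
    y <- as.numeric(h$W3 %*% r2 + h$b3)
    list(y = y, Z = Z, a1 = a1, r1 = r1, a2 = a2, r2 = r2)
}

.headBackward <- function(h, dy, cc) {
    dy <- matrix(dy, 1)
    dW3 <- tcrossprod(dy, cc$r2); db3 <- sum(dy)
    dr2 <- crossprod(h$W3, dy)
    da2 <- dr2 * (cc$a2 > 0)
    dW2 <- tcrossprod(da2, cc$r1); db2 <- rowSums(da2)
    dr1 <- crossprod(h$W2, da2)
    da1 <- dr1 * (cc$a1 > 0)
    dW1 <- tcrossprod(da1, cc$Z); db1 <- rowSums(da1)
    dZ <- crossprod(h$W1, da1)
    list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                      W3 = dW3, b3 = db3),
         dZ = dZ)
}

## ---- losses -----------------------------------------------------------

#' Label (VSI) prediction loss
#'
#' Mean squared error between predicted and reference VSI (percent units).
#'
#' @param predictions,labels numeric vectors of equal length
#' @return scalar loss
#' @export
labelLoss <- function(predictions, labels) {
    if (!length(predictions)) stop("empty batch")
    mean((labels - predictions)^2)
}

#' Disturbance (adversarial) regression loss
#'
#' Bounded-gradient loss on the standardized height/age prediction error:
#' \code{mean(log(1 / (1 - tanh(|e|))))}.  Zero iff every error is zero,
#' symmetric in the error sign, strictly increasing in \code{|e|} and
#' asymptotically \code{2|e| - log(2)} for large errors.
#'
#' @param predictions,targets numeric vectors; targets should be
#'   standardized to zero mean and unit variance over the training set
#' @return scalar loss
#' @export
disturbanceLoss <- function(predictions, targets) {
    if (!length(predictions)) stop("empty batch")
    e <- abs(targets - predictions)
    mean(log(1 / (1 - tanh(e))))
}

## d loss / d prediction for the disturbance loss
.disturbanceGrad <- function(predictions, targets) {
    e <- targets - predictions
    -sign(e) * (1 + tanh(abs(e))) / length(e)
}

#' Standardize network inputs
#'
#' Stacks the brachial and tibial waveforms as two rows and z-scores each
#' row independently (waveform amplitude units are arbitrary for PVR, so
#' the network must be scale-invariant).
#'
#' @param brachial,tibial equal-length waveforms
#' @return matrix (2 x width)
#' @export
inputPreprocess <- function(brachial, tibial) {
    if (length(brachial) != length(tibial))
        stop("row lengths differ")
    z <- function(x) {
        s <- sd(x)
        if (!is.finite(s) || s < 1e-12) return(x * 0)
        (x - mean(x)) / s
    }
    rbind(brachial = z(brachial), tibial = z(tibial))
}

## build (B x width) row matrix from a cohort's two assay matrices
.stackInputs <- function(brachialMat, tibialMat) {
    N <- ncol(brachialMat)
    X <- matrix(0, 2L * N, nrow(brachialMat))
    for (i in seq_len(N)) {
        pp <- inputPreprocess(brachialMat[, i], tibialMat[, i])
        X[2L * i - 1L, ] <- pp[1, ]
        X[2L * i, ] <- pp[2, ]
    }
    X
}

## ---- Adam -------------------------------------------------------------

.adamInit <- function(params) {
    rapply(params, function(x) list(m = x * 0, v = x * 0),
           how = "list")
}

## leaf paths of a nested parameter list (cached per structure signature)
.leafPathCache <- new.env(parent = emptyenv())
.leafPaths <- function(g, prefix = character()) {
    out <- list()
    keys <- if (is.null(names(g))) as.character(seq_along(g)) else names(g)
    for (nm in keys) {
        el <- g[[nm]]
        if (is.null(el)) next
        if (is.list(el)) out <- c(out, .leafPaths(el, c(prefix, nm)))
        else out[[length(out) + 1L]] <- c(prefix, nm)
    }
    out
}

## update params (nested list); returns list(p = params, s = state)
.adamStep <- function(params, grads, state, lr, beta1, beta2, t,
                      eps = 1e-8, skipNames = c("rm", "rv")) {
    key <- paste(vapply(grads, function(x)
        if (is.list(x)) length(x) else 1L, 1L), collapse = "_")
    paths <- .leafPathCache[[key]]
    if (is.null(paths)) {
        paths <- .leafPaths(grads)
        .leafPathCache[[key]] <- paths
    }
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    for (pth in paths) {
        leaf <- pth[length(pth)]
        if (leaf %in% skipNames) next
        s <- state[[pth]]
        adam_update_cpp(params[[pth]], s$m, s$v, grads[[pth]],
                        lr, beta1, beta2, c1, c2, eps)
    }
    list(p = params, s = state)
}

## deep copy of a nested numeric parameter list (detaches from the
## in-place optimizer buffers)
.deepCopy <- function(x) rapply(x, function(v) v + 0, how = "replace")
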