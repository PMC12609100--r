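## BP -> PVR viscoelastic transfer functions of the artery-tissue-cuff
## interface.  Brachial: standard linear solid (spring E_B1 parallel to a
## dashpot eta_B in series with spring E_B2); tibial: Voigt body (spring E_T
## parallel to dashpot eta_T).  Applied as exact frequency-domain
## multiplication on the periodic record; a bilinear-transform IIR variant
## is available for streaming-style use.

#' Viscoelastic BP-PVR parameters
#'
#' @param eB1,eB2 brachial standard-linear-solid elastic constants
#'   (pressure per unit cuff volume, arbitrary normalized units)
#' @param etaB brachial damping constant
#' @param eT,etaT tibial Voigt elastic and damping constants
#' @return named list of the five parameters
#' @export
viscoelasticParams <- function(eB1 = 1, eB2 = 4, etaB = 0.2,
                               eT = 1, etaT = 0.1) {
    p <- list(eB1 = eB1, eB2 = eB2, etaB = etaB, eT = eT, etaT = etaT)
    if (any(unlist(p) <= 0)) stop("viscoelastic constants must be positive")
    p
}

#' Brachial transfer function (standard linear solid)
#'
#' \code{H_B(s) = (E_B2 + eta_B s) / (E_B1 E_B2 + (E_B1 + E_B2) eta_B s)}:
#' DC gain \code{1/E_B1}, high-frequency gain \code{1/(E_B1 + E_B2)},
#' monotone non-increasing magnitude.
#'
#' @param omega angular frequency, rad/s
#' @param params a [viscoelasticParams()] list
#' @return complex gain
#' @export
brachialTransfer <- function(omega, params) {
    s <- 1i * omega
    (params$eB2 + params$etaB * s) /
        (params$eB1 * params$eB2 + (params$eB1 + params$eB2) * params$etaB * s)
}

#' Tibial transfer function (Voigt body)
#'
#' \code{H_T(s) = 1 / (E_T + eta_T s)}: DC gain \code{1/E_T}, strictly
#' low-pass.
#'
#' @inheritParams brachialTransfer
#' @return complex gain
#' @export
tibialTransfer <- function(omega, params)
    1 / (params$eT + params$etaT * 1i * omega)

## exact frequency-domain application of a transfer function to a periodic
## record: multiply each FFT bin by H(j w), conjugate-symmetric.
.applyTransfer <- function(p, fs, H) {
    n <- length(p)
    X <- fft(p)
    kk <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    w <- 2 * pi * kk * fs / n
    Re(fft(X * H(w), inverse = TRUE)) / n
}

#' Convert a brachial pressure waveform to PVR
#'
#' Applies the standard-linear-solid transfer function per Fourier harmonic
#' of the periodic record.  PVR amplitude units are arbitrary; no
#' re-normalization is performed here.
#'
#' @param p pressure waveform (one periodic record)
#' @param params a [viscoelasticParams()] list
#' @param fs sampling frequency, Hz
#' @param method \code{"spectral"} (exact on periodic records) or
#'   \code{"bilinear"} (causal IIR discretization)
#' @return PVR waveform, same length as \code{p}
#' @export
brachialPvr <- function(p, params, fs = 128,
                        method = c("spectral", "bilinear")) {
    method <- match.arg(method)
    if (method == "spectral")
        .applyTransfer(p, fs, function(w) brachialTransfer(w, params))
    else {
        ## bilinear transform of (b0 + b1 s)/(a0 + a1 s), warped at s = 2fs(1-z^-1)/(1+z^-1)
        .bilinear1(p, b0 = params$eB2, b1 = params$etaB,
                   a0 = params$eB1 * params$eB2,
                   a1 = (params$eB1 + params$eB2) * params$etaB, fs = fs)
    }
}

#' Convert a tibial pressure waveform to PVR
#'
#' Applies the Voigt-body transfer function per Fourier harmonic of the
#' periodic record.
#'
#' @inheritParams brachialPvr
#' @return PVR waveform
#' @export
tibialPvr <- function(p, params, fs = 128,
                      method = c("spectral", "bilinear")) {
    method <- match.arg(method)
    if (method == "spectral")
        .applyTransfer(p, fs, function(w) tibialTransfer(w, params))
    else
        .bilinear1(p, b0 = 1, b1 = 0, a0 = params$eT, a1 = params$etaT,
                   fs = fs)
}

## first-order bilinear-transform filter for H(s) = (b0 + b1 s)/(a0 + a1 s),
## run over two periods and the second one kept (start-up transient decay)
.bilinear1 <- function(p, b0, b1, a0, a1, fs) {
    c2 <- 2 * fs
    B <- c(b0 + b1 * c2, b0 - b1 * c2)
    A <- c(a0 + a1 * c2, a0 - a1 * c2)
    x <- c(p, p)
    y <- numeric(length(x))
    xprev <- x[1]; yprev <- (b0 / a0) * x[1]
    for (i in seq_along(x)) {
        y[i] <- (B[1] * x[i] + B[2] * xprev - A[2] * yprev) / A[1]
        xprev <- x[i]; yprev <- y[i]
    }
    y[(length(p) + 1):(2 * length(p))]
}
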