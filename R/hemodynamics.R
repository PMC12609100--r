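## Frequency-domain transmission-line solver.
##
## Each artery is a uniform lossy line with Womersley longitudinal impedance
## Z'(w) = (j w rho / A) / (1 - F10(alpha)) per unit length and thin-wall
## elastic compliance C' = 3 pi r^3 / (2 E h) per unit length.  Terminals
## carry 3-element Windkessel loads.  The periodic solution is assembled per
## harmonic of the heart rate: leaf-to-root input-impedance recursion, then
## root pressure P = Zin * Q, then root-to-leaf propagation of the
## forward/backward wave amplitudes.  The mean (DC) component is solved on
## the Poiseuille-resistance skeleton.

.MMHG <- 133.322

## J1(z)/J0(z) for complex z (upper half-plane arguments).  Backward
## continued fraction for moderate |z|; large-|z| Hankel asymptotics
## (the H2 component dominates for Im z > 0), relative error < 1e-4 at the
## switch point.
.besselRatioJ1J0 <- function(z) {
    out <- complex(length.out = length(z))
    big <- Mod(z) > 14
    if (any(!big)) {
        zz <- z[!big]
        r <- complex(length.out = length(zz))
        for (m in 60:1L) r <- 1 / (2 * m / zz - r)
        out[!big] <- r
    }
    if (any(big)) {
        zz <- z[big]
        s0 <- 1 + 1i / (8 * zz) - 9 / (128 * zz^2)
        s1 <- 1 - 3i / (8 * zz) + 15 / (128 * zz^2)
        out[big] <- 1i * s1 / s0
    }
    out
}

## Womersley function F10(alpha) = 2 J1(zeta) / (zeta J0(zeta)),
## zeta = alpha * i^(3/2).
.womersleyF10 <- function(alpha) {
    zeta <- alpha * complex(modulus = 1, argument = 3 * pi / 4)
    2 * .besselRatioJ1J0(zeta) / zeta
}

#' Longitudinal (per-length) impedance of an arterial segment
#'
#' Womersley oscillatory-flow theory:
#' \code{Z' = (j w rho / A) / (1 - F10(alpha))} with Womersley number
#' \code{alpha = r * sqrt(w * rho / mu)}.  At \code{w = 0} this reduces to
#' the Poiseuille resistance per unit length, \code{8 mu / (pi r^4)}.
#'
#' @param radius inner radius, m
#' @param omega angular frequency, rad/s (scalar or vector, >= 0)
#' @param density blood density, kg/m^3
#' @param viscosity blood dynamic viscosity, Pa s
#' @return complex impedance per unit length, Pa s/m^4
#' @export
longitudinalImpedance <- function(radius, omega, density = 1050,
                                  viscosity = 4e-3) {
    if (any(omega < 0)) stop("omega must be non-negative")
    A <- pi * radius^2
    out <- complex(length.out = length(omega))
    dc <- omega == 0
    out[dc] <- 8 * viscosity / (pi * radius^4)
    if (any(!dc)) {
        w <- omega[!dc]
        alpha <- radius * sqrt(w * density / viscosity)
        F10 <- .womersleyF10(alpha)
        out[!dc] <- (1i * w * density / A) / (1 - F10)
    }
    out
}

#' Wall compliance per unit length
#'
#' Thin-wall elastic tube: \code{C' = 3 pi r^3 / (2 E h)}, implying a local
#' lossless wave speed \code{c = sqrt(2 E h / (3 rho r))}
#' (Moens-Korteweg type).
#'
#' @param radius inner radius, m
#' @param thickness wall thickness, m
#' @param youngs Young's modulus, Pa
#' @return compliance per unit length, m^3/(Pa m)
#' @export
wallCompliancePerLength <- function(radius, thickness, youngs)
    3 * pi * radius^3 / (2 * youngs * thickness)

#' Characteristic impedance and propagation constant
#'
#' \code{Zc = sqrt(Z' / (j w C'))} and \code{gamma = sqrt(Z' * j w C')};
#' in the inviscid limit \code{Zc -> rho c / A} (real) and
#' \code{gamma -> j w / c}.
#'
#' @param radius,thickness,youngs segment geometry and stiffness (SI)
#' @param omega angular frequency, rad/s (> 0)
#' @param density,viscosity blood properties
#' @return complex vector of \code{Zc} (Pa s/m^3) or \code{gamma} (1/m)
#' @export
characteristicImpedance <- function(radius, thickness, youngs, omega,
                                    density = 1050, viscosity = 4e-3) {
    if (any(omega <= 0)) stop("omega must be positive (DC handled separately)")
    Zp <- longitudinalImpedance(radius, omega, density, viscosity)
    Cp <- wallCompliancePerLength(radius, thickness, youngs)
    sqrt(Zp / (1i * omega * Cp))
}

#' @rdname characteristicImpedance
#' @export
propagationConstant <- function(radius, thickness, youngs, omega,
                                density = 1050, viscosity = 4e-3) {
    if (any(omega <= 0)) stop("omega must be positive (DC handled separately)")
    Zp <- longitudinalImpedance(radius, omega, density, viscosity)
    Cp <- wallCompliancePerLength(radius, thickness, youngs)
    sqrt(Zp * 1i * omega * Cp)
}

#' Three-element Windkessel input impedance
#'
#' \code{Z(w) = R1 + R2 / (1 + j w R2 C)} with \code{R1} the proximal share
#' of the total resistance and \code{C} the terminal compliance.
#'
#' @param rTotal total terminal resistance R1 + R2, Pa s/m^3
#' @param compliance terminal compliance, m^3/Pa
#' @param proximalFraction R1 / (R1 + R2), in (0, 1)
#' @param omega angular frequency, rad/s (>= 0)
#' @return complex impedance
#' @export
windkesselImpedance <- function(rTotal, compliance, proximalFraction, omega) {
    R1 <- proximalFraction * rTotal
    R2 <- (1 - proximalFraction) * rTotal
    R1 + R2 / (1 + 1i * omega * R2 * compliance)
}

#' Input impedance of a loaded transmission line
#'
#' Standard lossy-line recursion
#' \code{Zin = Zc (ZL + Zc tanh(gamma l)) / (Zc + ZL tanh(gamma l))}; a
#' matched load (\code{ZL = Zc}) returns \code{Zc} exactly.
#'
#' @param zc characteristic impedance (complex)
#' @param gamma propagation constant (complex, 1/m)
#' @param len segment length, m
#' @param zLoad distal load impedance (complex)
#' @return complex input impedance
#' @export
inputImpedance <- function(zc, gamma, len, zLoad) {
    t <- tanh(gamma * len)
    zc * (zLoad + zc * t) / (zc + zLoad * t)
}

#' Aortic inflow waveform
#'
#' Half-sine systolic ejection with configurable systolic duration
#' \code{Tsys = tsysScale * sqrt(60 / hr)} seconds and zero diastolic flow;
#' the per-beat integral equals the stroke volume exactly and the peak flow
#' is \code{sv * pi / (2 * Tsys)}.
#'
#' @param hr heart rate, bpm
#' @param sv stroke volume, m^3
#' @param tsysScale systolic-duration scale, s (at 60 bpm)
#' @return a list of class \code{"AorticInflow"} with fields \code{hr},
#'   \code{sv}, \code{tsys} and \code{period}
#' @examples
#' q <- aorticInflow(75, 70e-6)
#' beat <- inflowBeat(q, 512)
#' sum(beat) * q$period / 512  # integrates to the stroke volume
#' @export
aorticInflow <- function(hr, sv, tsysScale = 0.3) {
    stopifnot(hr > 0, sv > 0)
    structure(list(hr = hr, sv = sv,
                   tsys = tsysScale * sqrt(60 / hr),
                   period = 60 / hr),
              class = "AorticInflow")
}

#' Sample one beat of an aortic inflow
#'
#' @param inflow an \code{"AorticInflow"}
#' @param n number of samples over one beat
#' @return numeric vector of flows (m^3/s) at times \code{(0:(n-1))/n * T}
#' @export
inflowBeat <- function(inflow, n = 256L) {
    t <- (seq_len(n) - 1) / n * inflow$period
    qp <- inflow$sv * pi / (2 * inflow$tsys)
    ifelse(t < inflow$tsys, qp * sin(pi * t / inflow$tsys), 0)
}

## Complex one-sided Fourier coefficients c_k = (1/T) int q(t) e^{-i w_k t}
## of the half-sine ejection, closed form; k a vector of harmonic numbers.
.inflowHarmonics <- function(inflow, k) {
    T <- inflow$period; Ts <- inflow$tsys
    qp <- inflow$sv * pi / (2 * Ts)
    w <- 2 * pi * k / T
    a <- pi / Ts
    ## int_0^Ts sin(a t) e^{-i w t} dt = a (1 + e^{-i w Ts}) / (a^2 - w^2)
    num <- a * (1 + exp(-1i * w * Ts))
    den <- a^2 - w^2
    res <- complex(length.out = length(k))
    sing <- abs(den) < 1e-9 * a^2
    res[!sing] <- num[!sing] / den[!sing]
    if (any(sing)) {
        ## exact value at w = a: sin(at) e^{-iat} integrates to
        ## (1 - cos(2aTs))/(4a) - i (Ts/2 - sin(2aTs)/(4a))
        res[sing] <- (1 - cos(2 * a * Ts)) / (4 * a) -
            1i * (Ts / 2 - sin(2 * a * Ts) / (4 * a))
    }
    qp * res / T
}

## Core periodic solve.  ctree: .compileTree output (possibly with per-record
## parameter vectors already scaled).  Returns list(sites=named list of
## 256-sample mmHg waveforms, meanRootPa, rootDcResistance, flowResidual).
.solveTree <- function(ctree, inflow, settings, sites) {
    f0 <- inflow$hr / 60
    K <- settings$nHarmonics
    if (is.null(K)) K <- max(10L, floor(settings$fmax / f0))
    K <- min(K, floor((settings$fs / 2 - 1e-9) / f0))
    kvec <- seq_len(K)
    omega <- 2 * pi * f0 * kvec
    n <- ctree$n
    rho <- ctree$rho; mu <- ctree$mu
    r <- ctree$r; L <- ctree$L
    A <- pi * r^2
    ## S x K complex matrices of line constants
    alpha <- outer(r, sqrt(omega * rho / mu))
    zeta <- alpha * complex(modulus = 1, argument = 3 * pi / 4)
    F10 <- 2 * .besselRatioJ1J0(zeta) / zeta
    Zp <- (matrix(1i * omega * rho, n, K, byrow = TRUE) / A) / (1 - F10)
    Cp <- wallCompliancePerLength(r, ctree$h, ctree$E)
    jwC <- matrix(1i * omega, n, K, byrow = TRUE) * Cp
    Zc <- sqrt(Zp / jwC)
    gamma <- sqrt(Zp * jwC)
    tgl <- tanh(gamma * L)
    ## DC resistances
    Rseg <- 8 * mu * L / (pi * r^4)
    ## leaf-to-root recursion (reverse topological order)
    Zin <- matrix(0i, n, K)
    Rdc <- numeric(n)
    ZL <- matrix(0i, n, K)
    for (i in rev(ctree$order)) {
        if (ctree$terminal[i]) {
            zl <- windkesselImpedance(ctree$rT[i], ctree$cT[i],
                                      ctree$pf[i], omega)
            rl <- ctree$rT[i]
        } else {
            ch <- ctree$children[[i]]
            zl <- 1 / colSums(matrix(1 / Zin[ch, , drop = FALSE],
                                     length(ch), K))
            rl <- 1 / sum(1 / Rdc[ch])
        }
        ZL[i, ] <- zl
        Zin[i, ] <- Zc[i, ] * (zl + Zc[i, ] * tgl[i, ]) /
            (Zc[i, ] + zl * tgl[i, ])
        Rdc[i] <- Rseg[i] + rl
    }
    ## harmonic inflow and root pressure
    Qk <- .inflowHarmonics(inflow, kvec)
    Qmean <- inflow$sv / inflow$period
    root <- ctree$root
    ## root-to-leaf propagation
    Pin <- matrix(0i, n, K); Qin <- matrix(0i, n, K)
    PinDc <- numeric(n); QinDc <- numeric(n)
    Pf <- matrix(0i, n, K); Pb <- matrix(0i, n, K)
    Pin[root, ] <- Zin[root, ] * Qk
    Qin[root, ] <- Qk
    PinDc[root] <- Qmean * Rdc[root]
    QinDc[root] <- Qmean
    flowResid <- 0
    for (i in ctree$order) {
        Pf[i, ] <- (Pin[i, ] + Zc[i, ] * Qin[i, ]) / 2
        Pb[i, ] <- (Pin[i, ] - Zc[i, ] * Qin[i, ]) / 2
        eM <- exp(-gamma[i, ] * L[i]); eP <- 1 / eM
        Pout <- Pf[i, ] * eM + Pb[i, ] * eP
        Qout <- (Pf[i, ] * eM - Pb[i, ] * eP) / Zc[i, ]
        PoutDc <- PinDc[i] - QinDc[i] * Rseg[i]
        if (!ctree$terminal[i]) {
            ch <- ctree$children[[i]]
            qsum <- 0
            for (c_ in ch) {
                Pin[c_, ] <- Pout
                Qin[c_, ] <- Pout / Zin[c_, ]
                qsum <- qsum + Qin[c_, ]
                PinDc[c_] <- PoutDc
                QinDc[c_] <- PoutDc / Rdc[c_]
            }
            flowResid <- max(flowResid,
                             max(Mod(qsum - Qout) / pmax(Mod(Qout), 1e-30)))
        }
    }
    ## site waveforms
    tgrid <- (seq_len(settings$fs * settings$duration) - 1) / settings$fs
    Emat <- exp(outer(tgrid, 2i * pi * f0 * kvec))   # T x K
    siteIdx <- match(sites, ctree$siteName)
    if (anyNA(siteIdx)) stop("unknown site(s): ",
                             paste(sites[is.na(siteIdx)], collapse = ", "))
    out <- vector("list", length(sites)); names(out) <- sites
    for (s in seq_along(sites)) {
        i <- ctree$siteSeg[siteIdx[s]]
        x <- ctree$sitePos[siteIdx[s]] * L[i]
        Pk <- Pf[i, ] * exp(-gamma[i, ] * x) + Pb[i, ] * exp(gamma[i, ] * x)
        Pdc <- PinDc[i] - QinDc[i] * Rseg[i] * ctree$sitePos[siteIdx[s]]
        wave <- as.numeric(Pdc + 2 * Re(Emat %*% Pk))
        out[[s]] <- wave / .MMHG
    }
    list(sites = out, meanRootPa = PinDc[root] - 0,
         rootDcResistance = Rdc[root], flowResidual = flowResid)
}

#' Simulation settings
#'
#' @param fs sampling frequency, Hz
#' @param duration record duration, s (\code{fs * duration} must be an
#'   integer sample count; the defaults give 256 samples)
#' @param nHarmonics number of heart-rate harmonics to solve, or \code{NULL}
#'   to use all harmonics up to \code{fmax} (at least 10), capped below the
#'   Nyquist frequency
#' @param fmax harmonic frequency cap, Hz
#' @return settings list
#' @export
simSettings <- function(fs = 128, duration = 2, nHarmonics = NULL,
                        fmax = 40) {
    stopifnot(abs(fs * duration - round(fs * duration)) < 1e-9)
    if (!is.null(nHarmonics) && nHarmonics < 1)
        stop("nHarmonics must be positive")
    list(fs = fs, duration = duration, nHarmonics = nHarmonics, fmax = fmax)
}

#' Simulate site pressure waveforms
#'
#' Solves the periodic pressure field of the arterial network driven by an
#' aortic inflow: the inflow is decomposed into heart-rate harmonics, the
#' root input impedance is obtained by a leaf-to-root recursion (parallel
#' combination at bifurcations), the root pressure \code{P = Zin * Q} is
#' propagated root-to-leaf through forward/backward wave amplitudes, the
#' mean component is solved on the DC-resistance skeleton, and site
#' waveforms are reconstructed on the sampling grid.  The solution is
#' periodic (steady state by construction).
#'
#' @param model an [ArterialModel-class]
#' @param inflow an \code{"AorticInflow"} from [aorticInflow()]
#' @param settings a [simSettings()] list
#' @param sites character vector of site names to report
#' @param details if \code{TRUE}, also return the mean root pressure, the
#'   network DC resistance and the worst per-harmonic bifurcation flow
#'   residual
#' @return named list of waveforms (mmHg, \code{fs * duration} samples), or
#'   a list with elements \code{sites}, \code{meanRootPa},
#'   \code{rootDcResistance}, \code{flowResidual} when \code{details = TRUE}
#' @examples
#' tree <- defaultArterialTree()
#' p <- simulatePressures(tree, aorticInflow(75, 70e-6), simSettings(),
#'                        sites = "carotid")
#' range(p$carotid)
#' @export
simulatePressures <- function(model, inflow, settings = simSettings(),
                              sites = c("carotid", "femoral"),
                              details = FALSE) {
    ctree <- .compileTree(model)
    res <- .solveTree(ctree, inflow, settings, sites)
    if (any(!is.finite(unlist(res$sites))))
        stop("numerical failure: non-finite pressures")
    if (details) res else res$sites
}
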