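## shared fixtures: tiny arterial trees, synthetic beats, small network
## configurations

## one-segment tree with a stiff-load termination, for wave-propagation
## oracles
singleTubeTree <- function(len = 0.4, r = 0.01, h = 0.0012, E = 4e5,
                           rTotal = NULL, compliance = 1e-15,
                           proximalFraction = 0.5, viscosity = 4e-3) {
    rho <- 1050
    cloc <- sqrt(2 * E * h / (3 * rho * r))
    zc <- rho * cloc / (pi * r^2)
    if (is.null(rTotal)) rTotal <- zc       # resistive match
    seg <- data.frame(id = 1L, name = "tube", parent = NA_integer_,
                      length = len, radius = r, thickness = h, youngs = E,
                      terminal = TRUE, stringsAsFactors = FALSE)
    loads <- data.frame(id = 1L, r_total = rTotal,
                        compliance = compliance,
                        proximal_fraction = proximalFraction)
    sites <- data.frame(site = c("inlet", "outlet"), id = c(1L, 1L),
                        position = c(0, 1), stringsAsFactors = FALSE)
    new("ArterialModel", segments = seg, loads = loads, sites = sites,
        blood = c(density = rho, viscosity = viscosity))
}

## piecewise-linear beat rising through a breakpoint, then linear decay;
## breakFrac = height fraction of the breakpoint
twoLineBeat <- function(n = 60, breakFrac = 0.4, tBreak = 0.3,
                        fs = 128) {
    nUp <- round(0.5 * n)
    nB <- round(tBreak * nUp)
    up1 <- seq(0, breakFrac, length.out = nB + 1)
    up2 <- seq(breakFrac, 1, length.out = nUp - nB + 1)[-1]
    down <- seq(1, 0, length.out = n - nUp + 1)[-1]
    y <- c(up1, up2, down)
    list(samples = y, onset = 1L, peak = which.max(y), fs = fs)
}

## triangular beat peaking at a fraction of the beat duration
triangleBeat <- function(n = 101, peakFrac = 0.5, fs = 128) {
    np <- round(peakFrac * (n - 1)) + 1
    y <- c(seq(0, 1, length.out = np), seq(1, 0, length.out = n - np + 1)[-1])
    list(samples = y, onset = 1L, peak = which.max(y), fs = fs)
}

## small network configuration for fast tests
tinyNetConfig <- function(width = 64L)
    networkConfig(channels = c(4L, 6L, 6L, 6L, 8L), width = width,
                  poolFactor = 4L, reduction = 2L)

## reference power-series evaluation of J1(z)/J0(z) for |z| modest
besselRatioSeries <- function(z, terms = 40) {
    j0 <- 0 + 0i; j1 <- 0 + 0i
    for (m in 0:terms) {
        j0 <- j0 + (-1)^m * (z / 2)^(2 * m) / factorial(m)^2
        j1 <- j1 + (-1)^m * (z / 2)^(2 * m + 1) /
            (factorial(m) * factorial(m + 1))
    }
    j1 / j0
}

## ABCD (transmission-matrix) chain solution for a cascade of segments
## terminated by zLoad: returns input impedance
abcdInputImpedance <- function(segs, blood, omega, zLoad) {
    M <- diag(2) + 0i
    for (s in segs) {
        zc <- characteristicImpedance(s$r, s$h, s$E, omega,
                                      blood["density"], blood["viscosity"])
        g <- propagationConstant(s$r, s$h, s$E, omega,
                                 blood["density"], blood["viscosity"])
        gl <- g * s$len
        Mi <- matrix(c(cosh(gl), sinh(gl) / zc,
                       zc * sinh(gl), cosh(gl)), 2, 2)
        M <- M %*% Mi
    }
    (M[1, 1] * zLoad + M[1, 2]) / (M[2, 1] * zLoad + M[2, 2])
}
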