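test_that("longitudinal impedance recovers the Poiseuille and inviscid limits", {
    mu <- 4e-3; rho <- 1050
    r <- 0.002
    ## alpha = 0.05
    w <- (0.05 / r)^2 * mu / rho
    zp <- longitudinalImpedance(r, w, rho, mu)
    pois <- 8 * mu / (pi * r^4)
    expect_lt(Mod(zp - pois) / pois, 1e-3)
    ## large alpha: inertance-dominated, phase -> 90 degrees
    wBig <- (60 / r)^2 * mu / rho
    zb <- longitudinalImpedance(r, wBig, rho, mu)
    expect_lt(abs(Arg(zb) * 180 / pi - 90), 2)
    expect_error(longitudinalImpedance(r, -1), "omega")
})

test_that("Womersley ratio matches an independent series expansion", {
    for (alpha in c(0.5, 1, 3, 6)) {
        z <- alpha * complex(modulus = 1, argument = 3 * pi / 4)
        got <- PulseAAA:::.besselRatioJ1J0(z)
        ref <- besselRatioSeries(z)
        expect_lt(Mod(got - ref) / Mod(ref), 1e-6)
    }
})

test_that("wall compliance gives the thin-wall wave speed", {
    expect_equal(wallCompliancePerLength(0.01, 0.001, 8e5),
                 wallCompliancePerLength(0.01, 0.001, 4e5) / 2)
    r <- 5e-3; h <- 0.5e-3; E <- 0.4e6; rho <- 1050
    cp <- wallCompliancePerLength(r, h, E)
    cloc <- sqrt(pi * r^2 / (rho * cp))
    expect_equal(cloc, sqrt(2 * E * h / (3 * rho * r)), tolerance = 1e-12)
    expect_equal(cloc, 5.04, tolerance = 0.01)
    ## c scales as sqrt(E / r) at fixed h: doubling both E and r cancels
    c2 <- sqrt(pi * (2 * r)^2 / (rho * wallCompliancePerLength(2 * r, h, 2 * E)))
    expect_equal(c2 / cloc, 1, tolerance = 1e-12)
    c3 <- sqrt(pi * r^2 / (rho * wallCompliancePerLength(r, h, 4 * E)))
    expect_equal(c3 / cloc, 2, tolerance = 1e-12)
})

test_that("characteristic impedance and propagation constant reach the lossless limit", {
    mu <- 4e-3; rho <- 1050; r <- 0.01; h <- 0.0012; E <- 4e5
    wBig <- (100 / r)^2 * mu / rho
    zc <- characteristicImpedance(r, h, E, wBig, rho, mu)
    expect_lt(abs(Im(zc)) / Mod(zc), 0.02)
    cloc <- sqrt(2 * E * h / (3 * rho * r))
    expect_lt(Mod(zc - rho * cloc / (pi * r^2)) / Mod(zc), 0.02)
    ## phase delay of a 10 cm segment at c = 5 m/s, f = 1 Hz is 0.1257 rad
    E5 <- 3 * rho * r * 5^2 / (2 * h)
    g <- propagationConstant(r, h, E5, 2 * pi, rho, mu * 1e-6)
    expect_equal(Im(g) * 0.1, 2 * pi * 0.1 / 5, tolerance = 1e-3)
    expect_error(propagationConstant(r, h, E, 0), "omega")
})

test_that("Windkessel impedance has the textbook limits", {
    rT <- 2e9; C <- 1e-9; pf <- 0.2
    expect_equal(Mod(windkesselImpedance(rT, C, pf, 0)), rT)
    expect_equal(Mod(windkesselImpedance(rT, C, pf, 1e9)), pf * rT,
                 tolerance = 1e-4)
    R2 <- (1 - pf) * rT
    z <- windkesselImpedance(rT, C, pf, 1 / (R2 * C))
    expect_equal(z, pf * rT + R2 * (1 - 1i) / 2, tolerance = 1e-12)
})

test_that("line input impedance: matched load, quarter wave, ABCD oracle", {
    mu <- 4e-3; rho <- 1050
    blood <- c(density = rho, viscosity = mu)
    set.seed(7)
    for (i in 1:5) {
        r <- runif(1, 0.002, 0.012); h <- 0.12 * r; E <- runif(1, 3e5, 1e6)
        w <- runif(1, 2, 200)
        zc <- characteristicImpedance(r, h, E, w, rho, mu)
        g <- propagationConstant(r, h, E, w, rho, mu)
        expect_equal(inputImpedance(zc, g, 0.3, zc), zc, tolerance = 1e-12)
    }
    ## lossless quarter-wave line with an open end is a short at the inlet
    r <- 0.01; h <- 0.0012; E <- 4e5
    cloc <- sqrt(2 * E * h / (3 * rho * r))
    len <- 0.25
    w <- 2 * pi * cloc / (4 * len)           # quarter wavelength
    muTiny <- 1e-12
    zc <- characteristicImpedance(r, h, E, w, rho, muTiny)
    g <- propagationConstant(r, h, E, w, rho, muTiny)
    zin <- inputImpedance(zc, g, len, 1e30 + 0i)
    expect_lt(Mod(zin), 1e-6 * Mod(zc))
    ## cascade equals the ABCD transmission-matrix product
    segs <- list(list(r = 0.010, h = 0.0012, E = 4e5, len = 0.25),
                 list(r = 0.007, h = 0.0009, E = 6e5, len = 0.18),
                 list(r = 0.004, h = 0.0007, E = 8e5, len = 0.30))
    zLoad <- 5e9 + 0i
    for (w in c(5, 30, 120)) {
        zin <- zLoad
        for (s in rev(segs)) {
            zc <- characteristicImpedance(s$r, s$h, s$E, w, rho, mu)
            g <- propagationConstant(s$r, s$h, s$E, w, rho, mu)
            zin <- inputImpedance(zc, g, s$len, zin)
        }
        zRef <- abcdInputImpedance(segs, blood, w, zLoad)
        expect_lt(Mod(zin - zRef) / Mod(zRef), 1e-10)
    }
})

test_that("aortic inflow integrates to the stroke volume with a half-sine peak", {
    q <- aorticInflow(75, 70e-6)
    qp <- 70e-6 * pi / (2 * q$tsys)
    f <- function(t) qp * sin(pi * t / q$tsys)
    expect_equal(integrate(f, 0, q$tsys, rel.tol = 1e-12)$value, 70e-6,
                 tolerance = 1e-10)
    beat <- inflowBeat(q, 1024)
    tgrid <- (0:1023) / 1024 * q$period
    expect_true(all(beat[tgrid >= q$tsys] == 0))
    expect_equal(max(beat), qp, tolerance = 1e-3)
})

test_that("matched single tube behaves as a pure delay line", {
    tree <- singleTubeTree(len = 0.4, viscosity = 1e-5)
    seg <- arterialSegments(tree)
    rho <- 1050
    cloc <- sqrt(2 * seg$youngs * seg$thickness / (3 * rho * seg$radius))
    inflow <- aorticInflow(75, 70e-6)
    st <- simSettings(nHarmonics = 25)
    p <- simulatePressures(tree, inflow, st, c("inlet", "outlet"))
    delay <- seg$length / cloc
    shift <- delay * st$fs
    ## compare outlet with inlet delayed via Fourier shift
    X <- fft(p$inlet)
    n <- length(X)
    k <- c(0:(n / 2), -((n / 2 - 1):1))
    shifted <- Re(fft(X * exp(-2i * pi * k * shift / n), inverse = TRUE)) / n
    err <- sqrt(mean((p$outlet - shifted)^2)) / diff(range(p$inlet))
    expect_lt(err, 0.01)
})

test_that("DC pressure equals flow times network resistance and flow is conserved", {
    tree <- defaultArterialTree()
    inflow <- aorticInflow(75, 70e-6)
    res <- simulatePressures(tree, inflow, simSettings(),
                             sites = "ascending_aorta", details = TRUE)
    ## independent DC resistance: segment Poiseuille + load recursion
    seg <- arterialSegments(tree); loads <- terminalLoads(tree)
    mu <- 4e-3
    rseg <- 8 * mu * seg$length / (pi * seg$radius^4)
    rdc <- setNames(rep(NA_real_, nrow(seg)), seg$id)
    repeat {
        done <- TRUE
        for (i in seq_len(nrow(seg))) {
            if (!is.na(rdc[i])) next
            if (seg$terminal[i]) {
                rdc[i] <- rseg[i] + loads$r_total[match(seg$id[i], loads$id)]
            } else {
                ch <- which(seg$parent %in% seg$id[i])
                if (anyNA(rdc[ch])) { done <- FALSE; next }
                rdc[i] <- rseg[i] + 1 / sum(1 / rdc[ch])
            }
        }
        if (done) break
    }
    root <- which(is.na(seg$parent))
    qMean <- 70e-6 * 75 / 60
    expect_equal(res$meanRootPa, unname(qMean * rdc[root]),
                 tolerance = 0.005)
    expect_lt(res$flowResidual, 1e-8)
})

test_that("nominal simulation yields physiologic carotid pressures", {
    tree <- defaultArterialTree()
    p <- simulatePressures(tree, aorticInflow(75, 70e-6), simSettings(),
                           "carotid")$carotid
    expect_gt(max(p), 100)
    expect_lt(max(p), 180)
    expect_gt(min(p), 40)
})

test_that("cf-PWV increases monotonically with the stiffness coefficient", {
    st <- simSettings()
    inflow <- aorticInflow(75, 70e-6)
    pwv <- vapply(c(0.7, 1.0, 1.3, 1.6), function(sc) {
        tree <- defaultArterialTree(stiffnessScale = 1.7 * sc)
        p <- simulatePressures(tree, inflow, st, c("carotid", "femoral"))
        cfPwv(p$carotid, p$femoral,
              sitePathLength(tree, "femoral") - sitePathLength(tree, "carotid"),
              st$fs, 75)
    }, numeric(1))
    expect_true(all(diff(pwv) > 0))
})
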