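## smooth periodic test pulse with a given heart rate
testPulse <- function(hr, fs = 128, dur = 2, phases = 0) {
    t <- (0:(fs * dur - 1)) / fs
    f0 <- hr / 60
    100 + 20 * sin(2 * pi * f0 * t - pi / 2 + phases) +
        6 * sin(4 * pi * f0 * t + 0.4 + 2 * phases)
}

test_that("harmonic fit reconstructs a periodic signal exactly", {
    hr <- 75; fs <- 128
    x <- testPulse(hr)
    a <- harmonicFit(x, fs, hr / 60)
    t <- (0:255) / fs
    xr <- PulseAAA:::.harmonicEval(a, hr / 60, t)
    expect_lt(max(abs(x - xr)), 1e-9)
    expect_equal(Re(a[1]), 100, tolerance = 1e-9)
    expect_equal(2 * Mod(a[2]), 20, tolerance = 1e-9)
})

test_that("beat detection finds the right period and count", {
    x <- testPulse(75)
    b <- detectBeats(x, 128, 75)
    expect_gte(length(b), 1)
    period <- length(b[[1]]$samples) - 1
    expect_lt(abs(period - 128 * 60 / 75), 1.5)
    expect_length(detectBeats(rep(5, 256), 128, 75), 0)
    for (hr in c(60, 75, 90)) {
        nb <- length(detectBeats(testPulse(hr), 128, hr))
        expect_true(nb %in% c(1, 2, 3))
        expect_lte(nb, floor(2 * hr / 60))
    }
})

test_that("intersecting tangent recovers exact feet", {
    ## flat baseline then linear ramp starting at t0
    fs <- 128
    n0 <- 20
    y <- c(rep(0, n0), seq(0, 1, length.out = 40))
    beat <- list(samples = y, onset = 1L, peak = which.max(y), fs = fs)
    t0 <- n0 / fs                          # ramp start time
    expect_equal(tangentFoot(beat), t0, tolerance = 1e-9)
    ## time-shift equivariance
    y2 <- c(rep(0, n0 + 8), seq(0, 1, length.out = 40))
    beat2 <- list(samples = y2, onset = 1L, peak = which.max(y2), fs = fs)
    expect_equal(tangentFoot(beat2) - tangentFoot(beat), 8 / fs,
                 tolerance = 1e-9)
    ## sigmoid upstroke: analytic tangent intersection
    tt <- seq(0, 1, by = 1 / fs)
    y3 <- 1 / (1 + exp(-(tt - 0.5) * 20))
    beat3 <- list(samples = y3, onset = 1L, peak = length(y3), fs = fs)
    ## max slope at t = 0.5 (value 1/2, slope 5); min ~ 0
    ymin <- min(y3)
    expected <- 0.5 - (0.5 - ymin) / 5
    expect_equal(tangentFoot(beat3), expected, tolerance = 1e-3)
})

test_that("cf-PWV recovers a known transit time", {
    hr <- 75; fs <- 128
    x <- testPulse(hr)
    dt <- 0.05
    y <- testPulse(hr, phases = 0)          # same shape
    ## delay via exact phase shift of each harmonic
    t <- (0:255) / fs
    f0 <- hr / 60
    y <- 100 + 20 * sin(2 * pi * f0 * (t - dt) - pi / 2) +
        6 * sin(4 * pi * f0 * (t - dt) + 0.4)
    expect_equal(cfPwv(x, y, 0.5, fs, hr), 0.5 / dt, tolerance = 0.02)
})

test_that("severity lowers PWV and raises CUI in matched simulations", {
    ## probe a stiff subject: the aneurysm reflection returns during
    ## systole only when aortic wave speed is high enough
    tree <- defaultArterialTree(stiffnessScale = 1.7 * 1.8)
    inflow <- aorticInflow(75, 70e-6)
    st <- simSettings()
    path <- sitePathLength(tree, "femoral") - sitePathLength(tree, "carotid")
    run <- function(vsi) {
        tr <- if (vsi > 0)
            insertAneurysm(tree, aneurysmSpec(vsi = vsi, lAaa = 1, kE = 1.8))
        else tree
        p <- simulatePressures(tr, inflow, st, c("carotid", "femoral"))
        beat <- canonicalBeat(p$carotid, st$fs, 75)
        c(pwv = cfPwv(p$carotid, p$femoral, path, st$fs, 75),
          cui = cui(beat))
    }
    healthy <- run(0); severe <- run(60)
    expect_lt(severe[["pwv"]], healthy[["pwv"]])
    expect_gt(severe[["cui"]], healthy[["cui"]])
})

test_that("upstroke index exactly recovers two-line constructions", {
    b <- twoLineBeat(breakFrac = 0.4)
    expect_equal(cui(b), 0.6, tolerance = 1e-6)
    b5 <- twoLineBeat(breakFrac = 0.5)
    expect_equal(cui(b5), 0.5, tolerance = 1e-6)
    ## amplitude scaling and baseline shifts leave CUI unchanged
    bs <- b; bs$samples <- 40 + 25 * bs$samples
    expect_equal(cui(bs), cui(b), tolerance = 1e-9)
    short <- list(samples = c(0, 1, 2, 1), onset = 1L, peak = 3L, fs = 128)
    expect_true(is.na(cui(short)))
})

test_that("area ratio matches triangle-area arithmetic", {
    expect_equal(carRatio(triangleBeat(peakFrac = 0.5)), 1,
                 tolerance = 1e-9)
    expect_equal(carRatio(triangleBeat(peakFrac = 0.25)), 3,
                 tolerance = 1e-9)
    b <- triangleBeat(peakFrac = 0.25)
    bs <- b; bs$samples <- 10 + 7 * b$samples
    expect_equal(carRatio(bs), carRatio(b), tolerance = 1e-9)
})

test_that("oscillatory ratio implements the 3-8 f0 band energies", {
    fs <- 128; hr <- 60; f0 <- 1
    t <- (0:255) / fs
    expect_equal(corRatio(sin(2 * pi * f0 * t), hr, fs), 0,
                 tolerance = 1e-9)
    x <- sin(2 * pi * 2 * f0 * t) + sin(2 * pi * 5 * f0 * t)
    expect_equal(corRatio(x, hr, fs), 1, tolerance = 1e-9)
    expect_equal(corRatio(10 * x, hr, fs), 1, tolerance = 1e-9)
    ## boundary harmonic 3 f0 belongs to the high band
    x3 <- sin(2 * pi * 1 * t) + sin(2 * pi * 3 * t)
    expect_equal(corRatio(x3, hr, fs), 1, tolerance = 1e-9)
})

test_that("age sweep reproduces the aging directions", {
    sw <- ageSweepStatistics(ages = c(30, 55, 80), nPerAge = 12, seed = 2)
    expect_equal(nrow(sw), 3)
    expect_true(all(diff(sw$pwv_mean) > 0))
    expect_true(all(diff(sw$ppAmp_mean) < 0))
    expect_true(all(diff(sw$sbp_mean) > 0))
})

test_that("feature table and severity correlations have the right shape", {
    pc <- generateCohort(25, 1, seed = 17)
    fe <- extractFeatures(pc)
    expect_equal(nrow(fe), 25)
    expect_true(all(c("pwv", "cui", "car", "cor", "vsi") %in% names(fe)))
    expect_true(all(fe$cui > 0 & fe$cui < 1, na.rm = TRUE))
    expect_true(all(fe$car > 0, na.rm = TRUE))
    expect_true(all(fe$cor >= 0, na.rm = TRUE))
    tab <- featureSeverityCorrelations(fe)
    expect_equal(nrow(tab), 8)
    ## a feature column equal to the label itself correlates perfectly
    fe$pwv <- fe$vsi
    tab2 <- featureSeverityCorrelations(fe)
    expect_equal(tab2$rho[tab2$metric == "vsi" & tab2$feature == "pwv"], 1,
                 tolerance = 1e-12)
})
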