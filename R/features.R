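## AAA-sensitive pulse-waveform features: carotid-femoral PWV (intersecting
## tangent), carotid upstroke index (two-line fit), carotid area ratio, and
## carotid oscillatory ratio (spectral band energy).

#' Fourier upsampling of a periodic record
#'
#' Zero-pads the spectrum; exact for band-limited periodic signals.
#'
#' @param x numeric record
#' @param factor integer upsampling factor
#' @return numeric vector of length \code{length(x) * factor}
#' @export
fourierUpsample <- function(x, factor = 8L) {
    n <- length(x)
    if (factor == 1L) return(x)
    X <- fft(x)
    m <- n * factor
    Y <- complex(length.out = m)
    half <- n %/% 2
    Y[1:half] <- X[1:half]
    ## split the Nyquist bin between positive and negative frequencies
    Y[half + 1] <- X[half + 1] / 2
    Y[m - half + 1] <- Conj(X[half + 1]) / 2
    if (half > 1) Y[(m - half + 2):m] <- X[(half + 2):n]
    Re(fft(Y, inverse = TRUE)) / n
}

## brick-wall low-pass on a periodic record (bins above fcut zeroed)
.lowPass <- function(x, fs, fcut) {
    n <- length(x)
    X <- fft(x)
    f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * fs / n
    X[abs(f) > fcut] <- 0
    Re(fft(X, inverse = TRUE)) / n
}

#' Least-squares harmonic decomposition of a periodic record
#'
#' Fits \code{x(t) = a0 + sum_k 2 Re(a_k exp(2 pi i k f0 t))} for harmonics
#' \code{k = 1..kmax} of a known fundamental \code{f0} by linear least
#' squares.  Unlike binwise FFT energies, this is exact for band-limited
#' periodic signals even when the record holds a non-integer number of
#' beats, and it varies smoothly with heart rate.
#'
#' @param x record
#' @param fs sampling frequency, Hz
#' @param f0 fundamental frequency, Hz
#' @param kmax highest harmonic (defaults to all harmonics below 45% of
#'   the sampling frequency, capped at 40 Hz)
#' @return complex vector \code{a[0..kmax]} (element 1 is the real mean term)
#' @export
harmonicFit <- function(x, fs, f0, kmax = NULL) {
    n <- length(x)
    if (is.null(kmax)) kmax <- floor(min(40, 0.45 * fs) / f0)
    kmax <- min(kmax, floor((n - 1) / 2))
    t <- (seq_len(n) - 1) / fs
    ph <- outer(t, 2 * pi * f0 * seq_len(kmax))
    D <- cbind(1, cos(ph), sin(ph))
    cf <- qr.coef(qr(D), x)
    cf[is.na(cf)] <- 0
    a <- complex(real = c(cf[1], cf[2:(kmax + 1)] / 2),
                 imaginary = c(0, -cf[(kmax + 2):(2 * kmax + 1)] / 2))
    a
}

## evaluate a harmonicFit on an arbitrary time grid
.harmonicEval <- function(a, f0, t) {
    k <- seq_len(length(a) - 1)
    as.numeric(Re(exp(outer(t, 2i * pi * f0 * k)) %*% a[-1]) * 2 + Re(a[1]))
}

#' Canonical beat of a periodic record
#'
#' Folds the record to a single beat using its harmonic decomposition:
#' the beat is reconstructed on a dense phase grid, anchored at the
#' steepest systolic upstroke, rotated so that the onset (the local
#' minimum immediately preceding the upstroke) comes first, and the
#' systolic peak is taken as the earliest local maximum within 2% of the
#' beat's pulse range below the global maximum (stabilizing records whose
#' early and late systolic shoulders are nearly equal).
#'
#' @param x record
#' @param fs sampling frequency, Hz
#' @param hr heart rate, bpm
#' @param n phase samples of the folded beat
#' @return a beat list (\code{samples}, \code{onset} = 1, \code{peak},
#'   \code{fs} = \code{n * hr / 60}), or \code{NULL} for degenerate records
#' @export
canonicalBeat <- function(x, fs, hr, n = 512L) {
    f0 <- hr / 60
    a <- harmonicFit(x, fs, f0)
    t <- (seq_len(n) - 1) / (n * f0)
    y <- .harmonicEval(a, f0, t)
    rng <- diff(range(y))
    if (!is.finite(rng) || rng < 1e-9 * max(1, abs(mean(y))))
        return(NULL)
    d <- diff(c(y, y[1]))                 # circular slope
    anchor <- which.max(d)
    ## walk back circularly to the preceding local minimum
    eps <- 1e-6 * rng
    j <- anchor; steps <- 0L
    while (steps < n %/% 2) {
        jp <- if (j == 1L) n else j - 1L
        if (y[jp] >= y[j] - eps) break
        j <- jp; steps <- steps + 1L
    }
    yr <- if (j == 1L) y else c(y[j:n], y[seq_len(j - 1L)])
    ## earliest local maximum within 2% of the global maximum
    dm <- diff(yr)
    locmax <- which(dm[-length(dm)] > 0 & dm[-1] <= 0) + 1L
    if (!length(locmax)) locmax <- which.max(yr)
    big <- locmax[yr[locmax] >= max(yr) - 0.02 * rng]
    peak <- if (length(big)) big[1] else which.max(yr)
    list(samples = yr, onset = 1L, peak = peak, fs = n * f0)
}

## absolute foot time (s, within [0, T)) of a record: tangent foot on the
## (optionally band-limited) canonical beat, preserving absolute phase
.absFootTime <- function(x, fs, hr, bw = Inf, n = 2048L) {
    f0 <- hr / 60
    a <- harmonicFit(x, fs, f0)
    kmax <- min(length(a) - 1, floor(min(bw, 1e6) / f0))
    if (kmax < 2) kmax <- min(length(a) - 1, 2)
    a <- a[1:(kmax + 1)]
    t <- (seq_len(n) - 1) / (n * f0)
    y <- .harmonicEval(a, f0, t)
    d <- diff(c(y, y[1]))
    anchor <- which.max(d)
    eps <- 1e-6 * diff(range(y))
    j <- anchor; steps <- 0L
    while (steps < n %/% 2) {
        jp <- if (j == 1L) n else j - 1L
        if (y[jp] >= y[j] - eps) break
        j <- jp; steps <- steps + 1L
    }
    slope <- d[anchor] * n * f0
    if (slope <= 0) return(NA_real_)
    ymin <- y[j]
    tfoot <- t[anchor] - (y[anchor] - ymin) / slope
    tfoot %% (1 / f0)
}

#' Detect beats in a periodic pressure record
#'
#' Beats are anchored on the systolic upstroke: strong slope maxima
#' (at least half the record's steepest rise, separated by at least 60% of
#' the expected period) mark systole, and each beat onset is the waveform
#' minimum in the window preceding its upstroke.  This is robust to
#' reflection-induced diastolic undulations, which can dip below the
#' end-diastolic level in strongly oscillatory records.  Only complete
#' beats (onset to next onset) are returned.
#'
#' @param x pressure record
#' @param fs sampling frequency, Hz
#' @param hrHint heart rate, bpm (sets the expected period)
#' @return list of beats, each a list with \code{samples}, \code{onset}
#'   (index into \code{x}), \code{peak} (index within the beat, first
#'   local maximum after the anchoring upstroke) and \code{fs}; empty list
#'   if the record is degenerate (e.g. constant)
#' @export
detectBeats <- function(x, fs, hrHint) {
    n <- length(x)
    rng <- diff(range(x))
    if (!is.finite(rng) || rng < 1e-9 * max(1, abs(mean(x))))
        return(list())
    Tn <- fs * 60 / hrHint
    d <- diff(x)
    dmax <- max(d)
    if (dmax <= 0) return(list())
    ## slope maxima above half the steepest rise, spaced >= 0.6 T
    cand <- which(d >= 0.5 * dmax)
    if (!length(cand)) return(list())
    groups <- split(cand, cumsum(c(1, diff(cand) > 0.3 * Tn)))
    anchors <- vapply(groups, function(g) g[which.max(d[g])], numeric(1))
    anchors <- sort(anchors)
    keep <- c(TRUE, diff(anchors) >= 0.6 * Tn)
    anchors <- anchors[keep]
    ## onset: walk back from each upstroke to the local minimum immediately
    ## preceding it (stops at flat stretches and at diastolic ripples)
    eps <- 1e-6 * rng
    ons <- vapply(anchors, function(a) {
        j <- a
        lo <- max(1, floor(a - 0.35 * Tn))
        while (j > lo && x[j - 1] < x[j] - eps) j <- j - 1L
        j
    }, numeric(1))
    ons <- unique(ons)
    if (length(ons) < 2) return(list())
    beats <- list()
    for (b in seq_len(length(ons) - 1)) {
        span <- ons[b + 1] - ons[b]
        if (span < 0.55 * Tn || span > 1.45 * Tn) next
        smp <- x[ons[b]:ons[b + 1]]
        beats[[length(beats) + 1]] <- list(
            samples = smp, onset = ons[b], peak = which.max(smp), fs = fs)
    }
    beats
}

#' Intersecting-tangent foot of a beat
#'
#' The waveform foot is the intersection of the horizontal line through the
#' diastolic minimum with the tangent at the steepest point of the systolic
#' upstroke.
#'
#' @param beat a beat from [detectBeats()]
#' @return foot time in seconds relative to the beat onset, or \code{NA} if
#'   the upstroke has no positive slope maximum
#' @export
tangentFoot <- function(beat) {
    y <- beat$samples
    pk <- beat$peak
    if (pk < 3) return(NA_real_)
    up <- y[1:pk]
    d <- (up[3:pk] - up[1:(pk - 2)]) / 2      # central differences
    if (!length(d) || max(d) <= 0) return(NA_real_)
    i <- which.max(d) + 1L                     # index into up
    slope <- d[i - 1L] * beat$fs
    ymin <- min(up)
    tms <- (i - 1) / beat$fs
    tms - (up[i] - ymin) / slope
}

#' Carotid-femoral pulse wave velocity
#'
#' Intersecting-tangent transit time between the carotid and femoral
#' waveform feet divided into the aortic path length.  Feet are located on
#' band-limited canonical beats (harmonic folding preserves absolute
#' phase, so the transit time is the circular difference of the two foot
#' times).
#'
#' @param carotid,femoral pressure records from the same realization
#' @param pathLength path-length difference root-to-femoral minus
#'   root-to-carotid, m
#' @param fs sampling frequency, Hz
#' @param hr heart rate, bpm
#' @param footBandwidth optional low-pass cutoff (Hz) applied before foot
#'   timing (some tonometry devices band-limit before the tangent fit);
#'   \code{Inf} (default) uses the full available band, matching a tangent
#'   applied to the raw waveform
#' @return PWV in m/s, or \code{NA} on failure (degenerate records or
#'   out-of-range transit time)
#' @export
cfPwv <- function(carotid, femoral, pathLength, fs, hr,
                  footBandwidth = Inf) {
    tc <- .absFootTime(carotid, fs, hr, bw = footBandwidth)
    tf <- .absFootTime(femoral, fs, hr, bw = footBandwidth)
    if (is.na(tc) || is.na(tf)) return(NA_real_)
    Tb <- 60 / hr
    dt <- (tf - tc) %% Tb
    if (dt <= 0 || dt > 0.8 * Tb) return(NA_real_)
    pathLength / dt
}

#' Carotid upstroke index
#'
#' The foot-to-peak upstroke is split at the index minimizing the total
#' root-mean-squared error of least-squares lines fitted to the two
#' sub-regions (ties broken toward the earlier index); the two lines'
#' intersection defines the intersection amplitude, and
#' \code{CUI = (P_peak - P_intersection) / (P_peak - P_foot)}.
#'
#' @param beat a beat from [detectBeats()]
#' @return CUI in (0, 1), or \code{NA} for degenerate upstrokes
#'   (fewer than 6 samples)
#' @export
cui <- function(beat) {
    y <- beat$samples
    pk <- beat$peak
    if (pk < 6) return(NA_real_)
    up <- y[1:pk]
    t <- (seq_len(pk) - 1) / beat$fs
    fit <- function(i1, i2) {         # SSE + coefficients of a line fit
        ti <- t[i1:i2]; yi <- up[i1:i2]
        mt <- mean(ti); my <- mean(yi)
        sxx <- sum((ti - mt)^2)
        b <- if (sxx > 0) sum((ti - mt) * (yi - my)) / sxx else 0
        a <- my - b * mt
        list(a = a, b = b, sse = sum((yi - a - b * ti)^2))
    }
    best <- NULL; bestErr <- Inf
    for (s in 2:(pk - 1)) {
        f1 <- fit(1, s); f2 <- fit(s, pk)
        err <- sqrt((f1$sse + f2$sse) / (s + (pk - s + 1)))
        if (err < bestErr - 1e-15) {
            bestErr <- err; best <- list(f1 = f1, f2 = f2)
        }
    }
    b1 <- best$f1$b; b2 <- best$f2$b
    pInt <- if (abs(b1 - b2) < 1e-12 * max(abs(b1), abs(b2), 1))
        up[pk]                         # collinear upstroke: no inflection
    else {
        ts <- (best$f2$a - best$f1$a) / (b1 - b2)
        best$f1$a + b1 * ts
    }
    pp <- up[pk] - up[1]
    if (pp <= 0) return(NA_real_)
    ## the intersection amplitude is a point on the upstroke; bound it into
    ## the pulse range to guard against near-parallel fitted lines
    pInt <- min(max(pInt, up[1]), up[pk])
    (up[pk] - pInt) / pp
}

#' Carotid area ratio
#'
#' Areas above the diastolic minimum, split at the systolic peak:
#' \code{CAR = diastolic area / systolic area} (trapezoidal integration
#' from beat onset to peak, and peak to beat end).
#'
#' @param beat a beat from [detectBeats()]
#' @return CAR > 0, or \code{NA} if the systolic area vanishes
#' @export
carRatio <- function(beat) {
    y <- beat$samples - min(beat$samples)
    pk <- beat$peak
    n <- length(y)
    if (pk < 2 || pk > n - 1) return(NA_real_)
    trapz <- function(v) sum((v[-1] + v[-length(v)]) / 2)
    sys <- trapz(y[1:pk])
    dia <- trapz(y[pk:n])
    if (sys <= 0) return(NA_real_)
    dia / sys
}

#' Carotid oscillatory ratio
#'
#' The record is mean-subtracted and decomposed into harmonics of the
#' heart-rate fundamental \code{f0 = hr/60} ([harmonicFit()], which is the
#' record's spectrum resolved at the harmonic frequencies); COR is the
#' spectral energy in the high band (3 to 8 times f0; the 3 f0 boundary
#' belongs to the high band) divided by the energy in the low band (0 to
#' 3 f0, exclusive; DC excluded by mean subtraction).
#'
#' @param x carotid pressure record (full 2-s record, not per beat)
#' @param hr heart rate, bpm
#' @param fs sampling frequency, Hz
#' @return COR >= 0, or \code{NA} if the low band has no energy
#' @export
corRatio <- function(x, hr, fs) {
    f0 <- hr / 60
    a <- harmonicFit(x - mean(x), fs, f0)
    E <- Mod(a[-1])^2                  # DC excluded by mean subtraction
    k <- seq_along(E)
    hi <- k >= 3 & k <= 8              # 3 f0 boundary belongs to the high band
    lo <- k < 3
    if (sum(E[lo]) <= 0) return(NA_real_)
    sum(E[hi]) / sum(E[lo])
}

#' Extract the four AAA features for every record of a cohort
#'
#' @param cohort a [PulseCohort-class] with \code{bp_carotid} and
#'   \code{bp_femoral} assays
#' @return \code{data.frame} with one row per record: \code{pwv},
#'   \code{cui}, \code{car}, \code{cor}, plus the cohort annotation columns
#' @export
extractFeatures <- function(cohort) {
    fs <- samplingRate(cohort)
    car_ <- SummarizedExperiment::assay(cohort, "bp_carotid")
    fem <- SummarizedExperiment::assay(cohort, "bp_femoral")
    cd <- as.data.frame(SummarizedExperiment::colData(cohort))
    md <- S4Vectors::metadata(cohort)
    path <- if (!is.null(cd$path_cf)) cd$path_cf
            else rep(md$pathFemoral - md$pathCarotid, ncol(car_))
    n <- ncol(car_)
    out <- data.frame(pwv = numeric(n), cui = numeric(n),
                      car = numeric(n), cor = numeric(n))
    for (i in seq_len(n)) {
        hr <- cd$hr[i]
        xc <- car_[, i]
        out$pwv[i] <- cfPwv(xc, fem[, i], path[i], fs, hr)
        beat <- canonicalBeat(xc, fs, hr)
        out$cui[i] <- if (is.null(beat)) NA_real_ else cui(beat)
        out$car[i] <- if (is.null(beat)) NA_real_ else carRatio(beat)
        out$cor[i] <- corRatio(xc, hr, fs)
    }
    cbind(out, cd)
}

#' Age-sweep plausibility statistics
#'
#' Simulates healthy subjects over an age grid with a shared set of IIV
#' combinations (five equally spaced levels per coefficient, subsampled from
#' the full factorial grid; the same combinations are reused at every age so
#' the age trends are paired) and reports descriptive statistics of aortic
#' systolic pressure, aortic pulse pressure, aortic-brachial pulse pressure
#' amplification and carotid-femoral PWV per age.
#'
#' @param config a [cohortConfig()] list
#' @param ages age grid, years
#' @param nPerAge IIV combinations per age (the full factorial grid has
#'   5^8 = 390625 rows; \code{nPerAge} rows are drawn from it)
#' @param seed integer seed for the grid subsample
#' @return \code{data.frame}: one row per age with mean and SD of
#'   \code{sbp}, \code{pp} (mmHg), \code{ppAmp} (brachial/aortic pulse
#'   pressure) and \code{pwv} (m/s)
#' @export
ageSweepStatistics <- function(config = cohortConfig(),
                               ages = seq(30, 80, by = 5),
                               nPerAge = 100, seed = 1) {
    set.seed(seed)
    levelsOf <- function(rg) seq(rg[1], rg[2], length.out = 5)
    iivNames <- names(config$iiv)
    combos <- vapply(iivNames, function(nm)
        sample(levelsOf(config$iiv[[nm]]), nPerAge, replace = TRUE),
        numeric(nPerAge))
    base <- defaultArterialTree(stiffnessScale = config$stiffnessScale)
    st <- config$settings
    rows <- lapply(ages, function(age) {
        sbp <- pp <- ppa <- pwv <- numeric(nPerAge)
        for (i in seq_len(nPerAge)) {
            iiv <- combos[i, ]
            subj <- list(age = age, iiv = iiv,
                         hr = config$hrNominal * iiv[["hr"]],
                         sv = config$svNominal *
                             ageAdjustedNominals(age, config)[["sv"]] *
                             iiv[["sv"]],
                         height = config$heightNominal * iiv[["length"]],
                         aneurysm = aneurysmSpec(vsi = 0, lAaa = 0.7,
                                                 kE = 1),
                         viscoelastic = as.list(
                             config$viscoelastic$medians))
            model <- buildSubjectModel(subj, config, base)
            inflow <- aorticInflow(subj$hr, subj$sv, config$tsysScale)
            sol <- simulatePressures(model, inflow, st,
                sites = c("ascending_aorta", "brachial", "carotid",
                          "femoral"))
            sbp[i] <- max(sol$ascending_aorta)
            pp[i] <- diff(range(sol$ascending_aorta))
            ppa[i] <- diff(range(sol$brachial)) / pp[i]
            pwv[i] <- cfPwv(sol$carotid, sol$femoral,
                            sitePathLength(model, "femoral") -
                                sitePathLength(model, "carotid"),
                            st$fs, subj$hr)
        }
        data.frame(age = age,
                   sbp_mean = mean(sbp), sbp_sd = sd(sbp),
                   pp_mean = mean(pp), pp_sd = sd(pp),
                   ppAmp_mean = mean(ppa), ppAmp_sd = sd(ppa),
                   pwv_mean = mean(pwv, na.rm = TRUE),
                   pwv_sd = sd(pwv, na.rm = TRUE))
    })
    do.call(rbind, rows)
}

#' Feature-severity correlation table
#'
#' Pearson correlations (with two-sided p-values) of each waveform feature
#' against the two severity metrics: the volumetric severity index and the
#' maximum-diameter increase.
#'
#' @param features a [extractFeatures()] table containing \code{vsi} and
#'   \code{max_diameter_increase} columns
#' @return \code{data.frame} with columns \code{metric}, \code{feature},
#'   \code{rho}, \code{p}
#' @export
featureSeverityCorrelations <- function(features) {
    feats <- c("pwv", "cui", "car", "cor")
    metrics <- c(vsi = "vsi", max_diameter = "max_diameter_increase")
    rows <- list()
    for (m in names(metrics)) for (f in feats) {
        ok <- is.finite(features[[f]]) & is.finite(features[[metrics[m]]])
        if (sd(features[[f]][ok]) == 0) {
            rows[[length(rows) + 1]] <- data.frame(
                metric = m, feature = f, rho = NA_real_, p = NA_real_)
            next
        }
        ct <- cor.test(features[[f]][ok], features[[metrics[m]]][ok])
        rows[[length(rows) + 1]] <- data.frame(
            metric = m, feature = f, rho = unname(ct$estimate),
            p = ct$p.value)
    }
    do.call(rbind, rows)
}
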