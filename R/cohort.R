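#' Cohort generation configuration
#'
#' Bundles the study conditions of the synthetic population: the age range,
#' the eight inter-individual-variability (IIV) coefficient ranges (uniform
#' 0.8-1.2 for heart rate, stroke volume, lengths, radii, thicknesses,
#' terminal resistances and compliances; 0.7-1.6 for arterial stiffness),
#' the aneurysm parameter ranges (VSI 0-100%, length fraction 0.4-1,
#' wall-stiffness scaling 1.25-2.45), the sample-to-sample variability
#' (multiplicative normal, CV 0.01; viscoelastic parameters lognormal,
#' CV 0.01), the age-trend slopes of the nominal parameters, and the
#' subject-level viscoelastic parameter distributions.
#'
#' @param ageRange cohort age range, years
#' @param refAge reference age at which all age multipliers equal 1
#' @param hrNominal,svNominal nominal heart rate (bpm) and stroke volume (m^3)
#' @param heightNominal nominal body height, cm (scaled by the length IIV
#'   coefficient to yield subject height)
#' @param iiv named list of IIV coefficient ranges
#' @param aaa list of aneurysm parameter ranges and discretization
#' @param ssvCv sample-to-sample variability coefficient of variation
#' @param ageSlopes named per-year multiplier slopes (applied as
#'   \code{1 + slope * (age - refAge)}): lower stroke volume, longer
#'   proximal aorta, larger diameters, reduced compliance, increased
#'   peripheral resistance and arterial stiffness with age
#' @param viscoelastic list with \code{medians} (subject-level lognormal
#'   medians of eB1, eB2, etaB, eT, etaT), \code{sdlog} (subject-level
#'   dispersion) and \code{ssvCv}
#' @param stiffnessScale global Young's modulus calibration passed to
#'   [defaultArterialTree()]
#' @param tsysScale systolic-duration scale for [aorticInflow()]
#' @param settings a [simSettings()] list
#' @return configuration list
#' @export
cohortConfig <- function(ageRange = c(40, 80), refAge = 50,
                         hrNominal = 75, svNominal = 70e-6,
                         heightNominal = 170,
                         iiv = list(hr = c(0.8, 1.2), sv = c(0.8, 1.2),
                                    length = c(0.8, 1.2),
                                    radius = c(0.8, 1.2),
                                    thickness = c(0.8, 1.2),
                                    resistance = c(0.8, 1.2),
                                    compliance = c(0.8, 1.2),
                                    stiffness = c(0.7, 1.6)),
                         aaa = list(vsiRange = c(0, 100),
                                    lAaaRange = c(0.4, 1),
                                    kERange = c(1.25, 2.45),
                                    nSubsegments = 16L),
                         ssvCv = 0.01,
                         ageSlopes = c(sv = -0.004, proximal_length = 0.002,
                                       radius = 0.002, compliance = -0.006,
                                       resistance = 0.004,
                                       stiffness = 0.042),
                         viscoelastic = list(
                             medians = c(eB1 = 1, eB2 = 4, etaB = 0.2,
                                         eT = 1, etaT = 0.1),
                             sdlog = 0.2, ssvCv = 0.01),
                         stiffnessScale = 1.7, tsysScale = 0.34,
                         settings = simSettings()) {
    list(ageRange = ageRange, refAge = refAge, hrNominal = hrNominal,
         svNominal = svNominal, heightNominal = heightNominal, iiv = iiv,
         aaa = aaa, ssvCv = ssvCv, ageSlopes = ageSlopes,
         viscoelastic = viscoelastic, stiffnessScale = stiffnessScale,
         tsysScale = tsysScale, settings = settings)
}

#' Age-adjusted nominal parameter multipliers
#'
#' Linear-in-age multipliers on the nominal circulation parameters, equal to
#' 1 at the reference age, with the physiological directions: with older
#' age, stroke volume decreases, the proximal aorta lengthens, arterial
#' diameters enlarge, vascular compliance falls, and peripheral resistance
#' and arterial stiffness rise.
#'
#' @param age age in years, within [30, 80]
#' @param config a [cohortConfig()] list
#' @return named multipliers: \code{sv}, \code{proximal_length},
#'   \code{radius}, \code{compliance}, \code{resistance}, \code{stiffness}
#' @export
ageAdjustedNominals <- function(age, config = cohortConfig()) {
    if (age < 30 || age > 80) stop("age must lie in [30, 80]")
    m <- 1 + config$ageSlopes * (age - config$refAge)
    if (any(m <= 0)) stop("age slopes produce non-positive multipliers")
    m
}

#' Sample a synthetic subject
#'
#' Draws one subject: age uniform over the cohort range, the eight IIV
#' coefficients from their uniform ranges, an aneurysm severity VSI uniform
#' on [0, 100]% with length fraction conditional on feasibility
#' (\code{lAaa >= vsi/100} keeps the area parameter within its ceiling),
#' wall-stiffness scaling uniform on its range (independent of geometry),
#' and subject-level viscoelastic parameters from lognormal distributions.
#' Uses the R random number generator; seed via \code{set.seed()}.
#'
#' @param config a [cohortConfig()] list
#' @return list describing the subject: \code{age}, \code{iiv} (8 named
#'   coefficients), \code{hr}, \code{sv}, \code{height},
#'   \code{aneurysm} ([AneurysmSpec-class]), \code{viscoelastic}
#' @export
sampleSubject <- function(config = cohortConfig()) {
    age <- runif(1, config$ageRange[1], config$ageRange[2])
    iiv <- vapply(config$iiv, function(rg) runif(1, rg[1], rg[2]), numeric(1))
    am <- ageAdjustedNominals(age, config)
    hr <- config$hrNominal * iiv[["hr"]]
    sv <- config$svNominal * am[["sv"]] * iiv[["sv"]]
    vsi <- runif(1, config$aaa$vsiRange[1], config$aaa$vsiRange[2])
    lmin <- max(config$aaa$lAaaRange[1], vsi / 100)
    lAaa <- runif(1, lmin, config$aaa$lAaaRange[2])
    kE <- runif(1, config$aaa$kERange[1], config$aaa$kERange[2])
    ve <- config$viscoelastic
    vpar <- vapply(names(ve$medians), function(nm)
        rlnorm(1, meanlog = log(ve$medians[[nm]]), sdlog = ve$sdlog),
        numeric(1))
    list(age = age, iiv = iiv, hr = hr, sv = sv,
         height = config$heightNominal * iiv[["length"]],
         aneurysm = aneurysmSpec(vsi = vsi, lAaa = lAaa, kE = kE,
                                 nSubsegments = config$aaa$nSubsegments),
         viscoelastic = as.list(vpar))
}

#' Build the arterial model of a subject
#'
#' Applies the age multipliers and IIV coefficients to the nominal tree and
#' inserts the subject's aneurysm: radii scale by the age and radius-IIV
#' multipliers, the proximal aorta (ascending aorta and arch) additionally
#' lengthens with age, all lengths/thicknesses scale by their IIV
#' coefficients, Young's moduli by the age and stiffness-IIV multipliers,
#' and the terminal resistances/compliances by theirs.
#'
#' @param subject a [sampleSubject()] result
#' @param config a [cohortConfig()] list
#' @param baseTree nominal [ArterialModel-class] (defaults to
#'   [defaultArterialTree()] under the configured stiffness calibration)
#' @return an [ArterialModel-class] with the aneurysm inserted
#' @export
buildSubjectModel <- function(subject, config = cohortConfig(),
                              baseTree = defaultArterialTree(
                                  stiffnessScale = config$stiffnessScale)) {
    am <- ageAdjustedNominals(subject$age, config)
    iiv <- subject$iiv
    seg <- baseTree@segments
    proximal <- seg$name %in% c("ascending_aorta", "aortic_arch_a",
                                "aortic_arch_b")
    seg$length <- seg$length * iiv[["length"]] *
        ifelse(proximal, am[["proximal_length"]], 1)
    seg$radius <- seg$radius * iiv[["radius"]] * am[["radius"]]
    seg$thickness <- seg$thickness * iiv[["thickness"]]
    seg$youngs <- seg$youngs * iiv[["stiffness"]] * am[["stiffness"]]
    loads <- baseTree@loads
    loads$r_total <- loads$r_total * iiv[["resistance"]] * am[["resistance"]]
    loads$compliance <- loads$compliance * iiv[["compliance"]] *
        am[["compliance"]]
    model <- new("ArterialModel", segments = seg, loads = loads,
                 sites = baseTree@sites, blood = baseTree@blood)
    insertAneurysm(model, subject$aneurysm)
}

#' Sample-to-sample perturbation of a subject
#'
#' Draws the per-recording realization: every circulation parameter (heart
#' rate, stroke volume, each segment's length, radius, thickness and
#' Young's modulus, each terminal resistance and compliance) is multiplied
#' by an independent normal coefficient with mean 1 and the configured
#' standard deviation, and the viscoelastic parameters are re-drawn from
#' lognormal distributions whose medians are the subject values with the
#' configured coefficient of variation.
#'
#' @param subject a [sampleSubject()] result
#' @param nSegments number of segments in the subject's compiled model
#' @param nLoads number of terminal loads
#' @param config a [cohortConfig()] list
#' @return list of multipliers and realized scalar parameters
#' @export
perturbSample <- function(subject, nSegments, nLoads,
                          config = cohortConfig()) {
    cv <- config$ssvCv
    draw <- function(n) {
        x <- rnorm(n, 1, cv)
        while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), 1, cv)
        x
    }
    sdl <- sqrt(log(1 + config$viscoelastic$ssvCv^2))
    ve <- lapply(subject$viscoelastic, function(v)
        rlnorm(1, meanlog = log(v), sdlog = sdl))
    list(hr = subject$hr * draw(1), sv = subject$sv * draw(1),
         length = draw(nSegments), radius = draw(nSegments),
         thickness = draw(nSegments), youngs = draw(nSegments),
         rT = draw(nLoads), cT = draw(nLoads),
         viscoelastic = ve)
}

## apply an SSV realization to a compiled tree (numeric vectors only)
.perturbCompiled <- function(ctree, pert) {
    ctree$L <- ctree$L * pert$length
    ctree$r <- ctree$r * pert$radius
    ctree$h <- ctree$h * pert$thickness
    ctree$E <- ctree$E * pert$youngs
    term <- which(ctree$terminal)
    ctree$rT[term] <- ctree$rT[term] * pert$rT
    ctree$cT[term] <- ctree$cT[term] * pert$cT
    ctree
}

#' Generate a labeled or unlabeled waveform cohort
#'
#' Runs the full synthesis pipeline: sample subjects, build their
#' age-/IIV-adjusted aneurysmal arterial models, draw sample-to-sample
#' perturbations, solve the pressure field, and derive PVR waveforms at the
#' brachial and tibial sites through the viscoelastic cuff models.
#'
#' @param nSubjects number of subjects
#' @param nSamplesPerSubject recordings per subject
#' @param labeled if \code{FALSE} the severity labels (\code{vsi},
#'   \code{max_diameter_increase}) are omitted from the column annotation;
#'   height and age are always kept
#' @param config a [cohortConfig()] list
#' @param sites pressure sites to record
#' @param pvr if \code{TRUE} (and brachial/tibial sites are recorded), also
#'   compute PVR assays
#' @param seed optional integer seed (applied via \code{set.seed})
#' @param verbose print progress every 50 subjects
#' @return a [PulseCohort-class]
#' @examples
#' pc <- generateCohort(3, 2, seed = 1)
#' pc
#' @export
generateCohort <- function(nSubjects, nSamplesPerSubject = 1,
                           labeled = TRUE, config = cohortConfig(),
                           sites = c("carotid", "femoral", "brachial",
                                     "tibial"),
                           pvr = TRUE, seed = NULL, verbose = FALSE) {
    stopifnot(nSubjects >= 1, nSamplesPerSubject >= 1)
    if (!is.null(seed)) set.seed(seed)
    base <- defaultArterialTree(stiffnessScale = config$stiffnessScale)
    st <- config$settings
    nT <- st$fs * st$duration
    N <- nSubjects * nSamplesPerSubject
    assays <- lapply(sites, function(s) matrix(NA_real_, nT, N))
    names(assays) <- paste0("bp_", sites)
    doPvr <- pvr && all(c("brachial", "tibial") %in% sites)
    if (doPvr) {
        assays$pvr_brachial <- matrix(NA_real_, nT, N)
        assays$pvr_tibial <- matrix(NA_real_, nT, N)
    }
    cd <- data.frame(subject_id = integer(N), sample_id = integer(N),
                     age = numeric(N), height = numeric(N), hr = numeric(N),
                     sv = numeric(N), vsi = numeric(N),
                     max_diameter_increase = numeric(N),
                     l_aaa = numeric(N), k_e = numeric(N),
                     stiffness_iiv = numeric(N), path_cf = numeric(N))
    pathCar <- sitePathLength(base, "carotid")
    pathFem <- sitePathLength(base, "femoral")
    rec <- 0L
    for (s in seq_len(nSubjects)) {
        subj <- sampleSubject(config)
        model <- buildSubjectModel(subj, config, base)
        pcf <- sitePathLength(model, "femoral") -
            sitePathLength(model, "carotid")
        ctree0 <- .compileTree(model)
        nLoads <- sum(ctree0$terminal)
        for (k in seq_len(nSamplesPerSubject)) {
            rec <- rec + 1L
            pert <- perturbSample(subj, ctree0$n, nLoads, config)
            ctree <- .perturbCompiled(ctree0, pert)
            inflow <- aorticInflow(pert$hr, pert$sv, config$tsysScale)
            sol <- .solveTree(ctree, inflow, st, sites)
            for (nm in sites)
                assays[[paste0("bp_", nm)]][, rec] <- sol$sites[[nm]]
            if (doPvr) {
                vp <- do.call(viscoelasticParams, pert$viscoelastic)
                assays$pvr_brachial[, rec] <-
                    brachialPvr(sol$sites$brachial, vp, st$fs)
                assays$pvr_tibial[, rec] <-
                    tibialPvr(sol$sites$tibial, vp, st$fs)
            }
            cd$subject_id[rec] <- s
            cd$sample_id[rec] <- k
            cd$age[rec] <- subj$age
            cd$height[rec] <- subj$height
            cd$hr[rec] <- pert$hr
            cd$sv[rec] <- pert$sv
            cd$vsi[rec] <- subj$aneurysm@vsi
            cd$max_diameter_increase[rec] <-
                maxDiameterIncrease(subj$aneurysm@aSl)
            cd$l_aaa[rec] <- subj$aneurysm@lAaa
            cd$k_e[rec] <- subj$aneurysm@kE
            cd$stiffness_iiv[rec] <- subj$iiv[["stiffness"]]
            cd$path_cf[rec] <- pcf
        }
        if (verbose && s %% 50 == 0)
            message("  subject ", s, "/", nSubjects)
    }
    if (!labeled)
        cd <- cd[, setdiff(names(cd),
                           c("vsi", "max_diameter_increase", "l_aaa",
                             "k_e", "stiffness_iiv"))]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, colData = S4Vectors::DataFrame(cd))
    S4Vectors::metadata(se) <- list(
        fs = st$fs, duration = st$duration, labeled = labeled, seed = seed,
        pathCarotid = pathCar, pathFemoral = pathFem,
        config = config)
    new("PulseCohort", se)
}

#' Export a cohort to CSV files
#'
#' Writes one wide CSV per assay (records in rows, samples in columns) plus
#' an \code{annotation.csv} with the column data and a \code{manifest.yaml}
#' with sampling metadata.
#'
#' @param cohort a [PulseCohort-class]
#' @param dir output directory (created if missing)
#' @return \code{dir}, invisibly
#' @export
writeCohortCsv <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in SummarizedExperiment::assayNames(cohort)) {
        m <- t(SummarizedExperiment::assay(cohort, nm))
        write.csv(m, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    }
    write.csv(as.data.frame(SummarizedExperiment::colData(cohort)),
              file.path(dir, "annotation.csv"), row.names = FALSE)
    md <- S4Vectors::metadata(cohort)
    yaml::write_yaml(list(fs = md$fs, duration = md$duration,
                          labeled = md$labeled, seed = md$seed,
                          n_records = ncol(cohort),
                          assays = SummarizedExperiment::assayNames(cohort)),
                     file.path(dir, "manifest.yaml"))
    invisible(dir)
}
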