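test_that("age multipliers have the physiological directions", {
    cfg <- cohortConfig()
    ref <- ageAdjustedNominals(cfg$refAge, cfg)
    expect_true(all(abs(ref - 1) < 1e-12))
    m40 <- ageAdjustedNominals(40, cfg)
    m80 <- ageAdjustedNominals(80, cfg)
    expect_lt(m80[["sv"]], m40[["sv"]])
    expect_gt(m80[["proximal_length"]], m40[["proximal_length"]])
    expect_gt(m80[["radius"]], m40[["radius"]])
    expect_lt(m80[["compliance"]], m40[["compliance"]])
    expect_gt(m80[["resistance"]], m40[["resistance"]])
    expect_gt(m80[["stiffness"]], m40[["stiffness"]])
    expect_error(ageAdjustedNominals(25, cfg), "age")
})

test_that("subject sampling respects the configured ranges and identities", {
    cfg <- cohortConfig()
    set.seed(11)
    subs <- replicate(2000, sampleSubject(cfg), simplify = FALSE)
    hr <- vapply(subs, `[[`, 1, "hr")
    expect_true(all(hr >= 60 & hr <= 90))
    stiff <- vapply(subs, function(s) s$iiv[["stiffness"]], 1)
    expect_true(all(stiff >= 0.7 & stiff <= 1.6))
    vsi <- vapply(subs, function(s) s$aneurysm@vsi, 1)
    lA <- vapply(subs, function(s) s$aneurysm@lAaa, 1)
    aS <- vapply(subs, function(s) s$aneurysm@aSl, 1)
    kE <- vapply(subs, function(s) s$aneurysm@kE, 1)
    expect_true(all(abs(vsi - 100 * lA * aS / 2 / 2.625) < 1e-12))
    expect_true(all(lA >= pmax(0.4, vsi / 100) - 1e-12 & lA <= 1))
    expect_true(all(kE >= 1.25 & kE <= 2.45))
    ## geometry and wall stiffness sampled independently
    expect_lt(abs(cor(vsi, kE)), 0.05)
    ## height is the length-IIV anatomical axis
    ht <- vapply(subs, `[[`, 1, "height")
    lenIiv <- vapply(subs, function(s) s$iiv[["length"]], 1)
    expect_equal(ht, 170 * lenIiv)
    ## marginals match the configured uniforms
    expect_gt(ks.test(stiff, "punif", 0.7, 1.6)$p.value, 0.01)
    expect_gt(ks.test(vsi, "punif", 0, 100)$p.value, 0.01)
    age <- vapply(subs, `[[`, 1, "age")
    expect_gt(ks.test(age, "punif", 40, 80)$p.value, 0.01)
    ## determinism under a fixed seed
    set.seed(99); a <- sampleSubject(cfg)
    set.seed(99); b <- sampleSubject(cfg)
    expect_identical(a, b)
})

test_that("sample-to-sample perturbations have the configured spread", {
    cfg <- cohortConfig()
    set.seed(5)
    subj <- sampleSubject(cfg)
    draws <- replicate(4000, perturbSample(subj, 10, 4, cfg),
                       simplify = FALSE)
    rmult <- vapply(draws, function(d) d$radius[1], 1)
    expect_equal(sd(rmult), 0.01, tolerance = 0.1)
    expect_equal(mean(rmult), 1, tolerance = 0.001)
    ## viscoelastic log-sd recovers the lognormal moment identity
    ve <- vapply(draws, function(d) d$viscoelastic$eB2, 1)
    expect_equal(sd(log(ve)), sqrt(log(1 + 0.01^2)), tolerance = 0.1)
    expect_equal(median(ve), subj$viscoelastic$eB2, tolerance = 0.01)
    ## zero-variance configuration reproduces the subject exactly
    cfg0 <- cohortConfig(ssvCv = 0)
    cfg0$viscoelastic$ssvCv <- 0
    d0 <- perturbSample(subj, 10, 4, cfg0)
    expect_equal(d0$hr, subj$hr)
    expect_equal(d0$radius, rep(1, 10))
    expect_equal(unlist(d0$viscoelastic), unlist(subj$viscoelastic))
})

test_that("cohort generation is deterministic with labeled/unlabeled contracts", {
    pc <- generateCohort(3, 2, seed = 42)
    expect_s4_class(pc, "PulseCohort")
    expect_equal(ncol(pc), 6)
    expect_equal(nrow(SummarizedExperiment::assay(pc, "bp_carotid")), 256)
    expect_true(all(c("bp_brachial", "bp_tibial", "pvr_brachial",
                      "pvr_tibial") %in%
                    SummarizedExperiment::assayNames(pc)))
    expect_true(all(vsiLabels(pc) >= 0 & vsiLabels(pc) <= 100))
    expect_true(all(is.finite(SummarizedExperiment::assay(pc, "pvr_tibial"))))
    pc2 <- generateCohort(3, 2, seed = 42)
    expect_identical(SummarizedExperiment::assay(pc, "bp_carotid"),
                     SummarizedExperiment::assay(pc2, "bp_carotid"))
    un <- generateCohort(2, 2, labeled = FALSE, seed = 7)
    expect_null(vsiLabels(un))
    cd <- SummarizedExperiment::colData(un)
    expect_false(any(c("vsi", "max_diameter_increase", "l_aaa", "k_e")
                     %in% names(cd)))
    expect_true(all(c("height", "age") %in% names(cd)))
})

test_that("cohort CSV export writes the full layout", {
    pc <- generateCohort(2, 1, seed = 3)
    dir <- tempfile()
    writeCohortCsv(pc, dir)
    expect_true(file.exists(file.path(dir, "bp_carotid.csv")))
    expect_true(file.exists(file.path(dir, "annotation.csv")))
    expect_true(file.exists(file.path(dir, "manifest.yaml")))
    m <- read.csv(file.path(dir, "bp_carotid.csv"))
    expect_equal(dim(m), c(2L, 256L))
})
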