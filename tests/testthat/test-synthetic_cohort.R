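test_that("subject generation is deterministic and label-checked", {
    cfg <- cohortConfig(duration_s = 5, seed = 3)
    a <- generateSubject("HC", cfg, 42)
    b <- generateSubject("HC", cfg, 42)
    expect_identical(signalMatrix(a), signalMatrix(b))
    expect_equal(ncol(signalMatrix(a)), 19)
    expect_equal(nSamples(a), 5 * 256)
    c <- generateSubject("HC", cfg, 43)
    expect_false(identical(signalMatrix(a), signalMatrix(c)))
    expect_error(generateSubject("XX", cfg, 1), "label")
})

test_that("cohort composition and determinism match the configuration", {
    cfg <- cohortConfig(n_ad = 4, n_mci = 3, n_hc = 2, duration_s = 2,
                        seed = 9)
    coh <- generateCohort(cfg)
    expect_length(coh$recordings, 9)
    expect_equal(as.vector(table(factor(coh$labels,
                                        c("AD", "MCI", "HC")))), c(4, 3, 2))
    coh2 <- generateCohort(cfg)
    expect_identical(lapply(coh$recordings, signalMatrix),
                     lapply(coh2$recordings, signalMatrix))

    empty <- generateCohort(cohortConfig(n_ad = 0, n_mci = 0, n_hc = 0,
                                         duration_s = 1))
    expect_length(empty$recordings, 0)

    # default composition mirrors the clinical cohort sizes
    expect_equal(as.vector(table(factor(cohortLabels(cohortConfig()),
                                        c("AD", "MCI", "HC")))),
                 c(49, 37, 23))
})

test_that("AD cohorts show higher slow/fast band-power ratio than HC", {
    # independent periodogram oracle on the Cz channel, 50 subjects per class
    cfg <- cohortConfig(duration_s = 20, seed = 17)
    ratio <- function(label, seed) {
        x <- signalMatrix(generateSubject(label, cfg, seed))[, "Cz"]
        slow <- periodogramBandPower(x, 256, 0.5, 7)
        fast <- periodogramBandPower(x, 256, 8, 30)
        slow / fast
    }
    r_ad <- vapply(1:50, function(i) ratio("AD", 1000 + i), numeric(1))
    r_hc <- vapply(1:50, function(i) ratio("HC", 2000 + i), numeric(1))
    expect_gt(mean(r_ad), mean(r_hc))
    # MCI sits between the two class means
    r_mci <- vapply(1:50, function(i) ratio("MCI", 3000 + i), numeric(1))
    expect_gt(mean(r_mci), mean(r_hc))
    expect_lt(mean(r_mci), mean(r_ad))
})

test_that("noise- and artifact-free subjects obey the superposition bound", {
    cfg <- cohortConfig(duration_s = 4, noise_scale = 0, artifact_rate = 0,
                        seed = 2)
    rec <- generateSubject("HC", cfg, 7)
    bound <- sum(cfg$band_amplitudes)   # HC gains are all 1
    expect_lte(max(abs(signalMatrix(rec))), bound)

    # AD scales the bound by its band gains
    recAD <- generateSubject("AD", cfg, 7)
    boundAD <- sum(cfg$band_amplitudes * unlist(cfg$class_band_gains$AD))
    expect_lte(max(abs(signalMatrix(recAD))), boundAD)
})

test_that("slow/fast separation is reproducible across master seeds", {
    for (seed in 1:10) {
        cfg <- cohortConfig(n_ad = 20, n_mci = 0, n_hc = 20,
                            duration_s = 8, seed = seed)
        seeds <- subjectSeeds(cfg)
        labels <- cohortLabels(cfg)
        power <- vapply(seq_along(labels), function(i) {
            x <- signalMatrix(generateSubject(labels[i], cfg, seeds[i]))[, "Pz"]
            periodogramBandPower(x, 256, 0.5, 7)
        }, numeric(1))
        p <- stats::wilcox.test(power[labels == "AD"],
                                power[labels == "HC"],
                                alternative = "greater")$p.value
        expect_lt(p, 0.05)
    }
})

test_that("configuration validation rejects inconsistent settings", {
    expect_error(cohortConfig(band_defs = list(delta = c(0.5, 5),
                                               theta = c(4, 7),
                                               alpha = c(8, 13),
                                               beta = c(13, 30))),
                 "overlap")
    expect_error(cohortConfig(fs = 40), "fs/2")
    expect_error(cohortConfig(class_band_gains = list(
        HC = c(delta = 2, theta = 1, alpha = 1, beta = 1),
        MCI = c(delta = 1.2, theta = 1.25, alpha = 0.8, beta = 0.85),
        AD = c(delta = 1.4, theta = 1.5, alpha = 0.6, beta = 0.7))),
        "reference")
})
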