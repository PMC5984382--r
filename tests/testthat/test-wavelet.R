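# Reference single-level sym3 decomposition of a fixed length-13 signal,
# computed with an independent DWT implementation (symmetric extension).
.ref_x <- c(1.764052345967664, 0.4001572083672233, 0.9787379841057392,
            2.240893199201458, 1.8675579901499675, -0.977277879876411,
            0.9500884175255894, -0.1513572082976979, -0.10321885179355784,
            0.41059850193837233, 0.144043571160878, 1.454273506962975,
            0.7610377251469934)
.ref_cA <- c(1.3444445147441448, 2.30905547107836, 0.8632936164170381,
             3.03803767115699, 0.3133665179230623, 0.12995563948402078,
             0.1286545249326922, 1.3494147878489133, 1.4778718413807497)
.ref_cD <- c(0.5875676989038401, -0.2131146802296898, 0.7656824420359423,
             1.2401996439492216, -0.29625980139025854, -0.52191982892148,
             -0.29588905774302426, 0.8021183848125414, 0.19489353994932282)

test_that("single-level sym3 analysis matches the reference coefficients", {
    d <- dwtDecompose(.ref_x, "sym3", 1)
    expect_equal(d@approx, .ref_cA, tolerance = 1e-12)
    expect_equal(d@detail[[1]], .ref_cD, tolerance = 1e-12)
    expect_equal(dwtReconstruct(d), .ref_x, tolerance = 1e-9)
})

test_that("the filter bank reconstructs perfectly for both wavelets", {
    set.seed(10)
    for (i in 1:25) {
        n <- sample(1300:4200, 1)
        x <- rnorm(n)
        for (spec in list(c("sym3", 8), c("db4", 5))) {
            d <- dwtDecompose(x, spec[1], as.integer(spec[2]))
            expect_lt(max(abs(dwtReconstruct(d) - x)), 1e-8)
        }
    }
    # zero in, zero out
    z <- dwtDecompose(numeric(2048), "db4", 5)
    expect_true(all(abs(unlist(z@detail)) == 0) && all(z@approx == 0))
    # too short for the requested depth
    expect_error(dwtDecompose(rnorm(100), "sym3", 8), "levels")
})

test_that("the dyadic band map tiles (0, fs/2)", {
    d <- dwtDecompose(rnorm(2048), "db4", 5, fs = 256)
    bm <- bandMap(d)
    expect_equal(bm$D1, c(64, 128))
    expect_equal(bm$D2, c(32, 64))
    expect_equal(bm$D3, c(16, 32))
    expect_equal(bm$D4, c(8, 16))
    expect_equal(bm$D5, c(4, 8))
    expect_equal(bm$A5, c(0, 4))
    edges <- sort(unique(unlist(bm)))
    expect_equal(edges, c(0, 4, 8, 16, 32, 64, 128))
})

test_that("attenuation thresholds follow the mean +/- 1.5 sd rule", {
    # constant sub-band: sd = 0, both thresholds collapse onto the value
    thr <- computeThresholds(rep(2.5, 10))
    expect_equal(thrUp(thr), 2.5)
    expect_equal(thrDwn(thr), 2.5)

    # alternating +/- 1: mean 0, sample sd = 2/sqrt(3)
    thr2 <- computeThresholds(c(-1, 1, -1, 1))
    expect_equal(thrUp(thr2), sqrt(3), tolerance = 1e-12)
    expect_equal(thrDwn(thr2), -sqrt(3), tolerance = 1e-12)

    # the corridor width is 3 sd by construction
    set.seed(11)
    for (i in 1:20) {
        x <- rnorm(sample(5:200, 1), sd = runif(1, 0.1, 10))
        thr <- computeThresholds(x)
        expect_equal(thrUp(thr) - thrDwn(thr), 3 * sd(x), tolerance = 1e-12)
    }
    expect_error(computeThresholds(numeric(0)), "empty")
})

test_that("out-of-threshold samples are scaled by (up - dwn)/100", {
    thr <- new("ThresholdPair", up = 2, dwn = -2)
    expect_equal(attenuateOutliers(c(10), thr), 0.4)
    expect_equal(attenuateOutliers(c(1), thr), 1)
    expect_equal(attenuateOutliers(c(-30), thr), -1.2)

    # in-corridor content passes through unchanged
    x <- seq(-2, 2, length.out = 21)
    expect_identical(attenuateOutliers(x, thr), x)

    # attenuation never adds new out-of-corridor samples
    set.seed(12)
    for (i in 1:20) {
        x <- rnorm(500, sd = 5)
        thr <- computeThresholds(x)
        y <- attenuateOutliers(x, thr)
        out_before <- sum(x > thrUp(thr) | x < thrDwn(thr))
        out_after <- sum(y > thrUp(thr) | y < thrDwn(thr))
        expect_lte(out_after, out_before)
        expect_length(y, length(x))
    }
})

test_that("denoising is deterministic, removes spikes, spares smooth signals", {
    set.seed(13)
    t <- (0:46079) / 256
    # alpha/beta-dominant smooth signal, amplitudes on the generator scale;
    # its content lies in sub-bands the attenuation does not treat
    smooth <- 5 * sin(2 * pi * 13 * t) + 2 * sin(2 * pi * 26 * t + 1) +
        2.5 * sin(2 * pi * 2.5 * t + 2)

    expect_identical(denoiseChannel(smooth), denoiseChannel(smooth))

    reduced <- 0
    for (i in 1:20) {
        x <- smooth + rnorm(length(t), sd = 2)
        spike_at <- sample(1000:45000, 1)
        x[spike_at + 0:12] <- x[spike_at + 0:12] +
            10 * sd(x) * (1 - abs(-6:6) / 7)
        y <- denoiseChannel(x)
        if (max(abs(y)) < max(abs(x))) reduced <- reduced + 1
    }
    expect_gte(reduced, 19)

    y0 <- denoiseChannel(smooth)
    rel_rms <- sqrt(mean((y0 - smooth)^2)) / sqrt(mean(smooth^2))
    expect_lt(rel_rms, 0.05)
})

test_that("wavelet features have the documented layout and band mapping", {
    rec <- sineRecording(dur = 180)
    f <- extractWaveletFeatures(rec)
    expect_length(f, 912)
    expect_true(!anyNA(f))
    expect_equal(names(f)[1:3],
                 c("Fp1_e1_delta_mean", "Fp1_e1_delta_sd", "Fp1_e1_delta_psd"))

    # a pure 6 Hz tone concentrates PSD in the theta sub-band of every epoch
    one <- sineRecording(dur = 180, channels = "Cz", freqs = 6)
    f1 <- extractWaveletFeatures(one, denoise = FALSE)
    expect_length(f1, 48)
    for (e in 1:4) {
        psd <- f1[sprintf("Cz_e%d_%s_psd", e,
                          c("delta", "theta", "alpha", "beta"))]
        expect_equal(which.max(psd), 2, ignore_attr = TRUE)
    }
})

test_that("wavelet features scale as first and second moments", {
    set.seed(14)
    mat <- matrix(rnorm(256 * 60), ncol = 1, dimnames = list(NULL, "F3"))
    rec <- Recording(mat, 256)
    f1 <- extractWaveletFeatures(rec, denoise = FALSE)
    f2 <- extractWaveletFeatures(Recording(mat * 3, 256), denoise = FALSE)
    sel_lin <- grepl("_(mean|sd)$", names(f1))
    expect_equal(f2[sel_lin], 3 * f1[sel_lin], tolerance = 1e-10)
    expect_equal(f2[!sel_lin], 9 * f1[!sel_lin], tolerance = 1e-10)
    expect_true(all(f1[grepl("_psd$", names(f1))] >= 0))
})
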