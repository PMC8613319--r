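# Corruption, MAR inpainting and VMI emulation on small unilateral/bilateral
# sinograms.

uniSino <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- forwardProject(
                rasterizePhantom(smallSpec("unilateral", n = 192L)),
                nAngles = 96L)
        cache
    }
})

test_that("huge flux and zero beta leave the sinogram unchanged", {
    sino <- uniSino()
    out <- corruptSinogram(sino, c(beta = 0, i0 = 1e12, gamma = 0), seed = 1L)
    expect_equal(sinogramValues(out), sinogramValues(sino), tolerance = 1e-12)
})

test_that("beam hardening only depresses rays, and only near the trace", {
    sino <- uniSino()
    out <- corruptSinogram(sino, c(beta = 0.5, i0 = 1e12, gamma = 0),
                           seed = 1L)
    diffs <- sinogramValues(out) - sinogramValues(sino)
    expect_true(all(diffs <= 1e-12))
    tr <- metalTrace(sino)
    expect_true(all(diffs[tr] < 0))          # strictly lower on the trace
    # rays beyond the scatter penumbra are untouched (the depression acts
    # wherever the weighted metal path is positive, which extends slightly
    # beyond the thresholded trace)
    base <- sino@metalPath > 0
    reach <- ceiling(3 * 2.5 / sino@detSpacing) + 1L
    far <- !.dilateMask(base, reach)
    expect_true(all(abs(diffs[far]) < 1e-12))
    # penumbra rays just outside the trace are (weakly) depressed
    near <- .dilateMask(tr, 2L) & !tr
    expect_gt(sum(diffs[near] < -1e-9), 0)
})

test_that("photon starvation noise follows the delta-method variance", {
    p0 <- 1.5
    i0 <- 1e4
    sino <- uniSino()
    sino@values <- matrix(p0, 100, 100)
    sino@metalPath <- matrix(0, 100, 100)
    out <- corruptSinogram(sino, c(beta = 0, i0 = i0, gamma = 0), seed = 7L)
    v <- as.vector(sinogramValues(out))
    expect_equal(var(v), 1 / (i0 * exp(-p0)), tolerance = 0.2)
    expect_equal(mean(v), p0, tolerance = 0.01)
})

test_that("corruption is deterministic given the seed", {
    sino <- uniSino()
    a <- corruptSinogram(sino, c(beta = 0.5, i0 = 1e5, gamma = 0), seed = 3L)
    b <- corruptSinogram(sino, c(beta = 0.5, i0 = 1e5, gamma = 0), seed = 3L)
    c2 <- corruptSinogram(sino, c(beta = 0.5, i0 = 1e5, gamma = 0), seed = 4L)
    expect_identical(sinogramValues(a), sinogramValues(b))
    expect_false(identical(sinogramValues(a), sinogramValues(c2)))
})

test_that("corruption does not consume the caller's RNG stream", {
    sino <- uniSino()
    set.seed(99); before <- runif(3)
    set.seed(99); invisible(corruptSinogram(sino, c(beta = 0, i0 = 1e5,
                                                    gamma = 0), seed = 1L))
    after <- runif(3)
    expect_identical(before, after)
})

test_that("severity preconditions are enforced", {
    sino <- uniSino()
    expect_error(corruptSinogram(sino, c(beta = -1, i0 = 1e5, gamma = 0)),
                 "beta")
    expect_error(corruptSinogram(sino, c(beta = 0, i0 = -5, gamma = 0)),
                 "i0")
    expect_error(corruptSinogram(sino, c(beta = 0, i0 = 1e5, gamma = -1)),
                 "gamma")
})

test_that("MAR inpainting is the identity without metal and idempotent with", {
    clean <- forwardProject(rasterizePhantom(smallSpec("none", n = 128L)),
                            nAngles = 96L)
    expect_identical(sinogramValues(applyOMAREmulation(clean)),
                     sinogramValues(clean))
    corr <- corruptSinogram(uniSino(), c(beta = 0.5, i0 = 1e6, gamma = 0),
                            seed = 2L)
    once <- applyOMAREmulation(corr)
    twice <- applyOMAREmulation(once)
    expect_identical(sinogramValues(once), sinogramValues(twice))
    # untraced bins are untouched
    tr <- metalTrace(corr)
    expect_identical(sinogramValues(once)[!tr], sinogramValues(corr)[!tr])
})

test_that("a fully-shadowed detector row is flagged and filled", {
    sino <- uniSino()
    sino@metalPath[5, ] <- 10      # every bin of angle 5 on the trace
    # bridge-only inpainting zero-fills the hopeless row
    expect_warning(out <- applyOMAREmulation(sino, method = "spline"),
                   "whole detector")
    expect_true(all(sinogramValues(out)[5, ] == 0))
    # the prior-based default then repopulates it from the prior image
    expect_warning(out2 <- applyOMAREmulation(sino), "whole detector")
    expect_true(all(is.finite(sinogramValues(out2)[5, ])))
})

test_that("emulated MAR strictly reduces the streak index on severe cases", {
    spec <- smallSpec("bilateral", n = 192L)
    truth <- rasterizePhantom(spec)
    raw <- forwardProject(truth, nAngles = 120L)
    for (beta in c(0.35, 0.5, 0.8)) {
        corr <- corruptSinogram(raw, c(beta = beta, i0 = 1e9, gamma = 0),
                                seed = 11L)
        off <- reconstructFBP(corr)
        on <- reconstructFBP(applyOMAREmulation(corr), omar = "on")
        expect_lt(streakIndex(on, truth), streakIndex(off, truth),
                  label = paste("beta", beta))
    }
})

test_that("streak index rises with beam hardening and falls with flux", {
    spec <- smallSpec("bilateral", n = 128L)
    truth <- rasterizePhantom(spec)
    raw <- forwardProject(truth, nAngles = 96L)
    # fluxes in the regime where beam hardening, not photon starvation,
    # dominates the streak index (at strongly starved fluxes the depression
    # de-starves metal rays and the index is noise-driven)
    betas <- c(0.1, 0.5, 1)
    fluxes <- c(6.5e9, 5e10, 1e12)
    si <- matrix(NA_real_, 3, 3)
    for (i in 1:3) for (j in 1:3) {
        corr <- corruptSinogram(raw, c(beta = betas[i], i0 = fluxes[j],
                                       gamma = 0), seed = 5L)
        si[i, j] <- streakIndex(reconstructFBP(corr), truth)
    }
    for (j in 1:3) expect_true(all(diff(si[, j]) > 0),
                               label = paste("beta-monotone, flux", fluxes[j]))
    # non-increasing in flux (the two highest fluxes sit on the noiseless
    # plateau, where the index is exactly equal)
    for (i in 1:3) expect_true(all(diff(si[i, ]) <= 0),
                               label = paste("flux-monotone, beta", betas[i]))
})

test_that("VMI bright streaks are positive, trace-bound and removable by MAR", {
    sino <- uniSino()
    out <- vmiBrightStreaks(sino, gamma = 1.2, every = 5L)
    diffs <- sinogramValues(out) - sinogramValues(sino)
    expect_true(all(diffs >= 0))
    expect_gt(max(diffs), 0)
    expect_true(all(diffs[!metalTrace(sino)] == 0))
    expect_identical(sinogramValues(vmiBrightStreaks(sino, gamma = 0)),
                     sinogramValues(sino))
    # MAR inpainting overwrites the streak bins
    expect_equal(sinogramValues(applyOMAREmulation(out)),
                 sinogramValues(applyOMAREmulation(sino)), tolerance = 1e-9)
    expect_error(vmiBrightStreaks(sino, gamma = -1), "gamma")
})

test_that("artifact-free VMI limit reconstructs the rescaled ground truth", {
    spec <- smallSpec("none", n = 256L)
    truthVMI <- rasterizePhantom(spec, "vmi130")
    corr <- corruptSinogram(forwardProject(truthVMI, nAngles = 180L),
                            c(beta = 0, i0 = 1e15, gamma = 0), seed = 1L)
    rec <- reconstructFBP(corr)
    m <- measureROIs(rec, defaultROITemplate(useMM = TRUE))
    m <- m[m$label != "BG", ]
    expect_true(all(abs(m$mean_hu - 150.4) / 150.4 < 0.05))
})
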