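test_that("zero-attenuation (air) image projects to an all-zero sinogram", {
    img <- makeImage(matrix(-1000, 128, 128))
    sino <- forwardProject(img, nAngles = 96L)
    expect_true(all(abs(sinogramValues(sino)) < 1e-12))
    expect_false(any(metalTrace(sino)))
})

test_that("a centred disk projects identically at every angle", {
    n <- 192L
    dx <- 330 / n
    ax <- (seq_len(n) - (n + 1) / 2) * dx
    d <- sqrt(outer(rev(ax)^2, ax^2, "+")) - 50   # 50 mm water disk
    cov <- pmin(1, pmax(0, 0.5 - d / dx))         # antialiased edge
    px <- matrix(-1000 + 1000 * cov, n, n)
    sino <- forwardProject(makeImage(px), nAngles = 96L)
    v <- sinogramValues(sino)
    spread <- apply(v, 2, function(col) max(col) - min(col))
    # residual anisotropy reflects bilinear grid sampling of the raster
    expect_lt(max(spread) / max(v), 2e-2)
})

test_that("line integrals match the analytic chord of a known disk", {
    n <- 256L
    dx <- 330 / n
    ax <- (seq_len(n) - (n + 1) / 2) * dx
    r <- 20                       # water-equivalent disk, 40 mm across
    d <- sqrt(outer(rev(ax)^2, ax^2, "+")) - r
    cov <- pmin(1, pmax(0, 0.5 - d / dx))
    px <- matrix(-1000 + 1000 * cov, n, n)
    sino <- forwardProject(makeImage(px), nAngles = 96L,
                           stepMM = dx / 8)
    v <- sinogramValues(sino)[1, ]          # angle 0
    s <- (seq_len(ncol(sinogramValues(sino))) -
          (ncol(sinogramValues(sino)) + 1) / 2) * sino@detSpacing
    for (off in c(0, 8, 14)) {
        chord <- 2 * sqrt(r^2 - off^2) * huToMu(0)
        got <- approx(s, v, xout = off)$y
        expect_equal(got, chord, tolerance = 0.04,
                     info = paste("offset", off))
    }
})

test_that("projector conserves total attenuation at angle zero", {
    spec <- smallSpec("none", n = 192L)
    img <- rasterizePhantom(spec)
    sino <- forwardProject(img, nAngles = 96L)
    pixSum <- sum(huToMu(pixels(img))) * pixelSpacing(img)[1]^2
    projSum <- sum(sinogramValues(sino)[1, ]) * sino@detSpacing
    expect_equal(projSum, pixSum, tolerance = 0.01)
})

test_that("round-trip reconstruction is faithful inside the body", {
    spec <- smallSpec("none", n = 256L)
    img <- rasterizePhantom(spec)
    sino <- forwardProject(img, nAngles = 180L)
    # canonical ramp kernel for the fidelity check
    rec <- reconstructFBP(sino, kernel = "standard")
    body <- pixels(img) > -500
    rmse <- sqrt(mean((pixels(rec)[body] - pixels(img)[body])^2))
    expect_lt(rmse, 20)
    # per-pellet means within 5 percent of ground truth, for both kernels
    tpl <- defaultROITemplate(useMM = TRUE)
    for (kern in c("standard", "sharp")) {
        m <- measureROIs(reconstructFBP(sino, kernel = kern), tpl)
        m <- m[m$label != "BG", ]
        expect_true(all(abs(m$mean_hu - 248.4) / 248.4 < 0.05),
                    label = kern)
    }
})

test_that("zero sinogram backprojects to zero attenuation (air)", {
    img <- rasterizePhantom(smallSpec("none", n = 128L))
    sino <- forwardProject(img, nAngles = 96L)
    sino@values[] <- 0
    rec <- reconstructFBP(sino)
    expect_true(all(abs(pixels(rec) + 1000) < 1e-9))
})

test_that("degenerate projection geometries are rejected", {
    img <- makeImage(matrix(0, 64, 64))
    expect_error(forwardProject(img, nAngles = 10L), "nAngles")
    expect_error(forwardProject(img, nAngles = 96L, nBins = 10L), "nBins")
    sino <- forwardProject(img, nAngles = 96L)
    sino@angles <- sino@angles / 10   # spans only a tenth of pi
    expect_error(reconstructFBP(sino), "span")
})

test_that("metal trace marks exactly the rays crossing metal", {
    spec <- smallSpec("unilateral", n = 192L)
    sino <- forwardProject(rasterizePhantom(spec), nAngles = 96L)
    tr <- metalTrace(sino)
    expect_gt(sum(tr), 0)
    expect_lt(mean(tr), 0.5)        # metal shadows a minority of rays
    # trace rows exist at every angle (the implant is always in view)
    expect_true(all(rowSums(tr) > 0))
})
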