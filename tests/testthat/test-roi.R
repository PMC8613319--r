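test_that("constant image gives the constant mean and zero noise", {
    img <- makeImage(matrix(248.4, 512, 512))
    m <- measureROIs(img, defaultROITemplate())
    expect_equal(m$mean_hu, rep(248.4, 19))
    expect_equal(m$noise_hu, rep(0, 19))
    expect_true(all(is.na(m$snr)))   # SNR undefined at zero noise
    expect_true(all(m$n_pixels >= 9))
})

test_that("checkerboard ROI statistics match the enumeration bands", {
    n <- 512
    px <- matrix(0, n, n)
    px[(row(px) + col(px)) %% 2 == 1] <- 100
    img <- makeImage(px)
    m <- measureROIs(img, defaultROITemplate())
    expect_true(all(abs(m$mean_hu - 50) < 5))
    expect_true(all(abs(m$noise_hu - 50) < 2))
})

test_that("population vs sample SD differ by the n/(n-1) factor", {
    set.seed(7)
    img <- makeImage(matrix(rnorm(512^2, 100, 10), 512, 512))
    tpl <- defaultROITemplate()
    pop <- measureROIs(img, tpl, sdMode = "population")
    sam <- measureROIs(img, tpl, sdMode = "sample")
    k <- pop$n_pixels
    expect_equal(sam$noise_hu, pop$noise_hu * sqrt(k / (k - 1)),
                 tolerance = 1e-12)
    # below 1 percent at >= 100 pixels
    expect_true(all(abs(sam$noise_hu / pop$noise_hu - 1) < 0.01))
})

test_that("membership shifts identically with a one-pixel template shift", {
    set.seed(8)
    n <- 256
    px <- matrix(rnorm(n * n), n, n)
    dx <- 330 / n
    img <- makeImage(px)
    shifted <- makeImage(px[, c(n, 1:(n - 1))])  # shift content one column
    tpl <- roiTemplate(data.frame(label = c(paste0("R", 1:9),
                                            paste0("L", 1:9), "BG"),
                                  x_mm = seq(-90, 90, length.out = 19),
                                  y_mm = rep(c(-40, 0, 40), length.out = 19),
                                  diameter_mm = 20))
    tplShift <- tpl
    tplShift@rois$x_mm <- tpl@rois$x_mm + dx
    a <- measureROIs(img, tpl)
    b <- measureROIs(shifted, tplShift)
    expect_equal(a$mean_hu, b$mean_hu, tolerance = 1e-12)
    expect_equal(a$n_pixels, b$n_pixels)
})

test_that("SNR and CNR definitions and invariances hold", {
    expect_equal(snr(248.4, 6.9), 36, tolerance = 0.01)
    expect_equal(snr(0, 5), 0)
    expect_equal(cnr(248.4, 6.9, 0, 6.9), 36, tolerance = 0.01)
    expect_equal(cnr(100, 5, 100, 7), 0)
    set.seed(9)
    for (i in 1:30) {
        m <- rnorm(1, 100, 50); nz <- runif(1, 1, 20); c0 <- runif(1, 0.1, 9)
        expect_equal(snr(m, nz), snr(c0 * m, c0 * nz), tolerance = 1e-12)
        bm <- rnorm(1, 0, 10); bn <- runif(1, 1, 20); off <- rnorm(1, 0, 70)
        expect_equal(cnr(m, nz, bm, bn), cnr(m + off, nz, bm + off, bn),
                     tolerance = 1e-12)
    }
    expect_warning(out <- snr(100, 0), "zero noise")
    expect_true(is.na(out))
    expect_warning(out <- cnr(1, 0, 0, 0), "zero combined noise")
    expect_true(is.na(out))
})

test_that("CNR is signed, not absolute", {
    expect_lt(cnr(-50, 10, 0, 10), 0)
})

test_that("Rose criterion flag is strict and bounded to [3, 5]", {
    expect_true(roseFlag(36, 4))
    expect_false(roseFlag(2.9, 3))
    expect_false(roseFlag(4, 4))  # must strictly exceed
    expect_error(roseFlag(10, 2), "3, 5")
})

test_that("off-image and too-small ROIs raise labelled errors", {
    img <- makeImage(matrix(0, 64, 64))
    tplOff <- roiTemplate(data.frame(
        label = c(paste0("R", 1:9), paste0("L", 1:9), "BG"),
        x_mm = c(500, seq(-80, 80, length.out = 18)),
        y_mm = 0, diameter_mm = 12))
    expect_error(measureROIs(img, tplOff), "R1")
    tplTiny <- roiTemplate(data.frame(
        label = c(paste0("R", 1:9), paste0("L", 1:9), "BG"),
        x_mm = seq(-90, 90, length.out = 19), y_mm = 0,
        diameter_mm = 4))  # < 1 pixel at 64-matrix spacing
    expect_error(measureROIs(img, tplTiny), "fewer than 9")
})

test_that("template validity enforces one BG and 18 pellet ROIs", {
    bad <- data.frame(label = c("R1", "BG", "BG"), x_mm = 0, y_mm = 0,
                      diameter_mm = 10)
    expect_error(roiTemplate(bad), "BG|18")
})
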