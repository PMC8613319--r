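test_that("exact p matches full 2^n enumeration, with and without ties", {
    set.seed(101)
    for (i in 1:100) {
        n <- sample(2:12, 1)
        d <- rnorm(n)
        if (i %% 2 == 0) d <- round(d, 1)  # force ties / zeros
        if (all(d == 0)) d[1] <- 0.5
        res <- suppressWarnings(wilcoxonSignedRank(d, mode = "exact"))
        expect_equal(res$p.value, bruteSignedRankP(d), tolerance = 1e-12,
                     info = paste("case", i))
    }
})

test_that("known exact p-values are reproduced", {
    # six differences of one sign: most extreme of 2^6 assignments
    res <- wilcoxonSignedRank(c(1.2, 0.8, 1.1, 0.9, 1.4, 1.0))
    expect_equal(res$p.value, 2 / 64)
    expect_equal(unname(res$statistic), 21)
    # n = 9 with positive rank sum W = 2
    d <- c(-1, 2, -3, -4, -5, -6, -7, -8, -9)
    res <- wilcoxonSignedRank(d)
    expect_equal(unname(res$statistic), 2)
    expect_equal(res$p.value, 6 / 512)
})

test_that("exact p agrees with stats::wilcox.test on tie-free samples", {
    set.seed(202)
    for (i in 1:20) {
        n <- sample(5:15, 1)
        x <- rnorm(n); y <- rnorm(n)
        mine <- wilcoxonSignedRank(x, y, mode = "exact")
        ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
        expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
        expect_equal(unname(mine$statistic), unname(ref$statistic))
    }
})

test_that("normal approximation matches stats::wilcox.test with ties", {
    set.seed(303)
    for (i in 1:10) {
        d <- round(rnorm(30), 1)
        d <- d[d != 0]
        mine <- wilcoxonSignedRank(d, mode = "normal")
        ref <- suppressWarnings(wilcox.test(d, exact = FALSE,
                                            correct = TRUE))
        expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
    }
})

test_that("two-sidedness: p is invariant under a global sign flip", {
    set.seed(404)
    for (i in 1:20) {
        d <- round(rnorm(sample(3:15, 1)), 2)
        if (all(d == 0)) d[1] <- 1
        p1 <- suppressWarnings(wilcoxonSignedRank(d)$p.value)
        p2 <- suppressWarnings(wilcoxonSignedRank(-d)$p.value)
        expect_identical(p1, p2)
        expect_gt(p1, 0)
        expect_lte(p1, 1)
    }
})

test_that("symmetric pairs sit at the distribution centre", {
    res <- wilcoxonSignedRank(c(1, -1.1, 2, -2.1, 3, -3.1))
    expect_gte(res$p.value, 0.5)
})

test_that("zero handling: Wilcoxon drop vs Pratt, and all-zero degenerate", {
    d <- c(0, 0, 1, 2, 3)
    drop <- wilcoxonSignedRank(d, zeros = "wilcoxon")
    expect_equal(drop$n, 3L)
    expect_equal(drop$p.value, 2 / 8)
    pratt <- wilcoxonSignedRank(d, zeros = "pratt")
    expect_equal(pratt$n, 3L)
    # Pratt keeps the zero ranks: positive ranks are 3,4,5 of five
    expect_equal(unname(pratt$statistic), 12)
    expect_warning(res <- wilcoxonSignedRank(c(0, 0, 0)), "zero")
    expect_true(res$degenerate)
    expect_equal(res$p.value, 1)
    expect_true(is.na(res$statistic))
})

test_that("empirical type-I error under the null is close to alpha", {
    set.seed(505)
    reps <- 2000L
    rej <- 0L
    for (i in seq_len(reps)) {
        d <- rnorm(10)
        if (wilcoxonSignedRank(d)$p.value < 0.05) rej <- rej + 1L
    }
    rate <- rej / reps
    expect_gte(rate, 0.03)
    expect_lte(rate, 0.07)
})

test_that("auto mode switches to the normal approximation for large n", {
    set.seed(606)
    d <- rnorm(25)
    res <- wilcoxonSignedRank(d, mode = "auto")
    expect_match(res$method, "normal")
    res <- wilcoxonSignedRank(d[1:12], mode = "auto")
    expect_match(res$method, "exact")
})
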