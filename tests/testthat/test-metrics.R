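# Toy record tables for the delta V / relative MAR machinery.
toyRecords <- function(dvStd = c(0.2, 0.4, 0.6), dvRec = c(0.1, 0.2, 0.3),
                       ref = 250) {
    n <- length(dvStd)
    ids <- paste0("R", seq_len(n))
    mk <- function(fam, omar, dv, scale) {
        data.frame(pellet_id = ids, config = "unilateral",
                   reconstruction = fam, omar = omar,
                   mean_hu = scale * (1 - dv), noise = 10 + seq_len(n),
                   snr = 20 - seq_len(n), cnr = 21 - seq_len(n),
                   stringsAsFactors = FALSE)
    }
    rec <- rbind(mk("conventional", "off", dvStd, ref),
                 mk("conventional", "on", dvRec, ref),
                 mk("vmi130", "off", dvRec, 150),
                 mk("vmi130", "on", dvRec / 2, 150))
    assignCategories(rec)
}
toyRefs <- function(ref = 250) {
    data.frame(reconstruction = c("conventional", "vmi130"),
               mean_hu = c(ref, 150),
               cnr = 20, snr = 20, noise = 8, stringsAsFactors = FALSE)
}

test_that("deltaV evaluates the normalized deviation", {
    expect_equal(deltaV(100, 250), 0.6)
    expect_equal(deltaV(-50, 250), 1.2)
    expect_equal(deltaV(250, 250), 0)
    expect_warning(out <- deltaV(5, 0), "zero reference")
    expect_true(is.na(out))
})

test_that("relativeMAR evaluates the percentage reduction", {
    expect_equal(relativeMAR(0.11, 0.20), 45)
    expect_equal(relativeMAR(0.4, 0.1), -300)
    expect_equal(relativeMAR(0.3, 0.3), 0)
    expect_warning(out <- relativeMAR(0.1, 0), "zero standard")
    expect_true(is.na(out))
})

test_that("relativeMAR is strictly decreasing in the evaluated delta V", {
    set.seed(11)
    for (i in 1:50) {
        ds <- runif(1, 0.05, 1)
        d1 <- runif(1, 0, 2); d2 <- d1 + runif(1, 0.01, 1)
        expect_gt(relativeMAR(d1, ds), relativeMAR(d2, ds))
        expect_equal(relativeMAR(ds, ds), 0)
    }
})

test_that("delta V and relative MAR are scale invariant", {
    set.seed(12)
    for (i in 1:25) {
        v <- rnorm(1, 100, 80); ref <- runif(1, 50, 300)
        c0 <- runif(1, 0.1, 10)
        expect_equal(deltaV(v, ref), deltaV(c0 * v, c0 * ref),
                     tolerance = 1e-12)
    }
    rec <- toyRecords()
    refs <- toyRefs()
    recScaled <- rec
    recScaled$mean_hu <- rec$mean_hu * 3
    refsScaled <- refs
    refsScaled$mean_hu <- refs$mean_hu * 3
    a <- aggregateComparison(rec, "mean_hu", "mild", "conventional_omar",
                             "conventional_noomar", refs)
    b <- aggregateComparison(recScaled, "mean_hu", "mild",
                             "conventional_omar", "conventional_noomar",
                             refsScaled)
    expect_equal(relativeMARPct(a), relativeMARPct(b), tolerance = 1e-10)
})

test_that("three-pellet toy comparison reproduces the hand arithmetic", {
    rec <- toyRecords(dvStd = c(0.2, 0.4, 0.6), dvRec = c(0.1, 0.2, 0.3))
    cmp <- aggregateComparison(rec, "mean_hu", "mild", "conventional_omar",
                               "conventional_noomar", toyRefs())
    expect_equal(relativeMARPct(cmp), 50)           # 1 - 0.2/0.4
    expect_equal(cmp@n, 3L)
    expect_equal(sort(cmp@deltaStandard), c(0.2, 0.4, 0.6), tolerance = 1e-12)
    expect_equal(sort(cmp@deltaRecon), c(0.1, 0.2, 0.3), tolerance = 1e-12)
    # per-pellet ratios are all exactly 0.5 here, so both aggregations agree
    cmp2 <- aggregateComparison(rec, "mean_hu", "mild", "conventional_omar",
                                "conventional_noomar", toyRefs(),
                                aggregation = "mean_of_ratios")
    expect_equal(relativeMARPct(cmp2), 50, tolerance = 1e-10)
})

test_that("self-comparison yields 0 percent and p = 1", {
    rec <- toyRecords()
    cmp <- aggregateComparison(rec, "mean_hu", "mild", "conventional_noomar",
                               "conventional_noomar", toyRefs())
    expect_equal(relativeMARPct(cmp), 0)
    expect_equal(pValue(cmp), 1)
})

test_that("oracle equivalence: spreadsheet-style arithmetic on 5 pellets", {
    set.seed(99)
    n <- 5
    vStd <- c(60, 30, 180, 220, 140)
    vRec <- c(200, 150, 230, 240, 210)
    ref <- 248.4
    rec <- toyRecords(dvStd = 1 - vStd / ref, dvRec = 1 - vRec / ref,
                      ref = ref)
    cmp <- aggregateComparison(rec, "mean_hu", "mild", "conventional_omar",
                               "conventional_noomar",
                               toyRefs(ref))
    # independent spreadsheet-style computation
    dvS <- abs(1 - vStd / ref); dvR <- abs(1 - vRec / ref)
    expect_equal(relativeMARPct(cmp), (1 - mean(dvR) / mean(dvS)) * 100,
                 tolerance = 1e-12)
    expect_equal(pValue(cmp),
                 wilcox.test(dvR, dvS, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
})

test_that("category with no members is flagged absent, not zero", {
    rec <- toyRecords()  # all pellets mild, none severe
    res <- suppressWarnings(buildTables(rec, toyRefs()))
    t3 <- res$table3
    sev <- t3[t3$category == "severe", ]
    expect_true(all(is.na(sev$relative_mar_pct)))
    expect_true(all(sev$n == 0L))
    expect_error(aggregateComparison(rec, "mean_hu", "severe",
                                     "conventional_omar",
                                     "conventional_noomar", toyRefs()),
                 "no pellet-instances")
})

test_that("delta V pairs are matched by pellet and configuration", {
    rec <- toyRecords()
    # permute row order; pairing must not depend on it
    rec2 <- rec[sample(nrow(rec)), ]
    a <- aggregateComparison(rec, "mean_hu", "mild", "conventional_omar",
                             "conventional_noomar", toyRefs())
    b <- aggregateComparison(rec2, "mean_hu", "mild", "conventional_omar",
                             "conventional_noomar", toyRefs())
    expect_equal(relativeMARPct(a), relativeMARPct(b))
    expect_equal(a@deltaRecon[order(a@pelletId)],
                 b@deltaRecon[order(b@pelletId)])
})
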