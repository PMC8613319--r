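# Shared builders and a cached small study so the expensive simulation runs
# once per test session.

makeImage <- function(px, dx = 330 / nrow(px),
                      condition = c(config = "none",
                                    reconstruction = "conventional",
                                    omar = "off")) {
    new("SliceImage", pixels = px, pixelSpacing = c(dx, dx),
        condition = condition, provenance = "test fixture")
}

smallSpec <- function(config = "none", n = 192L, ...) {
    phantomSpec(config, matrixSize = n, ...)
}

# brute-force two-sided signed-rank p by explicit enumeration of all 2^n
# sign assignments (oracle; n <= 12)
bruteSignedRankP <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- as.vector(grid %*% r)
    pLe <- mean(Ws <= W + 1e-9)
    pGe <- mean(Ws >= W - 1e-9)
    min(1, 2 * min(pLe, pGe))
}

# dilate a logical mask along the detector (column) axis by k bins
.dilateMask <- function(m, k) {
    out <- m
    nb <- ncol(m)
    for (s in seq_len(k)) {
        out[, seq_len(nb - s)] <- out[, seq_len(nb - s)] |
            m[, (1 + s):nb]
        out[, (1 + s):nb] <- out[, (1 + s):nb] | m[, seq_len(nb - s)]
    }
    out
}

# one small study per session, reused across test files
.studyCache <- new.env(parent = emptyenv())
cachedStudy <- function() {
    if (is.null(.studyCache$study))
        .studyCache$study <- generateStudy(seed = 42L, matrixSize = 256L,
                                           nAngles = 180L)
    .studyCache$study
}
cachedRecords <- function() {
    if (is.null(.studyCache$records))
        .studyCache$records <- measureStudy(cachedStudy())
    .studyCache$records
}

# category-recovery results over a 3 x 3 (beta, flux) severity grid,
# computed once per session
cachedGridRecovery <- function() {
    if (!is.null(.studyCache$grid)) return(.studyCache$grid)
    betas <- c(0.45, 0.6, 0.75)
    fluxes <- c(2e9, 6.5e9, 2e10)
    rows <- list()
    for (b in betas) for (f in fluxes) {
        sev <- c(beta = b, i0 = f, gamma = 1)
        study <- generateStudy(seed = 7L, matrixSize = 192L,
                               nAngles = 120L, severity = sev)
        rec <- measureStudy(study)
        gt <- groundTruth(study)
        inst <- unique(rec[rec$config != "none",
                           c("pellet_id", "config", "category")])
        merged <- merge(gt, inst, by = c("pellet_id", "config"))
        rows[[length(rows) + 1L]] <- data.frame(
            beta = b, i0 = f,
            agree = sum(merged$injected_category == merged$category),
            total = nrow(merged))
    }
    .studyCache$grid <- do.call(rbind, rows)
    .studyCache$grid
}
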