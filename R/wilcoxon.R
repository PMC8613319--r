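# Paired Wilcoxon signed-rank test with an exact small-sample null
# distribution (dynamic programming over all 2^n sign assignments, midranks
# for ties) and a tie-corrected normal approximation for larger samples.

# Exact null distribution of 2*W over doubled midranks (integers).
# Returns probabilities for 2W = 0..sum(ranks2).
.signedRankDistribution <- function(ranks2) {
    S <- sum(ranks2)
    f <- numeric(S + 1)
    f[1] <- 1
    for (r in ranks2) {
        g <- f
        idx <- (r + 1):(S + 1)
        g[idx] <- g[idx] + f[idx - r]
        f <- g
    }
    f / sum(f)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired values (or on differences directly).
#' For small samples the p-value is exact: the full null distribution of the
#' positive-rank sum over all 2^n equiprobable sign assignments, with
#' midranks for tied absolute differences. Above the exact limit a
#' tie-corrected normal approximation with continuity correction is used;
#' \code{mode = "auto"} switches at n = 20. Zero differences are dropped
#' before ranking by default (Wilcoxon's rule); Pratt's method (rank with
#' zeros, then discard their ranks) is available. If every difference is
#' zero the result is degenerate: p = 1 with an undefined statistic, not an
#' error.
#'
#' @param x first paired sample, or the differences when \code{y} is NULL.
#' @param y optional second paired sample; differences are \code{x - y}.
#' @param mode \code{"auto"}, \code{"exact"} or \code{"normal"}.
#' @param zeros zero-difference policy: \code{"wilcoxon"} (drop) or
#'   \code{"pratt"}.
#' @param exactLimit largest n for which \code{"auto"} stays exact.
#' @return an object of class \code{htest}: statistic \code{V} (positive
#'   rank sum), \code{p.value}, \code{n} (pairs used after zero handling),
#'   \code{method}, and \code{degenerate} flag.
#' @examples
#' wilcoxonSignedRank(c(1.2, 0.8, 1.1, 0.9, 1.4, 1.0))  # all positive, n = 6
#' @export
wilcoxonSignedRank <- function(x, y = NULL,
                               mode = c("auto", "exact", "normal"),
                               zeros = c("wilcoxon", "pratt"),
                               exactLimit = 20L) {
    mode <- match.arg(mode)
    zeros <- match.arg(zeros)
    d <- if (is.null(y)) x else x - y
    if (any(!is.finite(d))) stop("differences must be finite")
    if (!length(d)) stop("at least one pair is required")

    out <- list(statistic = c(V = NA_real_), p.value = 1, n = 0L,
                alternative = "two.sided",
                method = "Paired Wilcoxon signed-rank test",
                data.name = deparse(substitute(x)), degenerate = TRUE)
    class(out) <- "htest"

    if (all(d == 0)) {
        warning("all differences are zero; degenerate result with p = 1")
        return(out)
    }

    if (zeros == "wilcoxon") {
        dd <- d[d != 0]
        ranks <- rank(abs(dd))
    } else {
        ranks <- rank(abs(d))
        keep <- d != 0
        dd <- d[keep]
        ranks <- ranks[keep]
    }
    n <- length(dd)
    if (n < 2L) warning("fewer than 2 non-zero differences; p is uninformative")
    W <- sum(ranks[dd > 0])

    useExact <- mode == "exact" || (mode == "auto" && n <= exactLimit)
    if (useExact) {
        ranks2 <- as.integer(round(2 * ranks))
        f <- .signedRankDistribution(ranks2)
        w2 <- as.integer(round(2 * W))
        pLe <- sum(f[seq_len(w2 + 1L)])
        pGe <- sum(f[(w2 + 1L):length(f)])
        p <- min(1, 2 * min(pLe, pGe))
        method <- "Paired Wilcoxon signed-rank test (exact)"
    } else {
        mu <- n * (n + 1) / 4
        tie <- table(ranks)
        sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
            sum(tie^3 - tie) / 48
        cc <- sign(W - mu) * 0.5
        z <- (W - mu - cc) / sqrt(sigma2)
        p <- min(1, 2 * stats::pnorm(-abs(z)))
        method <- "Paired Wilcoxon signed-rank test (normal approximation)"
    }
    out$statistic <- c(V = W)
    out$p.value <- max(p, .Machine$double.xmin)
    out$n <- n
    out$method <- method
    out$degenerate <- FALSE
    out
}

#' Annotate relative-MAR tables with significance
#'
#' Convenience wrapper around \code{\link{buildTables}} that flags every
#' comparison cell at a two-sided significance level.
#'
#' @param records long record table with categories.
#' @param references reference-value table.
#' @param alpha two-sided significance level.
#' @param aggregation delta V aggregation mode.
#' @return as \code{\link{buildTables}}, with a logical \code{significant}
#'   column added to both tables.
#' @export
compareAll <- function(records, references = referenceValues(),
                       alpha = 0.05, aggregation = "ratio_of_means") {
    res <- buildTables(records, references, aggregation)
    res$table3$significant <- !is.na(res$table3$p_value) &
        res$table3$p_value < alpha
    res$table4$significant <- !is.na(res$table4$p_value) &
        res$table4$p_value < alpha
    res
}
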