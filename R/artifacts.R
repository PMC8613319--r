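# Artifact corruption and correction emulation in the projection domain:
# quadratic beam hardening on the metal trace, Poisson photon starvation,
# linear-interpolation MAR inpainting, and VMI bright-streak injection.

# Flux at or above this is treated as noiseless (photon noise negligible).
.FLUX_NOISELESS <- 1e10

# Gaussian blur of each sinogram row along the detector axis (sigma in
# bins), via shifted sums with edge clamping disabled (zero padding).
.blurAlongBins <- function(x, sigmaBins) {
    if (sigmaBins <= 0) return(x)
    half <- max(1L, ceiling(3 * sigmaBins))
    w <- exp(-0.5 * ((-half):half / sigmaBins)^2)
    w <- w / sum(w)
    nb <- ncol(x)
    out <- matrix(0, nrow(x), nb)
    for (k in (-half):half) {
        src <- seq_len(nb) - k
        ok <- src >= 1L & src <= nb
        out[, ok] <- out[, ok] + w[k + half + 1L] * x[, src[ok]]
    }
    out
}

# Poisson draws with a normal fallback for large means (rpois overflows there;
# at such means the normal approximation error is far below the noise floor).
.rcounts <- function(lambda) {
    out <- numeric(length(lambda))
    big <- lambda > 1e7
    if (any(!big)) out[!big] <- rpois(sum(!big), lambda[!big])
    if (any(big)) out[big] <- round(stats::rnorm(sum(big), lambda[big],
                                                 sqrt(lambda[big])))
    pmax(out, 0)
}

#' Corrupt a sinogram with beam hardening and photon starvation
#'
#' Emulates the two artifact mechanisms of polychromatic CT near metal.
#' Beam hardening: on metal-trace rays the line integral p is depressed by
#' beta * m^2, where m is the attenuation-weighted metal path in cm —
#' depressed projections reconstruct as dark streaks. The depression
#' saturates smoothly toward \code{maxDepression} (default 85 percent) of
#' the ray's water-equivalent attenuation: the spectral shift can only
#' displace a fraction of the non-metal signal, and the bound keeps long
#' through-implant paths from producing nonphysical negative line
#' integrals. Photon starvation:
#' detector counts are drawn Poisson with mean i0 * exp(-p) and re-logged
#' (counts are clamped below at 0.25 so fully starved rays stay finite);
#' rays through much metal become noise-dominated. At
#' \code{i0 >= 1e10} photon noise is negligible and the sampling step is
#' skipped, making the high-flux limit exact. Deterministic given
#' \code{seed}; the caller's RNG state is restored on exit.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param severity named numeric with \code{beta} (>= 0), \code{i0} (> 0) and
#'   \code{gamma} (>= 0; unused here, consumed by
#'   \code{\link{vmiBrightStreaks}}).
#' @param seed integer seed for the photon-noise draw.
#' @param maxDepression saturation bound on the beam-hardening depression,
#'   as a fraction of the ray's water-equivalent line integral, in (0, 1).
#' @param penumbraMM Gaussian sigma (mm, along the detector axis) of the
#'   scatter penumbra through which the depression spills slightly beyond
#'   the metal trace; 0 disables the spill.
#' @return the corrupted \linkS4class{Sinogram}.
#' @export
setMethod("corruptSinogram", "Sinogram",
          function(sino, severity, seed = 1L, maxDepression = 0.85,
                   penumbraMM = 2.5) {
    beta <- unname(severity["beta"])
    i0 <- unname(severity["i0"])
    if (is.na(beta) || beta < 0) stop("severity beta must be >= 0")
    if (is.na(i0) || i0 <= 0) stop("severity i0 must be > 0")
    if (!is.na(severity["gamma"]) && severity["gamma"] < 0)
        stop("severity gamma must be >= 0")

    p <- sino@values
    trace <- metalTrace(sino)
    if (beta > 0 && any(trace)) {
        mCM <- sino@metalPath / 10
        # the depression saturates smoothly toward maxDepression times the
        # ray's water-equivalent attenuation (total minus the metal part):
        # equal to beta*m^2 while small, bounded by the non-metal signal the
        # spectral shift can actually displace, and smooth across the trace
        metalP <- 10 * sino@muWater * sino@metalPath
        cap <- maxDepression * pmax(p - metalP, 0)
        raw <- beta * mCM^2
        dep <- ifelse(cap > 0 & raw > 0,
                      cap * (1 - exp(-raw / pmax(cap, 1e-12))), 0)
        # scatter penumbra: part of the spectral error spills onto rays just
        # outside the metal shadow (detector-axis Gaussian tail). Projection-
        # domain MAR inpainting only repairs the trace, so this tail is the
        # beta-scaled residual artifact that survives MAR.
        dep <- .blurAlongBins(dep, penumbraMM / sino@detSpacing)
        p <- p - dep
    }
    if (i0 < .FLUX_NOISELESS) {
        if (exists(".Random.seed", envir = globalenv())) {
            oldSeed <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
        }
        set.seed(as.integer(seed))
        lambda <- i0 * exp(-p)
        counts <- .rcounts(lambda)
        p <- matrix(-log(pmax(counts, 0.25) / i0), nrow(p), ncol(p))
    }
    out <- sino
    out@values <- p
    out
})

# Replace metal-trace bins by interpolation across the trace from the
# untraced bins (anchors are never modified, so the operation is a
# projection: re-applying it reproduces the same values bit for bit).
.bridgeTrace <- function(sino, method = "spline", spar = 0.6) {
    trace <- metalTrace(sino)
    v <- sino@values
    idx <- seq_len(ncol(v))
    for (a in which(rowSums(trace) > 0)) {
        tr <- trace[a, ]
        if (all(tr)) {
            warning("metal trace covers the whole detector at angle index ",
                    a, "; filling with zeros")
            v[a, ] <- 0
            next
        }
        v[a, tr] <- if (method == "spline") {
            fit <- stats::smooth.spline(idx[!tr], v[a, !tr], spar = spar)
            stats::predict(fit, idx[tr])$y
        } else {
            approx(idx[!tr], v[a, !tr], xout = idx[tr], rule = 2)$y
        }
    }
    out <- sino
    out@values <- v
    out
}

#' Emulate projection-domain metal artifact reduction by trace inpainting
#'
#' Projection-completion MAR in the style of prior-based orthopedic MAR
#' algorithms. The default (\code{method = "prior"}) proceeds in two
#' deterministic stages: (1) bridge the metal-trace bins of each projection
#' with a smoothing spline fitted to the untraced bins; (2) reconstruct
#' that bridged sinogram, classify the image into a prior (air stays air,
#' water-like shading is flattened to 0 HU, bone-density structure and the
#' PMMA shell are kept), forward-project the prior, and replace the trace
#' bins with the prior's projections. Stage 2 restores the structure the
#' plain bridge erases — pellets between bilateral implants lie inside the
#' merged traces for most angles and would otherwise lose most of their
#' contrast — while flattening residual streak shading along trace
#' directions. Pure bridge variants are available as \code{"spline"} and
#' \code{"linear"}.
#'
#' Untraced bins are never modified, and both stages depend only on
#' untraced data, so the operation is idempotent (bit-identical on
#' re-application) and the identity on sinograms without metal; the
#' scatter penumbra just outside the trace is untouched and survives as
#' the beta-scaled residual artifact. The reconstructed MAR image does not
#' re-insert the metal itself. If the trace covers an entire detector row,
#' the row is filled with zeros and a warning names the angle.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param method \code{"prior"} (default), \code{"spline"} or
#'   \code{"linear"}.
#' @param spar smoothing parameter of the stage-1 spline fit (see
#'   \code{\link[stats]{smooth.spline}}).
#' @param priorIter number of prior-reprojection refinement passes.
#' @return the inpainted \linkS4class{Sinogram}.
#' @export
setMethod("applyOMAREmulation", "Sinogram",
          function(sino, method = c("prior", "spline", "linear"),
                   spar = 0.6, priorIter = 1L) {
    method <- match.arg(method)
    trace <- metalTrace(sino)
    if (!any(trace)) return(sino)
    out <- .bridgeTrace(sino, if (method == "linear") "linear" else "spline",
                        spar)
    if (method != "prior") return(out)
    dx <- out@pixelSpacing[1]
    for (k in seq_len(max(1L, as.integer(priorIter)))) {
        rec <- reconstructFBP(out, omar = "on")
        px <- pixels(rec)
        # body support per image row (the phantom is convex): everything
        # between the outermost clearly-attenuating pixels is interior, so
        # deep dark shading inside the body is flattened to water rather
        # than misclassified as air
        inside <- matrix(FALSE, nrow(px), ncol(px))
        for (r in seq_len(nrow(px))) {
            w <- which(px[r, ] > -300)
            if (length(w) >= 2L) inside[r, w[1]:w[length(w)]] <- TRUE
        }
        prior <- ifelse(!inside, -1000, ifelse(px < 100, 0, px))
        pp <- cpp_forward_project(huToMu(prior), out@angles,
                                  ncol(out@values), dx, out@detSpacing,
                                  dx / 2)
        out@values[trace] <- pp[trace]
    }
    out
})

#' Add VMI bright streaks to a corrupted sinogram
#'
#' High-keV virtual monochromatic images can introduce secondary bright
#' streaks near metal. Emulated by over-weighting the metal-trace residual
#' on the projection angles with the widest metal trace — the directions of
#' maximal spectral hardening, which with bilateral implants are the rays
#' passing through both prostheses. On the selected angles (the widest
#' fraction 1/every of trace-bearing angles) the positive part of the
#' trace's excess over its inpainting bridge is amplified by gamma. After
#' filtered back projection these over-weighted directions appear as
#' positive streaks radiating between the implants — which is where
#' severely affected pellets lie. With \code{gamma = 0} the sinogram is
#' unchanged. Because the additions live on the metal trace, subsequent
#' MAR inpainting removes them — matching the observation that VMI
#' combined with MAR shows no bright streaks.
#'
#' @param sino a corrupted VMI \linkS4class{Sinogram}.
#' @param gamma bright-streak amplification of the positive trace residual,
#'   >= 0 (dimensionless).
#' @param every reciprocal of the fraction of trace-bearing angles that
#'   receive streaks (the widest-trace angles are chosen).
#' @return the \linkS4class{Sinogram} with bright-streak bias added.
#' @export
setMethod("vmiBrightStreaks", "Sinogram", function(sino, gamma, every = 6L) {
    if (gamma < 0) stop("gamma must be >= 0")
    if (gamma == 0) return(sino)
    every <- max(1L, as.integer(every))
    trace <- metalTrace(sino)
    width <- rowSums(trace)
    cand <- which(width > 0)
    if (!length(cand)) return(sino)
    nPick <- max(1L, length(cand) %/% every)
    pick <- cand[order(width[cand], decreasing = TRUE)][seq_len(nPick)]
    bridged <- .bridgeTrace(sino)
    resid <- pmax(sino@values - bridged@values, 0)
    mask <- matrix(FALSE, nrow(trace), ncol(trace))
    mask[pick, ] <- trace[pick, ]
    out <- sino
    out@values[mask] <- out@values[mask] + gamma * resid[mask]
    out
})
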