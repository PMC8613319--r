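# Phantom geometry: a water-filled PMMA rounded-rectangle body carrying 18
# bone-density pellets (9 per side: 2 acetabular-zone, 7 femoral-zone) and
# optional hip prosthesis components (cup, head, stem) per side.

# Hip joint centre (right side; the left is mirrored in x), mm.
.HIP_CENTRE <- c(x = 85, y = 74)
.HEAD_RADIUS <- 14
.CUP_RADII <- c(inner = 22, outer = 29)
.STEM_TOP <- c(x = 85, y = 58)
.STEM_BOTTOM <- c(x = 85, y = -40)
.STEM_RADIUS <- 7

# Materials considered metallic (drive the metal trace and beam hardening).
.METAL_HU_MIN <- 3000

#' Default pellet layout
#'
#' Returns the packaged default pellet layout: 18 pellets of 10 mm diameter,
#' mirrored left/right, two per side near the acetabular cup and seven along
#' the femoral stem. The published phantom localises pellets to radiographic
#' zones only, so in-plane millimetre coordinates are a package default and
#' can be overridden via \code{\link{phantomSpec}}.
#'
#' @return data.frame with columns \code{label}, \code{x_mm}, \code{y_mm},
#'   \code{diameter_mm}.
#' @export
defaultPelletLayout <- function() {
    path <- system.file("extdata", "pellet_layout.csv", package = "phantoMAR",
                        mustWork = TRUE)
    read.csv(path, stringsAsFactors = FALSE)
}

#' Default artifact-severity parameters
#'
#' Beam-hardening coefficient \code{beta}, incident flux \code{i0} and VMI
#' bright-streak amplitude \code{gamma} used by the simulator unless
#' overridden. Chosen so that, at the default geometry, severe (sub-zero HU)
#' pellets arise only with bilateral prostheses, unilateral artifacts stay
#' mild, and the no-prosthesis pellet noise is close to 7 HU.
#'
#' @return named numeric vector (\code{beta}, \code{i0}, \code{gamma}).
#' @export
defaultSeverity <- function() {
    c(beta = 0.6, i0 = 6.5e9, gamma = 1.2)
}

#' Construct a phantom specification
#'
#' Builds and validates a \linkS4class{PhantomSpec}. Defaults follow the
#' simulated study design: 330 mm field of view on a 512 x 512 matrix, a
#' 320 x 290 mm water-filled PMMA body, 18 bone-density pellets of 10 mm
#' diameter (nominal 248.4 HU on conventional images, 150.4 HU on 130 keV
#' virtual monochromatic images), and prosthesis component materials matching
#' the study (unilateral: UHMWPE cup, ZTA head, TiAlV stem; bilateral adds a
#' left prosthesis with CoCrMo cup and head and TiAlV stem, and a CoCrMo stem
#' on the right).
#'
#' @param prosthesisConfig \code{"none"}, \code{"unilateral"} or
#'   \code{"bilateral"}.
#' @param fovMM field of view, mm.
#' @param matrixSize image matrix size, pixels per side.
#' @param bodyMM body width and depth, mm.
#' @param pelletLayout pellet layout data.frame
#'   (see \code{\link{defaultPelletLayout}}).
#' @param componentMaterials named list (\code{right}, \code{left}) of named
#'   character vectors (\code{cup}, \code{head}, \code{stem}).
#' @param materialHU named numeric of nominal HU per material (water must
#'   be 0).
#' @param pelletHU named numeric, nominal pellet HU per reconstruction family.
#' @param severity named numeric (\code{beta}, \code{i0}, \code{gamma}); see
#'   \code{\link{defaultSeverity}}.
#' @param vmi named numeric VMI emulation parameters: \code{beta_ratio}
#'   (residual beam hardening at 130 keV relative to conventional),
#'   \code{flux_ratio} (effective flux, sets the VMI noise level),
#'   \code{metal_hu_scale} (metal HU scale at 130 keV), \code{streak_every}
#'   (bright streaks on every k-th metal-trace angle).
#' @param cornerRadiusMM body corner radius, mm.
#' @param wallMM PMMA wall thickness, mm.
#' @param seed integer acquisition seed.
#' @return a validated \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec("bilateral", matrixSize = 128L)
#' spec
#' @export
phantomSpec <- function(prosthesisConfig = c("none", "unilateral", "bilateral"),
                        fovMM = 330,
                        matrixSize = 512L,
                        bodyMM = c(320, 290),
                        pelletLayout = defaultPelletLayout(),
                        componentMaterials = list(
                            right = c(cup = "uhmwpe", head = "zta",
                                      stem = "tialv"),
                            left = c(cup = "cocrmo", head = "cocrmo",
                                     stem = "tialv")),
                        materialHU = c(water = 0, pmma = 120, uhmwpe = 80,
                                       zta = 10000, tialv = 8000,
                                       cocrmo = 12000),
                        pelletHU = c(conventional = 248.4, vmi130 = 150.4),
                        severity = defaultSeverity(),
                        vmi = c(beta_ratio = 0.1, flux_ratio = 0.48,
                                metal_hu_scale = 0.55, streak_every = 5),
                        cornerRadiusMM = 50,
                        wallMM = 8,
                        seed = 1L) {
    prosthesisConfig <- match.arg(prosthesisConfig)
    if (identical(prosthesisConfig, "bilateral") &&
        missing(componentMaterials)) {
        # the bilateral study phantom swaps the right stem to CoCrMo
        componentMaterials$right["stem"] <- "cocrmo"
    }
    new("PhantomSpec",
        fovMM = as.numeric(fovMM),
        matrixSize = as.integer(matrixSize),
        bodyMM = as.numeric(bodyMM),
        cornerRadiusMM = as.numeric(cornerRadiusMM),
        wallMM = as.numeric(wallMM),
        pelletLayout = pelletLayout,
        prosthesisConfig = prosthesisConfig,
        componentMaterials = componentMaterials,
        materialHU = materialHU,
        pelletHU = pelletHU,
        severity = severity,
        vmi = vmi,
        seed = as.integer(seed))
}

# ---- geometric primitives (signed distances, mm; negative = inside) --------

# Prosthesis components of a spec as a list of primitives, each a list with
# $name, $type (circle/capsule/halfannulus), geometry fields and $material.
prosthesisPrimitives <- function(spec) {
    cfg <- spec@prosthesisConfig
    if (cfg == "none") return(list())
    sides <- if (cfg == "unilateral") "right" else c("right", "left")
    prims <- list()
    for (side in sides) {
        sgn <- if (side == "right") 1 else -1
        mats <- spec@componentMaterials[[side]]
        cx <- sgn * .HIP_CENTRE["x"]
        prims <- c(prims, list(
            list(name = paste0(side, "_stem"), type = "capsule",
                 a = c(sgn * .STEM_TOP["x"], .STEM_TOP["y"]),
                 b = c(sgn * .STEM_BOTTOM["x"], .STEM_BOTTOM["y"]),
                 r = .STEM_RADIUS, material = mats[["stem"]]),
            list(name = paste0(side, "_head"), type = "circle",
                 c = c(cx, .HIP_CENTRE["y"]), r = .HEAD_RADIUS,
                 material = mats[["head"]]),
            list(name = paste0(side, "_cup"), type = "halfannulus",
                 c = c(cx, .HIP_CENTRE["y"]),
                 r0 = .CUP_RADII["inner"], r1 = .CUP_RADII["outer"],
                 material = mats[["cup"]])))
    }
    prims
}

# Signed distance from points (x, y) to one primitive.
primitiveDistance <- function(p, x, y) {
    switch(p$type,
        circle = sqrt((x - p$c[1])^2 + (y - p$c[2])^2) - p$r,
        capsule = {
            abx <- p$b[1] - p$a[1]; aby <- p$b[2] - p$a[2]
            len2 <- abx^2 + aby^2
            t <- pmin(1, pmax(0, ((x - p$a[1]) * abx + (y - p$a[2]) * aby) / len2))
            sqrt((x - p$a[1] - t * abx)^2 + (y - p$a[2] - t * aby)^2) - p$r
        },
        halfannulus = {
            rr <- sqrt((x - p$c[1])^2 + (y - p$c[2])^2)
            mid <- (p$r0 + p$r1) / 2
            dAnn <- abs(rr - mid) - (p$r1 - p$r0) / 2
            # keep the upper half (cup opens downward onto the head)
            pmax(dAnn, p$c[2] - y)
        },
        stop("unknown primitive type: ", p$type))
}

.roundedRectDistance <- function(x, y, halfW, halfH, r) {
    qx <- abs(x) - (halfW - r)
    qy <- abs(y) - (halfH - r)
    mx <- pmax(qx, 0); my <- pmax(qy, 0)
    sqrt(mx^2 + my^2) + pmin(pmax(qx, qy), 0) - r
}

# Antialiased coverage (1 inside, 0 outside, linear ramp one pixel wide).
.coverage <- function(d, dx) pmin(1, pmax(0, 0.5 - d / dx))

#' Rasterize a phantom specification to a ground-truth slice
#'
#' Paints the artifact-free coronal slice of a phantom: air background
#' (-1000 HU), PMMA body shell, water interior (0 HU), the 18 pellets at
#' their nominal HU for the requested reconstruction family, and the
#' prosthesis components at their material HU (scaled on 130 keV virtual
#' monochromatic images, where metals attenuate less). Edges are antialiased
#' within one pixel by signed-distance coverage.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param reconstruction \code{"conventional"} or \code{"vmi130"}.
#' @return a \linkS4class{SliceImage} with O-MAR state \code{"off"}.
#' @examples
#' img <- rasterizePhantom(phantomSpec("unilateral", matrixSize = 128L))
#' range(pixels(img))
#' @export
setMethod("rasterizePhantom", "PhantomSpec",
          function(spec, reconstruction = "conventional") {
    reconstruction <- match.arg(reconstruction, c("conventional", "vmi130"))
    validObject(spec)
    n <- spec@matrixSize
    dx <- spec@fovMM / n
    ax <- ((seq_len(n)) - (n + 1) / 2) * dx
    x <- matrix(ax, n, n, byrow = TRUE)
    y <- matrix(rev(ax), n, n)

    hu <- matrix(-1000, n, n)
    paint <- function(img, d, value) {
        cov <- .coverage(d, dx)
        img * (1 - cov) + value * cov
    }

    matHU <- spec@materialHU
    metalScale <- if (reconstruction == "vmi130")
        unname(spec@vmi["metal_hu_scale"]) else 1
    # PMMA HU barely changes with keV; metals drop substantially
    shellHU <- unname(matHU["pmma"])

    halfW <- spec@bodyMM[1] / 2; halfH <- spec@bodyMM[2] / 2
    dBody <- .roundedRectDistance(x, y, halfW, halfH, spec@cornerRadiusMM)
    hu <- paint(hu, dBody, shellHU)
    w <- spec@wallMM
    dInner <- .roundedRectDistance(x, y, halfW - w, halfH - w,
                                   max(spec@cornerRadiusMM - w, 1))
    hu <- paint(hu, dInner, matHU["water"])

    pelHU <- unname(spec@pelletHU[reconstruction])
    lay <- spec@pelletLayout
    for (i in seq_len(nrow(lay))) {
        d <- sqrt((x - lay$x_mm[i])^2 + (y - lay$y_mm[i])^2) -
            lay$diameter_mm[i] / 2
        hu <- paint(hu, d, pelHU)
    }

    for (p in prosthesisPrimitives(spec)) {
        v <- unname(matHU[p$material])
        if (v >= .METAL_HU_MIN) v <- v * metalScale
        hu <- paint(hu, primitiveDistance(p, x, y), v)
    }

    new("SliceImage",
        pixels = hu,
        pixelSpacing = c(dx, dx),
        condition = c(config = spec@prosthesisConfig,
                      reconstruction = reconstruction, omar = "off"),
        provenance = sprintf("rasterizePhantom ground truth; seed %d",
                             spec@seed))
})

# Water mask of a ground-truth slice: interior pixels whose truth is water.
waterMask <- function(truth) {
    px <- pixels(truth)
    abs(px) < 0.5
}

#' Streak-artifact index
#'
#' Mean absolute HU deviation from the artifact-free ground truth over water
#' pixels — the simulator's internal quality-control measure of streak
#' severity.
#'
#' @param image reconstructed \linkS4class{SliceImage}.
#' @param truth ground-truth \linkS4class{SliceImage} from
#'   \code{\link{rasterizePhantom}}.
#' @return mean absolute deviation in HU over water pixels.
#' @export
streakIndex <- function(image, truth) {
    stopifnot(is(image, "SliceImage"), is(truth, "SliceImage"))
    m <- waterMask(truth)
    mean(abs(pixels(image)[m] - pixels(truth)[m]))
}
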