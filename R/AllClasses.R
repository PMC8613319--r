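#' PhantomSpec: geometry and acquisition parameters for one simulated phantom
#'
#' Describes the water-filled PMMA body (a rounded rectangle), the 18
#' bone-density pellets (9 per side, acetabular and femoral zones), the
#' prosthesis configuration with per-component materials, the HU assigned to
#' each material, and the artifact-severity parameters of the simulated
#' acquisition.
#'
#' Severity parameters: \code{beta} (beam-hardening coefficient, projection
#' units per cm^2 of attenuation-weighted metal path, squared), \code{i0}
#' (incident photon flux per detector bin; lower means more photon
#' starvation), \code{gamma} (bright-streak amplitude used by the VMI
#' emulation, projection units per cm of metal path).
#'
#' @slot fovMM field of view in mm (square).
#' @slot matrixSize reconstruction matrix size in pixels per side.
#' @slot bodyMM width and depth of the PMMA body in mm.
#' @slot cornerRadiusMM corner radius of the rounded-rectangle body, mm.
#' @slot wallMM PMMA wall thickness, mm.
#' @slot pelletLayout data.frame with columns \code{label}, \code{x_mm},
#'   \code{y_mm}, \code{diameter_mm}; 18 rows, labels L1..L9, R1..R9.
#' @slot prosthesisConfig one of \code{"none"}, \code{"unilateral"},
#'   \code{"bilateral"}.
#' @slot componentMaterials named list with elements \code{right} and
#'   \code{left}, each a named character vector (cup, head, stem) of material
#'   labels.
#' @slot materialHU named numeric of nominal HU per material on conventional
#'   images; water must map to 0.
#' @slot pelletHU named numeric: nominal pellet HU per reconstruction family
#'   (\code{conventional}, \code{vmi130}).
#' @slot severity named numeric: \code{beta}, \code{i0}, \code{gamma}.
#' @slot vmi named numeric: \code{beta_ratio} (VMI beam-hardening ratio r),
#'   \code{flux_ratio} (VMI flux relative to conventional),
#'   \code{metal_hu_scale} (metal HU scale at 130 keV),
#'   \code{streak_every} (bright streaks drawn on every k-th projection angle).
#' @slot seed integer RNG seed for the acquisition.
#' @export
setClass("PhantomSpec", representation(
    fovMM = "numeric",
    matrixSize = "integer",
    bodyMM = "numeric",
    cornerRadiusMM = "numeric",
    wallMM = "numeric",
    pelletLayout = "data.frame",
    prosthesisConfig = "character",
    componentMaterials = "list",
    materialHU = "numeric",
    pelletHU = "numeric",
    severity = "numeric",
    vmi = "numeric",
    seed = "integer"
))

setValidity("PhantomSpec", function(object) {
    msg <- character(0)
    if (length(object@fovMM) != 1L || object@fovMM <= 0)
        msg <- c(msg, "fovMM must be a single positive number")
    if (length(object@matrixSize) != 1L || object@matrixSize < 32L)
        msg <- c(msg, "matrixSize must be a single integer >= 32")
    if (length(object@bodyMM) != 2L || any(object@bodyMM <= 0))
        msg <- c(msg, "bodyMM must be two positive numbers (width, depth)")
    lay <- object@pelletLayout
    need <- c("label", "x_mm", "y_mm", "diameter_mm")
    if (!all(need %in% names(lay))) {
        msg <- c(msg, "pelletLayout must have columns label, x_mm, y_mm, diameter_mm")
    } else {
        if (nrow(lay) != 18L)
            msg <- c(msg, "pelletLayout must have exactly 18 pellets")
        if (anyDuplicated(lay$label))
            msg <- c(msg, "pellet labels must be unique")
        # pellets inside the body interior
        hw <- object@bodyMM[1] / 2 - object@wallMM
        hd <- object@bodyMM[2] / 2 - object@wallMM
        r <- lay$diameter_mm / 2
        out <- abs(lay$x_mm) + r > hw | abs(lay$y_mm) + r > hd
        if (any(out))
            msg <- c(msg, paste0("pellets outside the body interior: ",
                                 paste(lay$label[out], collapse = ", ")))
        # pairwise overlap
        if (nrow(lay) > 1L) {
            d <- as.matrix(stats::dist(lay[, c("x_mm", "y_mm")]))
            lim <- outer(r, r, "+")
            diag(d) <- Inf
            if (any(d < lim))
                msg <- c(msg, "pellets overlap each other")
        }
        # overlap with prosthesis components
        prim <- prosthesisPrimitives(object)
        for (p in prim) {
            dd <- primitiveDistance(p, lay$x_mm, lay$y_mm)
            hit <- dd < r
            if (any(hit))
                msg <- c(msg, paste0("pellet(s) ",
                                     paste(lay$label[hit], collapse = ", "),
                                     " overlap prosthesis component '", p$name, "'"))
        }
    }
    if (!object@prosthesisConfig %in% c("none", "unilateral", "bilateral"))
        msg <- c(msg, "prosthesisConfig must be none, unilateral or bilateral")
    if (is.na(object@materialHU["water"]) || object@materialHU["water"] != 0)
        msg <- c(msg, "materialHU must assign water = 0 HU")
    if (!all(c("conventional", "vmi130") %in% names(object@pelletHU)))
        msg <- c(msg, "pelletHU must name conventional and vmi130")
    sev <- object@severity
    if (!all(c("beta", "i0", "gamma") %in% names(sev))) {
        msg <- c(msg, "severity must name beta, i0 and gamma")
    } else {
        if (sev["beta"] < 0 || sev["gamma"] < 0)
            msg <- c(msg, "severity beta and gamma must be >= 0")
        if (sev["i0"] <= 0)
            msg <- c(msg, "severity i0 must be > 0")
    }
    if (!all(c("beta_ratio", "flux_ratio", "metal_hu_scale", "streak_every") %in%
             names(object@vmi))) {
        msg <- c(msg, "vmi must name beta_ratio, flux_ratio, metal_hu_scale, streak_every")
    } else if (object@vmi["beta_ratio"] < 0 || object@vmi["beta_ratio"] > 1) {
        msg <- c(msg, "vmi beta_ratio must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' SliceImage: a 2-D CT slice in Hounsfield units
#'
#' A square HU image with its pixel spacing and the study condition it
#' represents (prosthesis configuration, reconstruction family, O-MAR state).
#' Air background is -1000 HU, water 0 HU.
#'
#' @slot pixels numeric matrix of HU values (square).
#' @slot pixelSpacing numeric length 2, mm per pixel (dx, dy).
#' @slot condition named character: \code{config}, \code{reconstruction},
#'   \code{omar}.
#' @slot provenance free-text provenance (generator, seed).
#' @export
setClass("SliceImage", representation(
    pixels = "matrix",
    pixelSpacing = "numeric",
    condition = "character",
    provenance = "character"
))

setValidity("SliceImage", function(object) {
    msg <- character(0)
    px <- object@pixels
    if (nrow(px) != ncol(px))
        msg <- c(msg, "pixels must be a square matrix")
    if (!all(is.finite(px)))
        msg <- c(msg, "pixels must be finite")
    if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
        msg <- c(msg, "pixelSpacing must be two positive numbers")
    if (!all(c("config", "reconstruction", "omar") %in% names(object@condition)))
        msg <- c(msg, "condition must name config, reconstruction and omar")
    if (length(msg)) msg else TRUE
})

#' Sinogram: parallel-beam line integrals with a metal trace
#'
#' Holds the projection data (n_angles x n_bins line integrals of linear
#' attenuation, dimensionless), the projection angles, and the
#' attenuation-weighted metal path length per ray used to locate the metal
#' trace and to drive the beam-hardening model. Reconstruction geometry
#' (matrix size, pixel spacing) travels with the object so filtered back
#' projection is self-contained.
#'
#' @slot values numeric matrix, n_angles x n_bins.
#' @slot angles numeric, radians, uniform over [0, pi).
#' @slot metalPath numeric matrix, same shape; attenuation-weighted metal path
#'   per ray in mm (path length weighted by material HU / 10^4).
#' @slot detSpacing detector bin spacing, mm.
#' @slot matrixSize target reconstruction matrix, pixels.
#' @slot pixelSpacing target reconstruction pixel spacing, mm.
#' @slot muWater linear attenuation of water, mm^-1.
#' @slot traceThresholdMM weighted metal path above which a ray belongs to the
#'   metal trace, mm.
#' @slot condition condition labels inherited from the projected slice.
#' @export
setClass("Sinogram", representation(
    values = "matrix",
    angles = "numeric",
    metalPath = "matrix",
    detSpacing = "numeric",
    matrixSize = "integer",
    pixelSpacing = "numeric",
    muWater = "numeric",
    traceThresholdMM = "numeric",
    condition = "character"
))

setValidity("Sinogram", function(object) {
    msg <- character(0)
    if (!all(is.finite(object@values)))
        msg <- c(msg, "sinogram values must be finite")
    if (nrow(object@values) != length(object@angles))
        msg <- c(msg, "one angle per sinogram row is required")
    if (!identical(dim(object@values), dim(object@metalPath)))
        msg <- c(msg, "metalPath must have the same shape as values")
    if (length(object@angles) &&
        (min(object@angles) < 0 || max(object@angles) >= pi))
        msg <- c(msg, "angles must lie in [0, pi)")
    if (length(msg)) msg else TRUE
})

#' ROITemplate: a standardized set of circular regions of interest
#'
#' Eighteen pellet ROIs (L1..L9, R1..R9) plus one background ROI (BG) in a
#' homogeneous section of water. Diameters may be given in mm
#' (\code{diameter_mm}) or fixed in pixels (\code{diameter_px}); a finite
#' pixel diameter takes precedence when the template is applied.
#'
#' @slot rois data.frame: \code{label}, \code{x_mm}, \code{y_mm},
#'   \code{diameter_mm}, \code{diameter_px}.
#' @slot frame coordinate convention tag; \code{"isocentre_mm"} means x to the
#'   right and y upward, origin at image centre.
#' @export
setClass("ROITemplate", representation(
    rois = "data.frame",
    frame = "character"
))

setValidity("ROITemplate", function(object) {
    msg <- character(0)
    r <- object@rois
    need <- c("label", "x_mm", "y_mm", "diameter_mm", "diameter_px")
    if (!all(need %in% names(r)))
        return("rois needs columns label, x_mm, y_mm, diameter_mm, diameter_px")
    if (sum(r$label == "BG") != 1L)
        msg <- c(msg, "exactly one BG ROI is required")
    pel <- setdiff(r$label, "BG")
    if (length(pel) != 18L)
        msg <- c(msg, "exactly 18 pellet ROIs are required")
    dm <- ifelse(is.finite(r$diameter_px), r$diameter_px, r$diameter_mm)
    if (any(!is.finite(dm) | dm <= 0))
        msg <- c(msg, "every ROI needs a positive diameter (mm or px)")
    if (length(msg)) msg else TRUE
})

#' MARComparison: one cell of a relative metal-artifact-reduction table
#'
#' Pairs the per-pellet normalized artifact deviations (delta V) of a
#' reconstruction and a standard reconstruction for one metric and artifact
#' category, together with the category-level relative MAR percentage and the
#' paired Wilcoxon signed-rank p-value.
#'
#' @slot metric one of \code{mean_hu}, \code{cnr}, \code{snr}, \code{noise}.
#' @slot category \code{mild} or \code{severe}.
#' @slot reconstruction label of the evaluated reconstruction.
#' @slot standardReconstruction label of the standard reconstruction.
#' @slot deltaRecon per-pellet delta V under the evaluated reconstruction.
#' @slot deltaStandard per-pellet delta V under the standard reconstruction.
#' @slot pelletId pellet-instance identifiers (pellet x configuration).
#' @slot relativeMARPct relative metal artifact reduction, percent.
#' @slot pValue two-sided paired Wilcoxon signed-rank p-value.
#' @slot n number of paired pellet-instances.
#' @slot aggregation \code{ratio_of_means} or \code{mean_of_ratios}.
#' @export
setClass("MARComparison", representation(
    metric = "character",
    category = "character",
    reconstruction = "character",
    standardReconstruction = "character",
    deltaRecon = "numeric",
    deltaStandard = "numeric",
    pelletId = "character",
    relativeMARPct = "numeric",
    pValue = "numeric",
    n = "integer",
    aggregation = "character"
))

setValidity("MARComparison", function(object) {
    msg <- character(0)
    if (length(object@deltaRecon) != length(object@deltaStandard))
        msg <- c(msg, "paired delta V vectors must have equal length")
    if (object@n < 1L)
        msg <- c(msg, "at least one paired pellet-instance is required")
    if (any(object@deltaRecon < 0, na.rm = TRUE) ||
        any(object@deltaStandard < 0, na.rm = TRUE))
        msg <- c(msg, "delta V values must be non-negative")
    if (is.finite(object@relativeMARPct) && object@relativeMARPct > 100)
        msg <- c(msg, "relative MAR cannot exceed 100 percent")
    if (length(msg)) msg else TRUE
})

#' PhantomStudy: all simulated images and ground truth of one study run
#'
#' The full condition grid of a simulated phantom study: 3 prosthesis
#' configurations x 2 reconstruction families x 2 O-MAR states, plus the
#' injected (noise-free) artifact category of every pellet-instance for
#' parameter-recovery checks.
#'
#' @slot images named list of \linkS4class{SliceImage}; names are
#'   \code{<config>_<reconstruction>_<omar>}.
#' @slot groundTruth data.frame: \code{pellet_id}, \code{config},
#'   \code{injected_category}, \code{noiseless_mean_hu}.
#' @slot specs named list of the \linkS4class{PhantomSpec} used per
#'   configuration.
#' @slot seed integer study seed.
#' @export
setClass("PhantomStudy", representation(
    images = "list",
    groundTruth = "data.frame",
    specs = "list",
    seed = "integer"
))

setValidity("PhantomStudy", function(object) {
    msg <- character(0)
    if (!all(vapply(object@images, is, logical(1), "SliceImage")))
        msg <- c(msg, "images must all be SliceImage objects")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PhantomSpec", function(object) {
    cat("PhantomSpec:", object@prosthesisConfig, "prosthesis configuration\n")
    cat("  FOV", object@fovMM, "mm on a", object@matrixSize, "x",
        object@matrixSize, "grid; body",
        paste(object@bodyMM, collapse = " x "), "mm\n")
    cat("  18 pellets, d =", object@pelletLayout$diameter_mm[1], "mm\n")
    sev <- object@severity
    cat(sprintf("  severity: beta = %.3g, I0 = %.3g, gamma = %.3g; seed = %d\n",
                sev["beta"], sev["i0"], sev["gamma"], object@seed))
})

setMethod("show", "SliceImage", function(object) {
    cond <- object@condition
    cat(sprintf("SliceImage %d x %d @ %.3f mm [%s / %s / O-MAR %s]\n",
                nrow(object@pixels), ncol(object@pixels),
                object@pixelSpacing[1],
                cond["config"], cond["reconstruction"], cond["omar"]))
    cat(sprintf("  HU range: %.1f .. %.1f\n",
                min(object@pixels), max(object@pixels)))
})

setMethod("show", "Sinogram", function(object) {
    cat(sprintf("Sinogram: %d angles x %d bins (det %.3f mm), metal trace on %d rays\n",
                nrow(object@values), ncol(object@values), object@detSpacing,
                sum(object@metalPath > object@traceThresholdMM)))
})

setMethod("show", "MARComparison", function(object) {
    cat(sprintf("MARComparison [%s, %s]: %s vs %s\n",
                object@metric, object@category,
                object@reconstruction, object@standardReconstruction))
    cat(sprintf("  relative MAR = %.1f%% (p = %.4g, n = %d, %s)\n",
                object@relativeMARPct, object@pValue, object@n,
                object@aggregation))
})

setMethod("show", "PhantomStudy", function(object) {
    cat("PhantomStudy with", length(object@images), "condition images, seed",
        object@seed, "\n")
    cat(" ", paste(names(object@images), collapse = "\n  "), "\n")
})
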