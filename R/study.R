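# The simulated study: for each prosthesis configuration, one conventional
# and one 130 keV VMI acquisition sharing the seed, each reconstructed with
# and without MAR inpainting -> 12 condition images in total.

#' Simulate one acquisition (all four reconstructions of one configuration)
#'
#' Runs the physics chain for a single phantom configuration: rasterize the
#' conventional and VMI ground truths, forward-project, corrupt (beam
#' hardening + photon starvation; the VMI branch uses the reduced
#' beam-hardening ratio and flux ratio from the spec and adds bright
#' streaks), then reconstruct each corrupted sinogram with and without the
#' O-MAR emulation. Both energy branches share the acquisition seed, as on a
#' dual-layer detector where VMI derive from the same acquisition.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param nAngles projection angles over [0, pi).
#' @param noiseless if TRUE the photon-starvation draw is skipped (infinite
#'   flux); used to define injected ground-truth artifact classes.
#' @param families \code{"both"} or \code{"conventional"} (skip the VMI
#'   branch, e.g. for the ground-truth label pass that only needs the
#'   conventional reconstruction).
#' @return list with elements \code{images} (named list of four
#'   \linkS4class{SliceImage}: \code{conventional_noomar},
#'   \code{conventional_omar}, \code{vmi130_noomar}, \code{vmi130_omar}),
#'   \code{truth} (ground-truth slices per family) and \code{sinograms}
#'   (corrupted sinograms per family).
#' @export
simulateAcquisition <- function(spec, nAngles = 360L, noiseless = FALSE,
                                families = c("both", "conventional")) {
    families <- match.arg(families)
    sev <- spec@severity
    if (noiseless) sev["i0"] <- 1e15

    truthConv <- rasterizePhantom(spec, "conventional")
    corrConv <- corruptSinogram(forwardProject(truthConv, nAngles = nAngles),
                                sev, seed = spec@seed)
    images <- list(
        conventional_noomar = reconstructFBP(corrConv, omar = "off"),
        conventional_omar = reconstructFBP(applyOMAREmulation(corrConv),
                                           omar = "on"))
    truth <- list(conventional = truthConv)
    sinos <- list(conventional = corrConv)

    if (families == "both") {
        vmiPar <- spec@vmi
        sevVMI <- c(beta = unname(sev["beta"] * vmiPar["beta_ratio"]),
                    i0 = unname(sev["i0"] * vmiPar["flux_ratio"]),
                    gamma = unname(sev["gamma"]))
        truthVMI <- rasterizePhantom(spec, "vmi130")
        corrVMI <- corruptSinogram(forwardProject(truthVMI,
                                                  nAngles = nAngles),
                                   sevVMI, seed = spec@seed)
        corrVMI <- vmiBrightStreaks(corrVMI, unname(sev["gamma"]),
                                    every = as.integer(vmiPar["streak_every"]))
        images$vmi130_noomar <- reconstructFBP(corrVMI, omar = "off")
        images$vmi130_omar <- reconstructFBP(applyOMAREmulation(corrVMI),
                                             omar = "on")
        truth$vmi130 <- truthVMI
        sinos$vmi130 <- corrVMI
    }
    list(images = images, truth = truth, sinograms = sinos)
}

#' Generate the full simulated study
#'
#' Emits all 12 condition images (3 prosthesis configurations x 2
#' reconstruction families x 2 O-MAR states) plus the injected ground-truth
#' artifact category of every pellet-instance, obtained by categorizing the
#' noise-free (infinite-flux) conventional reconstruction without MAR — the
#' deterministic artifact field the noisy measurements should recover. Fully
#' deterministic given \code{seed}.
#'
#' @param seed study seed; per-configuration acquisition seeds are derived
#'   from it.
#' @param matrixSize image matrix, pixels per side.
#' @param nAngles projection angles.
#' @param severity artifact severity parameters
#'   (see \code{\link{defaultSeverity}}).
#' @param cutoff HU cutoff separating unaffected from mildly affected
#'   pellets when deriving injected categories.
#' @param template ROI template used for the injected-category measurement;
#'   NULL picks the packaged default, switching from the 15-pixel to the
#'   6.75 mm ROI diameter on grids coarser than the 512 reference.
#' @param ... further arguments passed to \code{\link{phantomSpec}}.
#' @return a \linkS4class{PhantomStudy}.
#' @examples
#' \donttest{
#' study <- generateStudy(seed = 7L, matrixSize = 192L, nAngles = 120L)
#' names(studyImages(study))
#' }
#' @export
generateStudy <- function(seed = 1L, matrixSize = 512L, nAngles = 360L,
                          severity = defaultSeverity(), cutoff = 235,
                          template = NULL, ...) {
    seed <- as.integer(seed)
    if (is.null(template))
        template <- defaultROITemplate(useMM = matrixSize < 512L)
    configs <- c("none", "unilateral", "bilateral")
    specs <- list()
    images <- list()
    gt <- list()
    for (k in seq_along(configs)) {
        cfg <- configs[k]
        spec <- phantomSpec(cfg, matrixSize = matrixSize,
                            severity = severity,
                            seed = seed + k - 1L, ...)
        specs[[cfg]] <- spec
        acq <- simulateAcquisition(spec, nAngles = nAngles)
        names(acq$images) <- paste(cfg, names(acq$images), sep = "_")
        images <- c(images, acq$images)
        if (cfg != "none") {
            quiet <- simulateAcquisition(spec, nAngles = nAngles,
                                         noiseless = TRUE,
                                         families = "conventional")
            meas <- measureROIs(quiet$images$conventional_noomar, template)
            meas <- meas[meas$label != "BG", ]
            gt[[cfg]] <- data.frame(
                pellet_id = meas$label,
                config = cfg,
                injected_category = as.character(
                    categorize(meas$mean_hu, cutoff = cutoff)),
                noiseless_mean_hu = meas$mean_hu,
                stringsAsFactors = FALSE)
        }
    }
    new("PhantomStudy",
        images = images,
        groundTruth = do.call(rbind, c(gt, list(make.row.names = FALSE))),
        specs = specs,
        seed = seed)
}

#' Measure every condition image of a study
#'
#' Applies the ROI template to all 12 condition images and assembles the
#' long-format per-pellet record table used by the categorization and MAR
#' metric stages: one row per pellet per condition, with the artifact
#' category assigned from the conventional no-O-MAR image of the same
#' configuration.
#'
#' @param study a \linkS4class{PhantomStudy}.
#' @param template an \linkS4class{ROITemplate}; NULL picks the packaged
#'   default, in mm on grids coarser than the 512 reference.
#' @param cutoff HU category cutoff (see \code{\link{categorize}}).
#' @return data.frame: \code{pellet_id}, \code{config},
#'   \code{reconstruction}, \code{omar}, \code{mean_hu}, \code{noise},
#'   \code{snr}, \code{cnr}, \code{category}.
#' @export
measureStudy <- function(study, template = NULL, cutoff = 235) {
    imgs <- studyImages(study)
    if (is.null(template)) {
        dx <- pixelSpacing(imgs[[1]])[1]
        template <- defaultROITemplate(useMM = dx > 330 / 512 + 1e-9)
    }
    rows <- list()
    for (nm in names(studyImages(study))) {
        img <- studyImages(study)[[nm]]
        cond <- condition(img)
        meas <- measureROIs(img, template)
        meas <- meas[meas$label != "BG", ]
        rows[[nm]] <- data.frame(
            pellet_id = meas$label,
            config = unname(cond["config"]),
            reconstruction = unname(cond["reconstruction"]),
            omar = ifelse(unname(cond["omar"]) == "on", "on", "off"),
            mean_hu = meas$mean_hu,
            noise = meas$noise_hu,
            snr = meas$snr,
            cnr = meas$cnr,
            stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    assignCategories(rec, cutoff = cutoff)
}
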