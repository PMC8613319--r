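# Pipeline orchestration: simulate -> write images -> measure -> categorize
# -> MAR metrics -> Wilcoxon -> tables, plus a re-analysis entry point for
# per-pellet measurement CSVs in the supplementary-table layout.

.logStage <- function(label, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    message(sprintf("[phantoMAR] %-28s %6.1f s", label,
                    proc.time()[["elapsed"]] - t0))
    res
}

#' Write a slice as 16-bit NIfTI
#'
#' Stores the image as int16 with a +1024 offset (HU + 1024, so air is 24
#' and water 1024; the offset is recorded in the NIfTI description field and
#' in a JSON sidecar next to the image, together with the condition labels
#' and provenance).
#'
#' @param image a \linkS4class{SliceImage}.
#' @param path output file, typically ending in .nii.
#' @return the path, invisibly.
#' @export
writeSliceNIfTI <- function(image, path) {
    arr <- round(pixels(image)) + 1024
    ni <- RNifti::asNifti(arr, pixdim = pixelSpacing(image),
                          datatype = "int16")
    RNifti::writeNifti(ni, path, datatype = "int16")
    sidecar <- list(hu_offset = 1024,
                    pixel_spacing_mm = as.numeric(pixelSpacing(image)),
                    condition = as.list(condition(image)),
                    provenance = provenance(image))
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Read a slice written by \code{writeSliceNIfTI}
#'
#' @param path NIfTI file; a JSON sidecar written alongside it supplies the
#'   HU offset and condition labels (without one, a zero offset and
#'   placeholder condition are assumed).
#' @return a \linkS4class{SliceImage}.
#' @export
readSliceNIfTI <- function(path) {
    ni <- RNifti::readNifti(path)
    arr <- matrix(as.numeric(ni), dim(ni)[1], dim(ni)[2])
    spacing <- RNifti::pixdim(ni)[1:2]
    offset <- 0
    cond <- c(config = "unknown", reconstruction = "unknown", omar = "off")
    prov <- paste("read from", path)
    sidecarPath <- paste0(path, ".json")
    if (file.exists(sidecarPath)) {
        sc <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
        offset <- sc$hu_offset
        cond <- unlist(sc$condition)
        prov <- sc$provenance
        if (!is.null(sc$pixel_spacing_mm)) spacing <- sc$pixel_spacing_mm
    }
    new("SliceImage", pixels = arr - offset,
        pixelSpacing = as.numeric(spacing),
        condition = cond, provenance = prov)
}

# serialize doubles at 17 significant digits so exported measurements
# round-trip exactly through read.csv (the re-analysis mode must reproduce
# the simulate-mode tables bit for bit)
.fullPrecision <- function(df) {
    for (nm in names(df))
        if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
    df
}

.writeTables <- function(res, records, references, outDir) {
    write.csv(.fullPrecision(records), file.path(outDir, "measurements.csv"),
              row.names = FALSE)
    write.csv(.fullPrecision(references),
              file.path(outDir, "references.csv"), row.names = FALSE)
    write.csv(res$table3, file.path(outDir, "table3.csv"), row.names = FALSE)
    write.csv(res$table4, file.path(outDir, "table4.csv"), row.names = FALSE)
    write.csv(tabulateCategories(records),
              file.path(outDir, "category_counts.csv"), row.names = FALSE)
    audit <- lapply(res$comparisons, function(cmp) {
        list(pellet_id = cmp@pelletId, delta_v_reconstruction = cmp@deltaRecon,
             delta_v_standard = cmp@deltaStandard,
             relative_mar_pct = cmp@relativeMARPct, p_value = cmp@pValue)
    })
    jsonlite::write_json(audit, file.path(outDir, "delta_v.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(NULL)
}

#' Run the full simulated phantom study
#'
#' Orchestrates simulate -> measure -> categorize -> MAR metrics -> Wilcoxon
#' -> report as one seeded, reproducible run. Outputs written to
#' \code{outDir}: the 12 condition images (NIfTI + JSON sidecars), injected
#' ground-truth labels, the long per-pellet measurement table, measured
#' no-prosthesis reference values, both relative-MAR tables with p-values,
#' category counts, a per-pellet delta V audit JSON, the run configuration
#' (YAML) and a manifest with MD5 checksums. Identical configuration and
#' seed reproduce every table byte for byte. If a stage fails, a
#' \code{RUN.partial} marker is left in \code{outDir}.
#'
#' @param outDir output directory (created if needed).
#' @param seed study seed.
#' @param matrixSize,nAngles simulation size parameters.
#' @param severity artifact severity (see \code{\link{defaultSeverity}}).
#' @param cutoff category cutoff, HU.
#' @param aggregation delta V aggregation mode.
#' @param references reference-value table, or NULL to measure references
#'   from the simulated no-prosthesis images (the direct analogue of using
#'   reference scans).
#' @param template ROI template; NULL picks the packaged default (in mm on
#'   grids coarser than the 512 reference).
#' @param writeImages write the NIfTI images (disable to keep runs light).
#' @return invisibly, a list: \code{study}, \code{records},
#'   \code{references}, \code{results} (tables + comparisons),
#'   \code{manifest}.
#' @export
runPhantomStudy <- function(outDir, seed = 1L, matrixSize = 512L,
                            nAngles = 360L, severity = defaultSeverity(),
                            cutoff = 235, aggregation = "ratio_of_means",
                            references = NULL,
                            template = NULL,
                            writeImages = TRUE) {
    if (is.null(template))
        template <- defaultROITemplate(useMM = matrixSize < 512L)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    marker <- file.path(outDir, "RUN.partial")
    file.create(marker)
    on.exit(if (file.exists(marker)) NULL)

    config <- list(mode = "simulate", seed = as.integer(seed),
                   matrix_size = as.integer(matrixSize),
                   n_angles = as.integer(nAngles),
                   severity = as.list(severity), cutoff = cutoff,
                   aggregation = aggregation,
                   references = if (is.null(references)) "measured"
                                else "supplied")
    yaml::write_yaml(config, file.path(outDir, "run_config.yaml"))

    study <- .logStage("simulate",
                       generateStudy(seed = seed, matrixSize = matrixSize,
                                     nAngles = nAngles, severity = severity,
                                     cutoff = cutoff, template = template))
    if (writeImages) {
        .logStage("write images", {
            for (nm in names(studyImages(study)))
                writeSliceNIfTI(studyImages(study)[[nm]],
                                file.path(outDir, paste0(nm, ".nii")))
        })
    }
    gt <- groundTruth(study)
    gt$side <- substr(gt$pellet_id, 1, 1)
    write.csv(gt[, c("pellet_id", "side", "config", "injected_category",
                     "noiseless_mean_hu")],
              file.path(outDir, "ground_truth_labels.csv"), row.names = FALSE)

    records <- .logStage("measure",
                         measureStudy(study, template, cutoff = cutoff))
    refs <- if (is.null(references)) computeReferenceValues(records)
            else references
    res <- .logStage("compare", compareAll(records, refs,
                                           aggregation = aggregation))
    .writeTables(res, records, refs, outDir)

    files <- setdiff(list.files(outDir), basename(marker))
    manifest <- list(
        package = "phantoMAR",
        version = as.character(packageVersion("phantoMAR")),
        seed = as.integer(seed),
        config = config,
        config_md5 = unname(tools::md5sum(file.path(outDir,
                                                    "run_config.yaml"))),
        files = as.list(tools::md5sum(file.path(outDir, sort(files)))))
    names(manifest$files) <- sort(files)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    file.remove(marker)
    invisible(list(study = study, records = records, references = refs,
                   results = res, manifest = manifest))
}

#' Re-analyse a per-pellet measurement table
#'
#' Entry point for measurements produced outside the simulator — either
#' exported by \code{\link{runPhantomStudy}} or hand-converted from a
#' spreadsheet of per-pellet CT values, CNR, SNR and noise. Expected long
#' format, one row per pellet per condition: \code{pellet_id}, \code{config}
#' (\code{none}/\code{unilateral}/\code{bilateral}), \code{reconstruction}
#' (\code{conventional}/\code{vmi130}), \code{omar} (\code{on}/\code{off}),
#' \code{mean_hu}, \code{noise}, \code{snr}, \code{cnr}. Categories are
#' assigned from the conventional no-MAR rows unless a \code{category}
#' column is already present.
#'
#' @param input CSV path or data.frame in the layout above.
#' @param references reference-value table; defaults to the published
#'   no-prosthesis values. Pass \code{NULL} to measure them from
#'   \code{config == "none"} rows of the input.
#' @param cutoff category cutoff, HU.
#' @param aggregation delta V aggregation mode.
#' @param outDir optional output directory for the table CSVs.
#' @return list: \code{records} (with categories), \code{references},
#'   \code{results} (tables + comparisons).
#' @export
reanalyzeMeasurements <- function(input, references = referenceValues(),
                                  cutoff = 235,
                                  aggregation = "ratio_of_means",
                                  outDir = NULL) {
    records <- if (is.character(input))
        read.csv(input, stringsAsFactors = FALSE) else as.data.frame(input)
    need <- c("pellet_id", "config", "reconstruction", "omar", "mean_hu",
              "noise", "snr", "cnr")
    missing <- setdiff(need, names(records))
    if (length(missing))
        stop("measurement table lacks column(s): ",
             paste(missing, collapse = ", "))
    if (!"category" %in% names(records))
        records <- assignCategories(records, cutoff = cutoff)
    if (is.null(references))
        references <- computeReferenceValues(records)
    res <- compareAll(records, references, aggregation = aggregation)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        .writeTables(res, records, references, outDir)
    }
    list(records = records, references = references, results = res)
}
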