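# Normalized artifact deviation (delta V) and relative metal artifact
# reduction: the headline quantification comparing each reconstruction
# against a standard reconstruction per metric and artifact category.

.METRICS <- c("mean_hu", "cnr", "snr", "noise")
.RECON_LABELS <- c("conventional_noomar", "conventional_omar",
                   "vmi130_noomar", "vmi130_omar")

#' Published no-prosthesis reference values
#'
#' All-pellet mean image-quality parameters of the phantom without
#' prostheses, per reconstruction family (identical with and without MAR
#' when no metal is present). These are the defaults normalizing delta V in
#' re-analysis mode; in simulate mode references are measured from the
#' simulated no-prosthesis images instead
#' (\code{\link{computeReferenceValues}}).
#'
#' @return data.frame: \code{reconstruction}, \code{mean_hu}, \code{cnr},
#'   \code{snr}, \code{noise}.
#' @export
referenceValues <- function() {
    data.frame(reconstruction = c("conventional", "vmi130"),
               mean_hu = c(248.4, 150.4),
               cnr = c(37.3, 18.0),
               snr = c(36.5, 19.3),
               noise = c(6.9, 8.0),
               stringsAsFactors = FALSE)
}

#' Measure reference values from no-prosthesis records
#'
#' All-pellet means of mean HU, CNR, SNR and noise from the
#' \code{config == "none"} rows of a long record table, per reconstruction
#' family (no-MAR images; with no metal, MAR leaves them unchanged). SNR and
#' CNR references are means of the per-pellet ratios.
#'
#' @param records long record table (see \code{\link{measureStudy}}).
#' @return data.frame in the layout of \code{\link{referenceValues}}.
#' @export
computeReferenceValues <- function(records) {
    base <- records[records$config == "none" & records$omar == "off", ]
    if (!nrow(base)) stop("records contain no no-prosthesis (config none) rows")
    out <- lapply(split(base, base$reconstruction), function(d) {
        data.frame(reconstruction = d$reconstruction[1],
                   mean_hu = mean(d$mean_hu),
                   cnr = mean(d$cnr),
                   snr = mean(d$snr),
                   noise = mean(d$noise),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Normalized artifact deviation (delta V)
#'
#' Absolute deviation of a metric from its no-prosthesis reference,
#' normalized by the reference: |1 - v / vRef|. Normalization makes metrics
#' comparable across reconstruction families whose absolute scales differ
#' (VMI CT values are markedly lower). A zero reference leaves delta V
#' undefined (NA, with a warning); values beyond the reference range exceed 1.
#'
#' @param vWith metric value with prostheses (vectorized).
#' @param vReference no-prosthesis reference value.
#' @return non-negative delta V.
#' @examples
#' deltaV(100, 250)   # 0.6
#' deltaV(-50, 250)   # 1.2
#' @export
deltaV <- function(vWith, vReference) {
    out <- abs(1 - vWith / vReference)
    bad <- rep_len(!is.na(vReference) & vReference == 0, length(out))
    if (any(bad)) {
        warning("deltaV undefined for a zero reference; returning NA")
        out[bad] <- NA_real_
    }
    out
}

#' Relative metal artifact reduction
#'
#' Percentage reduction of the normalized artifact deviation relative to a
#' standard reconstruction: (1 - deltaRecon / deltaStandard) * 100. Negative
#' values indicate aggravation of the artifacts.
#'
#' @param deltaRecon delta V under the evaluated reconstruction (>= 0).
#' @param deltaStandard delta V under the standard reconstruction (> 0; a
#'   zero yields NA with a warning).
#' @return percent (vectorized), at most 100.
#' @examples
#' relativeMAR(0.11, 0.20)  # 45
#' relativeMAR(0.4, 0.1)    # -300 (aggravation)
#' @export
relativeMAR <- function(deltaRecon, deltaStandard) {
    out <- (1 - deltaRecon / deltaStandard) * 100
    bad <- rep_len(!is.na(deltaStandard) & deltaStandard <= 0, length(out))
    if (any(bad)) {
        warning("relativeMAR undefined for zero standard delta V; returning NA")
        out[bad] <- NA_real_
    }
    out
}

# Rows of a long record table belonging to one reconstruction label
# ("<family>_<omar|noomar>"), prosthesis configurations only.
.reconRows <- function(records, label) {
    fam <- sub("_(omar|noomar)$", "", label)
    om <- if (grepl("_omar$", label)) "on" else "off"
    records[records$reconstruction == fam & records$omar == om &
            records$config != "none", , drop = FALSE]
}

.reconFamily <- function(label) sub("_(omar|noomar)$", "", label)

#' Aggregate one relative-MAR comparison cell
#'
#' Computes per-pellet-instance delta V for an evaluated and a standard
#' reconstruction (each normalized by its own family's reference), pairs
#' them by pellet and configuration within one artifact category, derives
#' the category-level relative MAR, and attaches the paired two-sided
#' Wilcoxon signed-rank p-value over the per-pellet delta V pairs.
#'
#' The default aggregation is the ratio of category means of delta V
#' (robust to near-zero per-pellet standard deviations); per-pellet relative
#' MAR averaged across pellets is available as \code{"mean_of_ratios"}.
#'
#' @param records long record table with categories
#'   (see \code{\link{measureStudy}}).
#' @param metric one of \code{mean_hu}, \code{cnr}, \code{snr}, \code{noise}.
#' @param category \code{"mild"} or \code{"severe"}.
#' @param reconstruction evaluated reconstruction label, e.g.
#'   \code{"vmi130_omar"}.
#' @param standard standard reconstruction label, e.g.
#'   \code{"conventional_noomar"}.
#' @param references reference-value table (see
#'   \code{\link{referenceValues}}).
#' @param aggregation \code{"ratio_of_means"} or \code{"mean_of_ratios"}.
#' @return a \linkS4class{MARComparison}.
#' @export
aggregateComparison <- function(records, metric, category, reconstruction,
                                standard, references = referenceValues(),
                                aggregation = c("ratio_of_means",
                                                "mean_of_ratios")) {
    metric <- match.arg(metric, .METRICS)
    category <- match.arg(category, c("mild", "severe"))
    reconstruction <- match.arg(reconstruction, .RECON_LABELS)
    standard <- match.arg(standard, .RECON_LABELS)
    aggregation <- match.arg(aggregation)

    dvOf <- function(label) {
        rows <- .reconRows(records, label)
        rows <- rows[!is.na(rows$category) & rows$category == category, ]
        if (!nrow(rows))
            stop("no pellet-instances in category '", category,
                 "' for reconstruction '", label, "'")
        ref <- references[references$reconstruction == .reconFamily(label),
                          metric]
        if (!length(ref) || is.na(ref))
            stop("no reference value for family '", .reconFamily(label),
                 "', metric '", metric, "'")
        data.frame(id = paste(rows$pellet_id, rows$config, sep = ":"),
                   dv = deltaV(rows[[metric]], ref),
                   stringsAsFactors = FALSE)
    }

    dr <- dvOf(reconstruction)
    ds <- dvOf(standard)
    ids <- intersect(dr$id, ds$id)
    if (!length(ids))
        stop("no paired pellet-instances between '", reconstruction,
             "' and '", standard, "'")
    dvR <- dr$dv[match(ids, dr$id)]
    dvS <- ds$dv[match(ids, ds$id)]
    ok <- is.finite(dvR) & is.finite(dvS)
    if (!all(ok)) {
        warning(sum(!ok), " pellet-instance(s) excluded (undefined delta V)")
        dvR <- dvR[ok]; dvS <- dvS[ok]; ids <- ids[ok]
    }
    if (!length(ids)) stop("no usable pellet-instance pairs remain")

    if (identical(reconstruction, standard)) {
        rel <- 0
        p <- 1
    } else if (aggregation == "ratio_of_means") {
        rel <- relativeMAR(mean(dvR), mean(dvS))
        p <- wilcoxonSignedRank(dvR, dvS)$p.value
    } else {
        usable <- dvS > 0
        if (!all(usable))
            warning(sum(!usable),
                    " pair(s) with zero standard delta V excluded from ",
                    "mean-of-ratios aggregation")
        rel <- mean(relativeMAR(dvR[usable], dvS[usable]))
        p <- wilcoxonSignedRank(dvR, dvS)$p.value
    }

    new("MARComparison",
        metric = metric, category = category,
        reconstruction = reconstruction, standardReconstruction = standard,
        deltaRecon = dvR, deltaStandard = dvS, pelletId = ids,
        relativeMARPct = unname(rel), pValue = unname(p),
        n = length(ids), aggregation = aggregation)
}

#' Build the relative-MAR result tables
#'
#' Assembles the two headline tables: every metric and artifact category for
#' the reconstructions compared against conventional imaging without MAR
#' (table 3 layout: conventional + O-MAR, 130 keV VMI, 130 keV VMI + O-MAR)
#' and against conventional imaging with MAR (table 4 layout: 130 keV VMI,
#' 130 keV VMI + O-MAR). Categories with no pellet-instances are flagged
#' absent (NA, n = 0), never zero.
#'
#' @param records long record table with categories.
#' @param references reference-value table.
#' @param aggregation delta V aggregation mode
#'   (see \code{\link{aggregateComparison}}).
#' @return list with data.frames \code{table3} and \code{table4} (columns
#'   \code{reconstruction}, \code{metric}, \code{category}, \code{n},
#'   \code{relative_mar_pct}, \code{p_value}) and \code{comparisons}, the
#'   underlying \linkS4class{MARComparison} objects keyed by
#'   \code{standard|reconstruction|metric|category}.
#' @export
buildTables <- function(records, references = referenceValues(),
                        aggregation = "ratio_of_means") {
    plans <- list(
        table3 = list(standard = "conventional_noomar",
                      recons = c("conventional_omar", "vmi130_noomar",
                                 "vmi130_omar")),
        table4 = list(standard = "conventional_omar",
                      recons = c("vmi130_noomar", "vmi130_omar")))
    present <- unique(records$category[!is.na(records$category)])
    comparisons <- list()
    tables <- lapply(plans, function(plan) {
        rows <- list()
        for (rec in plan$recons) for (m in .METRICS)
            for (cat in c("mild", "severe")) {
                if (!cat %in% present) {
                    rows[[length(rows) + 1L]] <- data.frame(
                        reconstruction = rec, metric = m, category = cat,
                        n = 0L, relative_mar_pct = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE)
                    next
                }
                cmp <- aggregateComparison(records, m, cat, rec,
                                           plan$standard, references,
                                           aggregation)
                key <- paste(plan$standard, rec, m, cat, sep = "|")
                comparisons[[key]] <<- cmp
                rows[[length(rows) + 1L]] <- data.frame(
                    reconstruction = rec, metric = m, category = cat,
                    n = cmp@n, relative_mar_pct = cmp@relativeMARPct,
                    p_value = cmp@pValue, stringsAsFactors = FALSE)
            }
        do.call(rbind, c(rows, list(make.row.names = FALSE)))
    })
    list(table3 = tables$table3, table4 = tables$table4,
         comparisons = comparisons)
}
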