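# Pellet artifact-severity categorization from the mean HU on the
# conventional image without MAR: < 0 HU severe, below the cutoff mild,
# at or above the cutoff unaffected.

.CATEGORY_LEVELS <- c("severe", "mild", "unaffected")

#' Derive an artifact category cutoff from reference statistics
#'
#' The cutoff separates unaffected from mildly affected pellets: mean minus
#' k standard deviations of the no-prosthesis reference, optionally rounded
#' down to the nearest multiple of \code{roundTo} HU. The published analysis
#' used a fixed 235 HU cutoff; this derivation serves new phantoms and does
#' not override that default.
#'
#' @param referenceMean reference mean HU (all pellets, no prostheses).
#' @param referenceSD reference standard deviation, HU; must be > 0.
#' @param k multiplier on the standard deviation.
#' @param roundTo round the cutoff down to this multiple (HU); \code{NULL}
#'   or 0 disables rounding.
#' @return cutoff in HU.
#' @examples
#' deriveCutoff(248.4, 4.1, roundTo = NULL)  # 244.3
#' deriveCutoff(248.4, 4.1)                  # 240
#' @export
deriveCutoff <- function(referenceMean, referenceSD, k = 1, roundTo = 5) {
    if (referenceSD <= 0) stop("referenceSD must be positive")
    cut <- referenceMean - k * referenceSD
    if (!is.null(roundTo) && roundTo > 0) cut <- floor(cut / roundTo) * roundTo
    cut
}

#' Categorize pellets by artifact severity
#'
#' Mean HU below 0 is severely affected; from 0 (inclusive — the boundary is
#' assigned to the less severe adjacent class) up to the cutoff is mildly
#' affected; at or above the cutoff is unaffected. Total and monotone in the
#' mean HU.
#'
#' @param meanHU pellet mean HU (vectorized; must be finite).
#' @param cutoff unaffected/mild boundary, HU (> 0); default 235.
#' @return ordered factor with levels severe < mild < unaffected.
#' @examples
#' categorize(c(-50, 120, 235, 234.999, 0))
#' @export
categorize <- function(meanHU, cutoff = 235) {
    if (cutoff <= 0) stop("cutoff must be positive")
    if (any(!is.finite(meanHU))) stop("meanHU must be finite")
    out <- ifelse(meanHU < 0, "severe",
                  ifelse(meanHU < cutoff, "mild", "unaffected"))
    factor(out, levels = .CATEGORY_LEVELS, ordered = TRUE)
}

#' Attach artifact categories to a long record table
#'
#' Determines each pellet-instance's category solely from its mean HU on
#' the conventional no-MAR image of the same prosthesis configuration, and
#' attaches it to every row of that instance (all reconstructions).
#'
#' @param records long record table with columns \code{pellet_id},
#'   \code{config}, \code{reconstruction}, \code{omar}, \code{mean_hu}.
#' @param cutoff HU category cutoff (see \code{\link{categorize}}).
#' @return \code{records} with a \code{category} column.
#' @export
assignCategories <- function(records, cutoff = 235) {
    base <- records[records$reconstruction == "conventional" &
                    records$omar == "off" & records$config != "none", ]
    if (nrow(base)) {
        key <- paste(base$pellet_id, base$config)
        cat <- as.character(categorize(base$mean_hu, cutoff = cutoff))
        names(cat) <- key
        records$category <- unname(cat[paste(records$pellet_id,
                                             records$config)])
    } else {
        records$category <- NA_character_
    }
    records
}

#' Tabulate artifact categories per prosthesis configuration
#'
#' Counts unaffected, mildly affected and severely affected pellet-instances
#' for each prosthesis configuration (each physical pellet yields one
#' instance per configuration).
#'
#' @param records long record table with columns \code{pellet_id},
#'   \code{config} and \code{category} (one instance counted per pellet and
#'   configuration).
#' @return data.frame: \code{config}, \code{unaffected}, \code{mild},
#'   \code{severe}.
#' @export
tabulateCategories <- function(records) {
    inst <- unique(records[records$config != "none" &
                           !is.na(records$category),
                           c("pellet_id", "config", "category")])
    if (!nrow(inst))
        return(data.frame(config = character(0), unaffected = integer(0),
                          mild = integer(0), severe = integer(0)))
    out <- lapply(split(inst, inst$config), function(d) {
        data.frame(config = d$config[1],
                   unaffected = sum(d$category == "unaffected"),
                   mild = sum(d$category == "mild"),
                   severe = sum(d$category == "severe"))
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}
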