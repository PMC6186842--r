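#' Accessor functions
#'
#' Small accessors for the S4 containers: prefer these over direct slot
#' access.
#'
#' @param x an object of the documented classes.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("clinicalData", "ClinicalTable", function(x) x@data)

#' @rdname accessors
setMethod("channelLabels", "EpochedEEG", function(x) x@channelLabels)

#' @rdname accessors
setMethod("samplingRate", "EpochedEEG", function(x) x@samplingRate)

#' @rdname accessors
setMethod("nTrials", "EpochedEEG", function(x) length(x@trials))

#' @rdname accessors
setMethod("lesionSide", "EpochedEEG", function(x) x@lesionSide)

#' @rdname accessors
setMethod("lesionSide", "RegionTimeSeries", function(x) x@lesionSide)

#' @rdname accessors
setMethod("regionLabels", "RegionTimeSeries", function(x) rownames(x@data))

#' @rdname accessors
setMethod("regionLabels", "VariabilityProfile", function(x) names(x@values))

#' @rdname accessors
setMethod("trSeconds", "RegionTimeSeries", function(x) x@trSeconds)

#' @rdname accessors
setMethod("statistic", "TestResult", function(x) x@statistic)

#' @rdname accessors
setMethod("pValue", "TestResult", function(x) x@pValue)

#' @rdname accessors
setMethod("degreesFreedom", "TestResult", function(x) x@df)

#' @rdname accessors
setMethod("nUsed", "TestResult", function(x) x@nUsed)

#' @rdname accessors
setMethod("variability", "VariabilityProfile", function(x) x@values)

#' @rdname accessors
setMethod("windowLengths", "VariabilityProfile", function(x) x@windowLengths)

#' @rdname accessors
setMethod("windowLengths", "WindowedConnectivity",
          function(x) x@windowLength)

#' @rdname accessors
setMethod("subnetworkMeans", "VariabilityProfile",
          function(x) x@subnetworkMeans)

#' @rdname accessors
setMethod("suppressionScore", "MuSuppression", function(x) x@score)

setMethod("show", "ClinicalTable", function(object) {
    d <- object@data
    cat(sprintf("ClinicalTable: %d subjects (%d guided, %d sham)\n",
                nrow(d), sum(d$group == "guided"), sum(d$group == "sham")))
    cat(sprintf("  6-month follow-up missing for %d subject(s)\n",
                sum(is.na(d$fma_6mo))))
})

setMethod("show", "TestResult", function(object) {
    df_txt <- if (is.na(object@df)) "" else sprintf(", df = %g", object@df)
    cat(sprintf("%s: statistic = %.4f%s, two-tailed p = %.4g (n = %d%s)\n",
                object@method, object@statistic, df_txt, object@pValue,
                object@nUsed,
                if (object@tieCorrected) ", tie-corrected" else ""))
})

setMethod("show", "EpochedEEG", function(object) {
    dur <- if (length(object@trials))
        ncol(object@trials[[1]]$task) / object@samplingRate else 0
    cat(sprintf(
        "EpochedEEG: %d channels @ %g Hz, %d trials (%.1f s task + rest), lesion side %s\n",
        length(object@channelLabels), object@samplingRate,
        length(object@trials), dur, object@lesionSide))
})

setMethod("show", "MuSuppression", function(object) {
    cat(sprintf("MuSuppression: P_task = %.4g, P_rest = %.4g, MSS = %.2f\n",
                object@pTask, object@pRest, object@score))
})

setMethod("show", "LinearDiscriminantModel", function(object) {
    cat(sprintf("LinearDiscriminantModel: %s vs %s, %d features%s\n",
                object@classes[1], object@classes[2], length(object@weights),
                if (object@regularized) " (ridge-regularized)" else ""))
})

setMethod("show", "RegionTimeSeries", function(object) {
    cat(sprintf(
        "RegionTimeSeries: %d regions x %d time points (TR %g s), subject %s, session %s, lesion %s\n",
        nrow(object@data), ncol(object@data), object@trSeconds,
        object@subjectId, object@session, object@lesionSide))
})

setMethod("show", "WindowedConnectivity", function(object) {
    cat(sprintf("WindowedConnectivity: %d windows of %d time points, %d regions\n",
                length(object@windows), object@windowLength,
                if (length(object@windows)) nrow(object@windows[[1]]) else 0))
})

setMethod("show", "VariabilityProfile", function(object) {
    cat(sprintf("VariabilityProfile: %d regions, window lengths {%s}\n",
                length(object@values),
                paste(object@windowLengths, collapse = ", ")))
    if (length(object@subnetworkMeans)) {
        cat("  subnetwork means:\n")
        for (nm in names(object@subnetworkMeans))
            cat(sprintf("    %-4s %.4f\n", nm, object@subnetworkMeans[[nm]]))
    }
})
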