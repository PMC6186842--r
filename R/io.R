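## Readers and writers for the interchange formats, the bundled clinical
## fixture, and JSON reports.

#' Construct a ClinicalTable from a data.frame
#'
#' @param data data.frame with at least \code{subject_id}, \code{group},
#'   \code{lesion_side}, \code{fma_pre}, \code{fma_post}, \code{fma_6mo}.
#' @return a validated \code{\linkS4class{ClinicalTable}}.
#' @export
clinicalTable <- function(data) new("ClinicalTable", data = data)

#' Read a clinical score table from CSV
#'
#' Expects the header \code{subject_id,group,lesion_side,fma_pre,fma_post,
#' fma_6mo} (extra metadata columns are kept); empty fields are missing
#' values.  Validation failures name the offending row and column.
#'
#' @param path CSV file path.
#' @return a \code{\linkS4class{ClinicalTable}}.
#' @export
readClinicalTable <- function(path) {
    if (!file.size(path) > 0) stop("empty file: ", path)
    d <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
    required <- c("subject_id", "group", "lesion_side",
                  "fma_pre", "fma_post", "fma_6mo")
    miss <- setdiff(required, names(d))
    if (length(miss))
        stop("missing column(s) in ", path, ": ",
             paste(miss, collapse = ", "))
    for (col in c("fma_pre", "fma_post", "fma_6mo")) {
        v <- d[[col]]
        bad <- which(!is.na(v) & (is.na(suppressWarnings(as.numeric(v))) |
                                  as.numeric(v) < 0 | as.numeric(v) > 66))
        if (length(bad))
            stop("malformed score in row ", bad[1], ", column ", col,
                 ": '", v[bad[1]], "'")
        d[[col]] <- as.numeric(v)
    }
    dup <- d$subject_id[duplicated(d$subject_id)]
    if (length(dup))
        stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "))
    clinicalTable(d)
}

#' The bundled clinical characteristics fixture
#'
#' The 24-subject cohort (13 guided, 11 sham) with FMA-UE scores at
#' baseline, post-intervention and six-month follow-up, including the two
#' guided-group subjects with missing follow-up; demographics are carried
#' as metadata columns.  This is the default input for the clinical
#' analyses.
#'
#' @return a \code{\linkS4class{ClinicalTable}}.
#' @examples
#' clinicalFixture()
#' @export
clinicalFixture <- function() {
    readClinicalTable(system.file("extdata", "clinical_cohort.csv",
                                  package = "plastometrics",
                                  mustWork = TRUE))
}

#' Default six-subnetwork grouping of 84 paired regions
#'
#' A synthetic AAL-flavoured mapping of 42 left/right region pairs to the
#' six functional subnetworks (SMA sensory-motor, ATT attention, AUD
#' auditory, VIS visual recognition, DMN default mode, SUB subcortical).
#' The canonical region list of the original analysis is not public, so
#' this mapping is a documented stand-in with the right shape: 84 unique
#' labels with \code{L_}/\code{R_} prefixes, each in exactly one
#' subnetwork.
#'
#' @return named character vector: region label -> subnetwork code.
#' @export
defaultSubnetworkMap <- function() {
    pairs <- list(
        SMA = c("Precentral", "Postcentral", "Supp_Motor_Area",
                "Paracentral_Lobule", "Rolandic_Oper", "Cingulum_Mid"),
        ATT = c("Frontal_Sup", "Frontal_Mid", "Frontal_Inf_Tri",
                "Frontal_Inf_Oper", "Parietal_Sup", "Parietal_Inf",
                "Angular", "Supramarginal"),
        AUD = c("Temporal_Sup", "Temporal_Mid", "Temporal_Pole_Sup",
                "Temporal_Pole_Mid", "Heschl"),
        VIS = c("Calcarine", "Cuneus", "Lingual", "Occipital_Sup",
                "Occipital_Mid", "Occipital_Inf", "Fusiform"),
        DMN = c("Cingulum_Ant", "Cingulum_Post", "Precuneus",
                "Frontal_Med_Orb", "Frontal_Sup_Medial", "Rectus",
                "Hippocampus", "ParaHippocampal", "Temporal_Inf"),
        SUB = c("Thalamus", "Caudate", "Putamen", "Pallidum", "Amygdala",
                "Insula", "Olfactory"))
    out <- character()
    for (net in names(pairs))
        for (rg in pairs[[net]])
            out[paste0(c("L_", "R_"), rg)] <- net
    out
}

#' Read a subnetwork map from JSON
#'
#' @param path JSON file of the form \code{{"L_Precentral": "SMA", ...}}.
#' @return named character vector: region label -> subnetwork.
#' @export
readSubnetworkMap <- function(path) {
    m <- jsonlite::read_json(path)
    out <- unlist(m)
    if (is.null(names(out)) || anyDuplicated(names(out)))
        stop("subnetwork map must have unique region labels as keys")
    out
}

#' Read and write region-level BOLD time series
#'
#' TSV format: first column \code{region}, remaining columns the time
#' points; a JSON sidecar carries \code{tr_seconds}, \code{subject_id},
#' \code{session} and \code{lesion_side}.  \code{writeRegionTimeSeries}
#' writes both files; \code{readRegionTimeSeries} reads them back
#' (round-trip identical up to text precision).
#'
#' @param path TSV file path; the sidecar defaults to the same path with a
#'   \code{.json} extension.
#' @param sidecar JSON sidecar path.
#' @param ts a \code{\linkS4class{RegionTimeSeries}} (writer).
#' @return the \code{RegionTimeSeries} (reader) or \code{path} invisibly
#'   (writer).
#' @export
readRegionTimeSeries <- function(path, sidecar = sub("\\.tsv$", ".json",
                                                     path)) {
    d <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
    if (names(d)[1] != "region")
        stop("first column must be 'region'")
    if (anyDuplicated(d$region))
        stop("duplicate region label: ",
             paste(unique(d$region[duplicated(d$region)]), collapse = ", "))
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d$region
    colnames(m) <- NULL
    meta <- jsonlite::read_json(sidecar)
    regionTimeSeries(m, trSeconds = meta$tr_seconds,
                     subjectId = meta$subject_id %||% "subject",
                     session = meta$session %||% "unknown",
                     lesionSide = meta$lesion_side %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readRegionTimeSeries
#' @export
writeRegionTimeSeries <- function(ts, path,
                                  sidecar = sub("\\.tsv$", ".json", path)) {
    stopifnot(is(ts, "RegionTimeSeries"))
    d <- data.frame(region = rownames(ts@data), ts@data,
                    check.names = FALSE, stringsAsFactors = FALSE)
    names(d)[-1] <- paste0("t", seq_len(ncol(ts@data)))
    .writeTSV(d, path)
    jsonlite::write_json(
        list(tr_seconds = ts@trSeconds, subject_id = ts@subjectId,
             session = ts@session, lesion_side = ts@lesionSide),
        sidecar, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

.provenanceHeader <- function() {
    sprintf("# plastometrics %s | %s",
            as.character(utils::packageVersion("plastometrics")),
            format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
}

.writeTSV <- function(d, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.provenanceHeader(), con)
    utils::write.table(d, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a variability profile as TSV
#'
#' One row per region with the multi-length averaged variability, plus the
#' subnetwork means (when aggregated) appended as comment lines.
#'
#' @param profile a \code{\linkS4class{VariabilityProfile}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeVariability <- function(profile, path) {
    stopifnot(is(profile, "VariabilityProfile"))
    d <- data.frame(region = names(profile@values),
                    variability = unname(profile@values))
    .writeTSV(d, path)
    if (length(profile@subnetworkMeans)) {
        lines <- sprintf("# subnetwork %s\t%.6f",
                         names(profile@subnetworkMeans),
                         profile@subnetworkMeans)
        cat(lines, file = path, sep = "\n", append = TRUE)
    }
    invisible(path)
}

#' Read an epoched EEG recording from a delimited matrix + JSON sidecar
#'
#' The matrix is channels x samples (TSV, no header); the sidecar carries
#' \code{rate_hz}, \code{channel_labels}, \code{lesion_side},
#' \code{segment_seconds} and 1-based sample onsets \code{task_onsets} and
#' \code{rest_onsets} (one pair per trial).  Channel labels outside the
#' 16-channel montage are an error.
#'
#' @param path TSV matrix path.
#' @param sidecar JSON sidecar path.
#' @return an \code{\linkS4class{EpochedEEG}}.
#' @export
readEEGMatrix <- function(path, sidecar = sub("\\.tsv$", ".json", path)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    labels <- meta$channel_labels
    unknown <- setdiff(labels, montageChannels())
    if (length(unknown))
        stop("unknown channel label(s): ", paste(unknown, collapse = ", "),
             "; montage is: ", paste(montageChannels(), collapse = ", "))
    m <- as.matrix(utils::read.delim(path, header = FALSE,
                                     comment.char = "#"))
    dimnames(m) <- list(labels, NULL)
    if (nrow(m) != length(labels))
        stop("matrix has ", nrow(m), " rows but ", length(labels),
             " channel labels")
    n <- round(meta$segment_seconds * meta$rate_hz)
    if (length(meta$task_onsets) != length(meta$rest_onsets))
        stop("task_onsets and rest_onsets must pair up")
    trials <- Map(function(to, ro) {
        if (max(to, ro) + n - 1L > ncol(m))
            stop("trial segment extends past the end of the recording")
        list(task = m[, to:(to + n - 1L), drop = FALSE],
             rest = m[, ro:(ro + n - 1L), drop = FALSE])
    }, meta$task_onsets, meta$rest_onsets)
    new("EpochedEEG", channelLabels = labels,
        samplingRate = meta$rate_hz, trials = trials,
        lesionSide = meta$lesion_side %||% "unknown")
}

#' Write an epoched EEG recording (delimited matrix + sidecar)
#'
#' Concatenates rest and task segments trial by trial into one channels x
#' samples matrix and records the onsets in the sidecar, the inverse of
#' \code{\link{readEEGMatrix}}.
#'
#' @param epochs an \code{\linkS4class{EpochedEEG}}.
#' @param path output TSV path.
#' @param sidecar output JSON sidecar path.
#' @return \code{path}, invisibly.
#' @export
writeEEGMatrix <- function(epochs, path,
                           sidecar = sub("\\.tsv$", ".json", path)) {
    stopifnot(is(epochs, "EpochedEEG"))
    n <- if (nTrials(epochs)) ncol(epochs@trials[[1]]$task) else 0L
    segs <- unlist(lapply(epochs@trials,
                          function(tr) list(tr$rest, tr$task)),
                   recursive = FALSE)
    m <- do.call(cbind, segs)
    rest_onsets <- (seq_len(nTrials(epochs)) - 1L) * 2L * n + 1L
    task_onsets <- rest_onsets + n
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(
        list(rate_hz = samplingRate(epochs),
             channel_labels = channelLabels(epochs),
             lesion_side = lesionSide(epochs),
             segment_seconds = n / samplingRate(epochs),
             task_onsets = task_onsets, rest_onsets = rest_onsets),
        sidecar, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

.testResultAsList <- function(x) {
    list(method = x@method, statistic = x@statistic,
         df = if (is.na(x@df)) NULL else x@df, p_two_tailed = x@pValue,
         n_used = x@nUsed, tie_correction_applied = x@tieCorrected,
         statistic_3dp = round(x@statistic, 3))
}

#' Write an analysis report as JSON
#'
#' Serialises nested lists of \code{\linkS4class{TestResult}}s, data
#' frames and plain values (e.g. the output of
#' \code{\link{clinicalStatsReport}}) into a flat JSON report carrying
#' full-precision statistics plus their 3-decimal rendering, and a
#' provenance block (package version, seed when supplied).
#'
#' @param results nested list of results.
#' @param path output JSON path.
#' @param seed optional seed to record in the provenance block.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(results, path, seed = NULL) {
    walk <- function(x) {
        if (is(x, "TestResult")) return(.testResultAsList(x))
        if (is.data.frame(x)) return(x)
        if (is.list(x)) return(lapply(x, walk))
        x
    }
    payload <- list(
        provenance = list(
            package = "plastometrics",
            version = as.character(utils::packageVersion("plastometrics")),
            seed = seed),
        results = walk(results))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    invisible(path)
}
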