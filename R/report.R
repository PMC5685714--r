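# Per-sample JSON report: provenance, per-bin and per-segment tables for
# plotting, tumor-content estimate and event summary.

.REPORT_SCHEMA_VERSION <- "1.0"

#' Render the per-sample screening report
#'
#' Collects the pipeline outputs for one sample into a single JSON document
#' (schema-versioned, with provenance and the tables a genome-wide plot
#' needs). All inputs must carry the same sample identifier.
#'
#' @param counts a [BinCounts].
#' @param profile a [CopyRatioProfile].
#' @param seg a [SegmentedProfile].
#' @param tc a [TumorContentEstimate].
#' @param focal focal calls (from [callFocal()], optionally annotated).
#' @param arms named arm-status vector from [armLevelEvents()] (optional).
#' @param fga result of [computeFGA()] (optional).
#' @param path output file; NULL returns the report list invisibly without
#'   writing.
#' @param params list of pipeline parameters recorded as provenance.
#' @return the report list, invisibly.
#' @export
renderReport <- function(counts, profile, seg, tc, focal = NULL, arms = NULL,
                         fga = NULL, path = NULL, params = list()) {
    ids <- unique(c(sampleId(counts), sampleId(profile), sampleId(seg)))
    if (length(ids) != 1L)
        stop("inconsistent sample ids: ", paste(ids, collapse = ", "))
    b <- bins(counts)
    report <- list(
        schema_version = .REPORT_SCHEMA_VERSION,
        provenance = c(list(
            package = "plasmaCNA",
            version = as.character(utils::packageVersion("plasmaCNA")),
            created = "run-time", params = params)),
        sample = list(
            id = ids, total_reads = totalReads(counts),
            mean_read_length = counts@meanReadLength,
            effective_coverage = effectiveCoverage(counts),
            bin_width = profile@binWidth,
            sex = tc@sex),
        tumor_content = list(
            lss = tc@lss, classification = tc@classification,
            tc_fit = tc@tcFit, tc_lss = tc@tcLss,
            fit_residual = tc@fitResidual,
            single_event_flag = tc@singleEventFlag),
        fga = if (!is.null(fga)) fga else NULL,
        events = list(
            focal = if (!is.null(focal) && length(focal)) data.frame(
                chrom = as.character(GenomeInfoDb::seqnames(focal)),
                start = BiocGenerics::start(focal) - 1L,
                end = BiocGenerics::end(focal),
                direction = S4Vectors::mcols(focal)$direction,
                mean_log2 = S4Vectors::mcols(focal)$meanLog2,
                genes = vapply(S4Vectors::mcols(focal)$genes,
                               paste, "", collapse = ","),
                deep_deletion = S4Vectors::mcols(focal)$deepDeletion)
                else data.frame(),
            arms = if (!is.null(arms))
                as.list(arms[arms != "neutral"]) else NULL),
        segments = data.frame(
            chrom = as.character(GenomeInfoDb::seqnames(seg)),
            start = BiocGenerics::start(seg) - 1L,
            end = BiocGenerics::end(seg),
            n_bins = S4Vectors::mcols(seg)$nBins,
            mean_log2 = S4Vectors::mcols(seg)$meanLog2,
            assigned_cn = if (length(tc@assignments) == length(seg))
                tc@assignments else NA_integer_),
        bins = data.frame(
            chrom = as.character(GenomeInfoDb::seqnames(b)),
            start = BiocGenerics::start(b) - 1L,
            end = BiocGenerics::end(b),
            count = binCounts(counts),
            log2ratio = log2Ratio(profile)))
    if (!is.null(path))
        jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                             na = "null", pretty = TRUE)
    invisible(report)
}

#' Read back a screening report
#'
#' @param path JSON report written by [renderReport()].
#' @return the parsed report list.
#' @export
readReport <- function(path) {
    rep <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(rep$schema_version))
        stop("not a plasmaCNA report: missing schema_version")
    rep
}
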