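.METHOD_TYPES <- c("event_specific", "construct_specific",
                   "element_specific", "taxon_specific")

#' A collection of validated PCR detection methods
#'
#' Holds the assay definitions used for in silico screening: two primers and
#' an optional TaqMan probe per method, plus identity and target metadata.
#' Primers and probes are IUPAC nucleotide strings of length >= 10; method
#' identifiers are unique within the set.
#'
#' @slot methodId character, unique method identifiers.
#' @slot methodType character, one of event_specific, construct_specific,
#'   element_specific, taxon_specific.
#' @slot targetName character, targeted genetic element (e.g. "p35S").
#' @slot primer1,primer2 character, IUPAC primer sequences.
#' @slot probe character, IUPAC probe sequence or \code{NA} when the assay
#'   has no probe.
#' @aliases DetectionMethodSet-class
#' @exportClass DetectionMethodSet
setClass("DetectionMethodSet",
    representation(methodId = "character", methodType = "character",
                   targetName = "character", primer1 = "character",
                   primer2 = "character", probe = "character"))

setValidity("DetectionMethodSet", function(object) {
    n <- length(object@methodId)
    lens <- c(length(object@methodType), length(object@targetName),
              length(object@primer1), length(object@primer2),
              length(object@probe))
    if (any(lens != n))
        return("all slots must have the same length")
    dup <- object@methodId[duplicated(object@methodId)]
    if (length(dup) > 0L)
        return(sprintf("duplicate method_id: %s", dup[1L]))
    if (any(!object@methodType %in% .METHOD_TYPES))
        return(sprintf("unknown method_type '%s'",
                       setdiff(object@methodType, .METHOD_TYPES)[1L]))
    for (i in seq_len(n)) {
        for (fld in c("primer1", "primer2")) {
            p <- slot(object, fld)[i]
            if (is.na(p) || nchar(p) < 10L)
                return(sprintf("%s of method %s must be at least 10 nt",
                               fld, object@methodId[i]))
            if (!.validIupac(p))
                return(sprintf("%s of method %s contains a non-IUPAC character",
                               fld, object@methodId[i]))
        }
        pr <- object@probe[i]
        if (!is.na(pr)) {
            if (nchar(pr) < 10L)
                return(sprintf("probe of method %s must be at least 10 nt",
                               object@methodId[i]))
            if (!.validIupac(pr))
                return(sprintf("probe of method %s contains a non-IUPAC character",
                               object@methodId[i]))
        }
    }
    TRUE
})

#' Construct a DetectionMethodSet
#'
#' @param methodId character, unique identifiers.
#' @param methodType character, method specificity class.
#' @param targetName character, targeted element names.
#' @param primer1,primer2 character, IUPAC primer sequences (length >= 10).
#' @param probe character, IUPAC probe sequences; \code{NA} (or \code{""})
#'   for probe-less assays.
#' @return A \linkS4class{DetectionMethodSet}.
#' @examples
#' m <- DetectionMethodSet("M1", "element_specific", "p35S",
#'                         "ACGTACGTACGTACGTACGT", "TTGCATTGCATTGCATTGCA")
#' methodIds(m)
#' @export
DetectionMethodSet <- function(methodId, methodType, targetName,
                               primer1, primer2, probe = NA_character_) {
    n <- length(methodId)
    probe <- rep_len(as.character(probe), n)
    probe[!is.na(probe) & probe == ""] <- NA_character_
    new("DetectionMethodSet",
        methodId = as.character(methodId),
        methodType = rep_len(as.character(methodType), n),
        targetName = rep_len(as.character(targetName), n),
        primer1 = rep_len(toupper(as.character(primer1)), n),
        primer2 = rep_len(toupper(as.character(primer2)), n),
        probe = toupper(probe))
}

#' GM event sequence collection
#'
#' A \link[Biostrings]{DNAStringSet} whose records are the template sequences
#' of GM transformation events; an event may own several sequences (e.g. a
#' retransformation of an earlier event, or a stacked event), grouped by the
#' \code{event_id} metadata column.  Sequences are uppercase on ingest and
#' ungapped.
#'
#' @aliases GMOEventSet-class
#' @exportClass GMOEventSet
setClass("GMOEventSet", contains = "DNAStringSet")

setValidity("GMOEventSet", function(object) {
    mc <- mcols(object)
    if (is.null(mc) || !all(c("event_id", "label") %in% colnames(mc)))
        return("mcols must contain event_id and label")
    if (length(object) > 0L) {
        if (anyNA(mc$event_id) || any(mc$event_id == ""))
            return("event_id must be non-empty")
        af <- Biostrings::alphabetFrequency(object)
        if (any(af[, c("-", "+", "."), drop = FALSE] > 0))
            return("sequences must be ungapped nucleotide strings")
        if (any(BiocGenerics::width(object) == 0L))
            return("empty sequence record")
    }
    TRUE
})

#' Construct a GMOEventSet
#'
#' @param sequences character vector or \code{DNAStringSet} of template
#'   sequences (lowercase accepted, normalised to uppercase).
#' @param eventId character, event identifier per sequence; repeated
#'   identifiers group sequences into one event.
#' @param label character, per-sequence label (defaults to \code{"seq1"},
#'   \code{"seq2"}, ... within each event).
#' @return A \linkS4class{GMOEventSet}.
#' @examples
#' ev <- GMOEventSet(c("ACGTACGT", "ttttgggg"), c("EV1", "EV1"))
#' eventIds(ev)
#' @export
GMOEventSet <- function(sequences, eventId, label = NULL) {
    if (is(sequences, "DNAStringSet"))
        sequences <- as.character(sequences)
    sequences <- toupper(as.character(sequences))
    eventId <- as.character(eventId)
    stopifnot(length(sequences) == length(eventId))
    if (is.null(label)) {
        # index within event, in input order
        cnt <- stats::ave(seq_along(eventId), eventId, FUN = seq_along)
        label <- paste0("seq", cnt)
    }
    x <- Biostrings::DNAStringSet(sequences)
    names(x) <- paste(eventId, label, sep = "|")
    mcols(x) <- DataFrame(event_id = eventId, label = as.character(label))
    new("GMOEventSet", x)
}

#' Probe-to-amplicon alignment result
#'
#' Outcome of aligning a TaqMan probe against a candidate amplicon and its
#' reverse complement, keeping the better orientation.  Classification is
#' \code{"perfect"} (full-length exact annealing), \code{"imperfect"} (full
#' coverage within the mismatch/gap budgets) or \code{"none"}.
#'
#' @slot strand which amplicon orientation won ("+" or "-").
#' @slot mismatches,gapBases integer edit counts of the canonical alignment.
#' @slot covered logical, whole probe aligned within the amplicon.
#' @slot classification "perfect", "imperfect" or "none".
#' @slot score integer alignment score (match +1, mismatch -1, gap base -2).
#' @aliases ProbeAlignment-class
#' @exportClass ProbeAlignment
setClass("ProbeAlignment",
    representation(strand = "character", mismatches = "integer",
                   gapBases = "integer", covered = "logical",
                   classification = "character", score = "integer"))

setValidity("ProbeAlignment", function(object) {
    if (!object@classification %in% c("perfect", "imperfect", "none"))
        return("classification must be perfect/imperfect/none")
    if (object@classification == "perfect" &&
        (object@mismatches != 0L || object@gapBases != 0L || !object@covered))
        return("perfect implies 0 mismatches, 0 gap bases, full coverage")
    if (object@classification == "imperfect" &&
        (!object@covered || object@mismatches > 2L || object@gapBases > 2L))
        return("imperfect implies coverage and both edit budgets respected")
    TRUE
})

#' Pre-computed detection score for one method x event pair
#'
#' @slot eventId,methodId identifiers of the scored pair.
#' @slot score integer 0 (no detection), 1 (imperfect primer/probe binding)
#'   or 2 (perfect primers and probe).
#' @slot selfPairWarning logical, some retained amplicon was formed by a
#'   single primer pairing with itself.
#' @slot bestHit zero- or one-row \code{DataFrame} describing the best
#'   retained amplicon.
#' @slot probeAlignment the \linkS4class{ProbeAlignment} of the best hit, or
#'   \code{NULL}.
#' @aliases PairScore-class
#' @exportClass PairScore
setClass("PairScore",
    representation(eventId = "character", methodId = "character",
                   score = "integer", selfPairWarning = "logical",
                   bestHit = "DFrame", probeAlignment = "ANY"))

setValidity("PairScore", function(object) {
    if (!object@score %in% 0:2)
        return("score must be 0, 1 or 2")
    if (object@score == 0L && nrow(object@bestHit) != 0L)
        return("score 0 implies no best hit")
    if (object@score > 0L && nrow(object@bestHit) != 1L)
        return("positive score requires exactly one best hit")
    TRUE
})

#' Embedded score store
#'
#' The desk-scale stand-in for the platform's relational score database: a
#' keyed table of (event_id, method_id, score, warning) rows plus the edit
#' budget/amplicon thresholds the scores were computed under.  Persisted as a
#' single self-describing TSV file.
#'
#' @slot table data.frame with columns event_id, method_id, score, warning,
#'   unique on (event_id, method_id).
#' @slot thresholds named list: maxMismatches, maxGaps, ampliconMin,
#'   ampliconMax.
#' @aliases ScoreStore-class
#' @exportClass ScoreStore
setClass("ScoreStore",
    representation(table = "data.frame", thresholds = "list"))

setValidity("ScoreStore", function(object) {
    tb <- object@table
    need <- c("event_id", "method_id", "score", "warning")
    if (!identical(colnames(tb), need))
        return("table columns must be event_id, method_id, score, warning")
    if (nrow(tb) > 0L) {
        if (!all(tb$score %in% 0:2))
            return("scores must be 0, 1 or 2")
        if (anyDuplicated(paste(tb$event_id, tb$method_id, sep = "\r")))
            return("duplicate (event_id, method_id) pair")
    }
    th <- object@thresholds
    need <- c("maxMismatches", "maxGaps", "ampliconMin", "ampliconMax")
    if (!all(need %in% names(th)))
        return("thresholds must name maxMismatches, maxGaps, ampliconMin, ampliconMax")
    TRUE
})

#' Screening matrix of detection scores
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with GM events as rows
#' and detection methods as columns, carrying two assays: \code{score}
#' (integer 0/1/2) and \code{warning} (logical self-pair flag).
#'
#' @aliases ScreeningMatrix-class
#' @exportClass ScreeningMatrix
setClass("ScreeningMatrix", contains = "SummarizedExperiment")

setValidity("ScreeningMatrix", function(object) {
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("score", "warning") %in% an))
        return("assays 'score' and 'warning' are required")
    sc <- SummarizedExperiment::assay(object, "score")
    if (length(sc) > 0L && !all(sc %in% 0:2))
        return("scores must be 0, 1 or 2")
    TRUE
})

#' Observed screening pattern
#'
#' The positive/negative outcome of a set of screening assays run on one
#' laboratory sample, used as the query of the event finder.
#'
#' @slot positive,negative character vectors of method identifiers; a method
#'   may not appear twice.
#' @aliases ScreeningPattern-class
#' @exportClass ScreeningPattern
setClass("ScreeningPattern",
    representation(positive = "character", negative = "character"))

setValidity("ScreeningPattern", function(object) {
    both <- intersect(object@positive, object@negative)
    if (length(both) > 0L)
        return(sprintf("method %s listed as both positive and negative", both[1L]))
    if (anyDuplicated(object@positive) || anyDuplicated(object@negative))
        return("duplicated method in pattern")
    TRUE
})

#' Event finder result
#'
#' Minimal combinations of GM events (size 1 to maxComboSize) whose pooled in
#' silico detections reproduce an observed screening pattern, together with
#' the screening-matrix excerpt restricted to the involved events and the
#' pattern's methods.
#'
#' @slot combinations list of character vectors of event ids, each minimal,
#'   sorted by size then lexicographically.
#' @slot matrixExcerpt \linkS4class{ScreeningMatrix} for the involved events.
#' @slot pattern the queried \linkS4class{ScreeningPattern}.
#' @slot policy how ambiguous score-1 cells were interpreted.
#' @aliases FinderResult-class
#' @exportClass FinderResult
setClass("FinderResult",
    representation(combinations = "list", matrixExcerpt = "ScreeningMatrix",
                   pattern = "ScreeningPattern", policy = "character"))

#' Synthetic screening panel specification
#'
#' Parameters of the deterministic generator that emulates the confidential
#' reference collections: per-cell planted detection scores, planted self-pair
#' cassettes, and sequence geometry.  Defaults keep planted amplicons in the
#' 70-200 bp band typical of validated TaqMan screening assays.
#'
#' @slot nEvents,nMethods panel dimensions.
#' @slot backboneLength minimum event sequence length (bases).
#' @slot primerLength,probeLength oligo lengths (bases).
#' @slot spacerRange inclusive range of the inter-primer spacer (bases).
#' @slot scoreGrid nEvents x nMethods integer matrix of planted scores.
#' @slot selfPairCells two-column matrix of (event, method) indices receiving
#'   an additional same-primer convergent cassette; restricted to score-2
#'   cells so the planted grid stays the ground truth.
#' @slot probeMethods logical, which methods carry a probe.
#' @slot score1Mode "primer" or "probe": where the single planted
#'   substitution of score-1 cells goes.
#' @slot sequencesPerEvent integer, number of template sequences per event.
#' @slot seed integer RNG seed; all outputs are pure functions of the spec.
#' @aliases PanelSpec-class
#' @exportClass PanelSpec
setClass("PanelSpec",
    representation(nEvents = "integer", nMethods = "integer",
                   backboneLength = "integer", primerLength = "integer",
                   probeLength = "integer", spacerRange = "integer",
                   scoreGrid = "matrix", selfPairCells = "matrix",
                   probeMethods = "logical", score1Mode = "character",
                   sequencesPerEvent = "integer", seed = "integer"))

setValidity("PanelSpec", function(object) {
    if (object@nEvents < 1L || object@nMethods < 1L)
        return("panel must have at least one event and one method")
    if (!identical(dim(object@scoreGrid),
                   c(object@nEvents, object@nMethods)))
        return("scoreGrid dimensions must be nEvents x nMethods")
    if (!all(object@scoreGrid %in% 0:2))
        return("scoreGrid values must be 0, 1 or 2")
    sr <- object@spacerRange
    if (length(sr) != 2L || sr[1L] > sr[2L] || sr[1L] < 0L)
        return("spacerRange must be an increasing non-negative pair")
    amin <- 2L * object@primerLength + sr[1L]
    amax <- 2L * object@primerLength + sr[2L]
    if (amin < 20L || amax > 500L)
        return("spacerRange would push planted amplicons outside [20, 500] bp")
    if (any(object@probeMethods) && object@probeLength > sr[1L])
        return("probe must fit inside the smallest spacer")
    if (object@primerLength < 10L || object@probeLength < 10L)
        return("primers and probes must be at least 10 nt")
    if (nrow(object@selfPairCells) > 0L) {
        sp <- object@selfPairCells
        if (ncol(sp) != 2L)
            return("selfPairCells must have two columns (event, method)")
        if (any(sp[, 1L] < 1L | sp[, 1L] > object@nEvents |
                sp[, 2L] < 1L | sp[, 2L] > object@nMethods))
            return("selfPairCells indices out of range")
        if (any(object@scoreGrid[sp] != 2L))
            return("selfPairCells are only planted in score-2 cells")
    }
    if (!object@score1Mode %in% c("primer", "probe"))
        return("score1Mode must be 'primer' or 'probe'")
    if (object@score1Mode == "probe") {
        hasS1 <- apply(object@scoreGrid == 1L, 2L, any)
        if (any(hasS1 & !object@probeMethods))
            return("probe-mode score-1 cells require a probe-bearing method")
    }
    if (length(object@sequencesPerEvent) != object@nEvents ||
        any(object@sequencesPerEvent < 1L))
        return("sequencesPerEvent must be positive, one value per event")
    TRUE
})
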