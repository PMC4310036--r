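#' @name accessors
#' @title Accessors for gmoscreen classes
#' @description Small read-only accessors for the package's S4 containers;
#'   slot access from user code is never needed.
#' @param x an object of the documented class.
#' @param ... ignored.
#' @return The corresponding component (see each accessor).
NULL

#' @rdname accessors
#' @export
setGeneric("methodIds", function(x, ...) standardGeneric("methodIds"))

#' @rdname accessors
#' @export
setGeneric("methodTypes", function(x, ...) standardGeneric("methodTypes"))

#' @rdname accessors
#' @export
setGeneric("targetNames", function(x, ...) standardGeneric("targetNames"))

#' @rdname accessors
#' @export
setGeneric("primer1", function(x, ...) standardGeneric("primer1"))

#' @rdname accessors
#' @export
setGeneric("primer2", function(x, ...) standardGeneric("primer2"))

#' @rdname accessors
#' @export
setGeneric("probes", function(x, ...) standardGeneric("probes"))

#' @rdname accessors
#' @export
setGeneric("eventIds", function(x, ...) standardGeneric("eventIds"))

#' @rdname accessors
#' @export
setGeneric("eventLabels", function(x, ...) standardGeneric("eventLabels"))

#' @rdname accessors
#' @export
setGeneric("classification", function(x, ...) standardGeneric("classification"))

#' @rdname accessors
#' @export
setGeneric("selfPairWarning", function(x, ...) standardGeneric("selfPairWarning"))

#' @rdname accessors
#' @export
setGeneric("bestHit", function(x, ...) standardGeneric("bestHit"))

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x, ...) standardGeneric("scoreMatrix"))

#' @rdname accessors
#' @export
setGeneric("warningMatrix", function(x, ...) standardGeneric("warningMatrix"))

#' @rdname accessors
#' @export
setGeneric("storeThresholds", function(x, ...) standardGeneric("storeThresholds"))

#' @rdname accessors
#' @export
setGeneric("scoreTable", function(x, ...) standardGeneric("scoreTable"))

#' @rdname accessors
#' @export
setGeneric("combinations", function(x, ...) standardGeneric("combinations"))

#' @rdname accessors
#' @export
setGeneric("matrixExcerpt", function(x, ...) standardGeneric("matrixExcerpt"))

# ---- DetectionMethodSet ----

#' @rdname accessors
#' @export
setMethod("methodIds", "DetectionMethodSet", function(x, ...) x@methodId)

#' @rdname accessors
#' @export
setMethod("methodTypes", "DetectionMethodSet", function(x, ...)
    setNames(x@methodType, x@methodId))

#' @rdname accessors
#' @export
setMethod("targetNames", "DetectionMethodSet", function(x, ...)
    setNames(x@targetName, x@methodId))

#' @rdname accessors
#' @export
setMethod("primer1", "DetectionMethodSet", function(x, ...)
    setNames(x@primer1, x@methodId))

#' @rdname accessors
#' @export
setMethod("primer2", "DetectionMethodSet", function(x, ...)
    setNames(x@primer2, x@methodId))

#' @rdname accessors
#' @export
setMethod("probes", "DetectionMethodSet", function(x, ...)
    setNames(x@probe, x@methodId))

#' @export
setMethod("length", "DetectionMethodSet", function(x) length(x@methodId))

#' @export
setMethod("[", "DetectionMethodSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) {
        miss <- setdiff(i, x@methodId)
        if (length(miss) > 0L)
            stop(sprintf("unknown method_id: %s", miss[1L]), call. = FALSE)
        i <- match(i, x@methodId)
    }
    initialize(x, methodId = x@methodId[i], methodType = x@methodType[i],
               targetName = x@targetName[i], primer1 = x@primer1[i],
               primer2 = x@primer2[i], probe = x@probe[i])
})

setMethod("show", "DetectionMethodSet", function(object) {
    cat(sprintf("DetectionMethodSet with %d method(s)\n", length(object)))
    if (length(object) > 0L) {
        probed <- ifelse(is.na(object@probe), "-", "probe")
        cat(sprintf("  %s [%s] %s (%s)\n", object@methodId,
                    object@methodType, object@targetName, probed), sep = "")
    }
})

# ---- GMOEventSet ----

#' @rdname accessors
#' @export
setMethod("eventIds", "GMOEventSet", function(x, ...) unique(mcols(x)$event_id))

#' @rdname accessors
#' @export
setMethod("eventLabels", "GMOEventSet", function(x, ...)
    setNames(mcols(x)$label, mcols(x)$event_id))

#' Extract the sequences of one or more events
#'
#' @param x a \linkS4class{GMOEventSet}.
#' @param ids character vector of event identifiers; sequences are returned
#'   grouped in the requested event order, preserving each event's internal
#'   sequence order.
#' @return A \linkS4class{GMOEventSet} restricted to \code{ids}.
#' @export
selectEvents <- function(x, ids) {
    stopifnot(is(x, "GMOEventSet"))
    have <- eventIds(x)
    miss <- setdiff(ids, have)
    if (length(miss) > 0L)
        stop(sprintf("unknown event_id: %s", miss[1L]), call. = FALSE)
    keep <- unlist(lapply(ids, function(id) which(mcols(x)$event_id == id)))
    new("GMOEventSet", x[keep])
}

setMethod("show", "GMOEventSet", function(object) {
    ids <- eventIds(object)
    cat(sprintf("GMOEventSet: %d sequence(s) across %d event(s)\n",
                length(object), length(ids)))
    callNextMethod()
})

# ---- ProbeAlignment ----

#' @rdname accessors
#' @export
setMethod("classification", "ProbeAlignment", function(x, ...) x@classification)

#' @rdname accessors
#' @export
setMethod("strand", "ProbeAlignment", function(x, ...) x@strand)

#' @rdname accessors
#' @export
setMethod("score", "ProbeAlignment", function(x, ...) x@score)

setMethod("show", "ProbeAlignment", function(object) {
    cat(sprintf("ProbeAlignment: %s (strand %s, %d mismatch(es), %d gap base(s), score %d)\n",
                object@classification, object@strand, object@mismatches,
                object@gapBases, object@score))
})

# ---- PairScore ----

#' @rdname accessors
#' @export
setMethod("score", "PairScore", function(x, ...) x@score)

#' @rdname accessors
#' @export
setMethod("selfPairWarning", "PairScore", function(x, ...) x@selfPairWarning)

#' @rdname accessors
#' @export
setMethod("bestHit", "PairScore", function(x, ...) x@bestHit)

#' @rdname accessors
#' @export
setMethod("eventIds", "PairScore", function(x, ...) x@eventId)

#' @rdname accessors
#' @export
setMethod("methodIds", "PairScore", function(x, ...) x@methodId)

setMethod("show", "PairScore", function(object) {
    cat(sprintf("PairScore %s x %s: %d%s\n", object@eventId, object@methodId,
                object@score, if (object@selfPairWarning) " (self-pair warning)" else ""))
})

# ---- ScoreStore ----

#' @rdname accessors
#' @export
setMethod("scoreTable", "ScoreStore", function(x, ...) x@table)

#' @rdname accessors
#' @export
setMethod("storeThresholds", "ScoreStore", function(x, ...) x@thresholds)

#' @rdname accessors
#' @export
setMethod("eventIds", "ScoreStore", function(x, ...) unique(x@table$event_id))

#' @rdname accessors
#' @export
setMethod("methodIds", "ScoreStore", function(x, ...) unique(x@table$method_id))

#' @export
setMethod("length", "ScoreStore", function(x) nrow(x@table))

setMethod("show", "ScoreStore", function(object) {
    th <- object@thresholds
    cat(sprintf(
        "ScoreStore: %d pair(s), %d event(s) x %d method(s)\n  thresholds: mm<=%d, gaps<=%d, amplicon %d-%d bp\n",
        nrow(object@table), length(eventIds(object)), length(methodIds(object)),
        th$maxMismatches, th$maxGaps, th$ampliconMin, th$ampliconMax))
})

# ---- ScreeningMatrix ----

#' @rdname accessors
#' @export
setMethod("scoreMatrix", "ScreeningMatrix", function(x, ...)
    SummarizedExperiment::assay(x, "score"))

#' @rdname accessors
#' @export
setMethod("warningMatrix", "ScreeningMatrix", function(x, ...)
    SummarizedExperiment::assay(x, "warning"))

#' @rdname accessors
#' @export
setMethod("eventIds", "ScreeningMatrix", function(x, ...) rownames(x))

#' @rdname accessors
#' @export
setMethod("methodIds", "ScreeningMatrix", function(x, ...) colnames(x))

# ---- FinderResult ----

#' @rdname accessors
#' @export
setMethod("combinations", "FinderResult", function(x, ...) x@combinations)

#' @rdname accessors
#' @export
setMethod("matrixExcerpt", "FinderResult", function(x, ...) x@matrixExcerpt)

setMethod("show", "FinderResult", function(object) {
    n <- length(object@combinations)
    cat(sprintf("FinderResult: %d fitting combination(s) [policy: %s]\n",
                n, object@policy))
    for (cmb in object@combinations)
        cat("  ", paste(cmb, collapse = " + "), "\n", sep = "")
})

setMethod("show", "PanelSpec", function(object) {
    cat(sprintf(
        "PanelSpec: %d event(s) x %d method(s), seed %d\n  backbone >= %d bp, primer %d nt, probe %d nt, spacer %d-%d bp, %d self-pair cell(s)\n",
        object@nEvents, object@nMethods, object@seed, object@backboneLength,
        object@primerLength, object@probeLength, object@spacerRange[1L],
        object@spacerRange[2L], nrow(object@selfPairCells)))
})

setMethod("show", "ScreeningPattern", function(object) {
    cat(sprintf("ScreeningPattern: %d positive, %d negative\n",
                length(object@positive), length(object@negative)))
    if (length(object@positive)) cat("  +:", paste(object@positive, collapse = ", "), "\n")
    if (length(object@negative)) cat("  -:", paste(object@negative, collapse = ", "), "\n")
})
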