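.defaultThresholds <- function(maxMismatches = 2L, maxGaps = 2L,
                               ampliconMin = 20L, ampliconMax = 500L) {
    list(maxMismatches = as.integer(maxMismatches),
         maxGaps = as.integer(maxGaps),
         ampliconMin = as.integer(ampliconMin),
         ampliconMax = as.integer(ampliconMax))
}

#' Score one detection method against one GM event
#'
#' Runs the full in silico detection simulation for a single pair: candidate
#' amplicons are enumerated over all three primer pairings on every template
#' sequence of the event and pooled.  For probe-bearing methods each
#' amplicon is probe-classified and amplicons the probe cannot bind within
#' budget are discarded (a TaqMan signal requires probe hydrolysis).  The
#' score is then the best retained hit: 2 when both primer sites are exact
#' and the probe (if any) anneals perfectly, 1 when a potential amplicon
#' survives despite imperfect primer or probe binding, 0 when nothing is
#' retained.  Ties for the reported best hit are broken by quality, fewer
#' total primer edits, lower sequence index, then leftmost amplicon start.
#' Any retained self-pairing amplicon raises the self-pair warning flag.
#'
#' @param method a one-method \linkS4class{DetectionMethodSet}.
#' @param event a \linkS4class{GMOEventSet} holding the sequences of exactly
#'   one event.
#' @param maxMismatches,maxGaps per-primer-site edit budgets.
#' @param ampliconMin,ampliconMax amplicon length bounds (bases).
#' @return A \linkS4class{PairScore}.
#' @export
scorePair <- function(method, event, maxMismatches = 2L, maxGaps = 2L,
                      ampliconMin = 20L, ampliconMax = 500L) {
    stopifnot(is(method, "DetectionMethodSet"), length(method) == 1L)
    stopifnot(is(event, "GMOEventSet"))
    evIds <- eventIds(event)
    if (length(evIds) != 1L)
        stop("scorePair expects the sequences of exactly one event", call. = FALSE)
    p1 <- method@primer1
    p2 <- method@primer2
    probe <- method@probe

    hits <- list()
    probeAlns <- list()
    for (k in seq_along(event)) {
        tmpl <- as.character(event[[k]])
        h <- as.data.frame(enumerateAmplicons(p1, p2, tmpl,
                                              maxMismatches, maxGaps,
                                              ampliconMin, ampliconMax))
        if (nrow(h) == 0L) next
        h$sequenceIndex <- k
        if (!is.na(probe)) {
            pa <- lapply(seq_len(nrow(h)), function(r)
                alignProbe(probe, ampliconSequence(tmpl, h$ampliconStart[r],
                                                   h$ampliconEnd[r]),
                           maxMismatches, maxGaps))
            cls <- vapply(pa, classification, character(1))
            keep <- cls != "none"
            h <- h[keep, , drop = FALSE]
            pa <- pa[keep]
            if (nrow(h) == 0L) next
            h$probeClassification <- vapply(pa, classification, character(1))
            probeAlns <- c(probeAlns, pa)
        } else {
            h$probeClassification <- NA_character_
        }
        hits[[length(hits) + 1L]] <- h
    }

    if (length(hits) == 0L)
        return(new("PairScore", eventId = evIds, methodId = method@methodId,
                   score = 0L, selfPairWarning = FALSE,
                   bestHit = DataFrame(), probeAlignment = NULL))

    h <- do.call(rbind, hits)
    perfectPrimers <- h$leftMismatches + h$leftGapBases +
        h$rightMismatches + h$rightGapBases == 0L
    perfectProbe <- is.na(probe) | (!is.na(h$probeClassification) &
                                    h$probeClassification == "perfect")
    quality <- ifelse(perfectPrimers & perfectProbe, 2L, 1L)
    ord <- order(-quality, h$totalEdits, h$sequenceIndex, h$ampliconStart,
                 h$ampliconEnd)
    best <- h[ord[1L], , drop = FALSE]
    rownames(best) <- NULL
    bestProbe <- if (is.na(probe)) NULL else probeAlns[[ord[1L]]]
    new("PairScore", eventId = evIds, methodId = method@methodId,
        score = max(quality), selfPairWarning = any(h$pairKind != "p1_p2"),
        bestHit = DataFrame(best), probeAlignment = bestProbe)
}

#' Score every method x event pair of a panel
#'
#' @param methods a \linkS4class{DetectionMethodSet}.
#' @param events a \linkS4class{GMOEventSet}.
#' @param maxMismatches,maxGaps,ampliconMin,ampliconMax simulation
#'   thresholds, recorded in the returned store.
#' @return A \linkS4class{ScoreStore} with one row per pair, events in
#'   collection order as the outer loop.
#' @export
scorePanel <- function(methods, events, maxMismatches = 2L, maxGaps = 2L,
                       ampliconMin = 20L, ampliconMax = 500L) {
    stopifnot(is(methods, "DetectionMethodSet"), is(events, "GMOEventSet"))
    evIds <- eventIds(events)
    rows <- vector("list", length(evIds) * length(methods))
    n <- 0L
    for (ev in evIds) {
        evSeqs <- selectEvents(events, ev)
        for (j in seq_len(length(methods))) {
            ps <- scorePair(methods[j], evSeqs, maxMismatches, maxGaps,
                            ampliconMin, ampliconMax)
            n <- n + 1L
            rows[[n]] <- data.frame(event_id = ev,
                                    method_id = methods@methodId[j],
                                    score = score(ps),
                                    warning = selfPairWarning(ps),
                                    stringsAsFactors = FALSE)
        }
    }
    new("ScoreStore", table = do.call(rbind, rows),
        thresholds = .defaultThresholds(maxMismatches, maxGaps,
                                        ampliconMin, ampliconMax))
}

#' Create an empty or pre-filled score store
#'
#' @param table optional data.frame with columns event_id, method_id, score,
#'   warning.
#' @param thresholds named list of simulation thresholds (defaults to the
#'   standard budgets: 2 mismatches, 2 gap bases, amplicon 20-500 bp).
#' @return A \linkS4class{ScoreStore}.
#' @export
scoreStore <- function(table = NULL, thresholds = .defaultThresholds()) {
    if (is.null(table))
        table <- data.frame(event_id = character(0), method_id = character(0),
                            score = integer(0), warning = logical(0),
                            stringsAsFactors = FALSE)
    table$score <- as.integer(table$score)
    table$warning <- as.logical(table$warning)
    rownames(table) <- NULL
    new("ScoreStore", table = table[, c("event_id", "method_id",
                                        "score", "warning")],
        thresholds = thresholds)
}

#' Look up the score of one pair
#'
#' @param store a \linkS4class{ScoreStore}.
#' @param eventId,methodId identifiers of the pair.
#' @return Named list with \code{score} and \code{warning}.
#' @export
getScore <- function(store, eventId, methodId) {
    stopifnot(is(store, "ScoreStore"))
    i <- which(store@table$event_id == eventId &
               store@table$method_id == methodId)
    if (length(i) == 0L)
        stop(sprintf("no score stored for pair (%s, %s)", eventId, methodId),
             call. = FALSE)
    list(score = store@table$score[i], warning = store@table$warning[i])
}

#' Insert or replace pair scores
#'
#' Existing (event_id, method_id) rows are replaced in place; new pairs are
#' appended, supporting the regular-update workflow of the score database.
#'
#' @param store a \linkS4class{ScoreStore}.
#' @param pairs a list of \linkS4class{PairScore} objects, or a data.frame
#'   with columns event_id, method_id, score, warning.
#' @return The updated \linkS4class{ScoreStore}.
#' @export
upsertScores <- function(store, pairs) {
    stopifnot(is(store, "ScoreStore"))
    if (is.list(pairs) && !is.data.frame(pairs)) {
        pairs <- do.call(rbind, lapply(pairs, function(p) {
            stopifnot(is(p, "PairScore"))
            data.frame(event_id = p@eventId, method_id = p@methodId,
                       score = p@score, warning = p@selfPairWarning,
                       stringsAsFactors = FALSE)
        }))
    }
    tb <- store@table
    for (r in seq_len(nrow(pairs))) {
        i <- which(tb$event_id == pairs$event_id[r] &
                   tb$method_id == pairs$method_id[r])
        row <- data.frame(event_id = pairs$event_id[r],
                          method_id = pairs$method_id[r],
                          score = as.integer(pairs$score[r]),
                          warning = as.logical(pairs$warning[r]),
                          stringsAsFactors = FALSE)
        if (length(i) == 1L) tb[i, ] <- row else tb <- rbind(tb, row)
    }
    rownames(tb) <- NULL
    initialize(store, table = tb)
}

#' Persist a score store to a single file
#'
#' Writes the store as a self-describing TSV: two header comment lines
#' (format tag and the simulation thresholds) followed by the pair table.
#' [loadScores()] inverts it losslessly, and a load/persist round trip is
#' byte-identical.
#'
#' @param store a \linkS4class{ScoreStore}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
persistScores <- function(store, path) {
    stopifnot(is(store, "ScoreStore"))
    th <- store@thresholds
    tb <- store@table
    lines <- c("# gmoscreen score store v1",
               sprintf("# max_mismatches=%d\tmax_gaps=%d\tamplicon_min=%d\tamplicon_max=%d",
                       th$maxMismatches, th$maxGaps, th$ampliconMin,
                       th$ampliconMax),
               "event_id\tmethod_id\tscore\twarning",
               if (nrow(tb) > 0L)
                   paste(tb$event_id, tb$method_id, tb$score,
                         as.integer(tb$warning), sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Load a score store from file
#'
#' @param path path written by [persistScores()].
#' @return A \linkS4class{ScoreStore}.
#' @export
loadScores <- function(path) {
    if (!file.exists(path))
        stop(sprintf("score store not found: %s", path), call. = FALSE)
    lines <- readLines(path)
    if (length(lines) < 3L || lines[1L] != "# gmoscreen score store v1")
        stop("corrupt score store: missing format header", call. = FALSE)
    thm <- regmatches(lines[2L],
        regexec("^# max_mismatches=(\\d+)\tmax_gaps=(\\d+)\tamplicon_min=(\\d+)\tamplicon_max=(\\d+)$",
                lines[2L]))[[1L]]
    if (length(thm) != 5L)
        stop("corrupt score store: bad thresholds line", call. = FALSE)
    if (lines[3L] != "event_id\tmethod_id\tscore\twarning")
        stop("corrupt score store: bad column header", call. = FALSE)
    th <- .defaultThresholds(as.integer(thm[2L]), as.integer(thm[3L]),
                             as.integer(thm[4L]), as.integer(thm[5L]))
    body <- lines[-(1:3)]
    body <- body[nzchar(body)]
    if (length(body) == 0L) return(scoreStore(thresholds = th))
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 4L))
        stop("corrupt score store: malformed row", call. = FALSE)
    m <- do.call(rbind, parts)
    sc <- suppressWarnings(as.integer(m[, 3L]))
    wn <- suppressWarnings(as.integer(m[, 4L]))
    if (anyNA(sc) || anyNA(wn) || !all(sc %in% 0:2) || !all(wn %in% 0:1))
        stop("corrupt score store: invalid score or warning value", call. = FALSE)
    scoreStore(data.frame(event_id = m[, 1L], method_id = m[, 2L],
                          score = sc, warning = wn == 1L,
                          stringsAsFactors = FALSE),
               thresholds = th)
}
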