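.POLICIES <- c("wildcard", "as_positive", "as_negative")

#' Describe an observed screening pattern
#'
#' @param positive,negative character vectors of method identifiers that gave
#'   positive / negative laboratory results; a method may not appear in both.
#' @return A \linkS4class{ScreeningPattern}.
#' @export
screeningPattern <- function(positive = character(0), negative = character(0)) {
    new("ScreeningPattern", positive = as.character(positive),
        negative = as.character(negative))
}

# Per-method detection calls for a set of events under an ambiguity policy.
# Score 2 is always detected, score 0 never; score 1 ("imperfect") is
# empirically unpredictable, so its reading is a policy: wildcard treats it
# as detected when satisfying positives but undetected when checking
# negatives (the most permissive consistent reading), as_positive /
# as_negative force one reading for both checks.
.detectionCalls <- function(scores, policy) {
    list(forPositive = scores == 2L |
             (scores == 1L & policy %in% c("wildcard", "as_positive")),
         forNegative = scores == 2L |
             (scores == 1L & policy == "as_positive"))
}

.patternScores <- function(pattern, eventIds, store) {
    meths <- c(pattern@positive, pattern@negative)
    sc <- matrix(NA_integer_, length(eventIds), length(meths),
                 dimnames = list(eventIds, meths))
    for (ev in eventIds)
        for (m in meths)
            sc[ev, m] <- getScore(store, ev, m)$score
    sc
}

#' Does an event combination fit a screening pattern?
#'
#' A combination fits when every positive method detects at least one of its
#' member events and no negative method detects any member, with score-1
#' cells read according to \code{policy}.
#'
#' @param pattern a \linkS4class{ScreeningPattern}.
#' @param combo character vector of event identifiers (a candidate mix).
#' @param store a \linkS4class{ScoreStore} holding every required pair.
#' @param policy \code{"wildcard"} (default), \code{"as_positive"} or
#'   \code{"as_negative"}: how ambiguous score-1 cells count.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
patternFits <- function(pattern, combo, store,
                        policy = c("wildcard", "as_positive", "as_negative")) {
    stopifnot(is(pattern, "ScreeningPattern"), is(store, "ScoreStore"))
    policy <- match.arg(policy)
    combo <- unique(as.character(combo))
    if (length(combo) == 0L)
        return(length(pattern@positive) == 0L)
    sc <- .patternScores(pattern, combo, store)
    det <- .detectionCalls(sc, policy)
    posOk <- all(vapply(pattern@positive, function(m)
        any(det$forPositive[, m]), logical(1)))
    negOk <- !any(det$forNegative[, pattern@negative, drop = FALSE])
    posOk && negOk
}

#' Invert a screening pattern into candidate GM events
#'
#' Determines which GM events -- individually or as mixes of up to
#' \code{maxComboSize} different events -- would produce the observed pattern
#' of positive and negative screening results.  Detection calls are held as
#' per-method bit vectors over the event universe; positives are checked by
#' OR-accumulation over the combination and negatives exclude any event they
#' detect.  Only minimal fitting combinations are reported (no fitting proper
#' subset), deduplicated and sorted by size then lexicographically.
#'
#' @param pattern a \linkS4class{ScreeningPattern}.
#' @param store a \linkS4class{ScoreStore}; its event universe is searched.
#' @param maxComboSize largest mix size considered (default 3).
#' @param policy reading of ambiguous score-1 cells, see [patternFits()].
#' @return A \linkS4class{FinderResult}; its matrix excerpt covers the
#'   involved events (row order of first appearance) and the pattern's
#'   methods (positives first).
#' @export
findEvents <- function(pattern, store, maxComboSize = 3L,
                       policy = c("wildcard", "as_positive", "as_negative")) {
    stopifnot(is(pattern, "ScreeningPattern"), is(store, "ScoreStore"))
    policy <- match.arg(policy)
    if (maxComboSize < 1L)
        stop("maxComboSize must be at least 1", call. = FALSE)
    events <- eventIds(store)
    meths <- c(pattern@positive, pattern@negative)

    combos <- list()
    if (length(events) > 0L) {
        sc <- .patternScores(pattern, events, store)
        det <- .detectionCalls(sc, policy)
        # events detected by any negative method can join no fitting mix
        excluded <- if (length(pattern@negative) > 0L)
            apply(det$forNegative[, pattern@negative, drop = FALSE], 1L, any)
        else rep(FALSE, length(events))
        pool <- events[!excluded]
        posDet <- det$forPositive[pool, pattern@positive, drop = FALSE]

        covers <- function(ix) {
            ncol(posDet) == 0L ||
                all(apply(posDet[ix, , drop = FALSE], 2L, any))
        }
        for (size in seq_len(min(maxComboSize, length(pool)))) {
            sets <- utils::combn(seq_along(pool), size, simplify = FALSE)
            for (ix in sets) {
                if (!covers(ix)) next
                minimal <- size == 1L ||
                    !any(vapply(seq_along(ix), function(d)
                        covers(ix[-d]), logical(1)))
                if (minimal)
                    combos[[length(combos) + 1L]] <- sort(pool[ix])
            }
        }
    }
    if (length(combos) > 0L) {
        keyOrd <- order(lengths(combos),
                        vapply(combos, paste, character(1), collapse = "\r"))
        combos <- combos[keyOrd]
        combos <- combos[!duplicated(vapply(combos, paste, character(1),
                                            collapse = "\r"))]
    }

    involved <- unique(unlist(combos))
    excerpt <- buildMatrix(store,
                           eventIds = if (is.null(involved)) character(0)
                                      else involved,
                           methodIds = meths)
    new("FinderResult", combinations = combos, matrixExcerpt = excerpt,
        pattern = pattern, policy = policy)
}
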