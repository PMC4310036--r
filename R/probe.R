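# Best canonical window alignment of an encoded query against an encoded
# subject: maximise score, then fewest gap bases, then leftmost start, then
# shortest window.  Window lengths are searched within +/- band of the query
# length; with gap bases costing 2 and the binding budgets at 2, alignments
# beyond the default band of 4 can never classify as binding.
.bestWindowAlignment <- function(q, subj, band = 4L) {
    wins <- .scan_windows_cpp(q, subj, as.integer(band))
    if (nrow(wins) == 0L) return(NULL)
    mm <- .editCounts(wins[, "score"], wins[, "gaps"], wins[, "wlen"],
                      length(q))$mismatches
    # ties resolved on alignment quality (gaps, then mismatches) before
    # position, so the chosen edit class is independent of window placement
    o <- order(-wins[, "score"], wins[, "gaps"], mm,
               wins[, "start0"], wins[, "wlen"])
    best <- wins[o[1L], ]
    list(start0 = best[["start0"]], wlen = best[["wlen"]],
         score = best[["score"]], gaps = best[["gaps"]],
         mismatches = as.integer(mm[o[1L]]))
}

#' Align a TaqMan probe against a candidate amplicon
#'
#' A hydrolysis probe can anneal to either strand of the amplified fragment,
#' so the probe is aligned twice -- against the amplicon and against its
#' reverse complement -- and the better of the two canonical semi-global
#' alignments is kept (ties go to the plus orientation).  The full probe must
#' align within the amplicon.  Classification: \code{"perfect"} for exact
#' full-length annealing (degenerate codes matching at zero cost),
#' \code{"imperfect"} when the alignment stays within the mismatch/gap
#' budgets, \code{"none"} otherwise.
#'
#' @param probe IUPAC probe string, length >= 10.
#' @param amplicon plus-strand amplicon sequence (non-empty).
#' @param maxMismatches,maxGaps edit budgets for the imperfect class
#'   (defaults 2 and 2, mirroring the primer budgets).
#' @return A \linkS4class{ProbeAlignment}.
#' @export
alignProbe <- function(probe, amplicon, maxMismatches = 2L, maxGaps = 2L) {
    .checkBudgets(maxMismatches, maxGaps)
    p <- .encodeSeq(toupper(as.character(probe)), "probe")
    if (length(p) < 10L)
        stop("probe must be at least 10 nt", call. = FALSE)
    a <- .encodeSeq(toupper(as.character(amplicon)), "amplicon")
    if (length(a) == 0L)
        stop("empty amplicon", call. = FALSE)

    none <- new("ProbeAlignment", strand = "+", mismatches = NA_integer_,
                gapBases = NA_integer_, covered = FALSE,
                classification = "none", score = NA_integer_)
    plus <- .bestWindowAlignment(p, a)
    minus <- .bestWindowAlignment(p, .rcBits(a))
    if (is.null(plus) && is.null(minus)) return(none)
    # orientation ties are broken on quality (score, gaps, mismatches) before
    # defaulting to plus, making the classification invariant under
    # reverse-complementing the amplicon
    pick <- if (is.null(minus)) "+"
            else if (is.null(plus)) "-"
            else if (minus$score > plus$score ||
                     (minus$score == plus$score && minus$gaps < plus$gaps) ||
                     (minus$score == plus$score && minus$gaps == plus$gaps &&
                      minus$mismatches < plus$mismatches)) "-"
            else "+"
    best <- if (pick == "+") plus else minus
    cls <- if (best$mismatches == 0L && best$gaps == 0L) "perfect"
           else if (best$mismatches <= maxMismatches && best$gaps <= maxGaps)
               "imperfect"
           else "none"
    new("ProbeAlignment", strand = pick,
        mismatches = as.integer(best$mismatches),
        gapBases = as.integer(best$gaps), covered = TRUE,
        classification = cls, score = as.integer(best$score))
}
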