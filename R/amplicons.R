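.emptyHits <- function() {
    DataFrame(pairKind = character(0), leftPrimer = character(0),
              rightPrimer = character(0),
              leftStart = integer(0), leftEnd = integer(0),
              leftMismatches = integer(0), leftGapBases = integer(0),
              rightStart = integer(0), rightEnd = integer(0),
              rightMismatches = integer(0), rightGapBases = integer(0),
              ampliconStart = integer(0), ampliconEnd = integer(0),
              ampliconLength = integer(0), totalEdits = integer(0))
}

# cross all (plus site, minus site) pairs in convergent orientation and
# within the amplicon length bounds
.crossSites <- function(left, right, kind, leftRole, rightRole,
                        ampliconMin, ampliconMax, samePrimer) {
    if (is.null(left) || is.null(right) ||
        nrow(left) == 0L || nrow(right) == 0L) return(NULL)
    out <- list()
    for (a in seq_len(nrow(left))) {
        for (b in seq_len(nrow(right))) {
            if (samePrimer &&
                left$start[a] == right$start[b] && left$end[a] == right$end[b])
                next  # one footprint cannot prime against itself
            len <- right$end[b] - left$start[a] + 1L
            if (len < 1L) next          # divergent orientation
            if (len < ampliconMin || len > ampliconMax) next
            out[[length(out) + 1L]] <- data.frame(
                pairKind = kind, leftPrimer = leftRole, rightPrimer = rightRole,
                leftStart = left$start[a], leftEnd = left$end[a],
                leftMismatches = left$mismatches[a],
                leftGapBases = left$gapBases[a],
                rightStart = right$start[b], rightEnd = right$end[b],
                rightMismatches = right$mismatches[b],
                rightGapBases = right$gapBases[b],
                ampliconStart = left$start[a], ampliconEnd = right$end[b],
                ampliconLength = len,
                totalEdits = left$mismatches[a] + left$gapBases[a] +
                    right$mismatches[b] + right$gapBases[b],
                stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L) return(NULL)
    do.call(rbind, out)
}

#' Enumerate candidate amplicons on one template
#'
#' Replicates the re-PCR stage of the screening pipeline: binding sites for
#' both primers are located with [findBindingSites()], then amplicons are
#' formed for all three primer pairings -- the intended primer1/primer2 pair
#' and the two self pairings (primer1/primer1, primer2/primer2) -- from every
#' convergent (plus-strand site, minus-strand site) combination whose
#' end-to-end length, primer footprints included, lies within the amplicon
#' bounds.  Results are pooled across pairings; self-pairing amplicons fall
#' outside the assay's intent and set a warning downstream.
#'
#' @param primer1,primer2 IUPAC primer strings (length >= 10).
#' @param template nucleotide template string.
#' @param maxMismatches,maxGaps per-site edit budgets (defaults 2 and 2).
#' @param ampliconMin,ampliconMax inclusive amplicon length bounds in bases
#'   (defaults 20 and 500).
#' @return A \code{DataFrame} with one row per amplicon: pairing kind, both
#'   binding sites with their edit counts, amplicon interval (1-based
#'   inclusive), length and total primer edits.
#' @export
enumerateAmplicons <- function(primer1, primer2, template,
                               maxMismatches = 2L, maxGaps = 2L,
                               ampliconMin = 20L, ampliconMax = 500L) {
    if (ampliconMin < 1L || ampliconMin > ampliconMax)
        stop("amplicon bounds must satisfy 1 <= ampliconMin <= ampliconMax",
             call. = FALSE)
    s1 <- as.data.frame(findBindingSites(primer1, template, maxMismatches, maxGaps))
    s2 <- as.data.frame(findBindingSites(primer2, template, maxMismatches, maxGaps))
    plus1 <- s1[s1$strand == "+", , drop = FALSE]
    minus1 <- s1[s1$strand == "-", , drop = FALSE]
    plus2 <- s2[s2$strand == "+", , drop = FALSE]
    minus2 <- s2[s2$strand == "-", , drop = FALSE]

    parts <- list(
        .crossSites(plus1, minus2, "p1_p2", "primer1", "primer2",
                    ampliconMin, ampliconMax, samePrimer = FALSE),
        .crossSites(plus2, minus1, "p1_p2", "primer2", "primer1",
                    ampliconMin, ampliconMax, samePrimer = FALSE),
        .crossSites(plus1, minus1, "p1_p1", "primer1", "primer1",
                    ampliconMin, ampliconMax, samePrimer = TRUE),
        .crossSites(plus2, minus2, "p2_p2", "primer2", "primer2",
                    ampliconMin, ampliconMax, samePrimer = TRUE))
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0L) return(.emptyHits())
    d <- do.call(rbind, parts)
    kindOrd <- match(d$pairKind, c("p1_p2", "p1_p1", "p2_p2"))
    d <- d[order(kindOrd, d$ampliconStart, d$ampliconEnd, d$leftPrimer), ,
           drop = FALSE]
    rownames(d) <- NULL
    DataFrame(d)
}

#' Extract the plus-strand sequence of an amplicon
#'
#' @param template template string the hit was found on.
#' @param ampliconStart,ampliconEnd 1-based inclusive amplicon interval.
#' @return Character: the amplicon subsequence.
#' @export
ampliconSequence <- function(template, ampliconStart, ampliconEnd) {
    stopifnot(ampliconStart >= 1L, ampliconEnd <= nchar(template),
              ampliconStart <= ampliconEnd)
    substr(toupper(as.character(template)), ampliconStart, ampliconEnd)
}
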