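# Derive mismatch/deletion counts from the canonical alignment summary.
# For an alignment of an m-base query against a w-base window with score S
# and g gap bases, the split into insertions/deletions is forced by the
# lengths (ins - del = w - m, ins + del = g), which pins the mismatch count:
#   del = (g + m - w) / 2,  mismatches = (m - del - S - 2 g) / 2.
.editCounts <- function(score, gaps, wlen, m) {
    del <- (gaps + m - wlen) / 2
    mm <- (m - del - score - 2 * gaps) / 2
    list(del = del, mismatches = mm)
}

.emptySites <- function() {
    DataFrame(strand = character(0), start = integer(0), end = integer(0),
              width = integer(0), mismatches = integer(0),
              gapBases = integer(0), score = integer(0))
}

# Budget filter + local-optimum reduction for one strand of scan output.
# A window is a site when its canonical alignment respects both edit
# budgets; overlapping reports of the same annealing locus are then reduced
# to local optima: a site is dropped when a strictly better-scoring site's
# interval overlaps it.  (An exact footprint always spawns budget-passing
# one-base extensions of itself -- e.g. the window one base to the left
# aligns with one mismatch and one gap base -- so without this reduction
# every perfect site would be reported three times.)
.sitesOneStrand <- function(wins, m, maxMismatches, maxGaps) {
    if (nrow(wins) == 0L) return(NULL)
    ec <- .editCounts(wins[, "score"], wins[, "gaps"], wins[, "wlen"], m)
    keep <- wins[, "gaps"] <= maxGaps & ec$mismatches <= maxMismatches
    if (!any(keep)) return(NULL)
    st <- wins[keep, "start0", drop = TRUE]
    wl <- wins[keep, "wlen", drop = TRUE]
    sc <- wins[keep, "score", drop = TRUE]
    gp <- wins[keep, "gaps", drop = TRUE]
    mm <- ec$mismatches[keep]
    en <- st + wl
    n <- length(st)
    drop <- vapply(seq_len(n), function(k)
        any(sc > sc[k] & st < en[k] & st[k] < en), logical(1))
    if (all(drop)) return(NULL)
    data.frame(start0 = st[!drop], wlen = wl[!drop],
               score = sc[!drop], gaps = gp[!drop],
               mismatches = as.integer(mm[!drop]))
}

.assembleSites <- function(plus, minus) {
    parts <- list()
    if (!is.null(plus))
        parts$p <- data.frame(strand = "+", plus, stringsAsFactors = FALSE)
    if (!is.null(minus))
        parts$m <- data.frame(strand = "-", minus, stringsAsFactors = FALSE)
    if (length(parts) == 0L) return(.emptySites())
    d <- do.call(rbind, parts)
    d <- d[order(d$start0, d$start0 + d$wlen, d$strand), , drop = FALSE]
    DataFrame(strand = d$strand,
              start = as.integer(d$start0 + 1L),
              end = as.integer(d$start0 + d$wlen),
              width = as.integer(d$wlen),
              mismatches = as.integer(d$mismatches),
              gapBases = as.integer(d$gaps),
              score = as.integer(d$score))
}

.checkBudgets <- function(maxMismatches, maxGaps) {
    if (maxMismatches < 0 || maxGaps < 0)
        stop("edit budgets must be non-negative", call. = FALSE)
}

#' Find approximate primer binding sites
#'
#' Searches a template for all annealing footprints of a primer under the
#' re-PCR-style edit budgets (default: at most 2 mismatches and 2 gap bases
#' per primer site).  Each candidate template window is judged by its
#' canonical semi-global alignment of the full primer (match +1, mismatch -1,
#' gap base -2; score ties resolved towards fewer gap bases; no unaligned
#' template base at either alignment end), and reported when that single
#' alignment respects both budgets.  Overlapping reports are reduced to local
#' optima: a site is dropped when a strictly better-scoring site's interval
#' overlaps it.  Both strands are searched; minus-strand sites are
#' found with the reverse complement of the primer and reported in
#' plus-strand coordinates.
#'
#' @param primer IUPAC primer string, length >= 10; degenerate codes anneal
#'   to any base of their set at zero mismatch cost.
#' @param template nucleotide template string (IUPAC codes permitted,
#'   \code{N} intersects everything).
#' @param maxMismatches,maxGaps non-negative edit budgets per site; "gaps"
#'   counts gap bases (total inserted plus deleted bases), not gap openings.
#' @return A \code{DataFrame} with one row per site: \code{strand},
#'   \code{start}, \code{end} (1-based inclusive template coordinates),
#'   \code{width}, \code{mismatches}, \code{gapBases}, \code{score}.
#' @seealso [bruteForceBindingSites()] for the exhaustive reference search,
#'   [enumerateAmplicons()] for pairing sites into amplicons.
#' @export
findBindingSites <- function(primer, template, maxMismatches = 2L, maxGaps = 2L) {
    .checkBudgets(maxMismatches, maxGaps)
    p <- .encodeSeq(toupper(as.character(primer)), "primer")
    if (length(p) < 10L)
        stop("primer must be at least 10 nt", call. = FALSE)
    tm <- .encodeSeq(toupper(as.character(template)), "template")
    if (length(tm) < length(p)) return(.emptySites())
    m <- length(p)
    plus <- .sitesOneStrand(.scan_windows_cpp(p, tm, as.integer(maxGaps)),
                            m, maxMismatches, maxGaps)
    minus <- .sitesOneStrand(.scan_windows_cpp(.rcBits(p), tm, as.integer(maxGaps)),
                             m, maxMismatches, maxGaps)
    .assembleSites(plus, minus)
}

#' Exhaustive reference binding-site search
#'
#' Brute-force counterpart of [findBindingSites()]: every template window in
#' the gap band is aligned from scratch by an independent per-window dynamic
#' program, then filtered and reduced with separately written code.  Slower
#' by construction; used to cross-check the scanning implementation.
#'
#' @inheritParams findBindingSites
#' @return Same layout as [findBindingSites()].
#' @export
bruteForceBindingSites <- function(primer, template,
                                   maxMismatches = 2L, maxGaps = 2L) {
    .checkBudgets(maxMismatches, maxGaps)
    p <- .encodeSeq(toupper(as.character(primer)), "primer")
    if (length(p) < 10L)
        stop("primer must be at least 10 nt", call. = FALSE)
    tm <- .encodeSeq(toupper(as.character(template)), "template")
    if (length(tm) < length(p)) return(.emptySites())
    m <- length(p)

    oneStrand <- function(q) {
        wins <- .oracle_scan_cpp(q, tm, as.integer(maxGaps))
        if (nrow(wins) == 0L) return(NULL)
        del <- (wins[, "gaps"] + m - wins[, "wlen"]) / 2
        mm <- (m - del - wins[, "score"] - 2 * wins[, "gaps"]) / 2
        ok <- wins[, "gaps"] <= maxGaps & mm <= maxMismatches
        if (!any(ok)) return(NULL)
        d <- data.frame(start0 = wins[ok, "start0"], wlen = wins[ok, "wlen"],
                        score = wins[ok, "score"], gaps = wins[ok, "gaps"],
                        mismatches = as.integer(mm[ok]))
        keep <- rep(TRUE, nrow(d))
        for (a in seq_len(nrow(d))) {
            for (b in seq_len(nrow(d))) {
                if (d$score[b] > d$score[a] &&
                    d$start0[b] < d$start0[a] + d$wlen[a] &&
                    d$start0[a] < d$start0[b] + d$wlen[b]) {
                    keep[a] <- FALSE
                    break
                }
            }
        }
        if (!any(keep)) return(NULL)
        d[keep, , drop = FALSE]
    }

    .assembleSites(oneStrand(p), oneStrand(.rcBits(p)))
}
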