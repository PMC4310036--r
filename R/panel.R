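#' Specify a synthetic screening panel
#'
#' Builds the parameter object of the deterministic panel generator.  The
#' defaults emulate the realistic study conditions: 20-nt primers, 24-nt
#' TaqMan probes, spacers of 30-160 bases so planted amplicons fall in the
#' 70-200 bp band typical of validated screening assays, and backbones of at
#' least 2 kb.
#'
#' @param nEvents,nMethods panel dimensions.
#' @param backboneLength minimum event-sequence length in bases.
#' @param primerLength,probeLength oligo lengths in bases.
#' @param spacerRange integer pair, inclusive range of the spacer between the
#'   two primer footprints.
#' @param scoreGrid nEvents x nMethods matrix of planted scores in 0:2;
#'   default: deterministic draw with roughly half the cells empty.
#' @param selfPairCells two-column matrix of (event, method) indices that
#'   additionally receive a same-primer convergent cassette; must address
#'   score-2 cells (a perfect self-pair amplicon in a lower-scoring cell
#'   would raise that cell's score above its planted value).  Default: none.
#' @param probeMethods logical vector, which methods carry a probe; default
#'   alternates starting with a probe-bearing method.
#' @param score1Mode where the single substitution of a score-1 cell is
#'   planted: \code{"primer"} (default) degrades one primer footprint,
#'   \code{"probe"} degrades the probe site.
#' @param sequencesPerEvent integer vector, template sequences per event
#'   (default 1 each); with several sequences each cassette is planted into
#'   one randomly chosen sequence, emulating retransformed or stacked events.
#' @param seed integer RNG seed; every output is a pure function of the spec.
#' @return A \linkS4class{PanelSpec}.
#' @export
panelSpec <- function(nEvents, nMethods, backboneLength = 2000L,
                      primerLength = 20L, probeLength = 24L,
                      spacerRange = c(30L, 160L), scoreGrid = NULL,
                      selfPairCells = NULL, probeMethods = NULL,
                      score1Mode = c("primer", "probe"),
                      sequencesPerEvent = NULL, seed = 1L) {
    nEvents <- as.integer(nEvents); nMethods <- as.integer(nMethods)
    score1Mode <- match.arg(score1Mode)
    if (is.null(scoreGrid)) {
        set.seed(seed)
        scoreGrid <- matrix(sample(0:2, nEvents * nMethods, replace = TRUE,
                                   prob = c(0.5, 0.15, 0.35)),
                            nEvents, nMethods)
    }
    storage.mode(scoreGrid) <- "integer"
    if (is.null(selfPairCells))
        selfPairCells <- matrix(integer(0), 0L, 2L)
    selfPairCells <- matrix(as.integer(selfPairCells), ncol = 2L)
    if (is.null(probeMethods))
        probeMethods <- rep_len(c(TRUE, FALSE), nMethods)
    if (is.null(sequencesPerEvent))
        sequencesPerEvent <- rep(1L, nEvents)
    new("PanelSpec", nEvents = nEvents, nMethods = nMethods,
        backboneLength = as.integer(backboneLength),
        primerLength = as.integer(primerLength),
        probeLength = as.integer(probeLength),
        spacerRange = as.integer(spacerRange),
        scoreGrid = scoreGrid, selfPairCells = selfPairCells,
        probeMethods = as.logical(probeMethods), score1Mode = score1Mode,
        sequencesPerEvent = as.integer(sequencesPerEvent),
        seed = as.integer(seed))
}

#' Substitute bases inside a sequence interval
#'
#' Plants exactly \code{nSubstitutions} substitutions at distinct positions
#' of the interval, each to a different base than the original; positions
#' outside the interval are untouched.  Deterministic given the seed, which
#' is applied locally (the caller's RNG state is preserved).
#'
#' @param sequence nucleotide string.
#' @param start,end 1-based inclusive interval.
#' @param nSubstitutions number of positions to substitute.
#' @param seed integer seed.
#' @return The mutated sequence string.
#' @export
mutateSite <- function(sequence, start, end, nSubstitutions, seed = 1L) {
    sequence <- toupper(as.character(sequence))
    n <- nchar(sequence)
    if (start < 1L || end > n || start > end)
        stop("interval out of bounds", call. = FALSE)
    if (nSubstitutions > end - start + 1L)
        stop("more substitutions than interval positions", call. = FALSE)
    if (nSubstitutions == 0L) return(sequence)
    hadSeed <- exists(".Random.seed", envir = globalenv())
    if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(seed)
    pos <- sort(sample(start:end, nSubstitutions))
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    for (p in pos) {
        alt <- setdiff(c("A", "C", "G", "T"), chars[p])
        chars[p] <- sample(alt, 1L)
    }
    paste(chars, collapse = "")
}

# one cassette: primer1 + spacer (optionally embedding the probe) + rc(primer2)
# returns the cassette string plus footprint offsets relative to cassette start
.buildCassette <- function(p1, p2, probe, spacerRange, degrade = "none") {
    plen <- nchar(p1)
    spacer <- sample(spacerRange[1L]:spacerRange[2L], 1L)
    spacerSeq <- .randomDna(spacer)
    probeOff <- NA_integer_
    if (!is.na(probe)) {
        probeSeq <- probe
        if (degrade == "probe") {
            subPos <- sample(seq_len(nchar(probe)), 1L)
            probeSeq <- mutateSite(probe, subPos, subPos, 1L,
                                   seed = sample.int(1e6, 1L))
        }
        probeOff <- sample.int(spacer - nchar(probe) + 1L, 1L)
        substr(spacerSeq, probeOff, probeOff + nchar(probe) - 1L) <- probeSeq
    }
    p1Seq <- p1
    if (degrade == "primer") {
        subPos <- sample(seq_len(plen), 1L)
        p1Seq <- mutateSite(p1, subPos, subPos, 1L, seed = sample.int(1e6, 1L))
    }
    cassette <- paste0(p1Seq, spacerSeq, reverseComplement(p2))
    list(seq = cassette,
         p1Start = 1L, p1End = plen,
         p2Start = plen + spacer + 1L, p2End = plen + spacer + nchar(p2),
         probeStart = if (is.na(probeOff)) NA_integer_ else plen + probeOff,
         degrade = degrade)
}

# verify one event sequence against the planting plan with the brute-force
# reference search: for every primer and probe of every method, the observed
# binding-site set must equal exactly the planted footprints -- no accidental
# near-matches anywhere on either strand
.verifyEventSequence <- function(seqStr, plan, methods) {
    for (j in seq_len(length(methods))) {
        roles <- c("primer1", "primer2",
                   if (!is.na(methods@probe[j])) "probe")
        for (role in roles) {
            oligo <- slot(methods, role)[j]
            exp <- plan[plan$method == j & plan$role == role, , drop = FALSE]
            got <- as.data.frame(bruteForceBindingSites(oligo, seqStr))
            if (nrow(got) != nrow(exp)) return(FALSE)
            if (nrow(exp) > 0L) {
                exp <- exp[order(exp$start), , drop = FALSE]
                if (!all(got$start == exp$start & got$strand == exp$strand &
                         got$mismatches == exp$mismatches &
                         got$gapBases == 0L))
                    return(FALSE)
            }
        }
    }
    TRUE
}

#' Generate a synthetic screening panel with planted ground truth
#'
#' Emulates the confidential reference collections: for every cell of the
#' planted score grid, a score-2 cell receives an exact
#' primer1/spacer/rc(primer2) cassette (embedding an exact probe copy for
#' probe-bearing methods), a score-1 cell the same cassette with exactly one
#' substitution in a primer footprint (or in the probe site, per
#' \code{score1Mode}), and a score-0 cell nothing.  Self-pair cells receive
#' an additional primer1/spacer/rc(primer1) cassette (with probe copy where
#' applicable, so the self-pair hit survives probe filtering).  Backbones are
#' rejection-sampled against the brute-force reference search until no
#' unplanted primer window falls within the edit budgets, so the planted grid
#' is exact ground truth for the full pipeline.  All output is deterministic
#' given the spec's seed.
#'
#' @param spec a \linkS4class{PanelSpec}.
#' @param dir optional directory; when given, writes \code{events.fasta},
#'   \code{methods.tsv} and \code{truth.csv} (the planted score grid with
#'   self-pair flags, in [exportMatrixCsv()] format).
#' @param maxTries resampling attempts per event sequence before giving up.
#' @return Invisibly, a list with \code{events} (\linkS4class{GMOEventSet}),
#'   \code{methods} (\linkS4class{DetectionMethodSet}), \code{truth}
#'   (\linkS4class{ScreeningMatrix}) and, when \code{dir} is given,
#'   \code{paths}.
#' @export
generatePanel <- function(spec, dir = NULL, maxTries = 25L) {
    stopifnot(is(spec, "PanelSpec"))
    set.seed(spec@seed)
    nE <- spec@nEvents; nM <- spec@nMethods
    plen <- spec@primerLength

    methodId <- sprintf("SYN-MTH-%03d", seq_len(nM))
    methods <- DetectionMethodSet(
        methodId = methodId,
        methodType = rep_len(c("element_specific", "construct_specific"), nM),
        targetName = sprintf("synthElem%02d", seq_len(nM)),
        primer1 = vapply(seq_len(nM), function(i) .randomDna(plen), ""),
        primer2 = vapply(seq_len(nM), function(i) .randomDna(plen), ""),
        probe = ifelse(spec@probeMethods,
                       vapply(seq_len(nM), function(i)
                           .randomDna(spec@probeLength), ""),
                       NA_character_))

    eventId <- sprintf("SYN-EV-%03d", seq_len(nE))
    seqs <- character(0); seqEvent <- character(0); seqLabel <- character(0)

    for (i in seq_len(nE)) {
        nSeq <- spec@sequencesPerEvent[i]
        # assign each planted cassette (and self cassette) to a sequence slot
        cells <- which(spec@scoreGrid[i, ] > 0L)
        selfCells <- spec@selfPairCells[spec@selfPairCells[, 1L] == i, 2L]
        assignSeq <- if (nSeq == 1L) rep(1L, length(cells))
                     else sample.int(nSeq, length(cells), replace = TRUE)
        assignSelf <- if (nSeq == 1L) rep(1L, length(selfCells))
                      else sample.int(nSeq, length(selfCells), replace = TRUE)
        for (k in seq_len(nSeq)) {
            ok <- FALSE
            for (try in seq_len(maxTries)) {
                segs <- .randomDna(sample(50:150, 1L))
                plan <- data.frame(method = integer(0), role = character(0),
                                   strand = character(0), start = integer(0),
                                   mismatches = integer(0))
                addFootprint <- function(plan, method, role, strand, start, mm)
                    rbind(plan, data.frame(method = method, role = role,
                                           strand = strand, start = start,
                                           mismatches = mm))
                for (ci in seq_along(cells)) {
                    if (assignSeq[ci] != k) next
                    j <- cells[ci]
                    degrade <- if (spec@scoreGrid[i, j] == 1L)
                        spec@score1Mode else "none"
                    cas <- .buildCassette(methods@primer1[j], methods@primer2[j],
                                          methods@probe[j], spec@spacerRange,
                                          degrade)
                    off <- nchar(segs)
                    plan <- addFootprint(plan, j, "primer1", "+",
                                         off + cas$p1Start,
                                         if (degrade == "primer") 1L else 0L)
                    plan <- addFootprint(plan, j, "primer2", "-",
                                         off + cas$p2Start, 0L)
                    if (!is.na(methods@probe[j]))
                        plan <- addFootprint(plan, j, "probe", "+",
                                             off + cas$probeStart,
                                             if (degrade == "probe") 1L else 0L)
                    segs <- paste0(segs, cas$seq, .randomDna(sample(50:150, 1L)))
                }
                for (si in seq_along(selfCells)) {
                    if (assignSelf[si] != k) next
                    j <- selfCells[si]
                    cas <- .buildCassette(methods@primer1[j], methods@primer1[j],
                                          methods@probe[j], spec@spacerRange,
                                          "none")
                    off <- nchar(segs)
                    plan <- addFootprint(plan, j, "primer1", "+",
                                         off + cas$p1Start, 0L)
                    plan <- addFootprint(plan, j, "primer1", "-",
                                         off + cas$p2Start, 0L)
                    if (!is.na(methods@probe[j]))
                        plan <- addFootprint(plan, j, "probe", "+",
                                             off + cas$probeStart, 0L)
                    segs <- paste0(segs, cas$seq, .randomDna(sample(50:150, 1L)))
                }
                if (nchar(segs) < spec@backboneLength)
                    segs <- paste0(segs,
                                   .randomDna(spec@backboneLength - nchar(segs)))
                if (.verifyEventSequence(segs, plan, methods)) {
                    ok <- TRUE
                    break
                }
            }
            if (!ok)
                stop(sprintf("could not sample a clean backbone for event %s (sequence %d)",
                             eventId[i], k), call. = FALSE)
            seqs <- c(seqs, segs)
            seqEvent <- c(seqEvent, eventId[i])
            seqLabel <- c(seqLabel, paste0("seq", k))
        }
    }

    events <- GMOEventSet(seqs, seqEvent, seqLabel)

    wn <- matrix(FALSE, nE, nM, dimnames = list(eventId, methodId))
    if (nrow(spec@selfPairCells) > 0L)
        wn[spec@selfPairCells] <- TRUE
    sc <- spec@scoreGrid
    dimnames(sc) <- list(eventId, methodId)
    truth <- new("ScreeningMatrix", SummarizedExperiment(
        assays = list(score = sc, warning = wn),
        rowData = DataFrame(event_id = eventId, row.names = eventId),
        colData = DataFrame(method_id = methodId, row.names = methodId)))

    out <- list(events = events, methods = methods, truth = truth)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        paths <- list(events = file.path(dir, "events.fasta"),
                      methods = file.path(dir, "methods.tsv"),
                      truth = file.path(dir, "truth.csv"))
        writeEventsFasta(events, paths$events)
        writeMethodsTable(methods, paths$methods)
        exportMatrixCsv(truth, paths$truth)
        out$paths <- paths
    }
    invisible(out)
}
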