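# build a single-method set, optionally probed
mkMethod <- function(p1, p2, probe = NA_character_, id = "M1") {
    DetectionMethodSet(id, "element_specific", "elem", p1, p2, probe)
}

# plant a cassette p1 + spacer + rc(p2) into clean flanks; the spacer can
# embed a probe copy; resamples until the brute-force search confirms the
# planted sites are the only ones
plantCassette <- function(p1, p2, probe = NULL, spacerLen = 40,
                          degradeP1 = 0L, flank = 120) {
    for (i in 1:60) {
        spacer <- randDna(spacerLen)
        if (!is.null(probe)) {
            at <- sample(spacerLen - nchar(probe) + 1, 1)
            substr(spacer, at, at + nchar(probe) - 1) <- probe
        }
        p1Site <- if (degradeP1 > 0) substituteAt(p1, sample(nchar(p1), degradeP1))
                  else p1
        tmpl <- paste0(randDna(flank), p1Site, spacer, rcChar(p2), randDna(flank))
        n1 <- nrow(bruteForceBindingSites(p1, tmpl))
        n2 <- nrow(bruteForceBindingSites(p2, tmpl))
        okProbe <- is.null(probe) ||
            nrow(bruteForceBindingSites(probe, tmpl)) == 1L
        if (n1 == as.integer(degradeP1 <= 2) && n2 == 1L && okProbe)
            return(tmpl)
    }
    stop("could not plant cassette")
}

test_that("perfect cassette with exact probe scores 2", {
    set.seed(401)
    p1 <- randDna(20); p2 <- randDna(20); probe <- randDna(24)
    tmpl <- plantCassette(p1, p2, probe)
    ev <- GMOEventSet(tmpl, "EV1")
    ps <- scorePair(mkMethod(p1, p2, probe), ev)
    expect_identical(score(ps), 2L)
    expect_false(selfPairWarning(ps))
    expect_identical(classification(ps@probeAlignment), "perfect")
    bh <- bestHit(ps)
    expect_identical(bh$totalEdits, 0L)
    expect_identical(bh$pairKind, "p1_p2")
})

test_that("one substitution in a primer footprint drops the score to 1", {
    set.seed(402)
    p1 <- randDna(20); p2 <- randDna(20); probe <- randDna(24)
    tmpl <- plantCassette(p1, p2, probe, degradeP1 = 1L)
    ps <- scorePair(mkMethod(p1, p2, probe), GMOEventSet(tmpl, "EV1"))
    expect_identical(score(ps), 1L)
    expect_identical(bestHit(ps)$totalEdits, 1L)
})

test_that("an event with no admissible site scores 0", {
    set.seed(403)
    p1 <- randDna(20); p2 <- randDna(20)
    for (i in 1:50) {
        tmpl <- randDna(1000)
        if (nrow(bruteForceBindingSites(p1, tmpl)) == 0L &&
            nrow(bruteForceBindingSites(p2, tmpl)) == 0L) break
    }
    ps <- scorePair(mkMethod(p1, p2), GMOEventSet(tmpl, "EV1"))
    expect_identical(score(ps), 0L)
    expect_identical(nrow(bestHit(ps)), 0L)
})

test_that("the best sequence of a multi-sequence event determines the score", {
    set.seed(404)
    p1 <- randDna(20); p2 <- randDna(20)
    blank <- randDna(600)
    for (i in 1:50) {
        if (nrow(bruteForceBindingSites(p1, blank)) == 0L &&
            nrow(bruteForceBindingSites(p2, blank)) == 0L) break
        blank <- randDna(600)
    }
    good <- plantCassette(p1, p2)
    ev <- GMOEventSet(c(blank, good), c("EV1", "EV1"))
    ps <- scorePair(mkMethod(p1, p2), ev)
    expect_identical(score(ps), 2L)
    expect_identical(bestHit(ps)$sequenceIndex, 2L)
})

test_that("an unbindable probe turns a perfect amplicon into score 0", {
    set.seed(405)
    p1 <- randDna(20); p2 <- randDna(20)
    tmpl <- plantCassette(p1, p2)           # no probe copy planted
    probe <- randDna(24)
    amp <- bestHit(scorePair(mkMethod(p1, p2), GMOEventSet(tmpl, "EV1")))
    ampSeq <- ampliconSequence(tmpl, amp$ampliconStart, amp$ampliconEnd)
    # make sure the probe really cannot bind this amplicon
    for (i in 1:50) {
        if (classification(alignProbe(probe, ampSeq)) == "none") break
        probe <- randDna(24)
    }
    ps <- scorePair(mkMethod(p1, p2, probe), GMOEventSet(tmpl, "EV1"))
    expect_identical(score(ps), 0L)
})

test_that("removing the probe never lowers a score", {
    set.seed(406)
    for (i in 1:8) {
        p1 <- randDna(20); p2 <- randDna(20); probe <- randDna(24)
        tmpl <- switch(1 + i %% 4,
                       plantCassette(p1, p2, probe),
                       plantCassette(p1, p2, substituteAt(probe, c(4, 13))),
                       plantCassette(p1, p2),
                       plantCassette(p1, p2, probe, degradeP1 = 1L))
        ev <- GMOEventSet(tmpl, "EV1")
        withProbe <- score(scorePair(mkMethod(p1, p2, probe), ev))
        without <- score(scorePair(mkMethod(p1, p2), ev))
        expect_gte(without, withProbe)
    }
})

test_that("scores are invariant under reverse-complementing the event", {
    set.seed(407)
    for (i in 1:6) {
        p1 <- randDna(20); p2 <- randDna(20)
        probe <- if (i %% 2 == 0) randDna(24) else NULL
        tmpl <- plantCassette(p1, p2, probe,
                              degradeP1 = if (i %% 3 == 0) 1L else 0L)
        m <- mkMethod(p1, p2, if (is.null(probe)) NA_character_ else probe)
        fwd <- scorePair(m, GMOEventSet(tmpl, "EV1"))
        rev <- scorePair(m, GMOEventSet(rcChar(tmpl), "EV1"))
        expect_identical(score(fwd), score(rev), info = paste("case", i))
        expect_identical(selfPairWarning(fwd), selfPairWarning(rev))
    }
})

test_that("a retained self-pair amplicon raises the warning but scoring still works", {
    set.seed(408)
    p1 <- randDna(20); p2 <- randDna(20)
    # p1 ... rc(p1) cassette only: every amplicon is a self pairing
    for (i in 1:60) {
        tmpl <- paste0(randDna(120), p1, randDna(40), rcChar(p1), randDna(120))
        if (nrow(bruteForceBindingSites(p1, tmpl)) == 2L &&
            nrow(bruteForceBindingSites(p2, tmpl)) == 0L) break
    }
    ps <- scorePair(mkMethod(p1, p2), GMOEventSet(tmpl, "EV1"))
    expect_identical(score(ps), 2L)
    expect_true(selfPairWarning(ps))
    expect_identical(bestHit(ps)$pairKind, "p1_p1")
})

test_that("score store round trips all score/flag combinations losslessly", {
    tb <- expand.grid(event_id = c("E1", "E2", "E3"),
                      method_id = c("M1", "M2"),
                      stringsAsFactors = FALSE)
    tb$score <- rep(0:2, 2)
    tb$warning <- rep(c(FALSE, TRUE), 3)
    store <- scoreStore(tb)
    path <- withr::local_tempfile()
    persistScores(store, path)
    back <- loadScores(path)
    expect_identical(scoreTable(back), scoreTable(store))
    expect_identical(storeThresholds(back), storeThresholds(store))
    # load -> persist is byte-identical
    path2 <- withr::local_tempfile()
    persistScores(back, path2)
    expect_identical(readLines(path), readLines(path2))
})

test_that("upsert replaces existing pairs and appends new ones", {
    store <- scoreStore(data.frame(event_id = "E1", method_id = "M1",
                                   score = 0L, warning = FALSE))
    store <- upsertScores(store, data.frame(event_id = c("E1", "E2"),
                                            method_id = "M1",
                                            score = c(2L, 1L),
                                            warning = c(TRUE, FALSE)))
    expect_identical(length(store), 2L)
    expect_identical(getScore(store, "E1", "M1"),
                     list(score = 2L, warning = TRUE))
    expect_identical(getScore(store, "E2", "M1"),
                     list(score = 1L, warning = FALSE))
})

test_that("empty and corrupt stores load as expected", {
    path <- withr::local_tempfile()
    persistScores(scoreStore(), path)
    empty <- loadScores(path)
    expect_identical(length(empty), 0L)
    writeLines("scores go here", path)
    expect_error(loadScores(path), "corrupt")
    persistScores(scoreStore(), path)
    lines <- readLines(path)
    writeLines(c(lines, "E1\tM1\t7\t0"), path)
    expect_error(loadScores(path), "corrupt")
})

test_that("matrix building honours request order and validates pairs", {
    tb <- expand.grid(event_id = c("E1", "E2", "E3"),
                      method_id = c("M1", "M2"), stringsAsFactors = FALSE)
    tb$score <- c(2L, 0L, 1L, 0L, 2L, 1L)
    tb$warning <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
    store <- scoreStore(tb)
    m <- buildMatrix(store, c("E2", "E1"), c("M2", "M1"))
    expect_identical(rownames(scoreMatrix(m)), c("E2", "E1"))
    expect_identical(scoreMatrix(m)["E2", "M2"], 2L)
    expect_identical(scoreMatrix(m)["E1", "M1"], 2L)
    expect_identical(warningMatrix(m)["E1", "M1"], FALSE)
    m0 <- buildMatrix(store, c("E1", "E2", "E3"), character(0))
    expect_identical(dim(scoreMatrix(m0)), c(3L, 0L))
    expect_error(buildMatrix(store, "E9", "M1"), "E9")
})

test_that("matrix CSV export renders warnings and round trips byte-identically", {
    store <- scoreStore(data.frame(event_id = "E1", method_id = "M1",
                                   score = 2L, warning = FALSE))
    m <- buildMatrix(store)
    path <- withr::local_tempfile(fileext = ".csv")
    exportMatrixCsv(m, path)
    expect_identical(readLines(path), c("event_id,M1", "E1,2"))
    expect_identical(readChar(path, file.size(path)), "event_id,M1\nE1,2\n")

    tb <- data.frame(event_id = c("E1", "E1", "E2", "E2"),
                     method_id = c("M1", "M2", "M1", "M2"),
                     score = c(1L, 2L, 0L, 2L),
                     warning = c(TRUE, FALSE, FALSE, TRUE))
    m2 <- buildMatrix(scoreStore(tb))
    path2 <- withr::local_tempfile(fileext = ".csv")
    exportMatrixCsv(m2, path2)
    lines <- readLines(path2)
    expect_identical(lines[2], "E1,1!,2")
    back <- readMatrixCsv(path2)
    expect_identical(scoreMatrix(back), scoreMatrix(m2))
    expect_identical(warningMatrix(back), warningMatrix(m2))
    path3 <- withr::local_tempfile(fileext = ".csv")
    exportMatrixCsv(back, path3)
    expect_identical(readLines(path2), readLines(path3))
})
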