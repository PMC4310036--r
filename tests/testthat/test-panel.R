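test_that("the scoring pipeline recovers the planted grid of random panels", {
    set.seed(601)
    for (trial in 1:3) {
        spec <- panelSpec(4, 3, backboneLength = 1200L, seed = 600 + trial)
        res <- generatePanel(spec)
        store <- scorePanel(res$methods, res$events)
        m <- buildMatrix(store, eventIds(res$truth), methodIds(res$truth))
        expect_identical(scoreMatrix(m), scoreMatrix(res$truth),
                         info = paste("panel", trial))
        expect_identical(warningMatrix(m), warningMatrix(res$truth),
                         info = paste("panel", trial))
    }
})

test_that("self-pair cells score 2 with the warning flag planted", {
    set.seed(602)
    grid <- matrix(c(2L, 0L, 1L, 0L, 2L, 0L), 3, 2)
    spec <- panelSpec(3, 2, backboneLength = 1000L, scoreGrid = grid,
                      selfPairCells = matrix(c(1L, 1L), 1, 2), seed = 77)
    twos <- matrix(c(1L, 1L), 1, 2)
    res <- generatePanel(spec)
    store <- scorePanel(res$methods, res$events)
    cell <- twos[1, ]
    got <- getScore(store, eventIds(res$truth)[cell[1]],
                    methodIds(res$truth)[cell[2]])
    expect_identical(got$score, 2L)
    expect_true(got$warning)
    # and no other cell acquired a warning
    m <- buildMatrix(store, eventIds(res$truth), methodIds(res$truth))
    expect_identical(warningMatrix(m), warningMatrix(res$truth))
})

test_that("panel generation is byte-identical across runs with one seed", {
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    spec1 <- panelSpec(3, 2, backboneLength = 800L, seed = 42)
    spec2 <- panelSpec(3, 2, backboneLength = 800L, seed = 42)
    generatePanel(spec1, dir = d1)
    generatePanel(spec2, dir = d2)
    for (f in c("events.fasta", "methods.tsv", "truth.csv"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), info = f)
    # a different seed changes the sequences
    d3 <- withr::local_tempdir()
    generatePanel(panelSpec(3, 2, backboneLength = 800L, seed = 43), dir = d3)
    expect_false(identical(readLines(file.path(d1, "events.fasta")),
                           readLines(file.path(d3, "events.fasta"))))
})

test_that("multi-sequence events plant cassettes across their sequences", {
    set.seed(603)
    spec <- panelSpec(2, 2, backboneLength = 900L,
                      scoreGrid = matrix(c(2L, 0L, 2L, 2L), 2, 2),
                      sequencesPerEvent = c(2L, 1L), seed = 9)
    res <- generatePanel(spec)
    expect_identical(length(res$events), 3L)  # 2 + 1 sequences
    store <- scorePanel(res$methods, res$events)
    m <- buildMatrix(store, eventIds(res$truth), methodIds(res$truth))
    expect_identical(scoreMatrix(m), scoreMatrix(res$truth))
})

test_that("probe-mode score-1 cells degrade the probe site, not the primers", {
    set.seed(604)
    spec <- panelSpec(2, 2, backboneLength = 900L,
                      scoreGrid = matrix(c(1L, 0L, 0L, 1L), 2, 2),
                      probeMethods = c(TRUE, TRUE),
                      score1Mode = "probe", seed = 19)
    res <- generatePanel(spec)
    store <- scorePanel(res$methods, res$events)
    m <- buildMatrix(store, eventIds(res$truth), methodIds(res$truth))
    expect_identical(scoreMatrix(m), scoreMatrix(res$truth))
    # primers are perfect: the score-1 must come from the probe
    ev <- selectEvents(res$events, eventIds(res$truth)[1])
    ps <- scorePair(res$methods[1], ev)
    expect_identical(score(ps), 1L)
    expect_identical(bestHit(ps)$totalEdits, 0L)
    expect_identical(classification(ps@probeAlignment), "imperfect")
})

test_that("infeasible panel specifications are rejected", {
    expect_error(panelSpec(2, 2, spacerRange = c(480L, 500L)),
                 "outside \\[20, 500\\]")
    expect_error(panelSpec(2, 2, spacerRange = c(20L, 30L)),
                 "probe must fit")
    expect_error(panelSpec(2, 2, scoreGrid = matrix(0L, 3, 2)),
                 "dimensions")
    spec <- panelSpec(2, 2, scoreGrid = matrix(c(0L, 2L, 1L, 2L), 2, 2))
    expect_error({
        spec@selfPairCells <- matrix(c(1L, 1L), 1, 2)  # a score-0 cell
        validObject(spec)
    }, "score-2")
})

test_that("mutateSite substitutes exactly n distinct in-interval positions", {
    set.seed(605)
    s <- randDna(60)
    expect_identical(mutateSite(s, 11, 30, 0L), s)
    m1 <- mutateSite(s, 11, 30, 1L, seed = 3)
    d <- which(strsplit(s, "")[[1]] != strsplit(m1, "")[[1]])
    expect_length(d, 1L)
    expect_true(d >= 11 && d <= 30)
    m5 <- mutateSite(s, 11, 30, 5L, seed = 3)
    d5 <- which(strsplit(s, "")[[1]] != strsplit(m5, "")[[1]])
    expect_length(d5, 5L)
    expect_true(all(d5 >= 11 & d5 <= 30))
    expect_identical(mutateSite(s, 11, 30, 5L, seed = 3), m5)  # deterministic
    expect_error(mutateSite(s, 0, 30, 1L), "out of bounds")
    expect_error(mutateSite(s, 11, 12, 3L), "more substitutions")
})

test_that("five substitutions erase a planted binding site", {
    set.seed(606)
    P <- randDna(20)
    tmpl <- plantedTemplate(P, P, left = 50, right = 50)
    site <- findBindingSites(P, tmpl)
    expect_identical(nrow(site), 1L)
    broken <- mutateSite(tmpl, site$start, site$end, 5L, seed = 8)
    expect_identical(nrow(findBindingSites(P, broken)), 0L)
    expect_identical(nrow(bruteForceBindingSites(P, broken)), 0L)
})
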