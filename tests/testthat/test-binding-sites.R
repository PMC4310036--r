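test_that("a planted exact primer yields exactly one site per strand", {
    set.seed(101)
    P <- randDna(20)
    tmpl <- plantedTemplate(P, P, left = 10, right = 10)
    sites <- findBindingSites(P, tmpl)
    expect_identical(nrow(sites), 1L)
    expect_identical(sites$strand, "+")
    expect_identical(sites$start, 11L)   # planted after 10 flank bases
    expect_identical(sites$end, 30L)
    expect_identical(sites$mismatches, 0L)
    expect_identical(sites$gapBases, 0L)

    tmpl2 <- plantedTemplate(P, rcChar(P), left = 10, right = 10)
    sites2 <- findBindingSites(P, tmpl2)
    expect_identical(nrow(sites2), 1L)
    expect_identical(sites2$strand, "-")
    expect_identical(sites2$start, 11L)
    expect_identical(sites2$mismatches, 0L)
})

test_that("five substitutions exceed any admissible edit decomposition", {
    set.seed(102)
    P <- randDna(20)
    mutant <- substituteAt(P, c(3, 7, 11, 15, 19))
    tmpl <- paste0(randDna(30), mutant, randDna(30))
    expect_identical(nrow(findBindingSites(P, tmpl)), 0L)
    expect_identical(nrow(bruteForceBindingSites(P, tmpl)), 0L)
})

test_that("edit budgets admit (2,0), (0,2), (2,2) and reject (3,0), (0,3)", {
    set.seed(103)
    P <- randDna(20)
    cases <- list(
        list(site = substituteAt(P, c(5, 12)), mm = 2L, gap = 0L, hit = TRUE),
        list(site = deleteAt(P, c(6, 13)), mm = 0L, gap = 2L, hit = TRUE),
        list(site = substituteAt(deleteAt(P, c(6, 13)), c(3, 10)),
             mm = 2L, gap = 2L, hit = TRUE),
        list(site = substituteAt(P, c(5, 12, 17)), hit = FALSE),
        list(site = deleteAt(P, c(6, 13, 17)), hit = FALSE))
    for (cs in cases) {
        tmpl <- plantedTemplate(P, cs$site, left = 40, right = 40,
                                expectSites = as.integer(cs$hit))
        sites <- findBindingSites(P, tmpl)
        if (cs$hit) {
            expect_identical(nrow(sites), 1L)
            expect_identical(sites$mismatches, cs$mm)
            expect_identical(sites$gapBases, cs$gap)
        } else {
            expect_identical(nrow(sites), 0L)
        }
        # the reference search sees the same thing
        expect_identical(sites, bruteForceBindingSites(P, tmpl))
    }
})

test_that("degenerate primer codes anneal at zero mismatch cost", {
    set.seed(104)
    core <- randDna(18)
    primer <- paste0("N", core, "R")
    tmplSite <- paste0("T", core, "A")  # N matches T, R matches A
    tmpl <- plantedTemplate(primer, tmplSite, left = 25, right = 25)
    sites <- findBindingSites(primer, tmpl)
    expect_identical(nrow(sites), 1L)
    expect_identical(sites$mismatches, 0L)
    tmplBad <- paste0("T", core, "C")   # R = {A,G} does not cover C
    sites2 <- findBindingSites(primer, paste0(randDna(25), tmplBad, randDna(25)))
    expect_true(all(sites2$mismatches >= 1L))
})

test_that("scan equals the exhaustive per-window reference on random instances", {
    set.seed(105)
    for (i in 1:60) {
        m <- sample(15:25, 1)
        P <- randDna(m)
        L <- sample(60:300, 1)
        tmpl <- randDna(L)
        if (i %% 3 != 0) {
            # plant a randomly edited copy so sites actually occur
            copy <- P
            nSub <- sample(0:4, 1)
            if (nSub > 0)
                copy <- substituteAt(copy, sample(nchar(copy), nSub))
            nDel <- sample(0:3, 1)
            if (nDel > 0)
                copy <- deleteAt(copy, sort(sample(nchar(copy), nDel)))
            if (i %% 2 == 0) copy <- rcChar(copy)
            at <- sample(L - nchar(copy), 1)
            substr(tmpl, at, at + nchar(copy) - 1) <- copy
        }
        expect_identical(findBindingSites(P, tmpl),
                         bruteForceBindingSites(P, tmpl),
                         info = paste("instance", i))
    }
})

test_that("per-window DP agrees with exhaustive alignment enumeration", {
    set.seed(106)
    skipped <- 0L
    for (i in 1:40) {
        q <- randDna(10)
        w <- randDna(sample(8:12, 1))
        if (i %% 2 == 0) {
            # correlated case: window derived from the query by small edits
            w <- substituteAt(q, sample(10, sample(0:2, 1)))
            nd <- sample(0:2, 1)
            if (nd > 0) w <- deleteAt(w, sort(sample(nchar(w), nd)))
        }
        got <- gmoscreen:::.window_align_cpp(gmoscreen:::.encodeSeq(q),
                                             gmoscreen:::.encodeSeq(w))
        ref <- enumAlign(q, w, cap = 2L)
        if (!is.na(got[1]) && got[2] <= 2L) {
            expect_false(is.null(ref), info = paste("case", i))
            expect_identical(got[1], as.integer(ref$score), info = paste("case", i))
            expect_identical(got[2], as.integer(ref$gaps), info = paste("case", i))
        } else {
            skipped <- skipped + 1L
        }
    }
    expect_lt(skipped, 10L)  # nearly all canonical alignments are low-gap
})

test_that("site search validates its inputs", {
    expect_error(findBindingSites("ACGTACGTACGT", "ACGTACGTACGTACGT",
                                  maxMismatches = -1), "non-negative")
    expect_error(findBindingSites("ACGTACGTACGT", "ACGTACGTACGTACGT",
                                  maxGaps = -1), "non-negative")
    expect_error(findBindingSites("ACGTACGT", "ACGTACGTACGTACGT"),
                 "at least 10")
    expect_error(findBindingSites("ACGTACGTACXT", "ACGTACGTACGTACGT"), "X")
})
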