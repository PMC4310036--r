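# shared fixtures and independent reference implementations for the tests

BASES <- c("A", "C", "G", "T")

randDna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rcChar <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
              N = "N")
    paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# substitute selected 1-based positions to a fixed different base
substituteAt <- function(seq, positions) {
    ch <- strsplit(seq, "")[[1]]
    for (p in positions) {
        ch[p] <- setdiff(BASES, ch[p])[1]
    }
    paste(ch, collapse = "")
}

# delete selected 1-based positions
deleteAt <- function(seq, positions) {
    ch <- strsplit(seq, "")[[1]]
    paste(ch[-positions], collapse = "")
}

# a template with `insert` planted after `left` random bases, with flanks
# resampled until the brute-force search sees exactly the expected sites
plantedTemplate <- function(primer, insert, left = 30, right = 30,
                            expectSites = 1L, maxTries = 50L) {
    for (i in seq_len(maxTries)) {
        tmpl <- paste0(randDna(left), insert, randDna(right))
        hits <- bruteForceBindingSites(primer, tmpl)
        if (nrow(hits) == expectSites) return(tmpl)
    }
    stop("could not sample clean flanks")
}

# Exhaustive canonical alignment by path enumeration: all alignments of the
# full query against the full window, insertions forbidden at both alignment
# ends, insertions and deletions each capped at `cap`.  Returns list(score,
# gaps) of the best (score max, then gaps min) alignment found, or NULL.
# Exponential -- only for tiny cases; completely independent of the package's
# DP kernels.
enumAlign <- function(query, window, cap = 2L) {
    q <- strsplit(toupper(query), "")[[1]]
    w <- strsplit(toupper(window), "")[[1]]
    match <- outer(q, w, iupacMatch)
    best <- NULL
    consider <- function(score, gaps) {
        if (is.null(best) || score > best$score ||
            (score == best$score && gaps < best$gaps))
            best <<- list(score = score, gaps = gaps)
    }
    rec <- function(i, j, score, ins, del, lastOp) {
        if (i > length(q) && j > length(w)) {
            if (lastOp != "I") consider(score, ins + del)
            return()
        }
        if (i <= length(q) && j <= length(w))
            rec(i + 1, j + 1, score + if (match[i, j]) 1 else -1,
                ins, del, "M")
        if (i <= length(q) && del < cap)
            rec(i + 1, j, score - 2, ins, del + 1, "D")
        if (j <= length(w) && ins < cap && lastOp != "S") # no leading insertion
            rec(i, j + 1, score - 2, ins + 1, del, "I")
    }
    rec(1, 1, 0, 0, 0, "S")
    best
}

# independent re-implementation of the pattern-fitting rule, straight from
# a plain score lookup table (data.frame event_id, method_id, score)
refFits <- function(scores, positive, negative, combo, policy) {
    lookup <- function(ev, m)
        scores$score[scores$event_id == ev & scores$method_id == m]
    detPos <- function(s) s == 2 || (s == 1 && policy != "as_negative")
    detNeg <- function(s) s == 2 || (s == 1 && policy == "as_positive")
    for (m in positive) {
        if (!any(vapply(combo, function(ev) detPos(lookup(ev, m)), logical(1))))
            return(FALSE)
    }
    for (m in negative) {
        if (any(vapply(combo, function(ev) detNeg(lookup(ev, m)), logical(1))))
            return(FALSE)
    }
    TRUE
}

# brute-force finder: enumerate every subset of size <= k, keep fitting sets
# with no fitting proper subset, sort by size then lexicographically
refFindEvents <- function(scores, positive, negative, k, policy) {
    events <- unique(scores$event_id)
    fitting <- list()
    for (size in seq_len(min(k, length(events)))) {
        for (combo in utils::combn(events, size, simplify = FALSE)) {
            if (refFits(scores, positive, negative, combo, policy))
                fitting[[length(fitting) + 1L]] <- sort(combo)
        }
    }
    key <- vapply(fitting, paste, character(1), collapse = "\r")
    minimal <- vapply(seq_along(fitting), function(a) {
        sa <- fitting[[a]]
        !any(vapply(seq_along(fitting), function(b) {
            sb <- fitting[[b]]
            length(sb) < length(sa) && all(sb %in% sa)
        }, logical(1)))
    }, logical(1))
    fitting <- fitting[minimal]
    key <- key[minimal]
    ord <- order(lengths(fitting), key)
    fitting[ord][!duplicated(key[ord])]
}

# small deterministic method set for I/O tests (synthetic sequences in the
# style of validated element-specific screening assays)
fixtureMethods <- function() {
    DetectionMethodSet(
        methodId = c("QT-ELE-90-001", "QL-ELE-90-002"),
        methodType = c("element_specific", "element_specific"),
        targetName = c("synthProm", "synthTerm"),
        primer1 = c("GATTCGACCTGAATGGCAGT", "CCATTGAACGGTTATCGCTAAGT"),
        primer2 = c("TTGCCAGGTCAATCGGATAC", "GGTACATCCGGATTAACGCAT"),
        probe = c("ACCAGGTTCAATGCCTTGGAGCTA", NA))
}
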