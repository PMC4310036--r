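# Nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8); degenerate IUPAC
# codes are unions of the masks of the bases they denote.
.IUPAC_BITS <- local({
    base <- c(A = 1L, C = 2L, G = 4L, T = 8L)
    vapply(strsplit(Biostrings::IUPAC_CODE_MAP, ""),
           function(b) sum(base[b]), integer(1))
})

# complement of a bit mask: swap A<->T and C<->G bits
.BIT_COMP <- local({
    m <- 1:15
    as.integer(bitwOr(bitwOr(bitwShiftL(bitwAnd(m, 1L), 3L),
                             bitwShiftR(bitwAnd(m, 8L), 3L)),
                      bitwOr(bitwShiftL(bitwAnd(m, 2L), 1L),
                             bitwShiftR(bitwAnd(m, 4L), 1L))))
})

# Encode an IUPAC string as an integer mask vector; hard error naming the
# first offending character and its position.
.encodeSeq <- function(x, what = "sequence") {
    stopifnot(is.character(x), length(x) == 1L, !is.na(x))
    if (nchar(x) == 0L) return(integer(0))
    chars <- strsplit(x, "", fixed = TRUE)[[1L]]
    codes <- .IUPAC_BITS[chars]
    bad <- which(is.na(codes))
    if (length(bad) > 0L)
        stop(sprintf("non-IUPAC character '%s' at position %d in %s",
                     chars[bad[1L]], bad[1L], what), call. = FALSE)
    unname(codes)
}

.validIupac <- function(x) {
    grepl("^[ACGTRYSWKMBDHVN]*$", x)
}

#' Do two IUPAC nucleotide codes intersect?
#'
#' Two codes are compatible when the base sets they denote share at least one
#' base: \code{N} matches everything, \code{R} (A/G) does not match \code{Y}
#' (C/T).  Degenerate codes in validated primers and probes are treated as
#' wildcards over their base set, so a compatible pair counts as zero
#' mismatches during annealing.
#'
#' @param codeA,codeB character vectors of single IUPAC codes (recycled to a
#'   common length).
#' @return Logical vector: \code{TRUE} where the base sets intersect.
#' @examples
#' iupacMatch("N", "A")   # TRUE
#' iupacMatch("R", "Y")   # FALSE
#' @export
iupacMatch <- function(codeA, codeB) {
    a <- .IUPAC_BITS[toupper(as.character(codeA))]
    b <- .IUPAC_BITS[toupper(as.character(codeB))]
    if (anyNA(a))
        stop(sprintf("non-IUPAC code '%s'", codeA[which(is.na(a))[1L]]),
             call. = FALSE)
    if (anyNA(b))
        stop(sprintf("non-IUPAC code '%s'", codeB[which(is.na(b))[1L]]),
             call. = FALSE)
    unname(bitwAnd(a, b) != 0L)
}

#' Reverse complement of plain character sequences
#'
#' Character method for the \code{\link[Biostrings]{reverseComplement}}
#' generic, accepting IUPAC strings and returning character.  Degenerate
#' codes map to their complementary codes (R to Y, K to M, S/W/N to
#' themselves); the operation is an involution.
#'
#' @param x character vector of IUPAC nucleotide strings.
#' @param ... ignored.
#' @return Character vector of the same length.
#' @examples
#' reverseComplement("AAAC")  # "GTTT"
#' @export
setMethod("reverseComplement", "character", function(x, ...) {
    vapply(x, function(s) {
        s <- toupper(s)
        .encodeSeq(s)  # validates, errors name the offending character
        if (nchar(s) == 0L) return("")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }, character(1), USE.NAMES = FALSE)
})

# reverse complement directly on an encoded mask vector
.rcBits <- function(bits) {
    if (length(bits) == 0L) return(bits)
    rev(.BIT_COMP[bits])
}

# uniform random ACGT string, used by the panel generator
.randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
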