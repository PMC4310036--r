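.METHOD_COLS <- c("method_id", "method_type", "target_name",
                  "primer1", "primer2", "probe")

#' Read a detection-method table
#'
#' Parses a delimited table of PCR assays (one row per method) into a
#' \linkS4class{DetectionMethodSet}.  The delimiter (tab or comma) is
#' auto-detected from the header row.  Required columns: \code{method_id},
#' \code{method_type}, \code{target_name}, \code{primer1}, \code{primer2},
#' \code{probe} (empty string for probe-less assays).
#'
#' @param path path to the delimited file.
#' @return A \linkS4class{DetectionMethodSet}, rows in file order.
#' @seealso [writeMethodsTable()]
#' @export
readMethodsTable <- function(path) {
    if (!file.exists(path))
        stop(sprintf("methods table not found: %s", path), call. = FALSE)
    header <- readLines(path, n = 1L)
    if (length(header) == 0L)
        stop("empty methods table", call. = FALSE)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
    tb <- utils::read.delim(path, sep = sep, colClasses = "character",
                            check.names = FALSE, quote = "\"")
    miss <- setdiff(.METHOD_COLS, colnames(tb))
    if (length(miss) > 0L)
        stop(sprintf("missing required column '%s' in methods table", miss[1L]),
             call. = FALSE)
    dup <- tb$method_id[duplicated(tb$method_id)]
    if (length(dup) > 0L)
        stop(sprintf("duplicate method_id: %s", dup[1L]), call. = FALSE)
    for (i in seq_len(nrow(tb))) {
        for (col in c("primer1", "primer2", "probe")) {
            v <- toupper(tb[[col]][i])
            if (col == "probe" && v == "") next
            bad <- regmatches(v, regexpr("[^ACGTRYSWKMBDHVN]", v))
            if (length(bad) > 0L)
                stop(sprintf("non-IUPAC character '%s' in column %s, row %d (method %s)",
                             bad, col, i, tb$method_id[i]), call. = FALSE)
        }
    }
    DetectionMethodSet(methodId = tb$method_id, methodType = tb$method_type,
                       targetName = tb$target_name, primer1 = tb$primer1,
                       primer2 = tb$primer2, probe = tb$probe)
}

#' Write a detection-method table
#'
#' @param x a \linkS4class{DetectionMethodSet}.
#' @param path output path.
#' @param sep field delimiter, tab (default) or comma.
#' @return \code{path}, invisibly.
#' @export
writeMethodsTable <- function(x, path, sep = c("\t", ",")) {
    stopifnot(is(x, "DetectionMethodSet"))
    sep <- match.arg(sep)
    probe <- ifelse(is.na(x@probe), "", x@probe)
    lines <- c(paste(.METHOD_COLS, collapse = sep),
               paste(x@methodId, x@methodType, x@targetName,
                     x@primer1, x@primer2, probe, sep = sep))
    writeLines(lines, path)
    invisible(path)
}

#' Read GM event sequences from FASTA
#'
#' Headers follow the \code{>eventID|label} convention; records sharing an
#' event identifier are grouped into one event in file order (an event
#' carries several sequences when it is a retransformation of an earlier
#' event or only available stacked with another).  Sequences are uppercased.
#'
#' @param path path to a FASTA file.
#' @return A \linkS4class{GMOEventSet}.
#' @seealso [writeEventsFasta()]
#' @export
readEventsFasta <- function(path) {
    if (!file.exists(path))
        stop(sprintf("events FASTA not found: %s", path), call. = FALSE)
    x <- Biostrings::readDNAStringSet(path)
    if (length(x) == 0L)
        stop("no FASTA records found", call. = FALSE)
    if (any(BiocGenerics::width(x) == 0L))
        stop(sprintf("empty sequence record: %s",
                     names(x)[BiocGenerics::width(x) == 0L][1L]), call. = FALSE)
    hdr <- names(x)
    if (any(!grepl("^[^|[:space:]]+\\|", hdr)))
        stop(sprintf("malformed FASTA header (expected '>eventID|label'): %s",
                     hdr[!grepl("^[^|[:space:]]+\\|", hdr)][1L]), call. = FALSE)
    eventId <- sub("\\|.*$", "", hdr)
    label <- sub("^[^|]*\\|", "", hdr)
    ord <- order(match(eventId, unique(eventId)),
                 stats::ave(seq_along(eventId), eventId, FUN = seq_along))
    GMOEventSet(as.character(x)[ord], eventId[ord], label[ord])
}

#' Write GM event sequences to FASTA
#'
#' Inverse of [readEventsFasta()]: headers are \code{>eventID|label},
#' sequence lines wrapped at 60 columns.  A write/read round trip preserves
#' the in-memory object; a read/write round trip of a file produced by this
#' writer is byte-identical.
#'
#' @param x a \linkS4class{GMOEventSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEventsFasta <- function(x, path) {
    stopifnot(is(x, "GMOEventSet"))
    y <- Biostrings::DNAStringSet(as.character(x))
    names(y) <- paste(mcols(x)$event_id, mcols(x)$label, sep = "|")
    Biostrings::writeXStringSet(y, path, width = 60L)
    invisible(path)
}
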