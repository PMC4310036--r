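#' Build a screening matrix from stored scores
#'
#' Fetches pre-computed pair scores and lays them out as an events x methods
#' grid in the requested row and column order.  Every requested pair must be
#' present in the store.
#'
#' @param store a \linkS4class{ScoreStore}.
#' @param eventIds,methodIds identifiers selecting and ordering rows and
#'   columns; default to every event/method in the store, in store order.
#' @return A \linkS4class{ScreeningMatrix}.
#' @export
buildMatrix <- function(store, eventIds = NULL, methodIds = NULL) {
    stopifnot(is(store, "ScoreStore"))
    if (is.null(eventIds)) eventIds <- unique(store@table$event_id)
    if (is.null(methodIds)) methodIds <- unique(store@table$method_id)
    eventIds <- as.character(eventIds)
    methodIds <- as.character(methodIds)
    sc <- matrix(NA_integer_, length(eventIds), length(methodIds),
                 dimnames = list(eventIds, methodIds))
    wn <- matrix(NA, length(eventIds), length(methodIds),
                 dimnames = list(eventIds, methodIds))
    tb <- store@table
    key <- paste(tb$event_id, tb$method_id, sep = "\r")
    for (i in seq_along(eventIds)) {
        for (j in seq_along(methodIds)) {
            k <- match(paste(eventIds[i], methodIds[j], sep = "\r"), key)
            if (is.na(k))
                stop(sprintf("no score stored for pair (%s, %s)",
                             eventIds[i], methodIds[j]), call. = FALSE)
            sc[i, j] <- tb$score[k]
            wn[i, j] <- tb$warning[k]
        }
    }
    se <- SummarizedExperiment(
        assays = list(score = sc, warning = wn),
        rowData = DataFrame(event_id = eventIds, row.names = eventIds),
        colData = DataFrame(method_id = methodIds, row.names = methodIds))
    metadata(se)$thresholds <- store@thresholds
    new("ScreeningMatrix", se)
}

.csvQuote <- function(x) {
    need <- grepl('[",\n\r]', x)
    x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
    x
}

#' Export a screening matrix as CSV
#'
#' First column \code{event_id}, one column per method; cells are the 0/1/2
#' score with a \code{!} suffix where a self-pairing amplicon was retained
#' (the assay could fire outside its intent).  RFC-4180 quoting, trailing
#' newline; the output is byte-stable, and [readMatrixCsv()] inverts it.
#'
#' @param mat a \linkS4class{ScreeningMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
exportMatrixCsv <- function(mat, path) {
    stopifnot(is(mat, "ScreeningMatrix"))
    sc <- scoreMatrix(mat)
    wn <- warningMatrix(mat)
    header <- paste(.csvQuote(c("event_id", colnames(sc))), collapse = ",")
    body <- vapply(seq_len(nrow(sc)), function(i) {
        cells <- paste0(sc[i, ], ifelse(wn[i, ], "!", ""))
        paste(.csvQuote(c(rownames(sc)[i], cells)), collapse = ",")
    }, character(1))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(header, body), con, sep = "\n")
    invisible(path)
}

#' Read a screening-matrix CSV
#'
#' @param path a file written by [exportMatrixCsv()].
#' @return A \linkS4class{ScreeningMatrix}.
#' @export
readMatrixCsv <- function(path) {
    if (!file.exists(path))
        stop(sprintf("matrix CSV not found: %s", path), call. = FALSE)
    tb <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    if (colnames(tb)[1L] != "event_id")
        stop("matrix CSV must start with an event_id column", call. = FALSE)
    methods <- colnames(tb)[-1L]
    cells <- as.matrix(tb[, -1L, drop = FALSE])
    if (length(cells) > 0L && !all(grepl("^[012]!?$", cells)))
        stop("matrix CSV cells must be 0/1/2 with optional '!' flag",
             call. = FALSE)
    wn <- matrix(grepl("!", cells, fixed = TRUE), nrow(tb),
                 dimnames = list(tb$event_id, methods))
    sc <- matrix(as.integer(sub("!", "", cells, fixed = TRUE)), nrow(tb),
                 dimnames = list(tb$event_id, methods))
    se <- SummarizedExperiment(
        assays = list(score = sc, warning = wn),
        rowData = DataFrame(event_id = tb$event_id, row.names = tb$event_id),
        colData = DataFrame(method_id = methods, row.names = methods))
    new("ScreeningMatrix", se)
}

#' Render a screening matrix as a static HTML table
#'
#' Presentation-only companion of [exportMatrixCsv()]: same grid, no extra
#' semantics.  Self-pair warnings render as \code{!} after the score.
#'
#' @param mat a \linkS4class{ScreeningMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
renderMatrixHtml <- function(mat, path) {
    stopifnot(is(mat, "ScreeningMatrix"))
    esc <- function(x) {
        x <- gsub("&", "&amp;", x, fixed = TRUE)
        x <- gsub("<", "&lt;", x, fixed = TRUE)
        gsub(">", "&gt;", x, fixed = TRUE)
    }
    sc <- scoreMatrix(mat)
    wn <- warningMatrix(mat)
    rows <- c(paste0("<tr><th>event_id</th>",
                     paste0("<th>", esc(colnames(sc)), "</th>", collapse = ""),
                     "</tr>"),
              vapply(seq_len(nrow(sc)), function(i) {
                  cells <- paste0(sc[i, ], ifelse(wn[i, ], "!", ""))
                  paste0("<tr><td>", esc(rownames(sc)[i]), "</td>",
                         paste0("<td class=\"s", sc[i, ], "\">", cells,
                                "</td>", collapse = ""),
                         "</tr>")
              }, character(1)))
    writeLines(c("<!DOCTYPE html>",
                 "<html><head><meta charset=\"utf-8\">",
                 "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 6px}",
                 ".s2{background:#bfe6bf}.s1{background:#fff3b0}.s0{background:#f2f2f2}</style>",
                 "</head><body><table>", rows, "</table></body></html>"),
               path)
    invisible(path)
}
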