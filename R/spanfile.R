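## Rosetta-style spanfile parsing and writing.
##
## Dialect: line 1 free-text header; line 2 "<n_spans> <n_res>"; line 3
## "antiparallel"; line 4 "n2c"; then one "<start> <end>" pair per span
## (whitespace-separated, 1-based pose numbering, inclusive).

#' Construct a SpanFile
#'
#' Spans are normalised: sorted by start and overlapping or adjacent-by-
#' overlap ranges merged (with a warning when a merge occurs).
#'
#' @param spans two-column numeric matrix (or a single c(start, end) pair) of
#'   1-based inclusive residue ranges.
#' @param nRes total number of residues in the annotated protein.
#' @return a \linkS4class{SpanFile}.
#' @examples
#' spanFile(rbind(c(10, 30), c(25, 45)), nRes = 100)  # merged to 10-45
#' @export
spanFile <- function(spans, nRes) {
    if (is.null(dim(spans))) spans <- matrix(spans, ncol = 2L, byrow = TRUE)
    spans <- matrix(as.integer(round(spans)), ncol = 2L,
                    dimnames = list(NULL, c("start", "end")))
    nRes <- as.integer(nRes)
    if (nrow(spans) == 0L) stop("span list must not be empty")
    if (any(spans[, 1L] > spans[, 2L])) stop("span start must be <= end")
    if (any(spans[, 1L] < 1L)) stop("span start must be >= 1")
    if (any(spans[, 2L] > nRes)) {
        stop("span exceeds the protein length (nRes = ", nRes, ")")
    }
    spans <- spans[order(spans[, 1L], spans[, 2L]), , drop = FALSE]
    merged <- spans[1L, , drop = FALSE]
    didMerge <- FALSE
    if (nrow(spans) > 1L) {
        for (i in 2L:nrow(spans)) {
            last <- nrow(merged)
            if (spans[i, 1L] <= merged[last, 2L]) {
                merged[last, 2L] <- max(merged[last, 2L], spans[i, 2L])
                didMerge <- TRUE
            } else {
                merged <- rbind(merged, spans[i, , drop = FALSE])
            }
        }
    }
    if (didMerge) warning("overlapping spans merged")
    new("SpanFile", nRes = nRes, spans = merged)
}

#' Read a spanfile
#'
#' @param path path to a Rosetta-style spanfile.
#' @return a \linkS4class{SpanFile}.
#' @rdname spanfileIO
#' @examples
#' sf <- spanFile(c(5, 25), nRes = 40)
#' p <- tempfile(fileext = ".span")
#' writeSpanfile(sf, p)
#' readSpanfile(p)
#' @export
readSpanfile <- function(path) {
    if (!file.exists(path)) stop("spanfile not found: ", path)
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (length(lines) < 5L) {
        stop("spanfile too short: expected header, counts, topology lines ",
             "and >= 1 span")
    }
    counts <- suppressWarnings(as.integer(strsplit(lines[2L], "\\s+")[[1L]]))
    if (length(counts) != 2L || any(is.na(counts))) {
        stop("line 2 of a spanfile must be \"<n_spans> <n_res>\"")
    }
    nSpans <- counts[1L]
    nRes <- counts[2L]
    spanLines <- lines[-(1:4)]
    if (length(spanLines) != nSpans) {
        stop("spanfile declares ", nSpans, " span(s) but lists ",
             length(spanLines))
    }
    spans <- t(vapply(strsplit(spanLines, "\\s+"), function(f) {
        v <- suppressWarnings(as.integer(f[1:2]))
        if (any(is.na(v))) stop("malformed span line in spanfile")
        v
    }, integer(2L)))
    spanFile(spans, nRes)
}

#' Write a spanfile
#'
#' @param span a \linkS4class{SpanFile}.
#' @return invisibly, \code{path}.
#' @rdname spanfileIO
#' @export
writeSpanfile <- function(span, path) {
    stopifnot(is(span, "SpanFile"))
    validObject(span)
    s <- span@spans
    lines <- c(
        "TM region prediction",
        sprintf("%d %d", nrow(s), span@nRes),
        "antiparallel",
        "n2c",
        sprintf("%5d %5d", s[, 1L], s[, 2L])
    )
    writeLines(lines, path)
    invisible(path)
}

#' @rdname SpanFile-class
#' @export
setMethod("spans", "SpanFile", function(object) object@spans)

#' @rdname SpanFile-class
#' @export
setMethod("spanResidues", "SpanFile", function(object) {
    sort(unique(unlist(
        lapply(seq_len(nrow(object@spans)),
               function(i) object@spans[i, 1L]:object@spans[i, 2L])
    )))
})

setMethod("show", "SpanFile", function(object) {
    cat(sprintf("SpanFile: %d span(s) over %d residues\n",
                nrow(object@spans), object@nRes))
    for (i in seq_len(nrow(object@spans))) {
        cat(sprintf("  %d-%d\n", object@spans[i, 1L], object@spans[i, 2L]))
    }
})
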