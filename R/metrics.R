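## Decoy-discrimination and design-benchmark statistics.

#' Construct an ensemble table
#'
#' Per-model score/RMSD pairs consumed by the discrimination metrics.
#'
#' @param score numeric vector of model scores (lower = better).
#' @param rmsd numeric vector of RMSD values to the reference (Angstrom).
#' @param modelId optional character vector of model identifiers (defaults to
#'   \code{model_0001}, ...); used as the deterministic tie-break.
#' @return data.frame with columns \code{modelId}, \code{score}, \code{rmsd}.
#' @export
ensembleTable <- function(score, rmsd, modelId = NULL) {
    n <- length(score)
    if (length(rmsd) != n) stop("score and rmsd must have equal length")
    if (n < 1L) stop("ensemble must contain at least one model")
    if (any(!is.finite(score)) || any(!is.finite(rmsd))) {
        stop("scores and RMSDs must be finite")
    }
    if (is.null(modelId)) modelId <- sprintf("model_%05d", seq_len(n))
    if (anyDuplicated(modelId)) stop("modelId values must be unique")
    data.frame(modelId = as.character(modelId), score = as.numeric(score),
               rmsd = as.numeric(rmsd), stringsAsFactors = FALSE)
}

#' Read an ensemble table from a file
#'
#' Whitespace- or comma-separated columns; must contain \code{score} and
#' \code{rmsd} columns (a \code{modelId}/\code{model} column is used when
#' present).
#'
#' @param path path to the table file (with a header line).
#' @return an ensemble table data.frame (see [ensembleTable()]).
#' @export
readEnsembleTable <- function(path) {
    if (!file.exists(path)) stop("ensemble table not found: ", path)
    first <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
    tb <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    names(tb) <- tolower(names(tb))
    if (!all(c("score", "rmsd") %in% names(tb))) {
        stop("ensemble table needs 'score' and 'rmsd' columns")
    }
    id <- if ("modelid" %in% names(tb)) tb$modelid
          else if ("model" %in% names(tb)) tb$model
          else NULL
    ensembleTable(tb$score, tb$rmsd, modelId = id)
}

## Indices of the k smallest values, ties broken by modelId (stable,
## platform-independent).
topIndices <- function(values, modelId, k) {
    order(values, modelId)[seq_len(k)]
}

#' Enrichment of low-RMSD models among low-scoring models
#'
#' How many of the top-\code{fraction} models by score are also in the
#' top-\code{fraction} by RMSD, scaled so that complete overlap gives
#' \eqn{1/\mathrm{fraction}} (10 for the default 10 percent) and no overlap
#' gives 0:
#' \deqn{E = \frac{|S \cap R|}{k \cdot \mathrm{fraction}}}
#' with \eqn{k = \lceil \mathrm{fraction} \cdot N \rceil}, \eqn{S} the
#' indices of the k lowest scores and \eqn{R} of the k lowest RMSDs.
#'
#' @param table an ensemble table (see [ensembleTable()]).
#' @param fraction top fraction to compare (default 0.1).
#' @return enrichment value in \eqn{[0, 1/\mathrm{fraction}]}.
#' @examples
#' tab <- ensembleTable(score = 1:100, rmsd = 1:100)
#' enrichment(tab)  # perfect funnel: 10
#' @export
enrichment <- function(table, fraction = 0.1) {
    stopifnot(is.data.frame(table),
              all(c("modelId", "score", "rmsd") %in% names(table)))
    stopifnotScalar(fraction, "fraction", positive = TRUE)
    if (fraction > 1) stop("'fraction' must be in (0, 1]")
    n <- nrow(table)
    if (n * fraction < 1) {
        stop("ensemble too small: need at least ", ceiling(1 / fraction),
             " models for fraction ", fraction)
    }
    k <- ceiling(fraction * n)
    s <- topIndices(table$score, table$modelId, k)
    r <- topIndices(table$rmsd, table$modelId, k)
    length(intersect(s, r)) / (k * fraction)
}

#' Boltzmann-weighted funnel metric (Pnear)
#'
#' \deqn{P_{near} = \frac{\sum_i e^{-r_i^2/\lambda^2} e^{-E_i/kT}}
#'   {\sum_i e^{-E_i/kT}}}
#' over models with RMSD \eqn{r_i} and score \eqn{E_i}. Ranges from 0 to 1;
#' values near 1 mean the low-scoring models cluster at low RMSD. Scores are
#' shifted by their minimum before exponentiation, which leaves the ratio
#' unchanged and keeps it numerically stable.
#'
#' @param table an ensemble table (see [ensembleTable()]).
#' @param lambda RMSD similarity scale in Angstrom (default 2, a typical
#'   backbone/interface-RMSD scale).
#' @param kT score scale in the same units as \code{score} (default 1).
#' @return Pnear value in [0, 1].
#' @examples
#' pnear(ensembleTable(score = c(0, 1), rmsd = c(0.5, 8)))
#' @export
pnear <- function(table, lambda = 2, kT = 1) {
    stopifnot(is.data.frame(table),
              all(c("score", "rmsd") %in% names(table)))
    stopifnotScalar(lambda, "lambda", positive = TRUE)
    stopifnotScalar(kT, "kT", positive = TRUE)
    if (nrow(table) < 1L) stop("ensemble must contain at least one model")
    w <- exp(-(table$score - min(table$score)) / kT)
    sum(exp(-table$rmsd^2 / lambda^2) * w) / sum(w)
}

## Validate a native/designed sequence pair plus mask; returns the masked
## per-position character vectors.
maskedPair <- function(native, designed, mask = NULL) {
    native <- strsplit(toupper(native), "")[[1L]]
    designed <- strsplit(toupper(designed), "")[[1L]]
    if (length(native) != length(designed)) {
        stop("native and designed sequences must have equal length")
    }
    if (is.null(mask)) mask <- rep(TRUE, length(native))
    if (is.logical(mask)) {
        if (length(mask) != length(native)) {
            stop("logical mask must match the sequence length")
        }
        mask <- which(mask)
    }
    if (length(mask) == 0L) stop("mask selects no positions")
    list(native = native[mask], designed = designed[mask])
}

#' Sequence recovery
#'
#' Fraction of native residues recovered after design over the masked
#' (designable) positions.
#'
#' @param native,designed amino-acid strings of equal length (one-letter
#'   code).
#' @param mask logical vector or integer positions to evaluate (default all).
#' @return fraction in [0, 1].
#' @examples
#' sequenceRecovery("LIVF", "LIVA")  # 0.75
#' @export
sequenceRecovery <- function(native, designed, mask = NULL) {
    p <- maskedPair(native, designed, mask)
    mean(p$native == p$designed)
}

#' Non-random recovery per amino acid
#'
#' Recovery rate of each amino acid relative to the 1/20 background
#' probability of guessing it at random: a ratio of 1 is chance level, 20 is
#' perfect recovery. Amino acids absent from the masked native positions are
#' omitted.
#'
#' @inheritParams sequenceRecovery
#' @return named numeric vector of recovery ratios, one per native amino
#'   acid present in the mask.
#' @examples
#' nonrandomRecovery("LLLL", "LLLA")  # L recovered at 0.75 -> 15
#' @export
nonrandomRecovery <- function(native, designed, mask = NULL) {
    p <- maskedPair(native, designed, mask)
    aas <- sort(unique(p$native))
    vapply(aas, function(aa) {
        sel <- p$native == aa
        mean(p$designed[sel] == aa) / (1 / 20)
    }, numeric(1L))
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' KL divergence of designed vs native amino-acid composition
#'
#' \eqn{D(p_{designed} \| p_{native}) = \sum_{aa} p_d \log(p_d / p_n)} in
#' nats, over the 20 amino acids with a small pseudocount added to both
#' distributions to avoid zeros. Zero exactly when the two compositions are
#' identical; always non-negative.
#'
#' @inheritParams sequenceRecovery
#' @param pseudocount count added per amino acid before normalising
#'   (default 1e-4).
#' @return KL divergence in nats (>= 0).
#' @examples
#' klDivergence("LLVV", "LLVV")  # 0
#' @export
klDivergence <- function(native, designed, mask = NULL, pseudocount = 1e-4) {
    stopifnotScalar(pseudocount, "pseudocount", positive = TRUE)
    p <- maskedPair(native, designed, mask)
    counts <- function(x) {
        cc <- table(factor(x, levels = .AA20)) + pseudocount
        as.numeric(cc / sum(cc))
    }
    pd <- counts(p$designed)
    pn <- counts(p$native)
    sum(pd * log(pd / pn))
}

#' Empirical cumulative distribution of ensemble RMSDs
#'
#' Right-continuous ECDF of the RMSD column, returned as step points for
#' plotting cumulative decoy-quality curves.
#'
#' @param table an ensemble table (see [ensembleTable()]).
#' @return data.frame with columns \code{rmsd} (sorted unique values) and
#'   \code{cdf}; the CDF reaches 1 at the maximal RMSD.
#' @examples
#' cumulativeRmsd(ensembleTable(score = 1:3, rmsd = c(1, 2, 3)))
#' @export
cumulativeRmsd <- function(table) {
    stopifnot(is.data.frame(table), "rmsd" %in% names(table))
    if (nrow(table) < 1L) stop("ensemble must contain at least one model")
    fn <- stats::ecdf(table$rmsd)
    x <- sort(unique(table$rmsd))
    data.frame(rmsd = x, cdf = fn(x))
}
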