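#' @include AllClasses.R seqio.R
NULL

#' Find twin-arginine (RR) motifs
#'
#' Every position i with residues \code{RR} at i, i+1 yields a motif
#' (overlapping pairs, e.g. in \code{"RRR"}, are all reported). The
#' consensus context S/T-R-R-x-F-L-K is scored with one point per satisfied
#' position: S or T at i-1, F at i+3, L at i+4 and K at i+5 (the \code{x}
#' position i+2 is unscored), giving an integer score 0-4. In
#' \code{mode = "consensus"} only motifs with score >= \code{minScore} are
#' returned; the default \code{"rr-only"} mode reports every RR pair, since
#' dual-targeting screens key on the arginine pair plus the adjacent
#' transmembrane helix rather than on a strict consensus.
#'
#' @param x sequence (as in [segmentDG()]).
#' @param mode \code{"rr-only"} (default) or \code{"consensus"}.
#' @param minScore minimum consensus score in consensus mode (default 2).
#' @return \link[IRanges]{IRanges} over the two arginines, with metadata
#'   columns \code{context} (residues i-1..i+5, truncated at the sequence
#'   ends) and \code{consensus_score}.
#' @examples
#' findRRMotifs("MSTRRGFLKA")
#' @export
findRRMotifs <- function(x, mode = c("rr-only", "consensus"),
                         minScore = 2L) {
    mode <- match.arg(mode)
    s <- .asSeqString(x)
    n <- nchar(s)
    res <- strsplit(s, "")[[1L]]
    pos <- which(res[-n] == "R" & res[-1L] == "R")
    if (!length(pos) || n < 2L) {
        out <- IRanges()
        mcols(out) <- DataFrame(context = character(),
                                consensus_score = integer())
        return(out)
    }
    at <- function(p, off) {
        q <- p + off
        ifelse(q >= 1L & q <= n, res[pmax(pmin(q, n), 1L)], "")
    }
    score <- (at(pos, -1L) %in% c("S", "T")) +
        (at(pos, 3L) == "F") +
        (at(pos, 4L) == "L") +
        (at(pos, 5L) == "K")
    context <- vapply(pos, function(p)
        substr(s, max(1L, p - 1L), min(n, p + 5L)), character(1L))
    out <- IRanges(start = pos, width = 2L)
    mcols(out) <- DataFrame(context = context,
                            consensus_score = as.integer(score))
    if (mode == "consensus")
        out <- out[mcols(out)$consensus_score >= minScore]
    out
}
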