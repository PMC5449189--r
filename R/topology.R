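#' @include AllClasses.R dgscale.R
NULL

#' Orient a topology by the positive-inside rule
#'
#' Deterministic stand-in for an HMM-derived N-in probability: lysines and
#' arginines are counted in the loops on either side of the transmembrane
#' segments. Loop 0 runs from residue 1 to the first segment start - 1,
#' loop k lies between segments k and k+1, and the C-terminal tail is the
#' last loop. With \code{P_even} the K+R count over even-parity loops
#' (0, 2, 4, ...; the side the N-terminus is on) and \code{P_odd} the count
#' over odd-parity loops, the score is
#' \deqn{n_{in} = (P_{even} + c) / (P_{even} + P_{odd} + 2c)}
#' with pseudocount \eqn{c = 1}. Orientation is N-in iff the score is
#' >= 0.5; an exact tie resolves to N-in and is flagged. Histidine is not
#' counted (standard K+R convention). Because scanned helix boundaries
#' carry ~2 residues of noise (terminal window positions get near-zero
#' weight), residues in the outermost 2 positions of each segment are
#' counted with the adjacent loop: a charge at a helix terminus is a
#' flanking charge under the positive-inside rule, whichever side of the
#' predicted boundary it lands on.
#'
#' @param x sequence (as in [segmentDG()]).
#' @param segments \link[IRanges]{IRanges} of transmembrane segments
#'   (ascending, non-overlapping, at least one).
#' @return list with \code{orientation} (\code{"N-in"}/\code{"N-out"}),
#'   \code{nInScore} and \code{tie} (logical).
#' @examples
#' orientByCharge("KRKRKAAAAALLLLLLLLLLLLLLLLLLGG",
#'                IRanges::IRanges(start = 11, end = 29))
#' @export
orientByCharge <- function(x, segments) {
    s <- .asSeqString(x)
    if (length(segments) == 0L)
        stop("orientByCharge needs at least one segment")
    res <- strsplit(s, "")[[1L]]
    n <- length(res)
    # erode each segment by up to 2 residues per side (never past its
    # midpoint); the eroded positions count with the neighbouring loop
    ero <- pmin(2L, width(segments) %/% 2L)
    bounds_s <- c(1L, end(segments) + 1L - ero)
    bounds_e <- c(start(segments) - 1L + ero, n)
    kr <- vapply(seq_along(bounds_s), function(k) {
        if (bounds_s[k] > bounds_e[k]) return(0L)
        sum(res[bounds_s[k]:bounds_e[k]] %in% c("K", "R"))
    }, integer(1L))
    parity <- (seq_along(kr) - 1L) %% 2L
    p_even <- sum(kr[parity == 0L])
    p_odd <- sum(kr[parity == 1L])
    score <- (p_even + 1) / (p_even + p_odd + 2)
    list(orientation = if (score >= 0.5) "N-in" else "N-out",
         nInScore = score,
         tie = score == 0.5)
}

#' Assemble an oriented topology model
#'
#' Combines scanned segments (from [scanSegments()]) with an optional
#' imported prediction for the same protein. An imported topology always
#' takes precedence: its segments and first-loop side define the model
#' (\code{source = "imported"}), and its N-in probability (when present)
#' becomes the model's score. When the import carries no probability the
#' score is imputed as 1 (N-in) or 0 (N-out) and flagged
#' \code{"prob-imputed"}. Without an import, orientation comes from
#' [orientByCharge()]; a protein with no segments at all is modelled N-in
#' by convention with a \code{"no-TM"} flag.
#'
#' @param x sequence (as in [segmentDG()]); give a named
#'   single-record \link[Biostrings]{AAStringSet} (or use \code{id}) so the
#'   model knows its protein.
#' @param segments \link[IRanges]{IRanges} from [scanSegments()] (may be
#'   empty); ignored when \code{imported} is given.
#' @param imported optional \linkS4class{ImportedTopology}.
#' @param scale optional \linkS4class{HydrophobicityScale}; when supplied,
#'   per-segment dG_app values are (re)computed for imported segments.
#' @param id protein identifier (defaults to the record name).
#' @return a \linkS4class{TopologyModel}.
#' @export
buildTopology <- function(x, segments = IRanges(), imported = NULL,
                          scale = NULL, id = NULL) {
    s <- .asSeqString(x)
    if (is.null(id))
        id <- .recordId(x)
    if (!is.null(imported)) {
        if (imported@proteinId != id)
            stop("imported topology is for '", imported@proteinId,
                 "', not '", id, "'")
        seg <- imported@segments
        if (!is.null(scale) && length(seg)) {
            dg <- vapply(seq_along(seg), function(k)
                dgApp(segmentDG(s, start(seg)[k], end(seg)[k], scale)),
                numeric(1L))
            mcols(seg) <- DataFrame(dg_app = dg)
        } else if (length(seg)) {
            mcols(seg) <- DataFrame(dg_app = rep(NA_real_, length(seg)))
        }
        flags <- character()
        ori <- if (imported@firstLoop == "inside") "N-in" else "N-out"
        prob <- imported@nInProb
        if (is.na(prob)) {
            prob <- if (ori == "N-in") 1 else 0
            flags <- "prob-imputed"
        } else {
            # orientation follows the explicit probability when present
            ori <- if (prob >= 0.5) "N-in" else "N-out"
            if (prob == 0.5) flags <- "tie"
        }
        return(new("TopologyModel", proteinId = id, segments = seg,
                   orientation = ori, nInScore = prob,
                   source = "imported", flags = flags))
    }
    if (length(segments) == 0L) {
        return(new("TopologyModel", proteinId = id, segments = IRanges(),
                   orientation = "N-in", nInScore = 0.5,
                   source = "predicted", flags = "no-TM"))
    }
    ob <- orientByCharge(s, segments)
    new("TopologyModel", proteinId = id, segments = segments,
        orientation = ob$orientation, nInScore = ob$nInScore,
        source = "predicted", flags = if (ob$tie) "tie" else character())
}
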