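#' @include AllClasses.R topology.R tatmotif.R
NULL

#' Screen parameters
#'
#' Thresholds of the dual-targeting screen. The N-in class requires an
#' orientation score strictly above \code{nInThreshold} (default 0.9), the
#' N-out class a score strictly below \code{nOutThreshold} (default 0.5);
#' scores in between are left unclassified (reason \code{orientation}),
#' mirroring the original screen's unclassified zone. \code{maxGap} bounds
#' the residues allowed between the second arginine and the start of the
#' final helix ("directly precedes"); \code{rescueWeakFinalTmd} re-queries
#' the scanner for the best sub-threshold window after the motif when no
#' helix was called there, which is how weakly hydrophobic (positive
#' dG_app) Tat-dependent helices are recovered.
#' \code{allowZeroBefore} lifts the requirement of at least two helices
#' before the motif in the N-in class.
#'
#' @param nInThreshold,nOutThreshold orientation score cutoffs.
#' @param maxGap maximum motif-to-helix gap in residues.
#' @param rescueWeakFinalTmd logical, default TRUE.
#' @param allowZeroBefore logical, default FALSE.
#' @return named list of parameters.
#' @export
screenParams <- function(nInThreshold = 0.9, nOutThreshold = 0.5,
                         maxGap = 30L, rescueWeakFinalTmd = TRUE,
                         allowZeroBefore = FALSE) {
    list(nInThreshold = nInThreshold, nOutThreshold = nOutThreshold,
         maxGap = as.integer(maxGap),
         rescueWeakFinalTmd = isTRUE(rescueWeakFinalTmd),
         allowZeroBefore = isTRUE(allowZeroBefore))
}

# Evaluate one motif against a topology; returns either a classified
# partial result or a list(reason=...).
.evalMotif <- function(pos, topo, s, scale, params) {
    seg <- topo@segments
    # A motif interior to a helix span cannot be a loop-resident Tat
    # signal and is skipped. Scanned helix boundaries carry ~2 residues of
    # noise (terminal positions get near-zero weight), so a motif at or
    # within 2 residues of a helix N-terminus is treated as directly
    # preceding that helix (gap 0), not as inside it.
    adjoining <- 0L
    if (length(seg)) {
        ov <- which((pos >= start(seg) & pos <= end(seg)) |
                    (pos + 1L >= start(seg) & pos + 1L <= end(seg)))
        if (length(ov)) {
            if (pos - start(seg)[ov[1L]] > 2L)
                return(list(reason = "in-TMD"))
            adjoining <- ov[1L]
        }
    }
    before <- which(end(seg) < pos)
    if (adjoining)
        before <- setdiff(before, adjoining)
    after <- which(start(seg) > pos + 1L)
    nBefore <- length(before)
    nAfter <- length(after) + (adjoining > 0L)
    final <- if (adjoining) seg[adjoining]
             else if (length(after)) seg[after[1L]]
             else IRanges()
    rescued <- FALSE
    if (nAfter == 0L && params$rescueWeakFinalTmd &&
        !is.null(s) && !is.null(scale)) {
        win <- .bestWindowIn(s, scale, from = pos + 2L,
                             to = pos + 1L + params$maxGap, avoid = seg)
        if (!is.null(win)) {
            final <- win
            nAfter <- 1L
            rescued <- TRUE
        }
    }
    if (nAfter != 1L)
        return(list(reason = "tmd-count"))
    # gap convention: start(final) - rr_pos - 1 (6 for the Rieske
    # exemplar: twin arginines at 161-162, helix starting at 168)
    gap <- max(start(final) - pos - 1L, 0L)
    if (gap > params$maxGap)
        return(list(reason = "gap"))
    score <- topo@nInScore
    minBefore <- if (params$allowZeroBefore) 0L else 2L
    if (nBefore %% 2L == 0L && nBefore >= minBefore &&
        !is.na(score) && score > params$nInThreshold) {
        cls <- "N-in-even"
    } else if (nBefore %% 2L == 1L && nBefore <= 7L &&
               !is.na(score) && score < params$nOutThreshold) {
        cls <- "N-out-odd"
    } else if ((nBefore %% 2L == 0L && nBefore < minBefore) ||
               (nBefore %% 2L == 1L && nBefore > 7L)) {
        return(list(reason = "tmd-count"))
    } else {
        return(list(reason = "orientation"))
    }
    list(cls = cls, nBefore = nBefore, nAfter = nAfter, final = final,
         gap = gap, rescued = rescued)
}

#' Screen one protein for dual Sec/Tat targeting
#'
#' Applies the combined filters to a topology model and its RR motifs:
#' counting the transmembrane helices strictly N-terminal of the motif and
#' those starting after it, requiring exactly one helix after the motif,
#' and gating on orientation. The N-in class requires an even number
#' (>= 2 unless \code{allowZeroBefore}) of helices before the motif; the
#' N-out class an odd number (1, 3, 5 or 7). Motifs are evaluated in
#' ascending position; the first one satisfying either class wins (all
#' motifs are retained in the result). Motifs falling inside a helix span
#' are skipped — except within 2 residues of the helix N-terminus, where
#' scanned boundaries carry noise and the motif is taken to directly
#' precede that helix (gap 0). If no helix follows the motif and
#' \code{rescueWeakFinalTmd} is on, the scanner is re-queried for the best
#' sub-threshold window after the motif (within \code{maxGap}) before the
#' counts are re-checked.
#'
#' @param topology a \linkS4class{TopologyModel}.
#' @param motifs \link[IRanges]{IRanges} from [findRRMotifs()].
#' @param x optional sequence (needed for the rescue re-scan).
#' @param scale optional \linkS4class{HydrophobicityScale} (ditto).
#' @param params list from [screenParams()].
#' @return a \linkS4class{DualCandidate}; \code{cls = "none"} carries a
#'   reason code (\code{no-RR}, \code{tmd-count}, \code{orientation},
#'   \code{gap}).
#' @export
screenDual <- function(topology, motifs, x = NULL, scale = NULL,
                       params = screenParams()) {
    s <- if (is.null(x)) NULL else .asSeqString(x)
    none <- function(reason) new("DualCandidate",
        proteinId = topology@proteinId, cls = "none",
        rrPos = NA_integer_, nTmdBefore = 0L, nTmdAfter = 0L,
        finalTmd = IRanges(), gap = NA_integer_,
        nInScore = topology@nInScore, reason = reason,
        motifs = motifs, rescued = FALSE)
    if (length(motifs) == 0L)
        return(none("no-RR"))
    motifs <- motifs[order(start(motifs))]
    firstReason <- NULL
    for (k in seq_along(motifs)) {
        pos <- start(motifs)[k]
        ev <- .evalMotif(pos, topology, s, scale, params)
        if (!is.null(ev$cls)) {
            return(new("DualCandidate",
                proteinId = topology@proteinId, cls = ev$cls,
                rrPos = as.integer(pos),
                nTmdBefore = as.integer(ev$nBefore),
                nTmdAfter = as.integer(ev$nAfter),
                finalTmd = ev$final, gap = as.integer(ev$gap),
                nInScore = topology@nInScore, reason = "ok",
                motifs = motifs, rescued = ev$rescued))
        }
        if (is.null(firstReason) && ev$reason != "in-TMD")
            firstReason <- ev$reason
    }
    # every motif failed; report the first usable motif's reason
    none(if (is.null(firstReason)) "no-RR" else firstReason)
}
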