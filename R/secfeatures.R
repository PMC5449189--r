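#' @include AllClasses.R dualscreen.R
NULL

#' Cytoplasmic loop length between the penultimate helix and the RR motif
#'
#' Residues strictly between the end of the last transmembrane helix before
#' the motif and the first arginine:
#' \code{rr_pos - tmd_end - 1}. For the archetypal actinobacterial Rieske
#' protein (helix 2 ending at 117, twin arginines at 161-162) this is 43.
#'
#' @param candidate a classified \linkS4class{DualCandidate}.
#' @param topology the matching \linkS4class{TopologyModel}.
#' @return integer loop length (>= 0).
#' @export
loopLength <- function(candidate, topology) {
    if (is.na(candidate@rrPos))
        stop("candidate has no RR motif")
    seg <- topology@segments
    before <- which(end(seg) < candidate@rrPos)
    if (!length(before))
        stop("no transmembrane helix before the RR motif")
    as.integer(candidate@rrPos - max(end(seg)[before]) - 1L)
}

#' Count basic residues C-terminal of the final helix
#'
#' K+R count in the window \code{[end+1, min(end+windowLen, seq end)]}
#' after the final (Tat-dependent) helix — the "Sec-avoidance" charges.
#' Counting starts strictly after the helix end; the window is truncated at
#' the sequence end (an empty window counts 0).
#'
#' @param x sequence (as in [segmentDG()]).
#' @param finalTmd \link[IRanges]{IRanges} of length 1, the final helix.
#' @param windowLen window length in residues (default 20).
#' @return integer count.
#' @examples
#' ctermBasicCount(paste0(paste(rep("L", 21), collapse = ""), "GGKRGRKG"),
#'                 IRanges::IRanges(1, 21), windowLen = 8)
#' @export
ctermBasicCount <- function(x, finalTmd, windowLen = 20L) {
    s <- .asSeqString(x)
    stopifnot(length(finalTmd) == 1L)
    n <- nchar(s)
    from <- end(finalTmd) + 1L
    to <- min(end(finalTmd) + as.integer(windowLen), n)
    if (from > to)
        return(0L)
    sum(strsplit(substr(s, from, to), "")[[1L]] %in% c("K", "R"))
}

#' Leucine what-if substitutions in the final helix
#'
#' Ranks the in-span residues by decreasing centre contribution (i.e. least
#' hydrophobic first; ties broken by position), takes the top
#' \code{nSubs}, and reports the dG_app reduction obtained by substituting
#' each to leucine individually — plus, for \code{nSubs > 1}, all of them
#' combined. Deltas are \code{dg_wildtype - dg_variant} over the fixed
#' span, so a positive delta means insertion became more favourable.
#'
#' @param x sequence (as in [segmentDG()]).
#' @param finalTmd \link[IRanges]{IRanges} of length 1, the span to probe.
#' @param nSubs number of residues to substitute (1-3).
#' @param scale a \linkS4class{HydrophobicityScale}.
#' @return data.frame with columns \code{label}, \code{positions},
#'   \code{dg_wildtype}, \code{dg_variant}, \code{delta}.
#' @export
leucineWhatIf <- function(x, finalTmd, nSubs = 1L, scale) {
    s <- .asSeqString(x)
    stopifnot(length(finalTmd) == 1L)
    nSubs <- as.integer(nSubs)
    if (!nSubs %in% 1:3)
        stop("nSubs must be 1, 2 or 3")
    st <- start(finalTmd); en <- end(finalTmd)
    if (en - st + 1L < nSubs)
        stop("span shorter than the number of substitutions requested")
    residues <- strsplit(substr(s, st, en), "")[[1L]]
    dg0 <- scale@dg0[residues]
    ord <- order(-dg0, seq_along(residues))
    picks <- ord[seq_len(nSubs)]
    posns <- st + picks - 1L
    one <- function(positions) {
        subs <- data.frame(wt = residues[positions - st + 1L],
                           pos = positions, new = "L",
                           stringsAsFactors = FALSE)
        v <- variantDG(s, subs, st, en, scale, rescan = FALSE)
        data.frame(label = paste0(subs$wt, subs$pos, "L", collapse = ","),
                   positions = paste(positions, collapse = ","),
                   dg_wildtype = v$dg_wildtype,
                   dg_variant = v$dg_variant,
                   delta = v$delta, stringsAsFactors = FALSE)
    }
    rows <- lapply(sort(posns), one)
    if (nSubs > 1L)
        rows[[length(rows) + 1L]] <- one(sort(posns))
    do.call(rbind, rows)
}

#' Assemble the Sec-release feature report for a candidate
#'
#' Collects the features proposed to drive release of the final helix from
#' the Sec translocon: its dG_app and the raw difference to the first
#' helix's dG_app, the C-terminal K/R count, and the loop length between
#' the penultimate helix and the motif. Flags: \code{weak_final_tmd} when
#' the final helix has positive dG_app; \code{sec_avoidance} when the
#' C-terminal window holds at least 2 basic residues; \code{short_loop}
#' when the loop is shorter than \code{minLoop} (default 8, the approximate
#' minimum for Tat recognition of a tethered signal; a flag only, never a
#' filter).
#'
#' @param candidate a classified \linkS4class{DualCandidate}.
#' @param topology the matching \linkS4class{TopologyModel}.
#' @param x sequence (as in [segmentDG()]).
#' @param scale a \linkS4class{HydrophobicityScale}.
#' @param minLoop short-loop flag threshold (residues).
#' @param windowLen C-terminal counting window (residues).
#' @return a \linkS4class{SecReleaseReport}.
#' @export
secReleaseReport <- function(candidate, topology, x, scale,
                             minLoop = 8L, windowLen = 20L) {
    if (candidate@cls == "none")
        stop("cannot build a Sec-release report for an unclassified protein")
    s <- .asSeqString(x)
    final <- candidate@finalTmd
    finalDg <- dgApp(final)
    seg <- topology@segments
    if (!length(seg))
        stop("topology has no segments")
    firstDg <- mcols(seg)$dg_app[1L]
    if (is.null(firstDg) || is.na(firstDg))
        firstDg <- dgApp(segmentDG(s, start(seg)[1L], end(seg)[1L], scale))
    ll <- loopLength(candidate, topology)
    n <- nchar(s)
    cw <- c(min(end(final) + 1L, n),
            min(end(final) + as.integer(windowLen), n))
    cb <- ctermBasicCount(s, final, windowLen)
    flags <- c(weak_final_tmd = finalDg > 0,
               sec_avoidance = cb >= 2L,
               short_loop = ll < as.integer(minLoop))
    new("SecReleaseReport",
        proteinId = candidate@proteinId,
        finalTmdDg = finalDg, firstTmdDg = firstDg,
        dgGap = round(finalDg - firstDg, 3L),
        ctermBasicCount = as.integer(cb),
        ctermWindow = as.integer(cw),
        loopLen = ll, flags = flags)
}
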