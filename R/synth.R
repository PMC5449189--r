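#' @include AllClasses.R dgscale.R topology.R
NULL

.HYDRO_ALPHA <- c("L", "I", "V", "F", "A", "M")
.WIDE_ALPHA <- c("L", "I", "V", "F", "A", "M", "G", "S", "T", "C",
                 "W", "Y", "N", "Q", "P")
.POLAR_ALPHA <- c("S", "T", "N", "Q", "G", "P", "D", "E")

#' Construct a SyntheticSpec
#'
#' Defaults emulate the archetypal dual-targeted architecture: a 3-helix
#' protein whose two Sec-dependent helices target dG_app -2.0 kcal/mol, a
#' weakly hydrophobic final helix at +0.5 kcal/mol, a twin-arginine motif
#' 43 residues after the penultimate helix and 6 residues before the final
#' helix, and 5 K/R charges per cytoplasmic loop (enough for the
#' pseudocounted charge-bias score to clear the 0.9 N-in threshold).
#'
#' @param seed integer RNG seed (recorded in the FASTA header).
#' @param nTmd number of helices.
#' @param tmdTargetDg per-helix dG_app targets (kcal/mol), met to +/- 0.2.
#' @param tmdLen helix length(s) in residues: a single value recycled to
#'   all helices (default 21) or one length per helix.
#' @param loopLens optional explicit lengths for the nTmd+1 loops.
#' @param insideKrPerLoop,outsideKrPerLoop K/R per loop on each side.
#' @param rr place a twin-arginine motif (default TRUE).
#' @param rrBeforeTmd helix index the motif precedes (default the last).
#' @param rrGap residues between the second arginine and that helix
#'   (>= 4; the motif context needs the room).
#' @param rrLoopLen residues between the preceding helix and the first
#'   arginine.
#' @param ctermKr K/R charges placed within 20 residues after the final
#'   helix (the Sec-avoidance stretch).
#' @param orientation ground-truth orientation.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(seed, nTmd = 3L,
                          tmdTargetDg = c(-2, -2, 0.5),
                          tmdLen = 21L, loopLens = NULL,
                          insideKrPerLoop = 5L, outsideKrPerLoop = 0L,
                          rr = TRUE, rrBeforeTmd = nTmd, rrGap = 6L,
                          rrLoopLen = 43L, ctermKr = 0L,
                          orientation = "N-in") {
    nTmd <- as.integer(nTmd)
    tmdLen <- as.integer(tmdLen)
    if (length(tmdLen) == 1L)
        tmdLen <- rep(tmdLen, max(nTmd, 1L))
    if (nTmd > 0L && length(tmdLen) != nTmd)
        stop("tmdLen must be a single length or one per helix")
    if (is.null(loopLens)) {
        loopLens <- if (nTmd == 0L) 60L
                    else c(25L, rep(20L, max(nTmd - 1L, 0L)), 40L)
    }
    new("SyntheticSpec", seed = as.integer(seed), nTmd = nTmd,
        tmdTargetDg = as.numeric(tmdTargetDg), tmdLen = tmdLen,
        loopLens = as.integer(loopLens),
        insideKrPerLoop = as.integer(insideKrPerLoop),
        outsideKrPerLoop = as.integer(outsideKrPerLoop),
        rr = isTRUE(rr), rrBeforeTmd = as.integer(rrBeforeTmd),
        rrGap = as.integer(rrGap), rrLoopLen = as.integer(rrLoopLen),
        ctermKr = as.integer(ctermKr), orientation = orientation)
}

# Stochastic local search: swap single residues of a hydrophobic seed
# string until the helix dG_app is within tolerance of the target.
.buildTmd <- function(target, len, scale, index, tol = 0.2,
                      maxIter = 5000L) {
    M <- .contribMatrix(len, scale)
    lc <- .lengthCorrection(len, scale)
    alphabet <- rownames(M)
    res <- sample(.HYDRO_ALPHA, len, replace = TRUE)
    idx <- match(res, alphabet)
    cur <- sum(M[cbind(idx, seq_len(len))]) + lc
    for (it in seq_len(maxIter)) {
        if (abs(cur - target) <= tol * 0.6)
            break
        j <- sample.int(len, 1L)
        a <- match(sample(.WIDE_ALPHA, 1L), alphabet)
        nd <- cur - M[idx[j], j] + M[a, j]
        # accept improvements, plus occasional sideways moves to escape
        # single-swap dead ends
        if (abs(nd - target) < abs(cur - target) ||
            (it %% 97L == 0L && abs(nd - target) <= abs(cur - target) + 0.1)) {
            idx[j] <- a
            cur <- nd
        }
    }
    if (abs(cur - target) > tol)
        stop("synthetic TMD ", index, ": target dG_app ", target,
             " not reached (got ", round(cur, 3L), ")")
    alphabet[idx]
}

# Loop of polar residues with nKr K/R charges at (near-)evenly spaced
# positions restricted to [from, to]; adjacent R-R pairs are broken with K.
.buildLoop <- function(len, nKr, from = 1L, to = len) {
    res <- sample(.POLAR_ALPHA, len, replace = TRUE)
    if (nKr > 0L && len > 0L) {
        to <- min(to, len)
        span <- to - from + 1L
        if (span < 2L * nKr - 1L)
            stop("loop too short to place ", nKr, " separated charges")
        at <- from + round(seq(0L, span - 1L, length.out = nKr))
        res[at] <- sample(c("K", "R"), nKr, replace = TRUE)
        run <- which(res[-len] == "R" & res[-1L] == "R")
        if (length(run))
            res[run + 1L] <- "K"
    }
    res
}

#' Generate a synthetic protein with known architecture
#'
#' Builds a protein matching a \linkS4class{SyntheticSpec}: helices are
#' constructed by stochastic local search on random hydrophobic strings
#' until each measured dG_app is within 0.2 kcal/mol of its target; loops
#' are drawn from a polar alphabet with K/R charges placed on the
#' cytoplasmic or extracytoplasmic side as dictated by the ground-truth
#' orientation; when requested, the twin-arginine motif (context
#' \code{S-R-R-G-F-L-K}) is inserted \code{rrGap} residues before its
#' helix. Everything is reproducible from \code{spec@seed}, which is
#' recorded in the FASTA description. Accidental RR pairs outside the
#' intended motif are broken during assembly.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param scale a \linkS4class{HydrophobicityScale}.
#' @param id record identifier (default derived from the seed).
#' @return list with \code{record} (named single-record
#'   \link[Biostrings]{AAStringSet}) and \code{truth} (list: \code{segments}
#'   with measured \code{dg_app}, \code{rrPos}, \code{orientation},
#'   \code{firstLoop}, \code{nInProb}).
#' @examples
#' fx <- makeProtein(syntheticSpec(seed = 1), defaultScale())
#' fx$truth$rrPos
#' @export
makeProtein <- function(spec, scale, id = NULL) {
    validObject(spec)
    set.seed(spec@seed)
    if (is.null(id))
        id <- paste0("synth", spec@seed)
    nT <- spec@nTmd
    # which loops are cytoplasmic: even-parity loops iff N-in
    insideParity <- if (spec@orientation == "N-in") 0L else 1L
    loopLens <- spec@loopLens
    if (length(loopLens) != nT + 1L)
        stop("need ", nT + 1L, " loop lengths")
    parts <- character()
    segStart <- integer(nT)
    segEnd <- integer(nT)
    rrPos <- NA_integer_
    at <- 0L
    for (k in seq_len(nT + 1L)) {
        isRrLoop <- spec@rr && nT > 0L && k == spec@rrBeforeTmd
        nKr <- if ((k - 1L) %% 2L == insideParity) spec@insideKrPerLoop
               else spec@outsideKrPerLoop
        if (isRrLoop) {
            # [filler][S][RR][G F L K + filler], gap counted after the 2nd R
            fillerLen <- spec@rrLoopLen - 1L
            # short RR loops cannot hold the full charge allocation
            filler <- .buildLoop(fillerLen, min(nKr, (fillerLen + 1L) %/% 2L))
            tailCtx <- c("G", "F", "L", "K")
            gapFill <- sample(.POLAR_ALPHA, spec@rrGap - 4L, replace = TRUE)
            loop <- c(filler, "S", "R", "R", tailCtx, gapFill)
            rrPos <- at + fillerLen + 2L
        } else if (k == nT + 1L && spec@ctermKr > 0L) {
            # Sec-avoidance charges confined to the 20 residues after the
            # final helix; side charges would confound them, so none here
            loop <- .buildLoop(loopLens[k], spec@ctermKr,
                               from = 2L, to = 20L)
        } else {
            loop <- .buildLoop(loopLens[k], nKr)
        }
        parts <- c(parts, paste(loop, collapse = ""))
        at <- at + length(loop)
        if (k <= nT) {
            len_k <- spec@tmdLen[min(k, length(spec@tmdLen))]
            tmd <- .buildTmd(spec@tmdTargetDg[k], len_k, scale, k)
            segStart[k] <- at + 1L
            segEnd[k] <- at + len_k
            parts <- c(parts, paste(tmd, collapse = ""))
            at <- at + len_k
        }
    }
    s <- paste(parts, collapse = "")
    # break any accidental RR outside the intended motif (loops only; the
    # helix alphabet has no R)
    res <- strsplit(s, "")[[1L]]
    acc <- which(res[-length(res)] == "R" & res[-1L] == "R")
    acc <- setdiff(acc, rrPos)
    if (length(acc)) {
        res[acc + 1L] <- "K"
        s <- paste(res, collapse = "")
    }
    seg <- IRanges(start = segStart[seq_len(nT)],
                   end = segEnd[seq_len(nT)])
    if (nT > 0L) {
        dg <- vapply(seq_len(nT), function(k)
            dgApp(segmentDG(s, segStart[k], segEnd[k], scale)),
            numeric(1L))
        off <- abs(dg - spec@tmdTargetDg)
        if (any(off > 0.2))
            stop("synthetic TMD ", which.max(off),
                 ": measured dG_app off target by ",
                 round(max(off), 3L))
        mcols(seg) <- DataFrame(dg_app = dg)
    }
    record <- Biostrings::AAStringSet(s)
    names(record) <- id
    mcols(record) <- DataFrame(description = sprintf(
        "synthetic seed=%d nTmd=%d orientation=%s", spec@seed, nT,
        spec@orientation))
    firstLoop <- if (spec@orientation == "N-in") "inside" else "outside"
    list(record = record,
         truth = list(segments = seg, rrPos = rrPos,
                      orientation = spec@orientation,
                      firstLoop = firstLoop,
                      nInProb = if (spec@orientation == "N-in") 0.95
                                else 0.10))
}

#' Convert generator ground truth to an ImportedTopology
#'
#' Packages a fixture's ground truth the way an external topology
#' predictor's output would arrive, so importer-dependent code paths can be
#' exercised without external tools.
#'
#' @param truth the \code{truth} element returned by [makeProtein()].
#' @param id protein identifier.
#' @return an \linkS4class{ImportedTopology}.
#' @export
truthAsImported <- function(truth, id) {
    new("ImportedTopology", proteinId = id,
        nHelices = length(truth$segments),
        segments = IRanges(start(truth$segments), end(truth$segments)),
        firstLoop = truth$firstLoop,
        nInProb = truth$nInProb)
}

# Encode a topology as the short-format string "i10-32o..."
.encodeTopologyString <- function(segments, firstLoop) {
    side <- if (firstLoop == "inside") "i" else "o"
    out <- side
    for (k in seq_along(segments)) {
        side <- if (side == "i") "o" else "i"
        out <- paste0(out, start(segments)[k], "-", end(segments)[k], side)
    }
    out
}

#' Write fixtures' ground truth as a TMHMM-style short-format file
#'
#' One line per fixture with \code{PredHel=}, \code{Topology=} and
#' \code{Nin=} fields, mimicking an external prediction import for
#' round-trip and importer tests.
#'
#' @param fixtures list of [makeProtein()] results.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTmhmmShort <- function(fixtures, path) {
    lines <- vapply(fixtures, function(fx) {
        id <- names(fx$record)[1L]
        tr <- fx$truth
        sprintf("%s len=%d PredHel=%d Topology=%s Nin=%.2f", id,
                Biostrings::width(fx$record)[1L], length(tr$segments),
                .encodeTopologyString(tr$segments, tr$firstLoop),
                tr$nInProb)
    }, character(1L))
    writeLines(lines, path)
    invisible(path)
}

.ARCHITECTURES <- list(
    "2+1" = function(seed) syntheticSpec(seed),
    "4+1" = function(seed) syntheticSpec(seed, nTmd = 5L,
        tmdTargetDg = c(-2, -2, -2, -2, 0.5)),
    "3+1-out" = function(seed) syntheticSpec(seed, nTmd = 4L,
        tmdTargetDg = c(-2, -2, -2, 0.5), orientation = "N-out"),
    "neg-no-rr" = function(seed) syntheticSpec(seed, rr = FALSE),
    "neg-two-after" = function(seed) syntheticSpec(seed, nTmd = 4L,
        tmdTargetDg = c(-2, -2, -2, -2), rrBeforeTmd = 3L),
    # the four dual-targeted families, with their C-terminal Sec-avoidance
    # charge stretches
    "rieske" = function(seed) syntheticSpec(seed, ctermKr = 4L),
    "moco" = function(seed) syntheticSpec(seed, nTmd = 5L,
        tmdTargetDg = c(-2, -2, -2, -2, 0.5), ctermKr = 3L),
    "pfd" = function(seed) syntheticSpec(seed, nTmd = 5L,
        tmdTargetDg = c(-2, -2, -2, -2, 0.5), rrLoopLen = 12L,
        ctermKr = 3L),
    "ykue" = function(seed) syntheticSpec(seed, nTmd = 4L,
        tmdTargetDg = c(-2, -2, -2, 0.5), orientation = "N-out",
        ctermKr = 3L)
)

#' Generate a set of fixtures across architectures
#'
#' Architectures: \code{"2+1"}, \code{"4+1"} (N-in, even helices before the
#' motif), \code{"3+1-out"} (N-out, odd), negatives \code{"neg-no-rr"} and
#' \code{"neg-two-after"}, and the four dual-targeted family emulations
#' \code{"rieske"}, \code{"moco"}, \code{"pfd"}, \code{"ykue"} (which add
#' C-terminal Sec-avoidance charges).
#'
#' @param architectures character vector of architecture names.
#' @param nPer fixtures per architecture.
#' @param seedStart first seed; fixture i uses \code{seedStart + i - 1}.
#' @param scale a \linkS4class{HydrophobicityScale}.
#' @return list of fixtures, each a [makeProtein()] result plus
#'   \code{$arch}.
#' @export
makeFixtureSet <- function(architectures = c("2+1", "4+1", "3+1-out"),
                           nPer = 5L, seedStart = 1L,
                           scale = defaultScale()) {
    unknown <- setdiff(architectures, names(.ARCHITECTURES))
    if (length(unknown))
        stop("unknown architecture(s): ", paste(unknown, collapse = ", "))
    out <- list()
    seed <- as.integer(seedStart)
    for (arch in architectures) {
        for (i in seq_len(nPer)) {
            spec <- .ARCHITECTURES[[arch]](seed)
            fx <- makeProtein(spec, scale,
                              id = sprintf("synth_%s_s%d",
                                           gsub("[^0-9A-Za-z]", "", arch),
                                           seed))
            fx$arch <- arch
            out[[length(out) + 1L]] <- fx
            seed <- seed + 1L
        }
    }
    out
}

#' Synthetic stand-in for the actinobacterial Rieske exemplar
#'
#' A generated protein reproducing the documented coordinate architecture
#' of the Streptomyces coelicolor Rieske protein Sco2149 — helices at
#' 58-80, 96-117 and 168-187, twin arginines at 161-162 (43 residues after
#' the second helix, 5 before the third), and four basic residues in the
#' 20 residues following the final helix — with helix dG_app targets
#' matching the published predictions for that protein (-2.374, -0.117,
#' +0.614 kcal/mol, met to +/- 0.2). The sequence itself is synthetic: it
#' is a coordinate- and architecture-faithful stand-in for tests and
#' examples, not the real protein, and must not be used to reproduce
#' published per-residue values.
#'
#' @param scale a \linkS4class{HydrophobicityScale}.
#' @param seed RNG seed (default 2149).
#' @return a [makeProtein()] result (list with \code{record},
#'   \code{truth}).
#' @export
syntheticRieskeFixture <- function(scale = defaultScale(), seed = 2149L) {
    spec <- syntheticSpec(seed,
                          nTmd = 3L,
                          tmdTargetDg = c(-2.374, -0.117, 0.614),
                          tmdLen = c(23L, 22L, 20L),
                          loopLens = c(57L, 15L, 50L, 30L),
                          rrGap = 5L, rrLoopLen = 43L, ctermKr = 4L,
                          orientation = "N-in")
    makeProtein(spec, scale, id = "synthetic-Sco2149-like")
}
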