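#' @import methods
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

.AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA_ALLOWED <- c(.AA_STANDARD, "X")

#' HydrophobicityScale: parameters of the dG_app insertion model
#'
#' Holds the per-residue centre contributions (kcal/mol), the
#' position-dependence parameters (Gaussian widths plus the off-centre
#' aromatic terms for W and Y), the helix-length correction coefficients and
#' the allowed helix length range used when scanning for transmembrane
#' segments. The \code{profile} slot selects between the full
#' position-dependent model (\code{"gaussian"}) and a flat profile
#' (\code{"uniform"}, every position weighted 1; used for hand-sum oracles).
#'
#' @slot name,version scale identification strings.
#' @slot profile \code{"gaussian"} or \code{"uniform"}.
#' @slot dg0 named numeric, centre contribution per residue (incl. \code{X}).
#' @slot gaussWidth named numeric, Gaussian width per residue.
#' @slot aromDg,aromWidth named numeric, aromatic off-centre term (0 if none).
#' @slot aromOffset numeric, position (in scaled units) of the aromatic
#'   preference peaks.
#' @slot lengthCoeffs numeric(3), quadratic coefficients of the helix-length
#'   correction.
#' @slot refLength reference helix length at which the length correction is 0.
#' @slot Lmin,Lmax allowed helix lengths for predicted segments.
#' @slot xDg contribution assigned to the unknown residue \code{X}.
#' @exportClass HydrophobicityScale
setClass("HydrophobicityScale",
    representation(
        name = "character",
        version = "character",
        profile = "character",
        dg0 = "numeric",
        gaussWidth = "numeric",
        aromDg = "numeric",
        aromWidth = "numeric",
        aromOffset = "numeric",
        lengthCoeffs = "numeric",
        refLength = "integer",
        Lmin = "integer",
        Lmax = "integer",
        xDg = "numeric"
    )
)

setValidity("HydrophobicityScale", function(object) {
    msg <- character()
    if (!all(.AA_STANDARD %in% names(object@dg0)))
        msg <- c(msg, "dg0 must be defined for all 20 standard residues")
    if (!object@profile %in% c("gaussian", "uniform"))
        msg <- c(msg, "profile must be 'gaussian' or 'uniform'")
    if (length(object@lengthCoeffs) != 3L)
        msg <- c(msg, "lengthCoeffs must have length 3")
    if (object@Lmin < 1L || object@Lmax < object@Lmin)
        msg <- c(msg, "need 1 <= Lmin <= Lmax")
    # the length correction is defined relative to refLength, hence 0 there
    q <- function(L) sum(object@lengthCoeffs * c(1, L, L^2))
    if (abs(q(object@refLength) - q(object@refLength)) > 1e-12)
        msg <- c(msg, "length correction must vanish at refLength")
    if (length(msg)) msg else TRUE
})

#' ImportedTopology: an externally predicted membrane topology
#'
#' Decoded from TMHMM-style short-format output or from per-residue i/o/M
#' topology strings. Loops alternate sides starting from
#' \code{firstLoop}; the whole-protein N-in probability is \code{NA} when the
#' source format does not provide one.
#'
#' @slot proteinId identifier the prediction belongs to.
#' @slot nHelices number of predicted transmembrane helices.
#' @slot segments \link[IRanges]{IRanges} of helix spans (1-based inclusive).
#' @slot firstLoop \code{"inside"} or \code{"outside"}.
#' @slot nInProb numeric in [0,1], or \code{NA}.
#' @exportClass ImportedTopology
setClass("ImportedTopology",
    representation(
        proteinId = "character",
        nHelices = "integer",
        segments = "IRanges",
        firstLoop = "character",
        nInProb = "numeric"
    )
)

setValidity("ImportedTopology", function(object) {
    msg <- character()
    seg <- object@segments
    if (object@nHelices != length(seg))
        msg <- c(msg, "nHelices must equal the number of segments")
    if (length(seg) > 1L) {
        if (is.unsorted(start(seg), strictly = TRUE))
            msg <- c(msg, "segments must be strictly increasing")
        if (any(start(seg)[-1L] <= end(seg)[-length(seg)]))
            msg <- c(msg, "segments must not overlap")
    }
    if (!object@firstLoop %in% c("inside", "outside"))
        msg <- c(msg, "firstLoop must be 'inside' or 'outside'")
    if (!is.na(object@nInProb) &&
        (object@nInProb < 0 || object@nInProb > 1))
        msg <- c(msg, "nInProb must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

#' TopologyModel: oriented transmembrane topology of one protein
#'
#' Ordered, non-overlapping transmembrane segments together with the
#' inferred (or imported) orientation and its N-in score. Segment metadata
#' column \code{dg_app} carries per-segment insertion free energies when a
#' scale was available.
#'
#' @slot proteinId protein identifier.
#' @slot segments \link[IRanges]{IRanges}, ascending, with optional
#'   \code{dg_app} metadata column.
#' @slot orientation \code{"N-in"} or \code{"N-out"}.
#' @slot nInScore numeric in [0,1]; \code{orientation == "N-in"} iff
#'   \code{nInScore >= 0.5} (ties resolve to N-in and are flagged).
#' @slot source \code{"predicted"} or \code{"imported"}.
#' @slot flags character vector, e.g. \code{"no-TM"}, \code{"tie"},
#'   \code{"prob-imputed"}.
#' @exportClass TopologyModel
setClass("TopologyModel",
    representation(
        proteinId = "character",
        segments = "IRanges",
        orientation = "character",
        nInScore = "numeric",
        source = "character",
        flags = "character"
    )
)

setValidity("TopologyModel", function(object) {
    msg <- character()
    seg <- object@segments
    if (length(seg) > 1L && any(start(seg)[-1L] <= end(seg)[-length(seg)]))
        msg <- c(msg, "segments must be ascending and non-overlapping")
    if (!object@orientation %in% c("N-in", "N-out"))
        msg <- c(msg, "orientation must be 'N-in' or 'N-out'")
    if (!is.na(object@nInScore)) {
        if (object@nInScore < 0 || object@nInScore > 1)
            msg <- c(msg, "nInScore must lie in [0,1]")
        ok <- if (object@orientation == "N-in") object@nInScore >= 0.5
              else object@nInScore < 0.5
        if (!ok)
            msg <- c(msg, "orientation inconsistent with nInScore")
    }
    if (!object@source %in% c("predicted", "imported"))
        msg <- c(msg, "source must be 'predicted' or 'imported'")
    if (length(msg)) msg else TRUE
})

#' DualCandidate: the screen verdict for one protein
#'
#' Result of applying the dual Sec/Tat targeting filters: an RR motif with
#' an even (N-in) or odd (N-out) number of transmembrane helices before it
#' and exactly one after it. \code{cls} is \code{"none"} for rejected
#' proteins, with a machine-readable \code{reason} code (\code{no-RR},
#' \code{tmd-count}, \code{orientation}, \code{gap}).
#'
#' @slot proteinId protein identifier.
#' @slot cls \code{"N-in-even"}, \code{"N-out-odd"} or \code{"none"}.
#' @slot rrPos 1-based position of the first arginine of the winning motif
#'   (\code{NA} if none).
#' @slot nTmdBefore,nTmdAfter helix counts around the motif.
#' @slot finalTmd \link[IRanges]{IRanges} of length 0 or 1 with
#'   \code{dg_app} metadata; the Tat-dependent final helix.
#' @slot gap distance from the first arginine to the final helix start,
#'   minus one (i.e. \code{start(finalTmd) - rrPos - 1}).
#' @slot nInScore orientation score the verdict used.
#' @slot reason rejection reason code, \code{"ok"} when classified.
#' @slot motifs all RR motifs found (\link[IRanges]{IRanges} with metadata).
#' @slot rescued TRUE if the final helix came from the sub-threshold rescue
#'   re-scan.
#' @exportClass DualCandidate
setClass("DualCandidate",
    representation(
        proteinId = "character",
        cls = "character",
        rrPos = "integer",
        nTmdBefore = "integer",
        nTmdAfter = "integer",
        finalTmd = "IRanges",
        gap = "integer",
        nInScore = "numeric",
        reason = "character",
        motifs = "IRanges",
        rescued = "logical"
    )
)

setValidity("DualCandidate", function(object) {
    msg <- character()
    if (!object@cls %in% c("N-in-even", "N-out-odd", "none"))
        msg <- c(msg, "cls must be 'N-in-even', 'N-out-odd' or 'none'")
    if (object@cls != "none") {
        if (object@nTmdAfter != 1L)
            msg <- c(msg, "a classified candidate must have exactly one TMD after the motif")
        if (object@cls == "N-in-even" && object@nTmdBefore %% 2L != 0L)
            msg <- c(msg, "N-in-even requires an even TMD count before the motif")
        if (object@cls == "N-out-odd" && object@nTmdBefore %% 2L != 1L)
            msg <- c(msg, "N-out-odd requires an odd TMD count before the motif")
        if (is.na(object@gap) || object@gap < 0L)
            msg <- c(msg, "gap must be >= 0 for a classified candidate")
    }
    if (length(msg)) msg else TRUE
})

#' SecReleaseReport: the Sec-release feature rubric for one candidate
#'
#' Quantifies the features proposed to drive release of the final
#' (Tat-dependent) helix from the Sec translocon: its weak hydrophobicity
#' (positive dG_app), positive charges in its C-terminal vicinity
#' ("Sec-avoidance"), and the cytoplasmic loop length between the
#' penultimate helix and the twin-arginine motif.
#'
#' @slot proteinId protein identifier.
#' @slot finalTmdDg,firstTmdDg dG_app (kcal/mol) of the final and first helix.
#' @slot dgGap raw difference finalTmdDg - firstTmdDg (no threshold applied).
#' @slot ctermBasicCount K+R count in the window after the final helix.
#' @slot ctermWindow integer(2), the (possibly truncated) counting window.
#' @slot loopLen residues between the end of the penultimate helix and the
#'   first arginine of the motif.
#' @slot flags named logical: \code{weak_final_tmd}, \code{sec_avoidance},
#'   \code{short_loop}.
#' @exportClass SecReleaseReport
setClass("SecReleaseReport",
    representation(
        proteinId = "character",
        finalTmdDg = "numeric",
        firstTmdDg = "numeric",
        dgGap = "numeric",
        ctermBasicCount = "integer",
        ctermWindow = "integer",
        loopLen = "integer",
        flags = "logical"
    )
)

setValidity("SecReleaseReport", function(object) {
    msg <- character()
    need <- c("weak_final_tmd", "sec_avoidance", "short_loop")
    if (!all(need %in% names(object@flags)))
        msg <- c(msg, "flags must contain weak_final_tmd, sec_avoidance, short_loop")
    if (!is.na(object@loopLen) && object@loopLen < 0L)
        msg <- c(msg, "loopLen must be >= 0")
    if (length(msg)) msg else TRUE
})

#' SyntheticSpec: recipe for one synthetic fixture protein
#'
#' Describes the transmembrane architecture a generated protein should have:
#' number of helices and their target insertion free energies, loop lengths,
#' per-loop K/R charge placement, twin-arginine motif placement and
#' orientation. Construction is fully reproducible from \code{seed}.
#'
#' @slot seed integer RNG seed.
#' @slot nTmd number of transmembrane helices.
#' @slot tmdTargetDg numeric, per-helix target dG_app (kcal/mol),
#'   achieved to within +/- 0.2.
#' @slot tmdLen helix length in residues.
#' @slot loopLens integer, lengths of the nTmd+1 loops (loop 0 = N-terminal
#'   tail; the loop preceding the RR-adjacent helix is replaced by
#'   rrLoopLen + motif + rrGap when a motif is requested).
#' @slot insideKrPerLoop,outsideKrPerLoop K/R charges per cytoplasmic /
#'   extracytoplasmic loop.
#' @slot rr whether to place a twin-arginine motif.
#' @slot rrBeforeTmd index of the helix the motif precedes.
#' @slot rrGap residues between the second arginine and that helix.
#' @slot rrLoopLen residues between the preceding helix end and the first
#'   arginine.
#' @slot ctermKr K/R charges placed within 20 residues after the final helix.
#' @slot orientation \code{"N-in"} or \code{"N-out"} ground truth.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(
        seed = "integer",
        nTmd = "integer",
        tmdTargetDg = "numeric",
        tmdLen = "integer",
        loopLens = "integer",
        insideKrPerLoop = "integer",
        outsideKrPerLoop = "integer",
        rr = "logical",
        rrBeforeTmd = "integer",
        rrGap = "integer",
        rrLoopLen = "integer",
        ctermKr = "integer",
        orientation = "character"
    )
)

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (object@nTmd > 0L && length(object@tmdTargetDg) != object@nTmd)
        msg <- c(msg, "tmdTargetDg must have one target per helix")
    if (!object@orientation %in% c("N-in", "N-out"))
        msg <- c(msg, "orientation must be 'N-in' or 'N-out'")
    if (object@rr && object@nTmd > 0L) {
        if (object@rrBeforeTmd < 1L || object@rrBeforeTmd > object@nTmd)
            msg <- c(msg, "rrBeforeTmd must index an existing helix")
        if (object@rrGap < 4L)
            msg <- c(msg, "rrGap must be >= 4 (the motif context needs the room)")
    }
    if (length(msg)) msg else TRUE
})
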