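#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("proteinId", "TopologyModel", function(x) x@proteinId)
#' @rdname accessors
#' @export
setMethod("proteinId", "ImportedTopology", function(x) x@proteinId)
#' @rdname accessors
#' @export
setMethod("proteinId", "DualCandidate", function(x) x@proteinId)
#' @rdname accessors
#' @export
setMethod("proteinId", "SecReleaseReport", function(x) x@proteinId)

#' @rdname accessors
#' @export
setMethod("tmSegments", "TopologyModel", function(x) x@segments)
#' @rdname accessors
#' @export
setMethod("tmSegments", "ImportedTopology", function(x) x@segments)

#' @rdname accessors
#' @export
setMethod("orientation", "TopologyModel", function(x) x@orientation)

#' @rdname accessors
#' @export
setMethod("nInScore", "TopologyModel", function(x) x@nInScore)
#' @rdname accessors
#' @export
setMethod("nInScore", "DualCandidate", function(x) x@nInScore)

#' @rdname accessors
#' @export
setMethod("topologySource", "TopologyModel", function(x) x@source)

#' @rdname accessors
#' @export
setMethod("classification", "DualCandidate", function(x) x@cls)

#' @rdname accessors
#' @export
setMethod("rrPosition", "DualCandidate", function(x) x@rrPos)

#' @rdname accessors
#' @export
setMethod("finalTmd", "DualCandidate", function(x) x@finalTmd)

#' @rdname accessors
#' @export
setMethod("reportFlags", "SecReleaseReport", function(x) x@flags)

#' @rdname accessors
#' @export
setMethod("rejectionReason", "DualCandidate", function(x) x@reason)

setMethod("show", "HydrophobicityScale", function(object) {
    cat("HydrophobicityScale '", object@name, "' v", object@version,
        " (profile: ", object@profile, ")\n", sep = "")
    cat("  helix lengths ", object@Lmin, "-", object@Lmax,
        ", reference length ", object@refLength, "\n", sep = "")
    rng <- range(object@dg0[.AA_STANDARD])
    cat(sprintf("  centre contributions: %.3f (most favourable) to %.3f kcal/mol\n",
                rng[1L], rng[2L]))
})

setMethod("show", "TopologyModel", function(object) {
    cat("TopologyModel for", object@proteinId, "\n")
    cat("  ", length(object@segments), " TM segment(s), ",
        object@orientation, " (n_in_score ",
        ifelse(is.na(object@nInScore), "NA",
               sprintf("%.3f", object@nInScore)),
        ", source ", object@source, ")\n", sep = "")
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "ImportedTopology", function(object) {
    cat("ImportedTopology for ", object@proteinId, ": ",
        object@nHelices, " helices, first loop ", object@firstLoop,
        ", N-in prob ",
        ifelse(is.na(object@nInProb), "absent",
               sprintf("%.3f", object@nInProb)), "\n", sep = "")
})

setMethod("show", "DualCandidate", function(object) {
    cat("DualCandidate ", object@proteinId, ": class ", object@cls, sep = "")
    if (object@cls == "none") {
        cat(" (reason: ", object@reason, ")\n", sep = "")
    } else {
        cat("\n  RR at ", object@rrPos, ", ", object@nTmdBefore,
            " TMD before / ", object@nTmdAfter, " after, gap ",
            object@gap, "\n", sep = "")
        if (length(object@finalTmd))
            cat(sprintf("  final TMD %d-%d, dG_app %.3f kcal/mol%s\n",
                        start(object@finalTmd), end(object@finalTmd),
                        dgApp(object@finalTmd),
                        if (object@rescued) " (rescued sub-threshold window)"
                        else ""))
    }
})

setMethod("show", "SecReleaseReport", function(object) {
    cat("SecReleaseReport for", object@proteinId, "\n")
    cat(sprintf("  final TMD dG_app %.3f, first TMD dG_app %.3f (gap %.3f) kcal/mol\n",
                object@finalTmdDg, object@firstTmdDg, object@dgGap))
    cat("  C-terminal K/R count ", object@ctermBasicCount,
        " in window ", object@ctermWindow[1L], "-", object@ctermWindow[2L],
        "; loop length ", object@loopLen, "\n", sep = "")
    on <- names(object@flags)[object@flags]
    cat("  flags set:", if (length(on)) paste(on, collapse = ", ")
        else "(none)", "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
    cat("SyntheticSpec: ", object@nTmd, " TMD, orientation ",
        object@orientation, ", seed ", object@seed, "\n", sep = "")
    if (object@rr)
        cat("  RR motif ", object@rrGap, " residues before TMD",
            object@rrBeforeTmd, "\n", sep = "")
})
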