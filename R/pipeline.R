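#' @include secfeatures.R synth.R
NULL

#' Run the full dual-targeting screen over a FASTA file or record set
#'
#' For each protein: scan for transmembrane segments ([scanSegments()]),
#' find RR motifs ([findRRMotifs()]), assemble the topology
#' ([buildTopology()]; imported predictions take precedence where
#' supplied), apply the screen ([screenDual()]) and, for classified
#' candidates, attach the Sec-release features ([secReleaseReport()]).
#'
#' @param input path to a protein FASTA file, or an
#'   \link[Biostrings]{AAStringSet}.
#' @param scale a \linkS4class{HydrophobicityScale}.
#' @param params list from [screenParams()].
#' @param imported optional list of \linkS4class{ImportedTopology} (e.g.
#'   from [readTmhmmShort()]); matched to records by protein id.
#' @param thresholdDg scanner threshold (kcal/mol, default 0).
#' @param motifMode,minScore passed to [findRRMotifs()].
#' @param minLoop,windowLen passed to [secReleaseReport()].
#' @param features attach feature columns (default TRUE).
#' @return data.frame, one row per protein, with columns id, class,
#'   n_before, n_after, rr_pos, gap, n_in_score, source,
#'   final_tmd_start/end/dg, rescued, reason and (optionally) the feature
#'   columns first_tmd_dg, dg_gap, loop_len, cterm_basic_count and the
#'   three flags.
#' @examples
#' fx <- makeProtein(syntheticSpec(seed = 1), defaultScale())
#' screenFasta(fx$record, defaultScale())
#' @export
screenFasta <- function(input, scale = defaultScale(),
                        params = screenParams(), imported = NULL,
                        thresholdDg = 0, motifMode = "rr-only",
                        minScore = 2L, minLoop = 8L, windowLen = 20L,
                        features = TRUE) {
    records <- if (is.character(input)) readProteinFasta(input) else input
    stopifnot(is(records, "AAStringSet"))
    if (!is.null(imported))
        names(imported) <- vapply(imported, proteinId, character(1L))
    rows <- lapply(seq_along(records), function(k) {
        id <- names(records)[k]
        s <- as.character(records[[k]])
        seg <- withCallingHandlers(
            scanSegments(s, scale, thresholdDg = thresholdDg),
            warning = function(w) invokeRestart("muffleWarning"))
        imp <- imported[[id]]
        topo <- buildTopology(s, segments = seg, imported = imp,
                              scale = scale, id = id)
        motifs <- findRRMotifs(s, mode = motifMode, minScore = minScore)
        cand <- screenDual(topo, motifs, x = s, scale = scale,
                           params = params)
        row <- data.frame(
            id = id, class = cand@cls,
            n_before = cand@nTmdBefore, n_after = cand@nTmdAfter,
            rr_pos = cand@rrPos, gap = cand@gap,
            n_in_score = round(cand@nInScore, 4L),
            source = topo@source,
            final_tmd_start = if (length(cand@finalTmd))
                start(cand@finalTmd) else NA_integer_,
            final_tmd_end = if (length(cand@finalTmd))
                end(cand@finalTmd) else NA_integer_,
            final_tmd_dg = if (length(cand@finalTmd))
                dgApp(cand@finalTmd) else NA_real_,
            rescued = cand@rescued, reason = cand@reason,
            stringsAsFactors = FALSE)
        if (features) {
            if (cand@cls != "none") {
                rep <- secReleaseReport(cand, topo, s, scale,
                                        minLoop = minLoop,
                                        windowLen = windowLen)
                row$first_tmd_dg <- rep@firstTmdDg
                row$dg_gap <- rep@dgGap
                row$loop_len <- rep@loopLen
                row$cterm_basic_count <- rep@ctermBasicCount
                row$weak_final_tmd <- rep@flags[["weak_final_tmd"]]
                row$sec_avoidance <- rep@flags[["sec_avoidance"]]
                row$short_loop <- rep@flags[["short_loop"]]
            } else {
                row$first_tmd_dg <- NA_real_
                row$dg_gap <- NA_real_
                row$loop_len <- NA_integer_
                row$cterm_basic_count <- NA_integer_
                row$weak_final_tmd <- NA
                row$sec_avoidance <- NA
                row$short_loop <- NA
            }
        }
        row
    })
    do.call(rbind, rows)
}

#' Summarise screen results by filter stage
#'
#' Counts proteins at each stage of the screen: input, RR-containing,
#' per-class counts and rejections by reason. Used by the command-line
#' front-end's logging.
#'
#' @param df data.frame from [screenFasta()].
#' @return named integer vector.
#' @export
screenCounts <- function(df) {
    rr <- sum(df$reason != "no-RR")
    c(input = nrow(df),
      with_rr = rr,
      `N-in-even` = sum(df$class == "N-in-even"),
      `N-out-odd` = sum(df$class == "N-out-odd"),
      rejected_no_rr = sum(df$reason == "no-RR"),
      rejected_tmd_count = sum(df$reason == "tmd-count"),
      rejected_orientation = sum(df$reason == "orientation"),
      rejected_gap = sum(df$reason == "gap"))
}
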