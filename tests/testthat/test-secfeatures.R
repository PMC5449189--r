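scale <- defaultScale()

test_that("loop length is the residue count between helix end and the first arginine", {
    topo <- makeTopo("rieske", starts = c(58L, 96L, 168L),
                     ends = c(80L, 117L, 187L), score = 0.95)
    cand <- screenDual(topo, makeMotifs(161L))
    expect_equal(loopLength(cand, topo), 43L)

    # motif immediately after the helix: zero-length loop
    topo2 <- makeTopo("p", starts = c(20L, 80L), ends = c(40L, 100L),
                      orientation = "N-out", score = 0.1)
    cand2 <- screenDual(topo2, makeMotifs(41L),
                        params = screenParams(maxGap = 40L))
    expect_equal(classification(cand2), "N-out-odd")
    expect_equal(loopLength(cand2, topo2), 0L)
})

test_that("loopLength refuses candidates without a helix before the motif", {
    topo <- makeTopo("p", starts = 60L, ends = 80L, score = 0.95)
    cand <- screenDual(topo, makeMotifs(20L),
                       params = screenParams(allowZeroBefore = TRUE,
                                             maxGap = 60L))
    expect_error(loopLength(cand, topo), "no transmembrane helix before")
})

test_that("C-terminal basic counting truncates at the sequence end", {
    s <- paste0(strrep("L", 21L), "GGKRGRKG")
    tm <- IRanges(1L, 21L)
    expect_equal(ctermBasicCount(s, tm, windowLen = 8L), 4L)
    expect_equal(ctermBasicCount(s, tm, windowLen = 3L), 1L)
    expect_equal(ctermBasicCount(paste0(strrep("L", 21L), "GGSTG"), tm), 0L)
    # helix ends at the last residue: empty window
    expect_equal(ctermBasicCount(strrep("L", 21L), tm), 0L)
})

test_that("C-terminal basic counting is monotone in the window length", {
    set.seed(43)
    for (i in 1:10) {
        s <- paste0(strrep("L", 21L), randomSeq(30L))
        counts <- vapply(c(1L, 5L, 10L, 20L, 30L), function(w)
            ctermBasicCount(s, IRanges(1L, 21L), windowLen = w),
            integer(1L))
        expect_true(all(diff(counts) >= 0L))
    }
})

test_that("leucine what-ifs report zero deltas on an all-leucine span", {
    s <- paste0("GG", strrep("L", 21L), "GG")
    out <- leucineWhatIf(s, IRanges(3L, 23L), nSubs = 3L, scale)
    expect_equal(out$delta, rep(0, 4L))  # 3 singles + combined
})

test_that("leucine what-ifs target the least hydrophobic residues and lower dG_app", {
    # aspartate at centre is the least hydrophobic in-span residue
    s <- paste0("GG", strrep("L", 10L), "D", strrep("L", 10L), "GG")
    out <- leucineWhatIf(s, IRanges(3L, 23L), nSubs = 1L, scale)
    expect_equal(out$label, "D13L")
    expect_gt(out$delta, 1.5)
    expect_error(leucineWhatIf("GGLLG", IRanges(3L, 4L), nSubs = 3L, scale),
                 "span shorter")
})

test_that("what-if deltas add up on a synthetic weak final helix", {
    fx <- syntheticRieskeFixture(scale)
    s <- as.character(fx$record[[1L]])
    tm3 <- fx$truth$segments[3L]
    out <- leucineWhatIf(s, IRanges(start(tm3), end(tm3)), nSubs = 2L,
                         scale)
    expect_equal(nrow(out), 3L)
    expect_true(all(out$delta >= 0))
    # the combined substitution is at least as strong as either single
    expect_gte(out$delta[3L], max(out$delta[1:2]) - 2e-3)
})

test_that("the report flags weak hydrophobicity, Sec avoidance and short loops", {
    fx <- syntheticRieskeFixture(scale)
    s <- as.character(fx$record[[1L]])
    id <- names(fx$record)
    topo <- buildTopology(s, imported = truthAsImported(fx$truth, id),
                          scale = scale, id = id)
    cand <- screenDual(topo, findRRMotifs(s), x = s, scale = scale)
    rep <- secReleaseReport(cand, topo, s, scale)
    expect_true(reportFlags(rep)[["weak_final_tmd"]])
    expect_true(reportFlags(rep)[["sec_avoidance"]])
    expect_false(reportFlags(rep)[["short_loop"]])
    expect_equal(rep@loopLen, 43L)
    expect_equal(rep@ctermBasicCount, 4L)
    expect_equal(rep@dgGap, round(rep@finalTmdDg - rep@firstTmdDg, 3L))
})

test_that("a hydrophobic final helix with an uncharged tail sets no flags", {
    spec <- syntheticSpec(seed = 91, tmdTargetDg = c(-2, -2, -2))
    fx <- makeProtein(spec, scale)
    s <- as.character(fx$record[[1L]])
    id <- names(fx$record)
    topo <- buildTopology(s, imported = truthAsImported(fx$truth, id),
                          scale = scale, id = id)
    cand <- screenDual(topo, findRRMotifs(s), x = s, scale = scale)
    rep <- secReleaseReport(cand, topo, s, scale)
    expect_false(any(reportFlags(rep)))
})

test_that("the short-loop flag switches exactly at the minimum loop length", {
    for (ll in c(7L, 8L)) {
        fx <- makeProtein(syntheticSpec(seed = 95L + ll, rrLoopLen = ll),
                          scale)
        s <- as.character(fx$record[[1L]])
        id <- names(fx$record)
        topo <- buildTopology(s, imported = truthAsImported(fx$truth, id),
                              scale = scale, id = id)
        cand <- screenDual(topo, findRRMotifs(s), x = s, scale = scale)
        rep <- secReleaseReport(cand, topo, s, scale)
        expect_equal(rep@loopLen, ll)
        expect_equal(reportFlags(rep)[["short_loop"]], ll < 8L)
    }
})

test_that("reported loop lengths are recomputable from reported coordinates", {
    fx <- makeFixtureSet(c("2+1", "4+1", "3+1-out"), nPer = 3L,
                         seedStart = 401L, scale = scale)
    recs <- do.call(c, lapply(fx, `[[`, "record"))
    imp <- lapply(fx, function(f) truthAsImported(f$truth,
                                                  names(f$record)[1L]))
    df <- screenFasta(recs, scale, imported = imp)
    for (k in seq_len(nrow(df))) {
        truth <- fx[[k]]$truth
        lastBefore <- max(end(truth$segments)[end(truth$segments) <
                                              df$rr_pos[k]])
        expect_equal(df$loop_len[k], df$rr_pos[k] - lastBefore - 1L)
        expect_equal(df$gap[k], df$final_tmd_start[k] - df$rr_pos[k] - 1L)
    }
})

test_that("feature flags concord across the four family architectures", {
    fams <- makeFixtureSet(c("rieske", "moco", "pfd", "ykue"), nPer = 2L,
                           seedStart = 501L, scale = scale)
    recs <- do.call(c, lapply(fams, `[[`, "record"))
    imp <- lapply(fams, function(f) truthAsImported(f$truth,
                                                    names(f$record)[1L]))
    df <- screenFasta(recs, scale, imported = imp)
    expect_true(all(df$class != "none"))
    expect_true(all(df$weak_final_tmd))
    expect_true(all(df$sec_avoidance))
})
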