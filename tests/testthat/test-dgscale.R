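scaleG <- defaultScale()
scaleU <- defaultScale("uniform")

test_that("uniform-profile spans equal the hand sum over the scale file", {
    polyL <- strrep("L", 21L)
    expect_equal(dgApp(segmentDG(polyL, 1, 21, scaleU,
                                 lengthCorrection = FALSE)),
                 round(21 * rawDg0[["L"]], 3L))
    set.seed(3)
    for (i in 1:20) {
        s <- randomSeq(sample(40:150, 1L))
        from <- sample(nchar(s) - 20L, 1L)
        to <- from + sample(5:19, 1L)
        expect_equal(dgApp(segmentDG(s, from, to, scaleU,
                                     lengthCorrection = FALSE)),
                     round(handSumUniform(s, from, to), 3L))
    }
})

test_that("the length correction vanishes at the reference length", {
    s <- strrep("A", 60L)
    for (L in c(19L, 21L, 23L)) {
        with_lc <- dgApp(segmentDG(s, 1, L, scaleU))
        without <- dgApp(segmentDG(s, 1, L, scaleU,
                                   lengthCorrection = FALSE))
        if (L == scaleU@refLength)
            expect_equal(with_lc, without)
        else
            expect_false(isTRUE(all.equal(with_lc, without)))
    }
})

test_that("a substitution changes a uniform-profile score by exactly the dg0 difference", {
    set.seed(5)
    for (i in 1:15) {
        s <- randomSeq(60L)
        from <- sample(30L, 1L); to <- from + 20L
        j <- sample(from:to, 1L)
        old <- substr(s, j, j)
        new_res <- sample(setdiff(names(rawDg0), old), 1L)
        v <- variantDG(s, data.frame(wt = old, pos = j, new = new_res),
                       from, to, scaleU, rescan = FALSE)
        # both scores are independently rounded to 3 decimals, so their
        # difference can drift from the dg0 difference by up to 0.001
        expect_lt(abs((v$dg_variant - v$dg_wildtype) -
                      (rawDg0[[new_res]] - rawDg0[[old]])), 1.1e-3)
    }
})

test_that("dG_app depends only on the span's residue string, not its offset", {
    set.seed(9)
    core <- randomSeq(21L)
    for (pad in c(0L, 7L, 40L)) {
        s <- paste0(strrep("G", pad), core, strrep("S", 11L))
        expect_equal(dgApp(segmentDG(s, pad + 1L, pad + 21L, scaleG)),
                     dgApp(segmentDG(core, 1L, 21L, scaleG)))
    }
})

test_that("invalid spans are rejected", {
    expect_error(segmentDG("MKRLLG", 4, 2, scaleG), "invalid span")
    expect_error(segmentDG("MKRLLG", 1, 10, scaleG), "invalid span")
    expect_error(segmentDG("MKRLLG", 0, 3, scaleG), "invalid span")
})

test_that("spans containing X are scored with the configured contribution and flagged", {
    seg <- segmentDG(paste0(strrep("L", 10), "X", strrep("L", 10)),
                     1, 21, scaleU, lengthCorrection = FALSE)
    expect_true(mcols(seg)$has_x)
    expect_equal(dgApp(seg), round(20 * rawDg0[["L"]] + scaleU@xDg, 3L))
})

test_that("poly-glycine yields no segments and short input warns", {
    expect_length(scanSegments(strrep("G", 100L), scaleG), 0L)
    expect_warning(out <- scanSegments(strrep("L", 10L), scaleG),
                   "shorter than the minimum helix length")
    expect_length(out, 0L)
})

test_that("scanSegments matches brute-force window enumeration", {
    set.seed(21)
    for (i in 1:30) {
        # mix plain random sequences with ones seeded with hydrophobic
        # stretches so the scan has something to find
        s <- if (i %% 2L) randomSeq(sample(40:200, 1L))
             else paste0(randomSeq(30L), strrep("L", 21L), randomSeq(25L),
                         paste(sample(c("L", "I", "V", "S", "G"), 22L,
                                      replace = TRUE), collapse = ""),
                         randomSeq(30L))
        got <- suppressWarnings(scanSegments(s, scaleG))
        want <- bruteScan(s, scaleG)
        expect_equal(start(got), want$start, info = paste("seq", i))
        expect_equal(end(got), want$end, info = paste("seq", i))
        expect_equal(dgApp(got), round(want$dg, 3L), info = paste("seq", i))
    }
})

test_that("scanSegments recovers generated helices nearly exactly", {
    # 3 strongly hydrophobic helices; each recovered span must cover at
    # least 90% of its ground-truth span
    for (seed in c(31L, 32L, 33L)) {
        fx <- makeProtein(syntheticSpec(seed, tmdTargetDg = c(-2, -2, -2),
                                        rr = FALSE), scaleG)
        got <- scanSegments(as.character(fx$record[[1L]]), scaleG)
        truth <- fx$truth$segments
        expect_length(got, 3L)
        ov <- IRanges::pintersect(IRanges::findOverlapPairs(got, truth))
        expect_equal(length(ov), 3L)
        expect_true(all(width(ov) / width(truth) >= 0.9))
    }
})

test_that("replacing any residue with lysine never lowers a window's dG_app", {
    set.seed(41)
    for (i in 1:10) {
        s <- paste0(randomSeq(10L), strrep("L", 21L), randomSeq(10L))
        j <- sample(11:31, 1L)
        old <- substr(s, j, j)
        if (old == "K") next
        v <- variantDG(s, data.frame(wt = old, pos = j, new = "K"),
                       11L, 31L, scaleG, rescan = FALSE)
        expect_lte(v$delta, 0)  # K-variant never more insertion-favourable
    }
})

test_that("substituting a residue by itself leaves dG_app unchanged", {
    s <- paste0(strrep("G", 5L), strrep("L", 21L), strrep("G", 5L))
    v <- variantDG(s, "L10L", 6, 26, scaleG)
    expect_equal(v$delta, 0)
    expect_equal(v$dg_variant, v$dg_wildtype)
})

test_that("variant parsing validates the wildtype residue and position", {
    s <- strrep("LG", 15L)
    expect_error(variantDG(s, "S3L", 1, 20, scaleG), "sequence has 'L'")
    expect_error(variantDG(s, "L99F", 1, 20, scaleG), "outside the sequence")
    expect_error(parseSubstitutions("XYZ"), "cannot parse")
})

test_that("centre leucine substitution never raises dG_app relative to the wildtype residue", {
    # leucine has the lowest dg0 among non-branched aliphatics in the
    # shipped scale; isoleucine is marginally lower, so condition on the
    # replaced residue being less hydrophobic than leucine
    set.seed(55)
    for (i in 1:10) {
        s <- randomSeq(61L)
        from <- sample(30L, 1L); to <- from + sample(18:22, 1L)
        centre <- (from + to) %/% 2L
        old <- substr(s, centre, centre)
        if (rawDg0[[old]] < rawDg0[["L"]]) next
        v <- variantDG(s, data.frame(wt = old, pos = centre, new = "L"),
                       from, to, scaleG, rescan = FALSE)
        expect_gte(v$delta, 0)
    }
})
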