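test_that("FASTA parsing handles headers, wrapping, case and stops", {
    tf <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">p1 a demo protein", "MKR",
                 ">p2", "mkl", "lgr*",
                 ">p3", "MKXLG"), tf)
    recs <- readProteinFasta(tf)
    expect_equal(names(recs), c("p1", "p2", "p3"))
    expect_equal(as.character(recs[["p1"]]), "MKR")
    expect_equal(as.character(recs[["p2"]]), "MKLLGR")  # wrapped + * stripped
    expect_equal(as.character(recs[["p3"]]), "MKXLG")   # X allowed
    expect_equal(mcols(recs)$description[1L], "a demo protein")
})

test_that("FASTA parsing rejects duplicates, empties and illegal residues", {
    tf <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">a", "MK", ">a", "MR"), tf)
    expect_error(readProteinFasta(tf), "duplicate.*a")
    writeLines(character(), tf)
    expect_error(readProteinFasta(tf), "no FASTA records")
    writeLines(c(">b", "MKBLR"), tf)
    expect_error(readProteinFasta(tf), "illegal residue 'B'.*'b'.*position 3")
})

test_that("selenocysteine maps to cysteine on input", {
    tf <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">u", "MUKR"), tf)
    expect_equal(as.character(readProteinFasta(tf)[[1L]]), "MCKR")
})

test_that("FASTA write-read round-trip is the identity on (id, seq)", {
    set.seed(7)
    seqs <- vapply(1:10, function(i) randomSeq(sample(30:120, 1L)),
                   character(1L))
    x <- Biostrings::AAStringSet(seqs)
    names(x) <- paste0("rec", 1:10)
    tf <- withr::local_tempfile(fileext = ".fasta")
    writeProteinFasta(x, tf)
    y <- readProteinFasta(tf)
    expect_identical(names(y), names(x))
    expect_identical(as.character(y), stats::setNames(seqs, names(x)))
})

test_that("TMHMM short-format lines decode per the topology grammar", {
    tf <- withr::local_tempfile()
    writeLines(c("p1 len=200 PredHel=1 Topology=i10-32o",
                 "p2 len=200 PredHel=0 Topology=o",
                 "p3 len=200 PredHel=2 Topology=i10-32o40-62i",
                 "p4 len=200 PredHel=1 Topology=i10-32o Nin=0.93"), tf)
    tops <- readTmhmmShort(tf)
    expect_equal(tops[[1L]]@nHelices, 1L)
    expect_equal(start(tmSegments(tops[[1L]])), 10L)
    expect_equal(end(tmSegments(tops[[1L]])), 32L)
    expect_equal(tops[[1L]]@firstLoop, "inside")
    expect_true(is.na(tops[[1L]]@nInProb))
    expect_equal(tops[[2L]]@nHelices, 0L)
    expect_equal(tops[[2L]]@firstLoop, "outside")
    expect_equal(as.data.frame(tmSegments(tops[[3L]]))[, c("start", "end")],
                 data.frame(start = c(10L, 40L), end = c(32L, 62L)))
    expect_equal(tops[[4L]]@nInProb, 0.93)
})

test_that("malformed TMHMM input errors carry the line number", {
    tf <- withr::local_tempfile()
    writeLines(c("p1 len=200 PredHel=1 Topology=i10-32o",
                 "p2 len=200 PredHel=1 Topology=i10-32i"), tf)
    expect_error(readTmhmmShort(tf), "line 2.*malformed")
    writeLines("p1 len=200 PredHel=3 Topology=i10-32o", tf)
    expect_error(readTmhmmShort(tf), "PredHel=3 but topology encodes 1")
})

test_that("TMHMM decode inverts the synthetic encoder on random topologies", {
    set.seed(11)
    for (i in 1:25) {
        nSeg <- sample(0:5, 1L)
        starts <- sort(sample(seq(5L, 400L, by = 30L), nSeg))
        seg <- IRanges(start = starts, width = sample(19:23, max(nSeg, 1L),
                                                      replace = TRUE)[seq_len(nSeg)])
        truth <- list(segments = seg,
                      firstLoop = sample(c("inside", "outside"), 1L),
                      nInProb = round(stats::runif(1L), 2L))
        rec <- Biostrings::AAStringSet(randomSeq(450L))
        names(rec) <- paste0("t", i)
        tf <- withr::local_tempfile()
        writeTmhmmShort(list(list(record = rec, truth = truth)), tf)
        back <- readTmhmmShort(tf)[[1L]]
        expect_equal(back@nHelices, nSeg)
        expect_equal(start(tmSegments(back)), start(seg))
        expect_equal(end(tmSegments(back)), end(seg))
        expect_equal(back@firstLoop, truth$firstLoop)
        expect_equal(back@nInProb, truth$nInProb)
    }
})

test_that("per-residue topology strings decode to segments and loop sides", {
    tf <- withr::local_tempfile()
    writeLines(c(paste0("q1\t", strrep("i", 5), strrep("M", 20),
                        strrep("o", 4), strrep("M", 19), strrep("i", 3))),
               tf)
    top <- readTopologyStrings(tf)[[1L]]
    expect_equal(top@nHelices, 2L)
    expect_equal(start(tmSegments(top)), c(6L, 30L))
    expect_equal(end(tmSegments(top)), c(25L, 48L))
    expect_equal(top@firstLoop, "inside")
    expect_true(is.na(top@nInProb))
})

test_that("TSV writer produces a header-only file for no records and round-trips", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    empty <- data.frame(id = character(), class = character())
    writeResultsTsv(empty, tf)
    expect_equal(nrow(readResultsTsv(tf)), 0L)
    expect_equal(names(readResultsTsv(tf)), c("id", "class"))

    df <- data.frame(id = "p1", class = "N-in-even", gap = 6L,
                     dg = -2.374, stringsAsFactors = FALSE)
    writeResultsTsv(df, tf, params = list(`min-loop` = 8))
    lines <- readLines(tf)
    expect_true(any(grepl("^# min-loop=8$", lines)))
    expect_equal(readResultsTsv(tf), df)
})

test_that("GFF3 export emits helix and motif features with 1-based spans", {
    fx <- makeProtein(syntheticSpec(seed = 3), defaultScale())
    s <- as.character(fx$record[[1L]])
    topo <- buildTopology(s, imported = truthAsImported(fx$truth,
                                                        names(fx$record)),
                          scale = defaultScale(), id = names(fx$record))
    motifs <- list(findRRMotifs(s))
    names(motifs) <- names(fx$record)
    tf <- withr::local_tempfile(fileext = ".gff3")
    writeResultsGff3(list(topo), motifs, tf)
    gr <- rtracklayer::import(tf)
    expect_equal(sum(gr$type == "transmembrane_helix"), 3L)
    expect_equal(sum(gr$type == "sequence_motif"), 1L)
    helices <- gr[gr$type == "transmembrane_helix"]
    expect_equal(GenomicRanges::start(helices), start(fx$truth$segments))
    expect_equal(GenomicRanges::end(helices), end(fx$truth$segments))
    motif <- gr[gr$type == "sequence_motif"]
    expect_equal(GenomicRanges::start(motif), fx$truth$rrPos)
    expect_equal(GenomicRanges::width(motif), 2L)
})
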