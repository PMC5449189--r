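# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately re-derive quantities with plain-R code paths that do
# not share selection or summation logic with the package internals.

suppressPackageStartupMessages({
    library(Biostrings)
    library(IRanges)
    library(S4Vectors)
})

# scale parameters read straight from the shipped scale file, without
# going through readScale()
rawScaleCfg <- yaml::read_yaml(system.file("extdata", "scales",
                                           "biological_dg.yaml",
                                           package = "dualTat"))
rawDg0 <- vapply(rawScaleCfg$residues, function(r) as.numeric(r$dg0),
                 numeric(1L))

# independent transcription of the insertion model: position-weighted
# contributions plus the quadratic length correction anchored at the
# reference length
oracleWindowDg <- function(residues) {
    L <- length(residues)
    z <- if (L == 1L) 0 else 9 * (2 * (seq_len(L) - 1L) / (L - 1L) - 1)
    total <- 0
    for (j in seq_len(L)) {
        p <- rawScaleCfg$residues[[residues[j]]]
        v <- as.numeric(p$dg0) * exp(-as.numeric(p$width) * z[j]^2)
        if (!is.null(p$arom_dg)) {
            off <- as.numeric(rawScaleCfg$arom_offset)
            v <- v + as.numeric(p$arom_dg) *
                (exp(-as.numeric(p$arom_width) * (z[j] - off)^2) +
                 exp(-as.numeric(p$arom_width) * (z[j] + off)^2))
        }
        total <- total + v
    }
    q <- function(l) sum(as.numeric(rawScaleCfg$length_coeffs) *
                         c(1, l, l^2))
    total + q(L) - q(as.numeric(rawScaleCfg$ref_length))
}

# hand summation under the uniform profile (no length correction)
handSumUniform <- function(s, from, to) {
    res <- strsplit(substr(s, from, to), "")[[1L]]
    total <- 0
    for (r in res) total <- total + rawDg0[[r]]
    total
}

# brute-force scanner: enumerate every (start, length) window, score each
# with the independent model transcription above, filter by threshold,
# then pick non-overlapping windows in (dg, start, len) order using an
# explicit occupancy vector
bruteScan <- function(s, scale, threshold = 0) {
    n <- nchar(s)
    res <- strsplit(s, "")[[1L]]
    rows <- list()
    for (L in seq(scale@Lmin, min(scale@Lmax, n))) {
        for (st in seq_len(n - L + 1L)) {
            dg <- oracleWindowDg(res[st:(st + L - 1L)])
            if (dg <= threshold)
                rows[[length(rows) + 1L]] <- c(st, L, dg)
        }
    }
    if (!length(rows))
        return(data.frame(start = integer(), end = integer(),
                          dg = numeric()))
    m <- do.call(rbind, rows)
    m <- m[order(m[, 3L], m[, 1L], m[, 2L]), , drop = FALSE]
    occupied <- logical(n)
    picked <- list()
    for (k in seq_len(nrow(m))) {
        span <- seq(m[k, 1L], m[k, 1L] + m[k, 2L] - 1L)
        if (!any(occupied[span])) {
            occupied[span] <- TRUE
            picked[[length(picked) + 1L]] <- m[k, ]
        }
    }
    p <- do.call(rbind, picked)
    p <- p[order(p[, 1L]), , drop = FALSE]
    data.frame(start = as.integer(p[, 1L]),
               end = as.integer(p[, 1L] + p[, 2L] - 1L),
               dg = p[, 3L])
}

# count RR 2-mers by explicit substring comparison
bruteRRCount <- function(s) {
    n <- nchar(s)
    if (n < 2L) return(0L)
    hits <- 0L
    for (i in seq_len(n - 1L))
        if (substr(s, i, i + 1L) == "RR") hits <- hits + 1L
    hits
}

# random protein-like sequence; mildly hydrophobic-biased so scans find
# things sometimes
randomSeq <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                      "I", "K", "L", "M", "N", "P", "Q",
                                      "R", "S", "T", "V", "W", "Y")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a TopologyModel built directly from explicit pieces (bypasses the scan)
makeTopo <- function(id, starts, ends, dg = NULL, orientation = "N-in",
                     score = if (orientation == "N-in") 0.95 else 0.1,
                     source = "imported") {
    seg <- IRanges(start = starts, end = ends)
    if (is.null(dg)) dg <- rep(NA_real_, length(seg))
    mcols(seg) <- DataFrame(dg_app = dg)
    new("TopologyModel", proteinId = id, segments = seg,
        orientation = orientation, nInScore = score, source = source,
        flags = character())
}

# motif set at given first-arginine positions
makeMotifs <- function(pos) {
    out <- IRanges(start = pos, width = 2L)
    mcols(out) <- DataFrame(context = rep("", length(pos)),
                            consensus_score = rep(0L, length(pos)))
    out
}
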