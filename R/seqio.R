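#' @include AllClasses.R
NULL

# Coerce the various sequence carriers (character, AAString, single-record
# AAStringSet) to a plain uppercase character string.
.asSeqString <- function(x) {
    if (is(x, "AAStringSet")) {
        if (length(x) != 1L)
            stop("expected a single sequence, got ", length(x), " records")
        x <- x[[1L]]
    }
    if (is(x, "AAString"))
        x <- as.character(x)
    if (!is.character(x) || length(x) != 1L)
        stop("cannot interpret 'x' as a single protein sequence")
    toupper(x)
}

.recordId <- function(x, default = "protein") {
    if (is(x, "AAStringSet") && !is.null(names(x)) && nzchar(names(x)[1L]))
        return(names(x)[1L])
    nm <- names(x)
    if (!is.null(nm) && nzchar(nm[1L])) nm[1L] else default
}

#' Read protein sequences from a FASTA file
#'
#' Reads a (wrapped or unwrapped) multi-record protein FASTA file into an
#' \link[Biostrings]{AAStringSet}. The record identifier is the first
#' whitespace-delimited token of the header; the remainder is kept as a
#' \code{description} metadata column. Sequences are uppercased and a single
#' trailing \code{*} (stop) is stripped. Selenocysteine (\code{U}) is mapped
#' to \code{C}; the unknown residue \code{X} is allowed and later scored with
#' the scale's configurable \code{X} contribution; any other non-standard
#' letter (\code{B}, \code{Z}, \code{J}, ...) is an error naming the record
#' and position. Duplicate identifiers and empty files are errors: a genome
#' screen must not silently skip or merge records.
#'
#' @param path path to a FASTA file.
#' @return \link[Biostrings]{AAStringSet} with \code{description} in
#'   \code{mcols}.
#' @seealso [writeProteinFasta()]
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKR"), tf)
#' readProteinFasta(tf)
#' @export
readProteinFasta <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    aa <- Biostrings::readAAStringSet(path)
    if (length(aa) == 0L)
        stop("no FASTA records found in ", path)
    headers <- names(aa)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    if (anyDuplicated(ids)) {
        dups <- unique(ids[duplicated(ids)])
        stop("duplicate record id(s): ", paste(dups, collapse = ", "))
    }
    seqs <- toupper(as.character(aa))
    seqs <- sub("\\*$", "", seqs)
    seqs <- gsub("U", "C", seqs, fixed = TRUE)
    for (k in seq_along(seqs)) {
        if (!nzchar(seqs[k]))
            stop("record '", ids[k], "' has an empty sequence")
        bad <- which(!strsplit(seqs[k], "")[[1L]] %in% .AA_ALLOWED)
        if (length(bad))
            stop("illegal residue '",
                 substr(seqs[k], bad[1L], bad[1L]),
                 "' in record '", ids[k], "' at position ", bad[1L])
    }
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- ids
    mcols(out) <- DataFrame(description = desc)
    out
}

#' Write protein sequences to FASTA
#'
#' @param x \link[Biostrings]{AAStringSet} (descriptions in
#'   \code{mcols(x)$description} are appended to the headers).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeProteinFasta <- function(x, path) {
    stopifnot(is(x, "AAStringSet"))
    out <- x
    desc <- mcols(x)$description
    if (!is.null(desc)) {
        nm <- names(x)
        has <- !is.na(desc) & nzchar(desc)
        nm[has] <- paste(nm[has], desc[has])
        names(out) <- nm
    }
    Biostrings::writeXStringSet(out, path)
    invisible(path)
}

# Decode one TMHMM-style topology string, e.g. "i10-32o40-62i".
.decodeTopologyString <- function(topo) {
    if (!grepl("^[io](\\d+-\\d+[io])*$", topo))
        return(NULL)
    firstLoop <- if (substr(topo, 1L, 1L) == "i") "inside" else "outside"
    m <- gregexpr("\\d+-\\d+", topo)[[1L]]
    if (m[1L] == -1L)
        return(list(firstLoop = firstLoop, segments = IRanges()))
    spans <- regmatches(topo, gregexpr("\\d+-\\d+", topo))[[1L]]
    se <- do.call(rbind, lapply(strsplit(spans, "-"), as.integer))
    if (any(se[, 2L] < se[, 1L]))
        return(NULL)
    # loop side letters must alternate; the grammar guarantees each span is
    # bracketed by i/o, so check consistency of the bracketing letters
    letters_ <- strsplit(gsub("\\d+-\\d+", "|", topo), "")[[1L]]
    letters_ <- letters_[letters_ %in% c("i", "o")]
    if (any(letters_[-1L] == letters_[-length(letters_)]))
        return(NULL)
    seg <- IRanges(start = se[, 1L], end = se[, 2L])
    if (length(seg) > 1L &&
        (is.unsorted(start(seg), strictly = TRUE) ||
         any(start(seg)[-1L] <= end(seg)[-length(seg)])))
        return(NULL)
    list(firstLoop = firstLoop, segments = seg)
}

#' Read TMHMM short-format topology predictions
#'
#' Parses whitespace-separated short-format lines containing
#' \code{PredHel=<n>} and \code{Topology=<string>} fields (first field =
#' protein id). The topology grammar is a leading \code{i}/\code{o} loop
#' side followed by alternating \code{<start>-<end>} helix spans separated
#' by loop side letters. \code{PredHel} must match the number of decoded
#' spans. An optional \code{Nin=<p>} field supplies the whole-protein N-in
#' probability (the classic short format does not print one, in which case
#' it is left absent).
#'
#' @param path path to a short-format file.
#' @return list of \linkS4class{ImportedTopology}.
#' @examples
#' tf <- tempfile()
#' writeLines("p1 len=200 PredHel=1 Topology=i10-32o", tf)
#' readTmhmmShort(tf)[[1]]
#' @export
readTmhmmShort <- function(path) {
    if (!file.exists(path))
        stop("topology file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    lapply(seq_along(lines), function(ln) {
        fields <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
        id <- fields[1L]
        grab <- function(key) {
            hit <- grep(paste0("^", key, "="), fields, value = TRUE)
            if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else NA
        }
        predhel <- suppressWarnings(as.integer(grab("PredHel")))
        topo <- grab("Topology")
        if (is.na(predhel) || is.na(topo))
            stop("line ", ln, ": missing PredHel= or Topology= field")
        dec <- .decodeTopologyString(topo)
        if (is.null(dec))
            stop("line ", ln, ": malformed topology string '", topo, "'")
        if (predhel != length(dec$segments))
            stop("line ", ln, ": PredHel=", predhel, " but topology encodes ",
                 length(dec$segments), " helices")
        prob <- suppressWarnings(as.numeric(grab("Nin")))
        new("ImportedTopology", proteinId = id, nHelices = predhel,
            segments = dec$segments, firstLoop = dec$firstLoop,
            nInProb = as.numeric(prob))
    })
}

#' Read per-residue topology strings
#'
#' Parses lines of the form \code{id<TAB>iiiMMM...ooo}: runs of \code{M} are
#' helix spans; \code{i}/\code{o} mark inside/outside loops. The first loop
#' side is taken from the first non-\code{M} character (if the string starts
#' with a helix, the side opposite the following loop is used).
#'
#' @param path path to a two-column tab-separated file.
#' @return list of \linkS4class{ImportedTopology} (N-in probability absent).
#' @export
readTopologyStrings <- function(path) {
    if (!file.exists(path))
        stop("topology file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lapply(seq_along(lines), function(ln) {
        parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
        if (length(parts) != 2L)
            stop("line ", ln, ": expected 'id<TAB>topology-string'")
        id <- parts[1L]
        topo <- strsplit(parts[2L], "")[[1L]]
        if (!all(topo %in% c("i", "o", "M")))
            stop("line ", ln, ": topology string has characters outside {i,o,M}")
        r <- rle(topo)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        isM <- r$values == "M"
        seg <- IRanges(start = starts[isM], end = ends[isM])
        loops <- r$values[!isM]
        if (any(loops[-1L] == loops[-length(loops)]) && length(loops) > 1L)
            stop("line ", ln, ": loop sides do not alternate")
        firstLoop <- if (topo[1L] != "M") {
            if (topo[1L] == "i") "inside" else "outside"
        } else if (length(loops)) {
            if (loops[1L] == "i") "outside" else "inside"
        } else "inside"
        new("ImportedTopology", proteinId = id,
            nHelices = sum(isM), segments = seg,
            firstLoop = firstLoop, nInProb = NA_real_)
    })
}

#' Write screen results as TSV
#'
#' One row per protein with stable columns. The run parameters (if supplied)
#' are echoed verbatim as \code{# key=value} comment lines for provenance.
#'
#' @param df data.frame of results (as returned by [screenFasta()]).
#' @param path output path.
#' @param params optional named list echoed into the header.
#' @return invisibly, \code{path}.
#' @seealso [readResultsTsv()] for the round-trip reader.
#' @export
writeResultsTsv <- function(df, path, params = NULL) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (length(params))
        writeLines(sprintf("# %s=%s", names(params),
                           vapply(params, format, character(1L))), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}

#' @rdname writeResultsTsv
#' @export
readResultsTsv <- function(path) {
    utils::read.delim(path, comment.char = "#", na.strings = c("NA", ""),
                      stringsAsFactors = FALSE)
}

#' Write topology segments and RR motifs as GFF3
#'
#' Emits one \code{transmembrane_helix} feature per segment (score =
#' dG_app where available) and one \code{sequence_motif} feature per RR
#' motif, with 1-based inclusive coordinates on the protein sequence.
#'
#' @param topologies list of \linkS4class{TopologyModel}.
#' @param motifs named list of \link[IRanges]{IRanges} motif sets (names =
#'   protein ids), as returned by [findRRMotifs()]; may be \code{NULL}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeResultsGff3 <- function(topologies, motifs = NULL, path) {
    grs <- list()
    for (tp in topologies) {
        if (length(tp@segments)) {
            dg <- mcols(tp@segments)$dg_app
            gr <- GenomicRanges::GRanges(tp@proteinId,
                                         IRanges(start(tp@segments),
                                                 end(tp@segments)))
            mcols(gr)$type <- "transmembrane_helix"
            mcols(gr)$score <- if (is.null(dg)) NA_real_ else round(dg, 3L)
            grs[[length(grs) + 1L]] <- gr
        }
        mt <- motifs[[tp@proteinId]]
        if (!is.null(mt) && length(mt)) {
            gr <- GenomicRanges::GRanges(tp@proteinId,
                                         IRanges(start(mt), end(mt)))
            mcols(gr)$type <- "sequence_motif"
            mcols(gr)$score <- as.numeric(mcols(mt)$consensus_score)
            grs[[length(grs) + 1L]] <- gr
        }
    }
    if (!length(grs))
        gr_all <- GenomicRanges::GRanges()
    else
        gr_all <- suppressWarnings(do.call(c, grs))
    rtracklayer::export.gff3(gr_all, path)
    invisible(path)
}

#' Fetch protein sequences from UniProt
#'
#' Convenience downloader for single accessions (requires network access);
#' writes \code{<accession>.fasta} files into \code{destdir} and returns the
#' combined records. Used to obtain the real reference proteins when
#' reproducing published dG_app tables; all package tests run on generated
#' fixtures instead and do not require it.
#'
#' @param accessions character vector of UniProt accessions.
#' @param destdir directory to cache the downloads in.
#' @return \link[Biostrings]{AAStringSet} of the fetched records.
#' @export
fetchUniProt <- function(accessions, destdir = tempdir()) {
    paths <- vapply(accessions, function(acc) {
        dest <- file.path(destdir, paste0(acc, ".fasta"))
        if (!file.exists(dest)) {
            url <- paste0("https://rest.uniprot.org/uniprotkb/", acc,
                          ".fasta")
            utils::download.file(url, dest, quiet = TRUE, mode = "wb")
        }
        dest
    }, character(1L))
    recs <- lapply(paths, readProteinFasta)
    out <- do.call(c, lapply(recs, as, "AAStringSet"))
    # UniProt headers are 'db|ACC|NAME desc'; keep the accession as id
    names(out) <- vapply(strsplit(names(out), "|", fixed = TRUE),
                         function(p) if (length(p) >= 2L) p[2L] else p[1L],
                         character(1L))
    out
}
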