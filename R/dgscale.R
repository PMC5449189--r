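#' @include AllClasses.R seqio.R
NULL

#' Load a hydrophobicity scale from a YAML configuration file
#'
#' The scale file holds, per residue, the centre contribution \code{dg0}
#' (kcal/mol) and the parameters of the position dependence (see the file
#' header in \code{inst/extdata/scales/biological_dg.yaml} for the model),
#' plus the helix-length correction coefficients and the allowed helix
#' length range. \code{defaultScale()} loads the scale shipped with the
#' package; \code{profile = "uniform"} switches off the position dependence
#' (every position weighted 1), which is the configuration used by the
#' hand-sum test oracles.
#'
#' @param path path to a scale YAML file.
#' @param profile override the profile declared in the file
#'   (\code{"gaussian"} or \code{"uniform"}).
#' @return a \linkS4class{HydrophobicityScale}.
#' @examples
#' defaultScale()
#' @export
readScale <- function(path, profile = NULL) {
    cfg <- yaml::read_yaml(path)
    res <- cfg$residues
    aas <- names(res)
    num <- function(field, default = 0) {
        vapply(res, function(r) {
            v <- r[[field]]
            if (is.null(v)) default else as.numeric(v)
        }, numeric(1L))
    }
    dg0 <- stats::setNames(num("dg0"), aas)
    width <- stats::setNames(num("width"), aas)
    aromDg <- stats::setNames(num("arom_dg"), aas)
    aromWidth <- stats::setNames(num("arom_width"), aas)
    xDg <- if (is.null(cfg$x_dg)) 0 else as.numeric(cfg$x_dg)
    # X participates like any residue, with a flat configurable contribution
    dg0["X"] <- xDg
    width["X"] <- 0
    aromDg["X"] <- 0
    aromWidth["X"] <- 0
    new("HydrophobicityScale",
        name = as.character(cfg$name),
        version = as.character(cfg$version),
        profile = if (is.null(profile)) as.character(cfg$profile)
                  else match.arg(profile, c("gaussian", "uniform")),
        dg0 = dg0, gaussWidth = width,
        aromDg = aromDg, aromWidth = aromWidth,
        aromOffset = as.numeric(cfg$arom_offset),
        lengthCoeffs = as.numeric(cfg$length_coeffs),
        refLength = as.integer(cfg$ref_length),
        Lmin = as.integer(cfg$l_min),
        Lmax = as.integer(cfg$l_max),
        xDg = xDg)
}

#' @rdname readScale
#' @export
defaultScale <- function(profile = NULL) {
    readScale(system.file("extdata", "scales", "biological_dg.yaml",
                          package = "dualTat", mustWork = TRUE),
              profile = profile)
}

# Helix-length correction, defined relative to the reference length so that
# it is exactly 0 there.
.lengthCorrection <- function(L, scale) {
    q <- function(l) scale@lengthCoeffs[1L] + scale@lengthCoeffs[2L] * l +
        scale@lengthCoeffs[3L] * l^2
    q(L) - q(scale@refLength)
}

# Per-position contributions of the residues of one candidate helix.
# residues: character vector of single letters; returns numeric vector.
.dgContributions <- function(residues, scale) {
    L <- length(residues)
    base <- unname(scale@dg0[residues])
    if (anyNA(base))
        stop("residue(s) outside the scale alphabet: ",
             paste(unique(residues[is.na(base)]), collapse = ", "))
    if (scale@profile == "uniform")
        return(base)
    z <- if (L == 1L) 0 else 9 * (2 * (seq_len(L) - 1L) / (L - 1L) - 1)
    v <- base * exp(-unname(scale@gaussWidth[residues]) * z^2)
    ar <- unname(scale@aromDg[residues])
    has <- ar != 0
    if (any(has)) {
        w <- unname(scale@aromWidth[residues][has])
        v[has] <- v[has] + ar[has] *
            (exp(-w * (z[has] - scale@aromOffset)^2) +
             exp(-w * (z[has] + scale@aromOffset)^2))
    }
    v
}

#' Apparent free energy of membrane insertion of a sequence span
#'
#' Computes dG_app (kcal/mol) of the helix formed by residues
#' \code{start..end} (1-based, inclusive) under the given scale:
#' the sum of position-weighted per-residue contributions, plus the
#' helix-length correction when \code{lengthCorrection} is \code{TRUE}.
#' Negative values favour translocon-mediated insertion. The value is
#' deterministic and reported to 3 decimals. Spans containing \code{X} are
#' scored with the scale's configurable \code{X} contribution and flagged
#' via the \code{has_x} metadata column.
#'
#' @param x sequence: character string, \link[Biostrings]{AAString}, or a
#'   single-record \link[Biostrings]{AAStringSet}.
#' @param start,end span bounds, 1-based inclusive.
#' @param scale a \linkS4class{HydrophobicityScale}.
#' @param lengthCorrection apply the helix-length correction (default TRUE).
#' @return length-1 \link[IRanges]{IRanges} with metadata columns
#'   \code{dg_app} and \code{has_x}.
#' @examples
#' sc <- defaultScale()
#' segmentDG(paste(rep("L", 21), collapse = ""), 1, 21, sc)
#' @export
segmentDG <- function(x, start, end, scale, lengthCorrection = TRUE) {
    s <- .asSeqString(x)
    n <- nchar(s)
    start <- as.integer(start); end <- as.integer(end)
    if (is.na(start) || is.na(end) || start < 1L || end > n || start > end)
        stop("invalid span ", start, "-", end,
             " for a sequence of length ", n)
    residues <- strsplit(substr(s, start, end), "")[[1L]]
    dg <- sum(.dgContributions(residues, scale))
    if (lengthCorrection)
        dg <- dg + .lengthCorrection(length(residues), scale)
    out <- IRanges(start = start, end = end)
    mcols(out) <- DataFrame(dg_app = round(dg, 3L),
                            has_x = any(residues == "X"))
    out
}

# Residue x relative-position contribution matrix for helices of length L
# (closed form of .dgContributions for the whole alphabet at once).
.contribMatrix <- function(L, scale) {
    alphabet <- names(scale@dg0)
    if (scale@profile == "uniform" || L == 1L) {
        z <- rep(0, L)
        if (scale@profile == "uniform")
            return(matrix(scale@dg0, nrow = length(alphabet), ncol = L,
                          dimnames = list(alphabet, NULL)))
    } else {
        z <- 9 * (2 * (seq_len(L) - 1L) / (L - 1L) - 1)
    }
    M <- outer(seq_along(alphabet), seq_len(L), function(a, j)
        scale@dg0[alphabet[a]] *
            exp(-scale@gaussWidth[alphabet[a]] * z[j]^2))
    har <- which(scale@aromDg != 0)
    for (a in har) {
        w <- scale@aromWidth[a]
        M[a, ] <- M[a, ] + scale@aromDg[a] *
            (exp(-w * (z - scale@aromOffset)^2) +
             exp(-w * (z + scale@aromOffset)^2))
    }
    rownames(M) <- alphabet
    M
}

# dG_app of every window of lengths Lmin..Lmax; returns a data.frame
# (start, len, dg). Contributions are precomputed per window length as a
# residue x relative-position matrix.
.allWindows <- function(s, scale, lengthCorrection = TRUE) {
    n <- nchar(s)
    residues <- strsplit(s, "")[[1L]]
    idx <- match(residues, names(scale@dg0))
    if (anyNA(idx))
        stop("residue(s) outside the scale alphabet: ",
             paste(unique(residues[is.na(idx)]), collapse = ", "))
    res <- list()
    for (L in seq(scale@Lmin, min(scale@Lmax, n))) {
        M <- .contribMatrix(L, scale)
        starts <- seq_len(n - L + 1L)
        lc <- if (lengthCorrection) .lengthCorrection(L, scale) else 0
        dg <- vapply(starts, function(st) {
            sum(M[cbind(idx[st:(st + L - 1L)], seq_len(L))])
        }, numeric(1L)) + lc
        res[[length(res) + 1L]] <- data.frame(start = starts, len = L,
                                              dg = dg)
    }
    if (!length(res))
        return(data.frame(start = integer(), len = integer(),
                          dg = numeric()))
    do.call(rbind, res)
}

# Greedy non-overlapping selection by ascending dG (ties: smaller start,
# then shorter length) over a window table.
.greedySelect <- function(wins) {
    if (!nrow(wins))
        return(wins)
    wins <- wins[order(wins$dg, wins$start, wins$len), , drop = FALSE]
    taken_s <- integer(); taken_e <- integer()
    keep <- logical(nrow(wins))
    for (k in seq_len(nrow(wins))) {
        st <- wins$start[k]; en <- st + wins$len[k] - 1L
        if (!length(taken_s) || all(en < taken_s | st > taken_e)) {
            keep[k] <- TRUE
            taken_s <- c(taken_s, st); taken_e <- c(taken_e, en)
        }
    }
    wins[keep, , drop = FALSE]
}

#' Scan a sequence for candidate transmembrane segments
#'
#' Enumerates every window of length \code{Lmin..Lmax}, scores each with
#' [segmentDG()] (length correction on), and greedily selects
#' non-overlapping windows in order of ascending dG_app (ties broken by
#' smaller start, then shorter length). By default only segments with
#' \code{dg_app <= thresholdDg} are returned; \code{keepAll = TRUE} returns
#' the full non-overlapping set of local minima regardless of threshold,
#' which is what the screen's rescue step uses to call weakly hydrophobic
#' (positive dG_app) final helices.
#'
#' @param x sequence (as in [segmentDG()]).
#' @param scale a \linkS4class{HydrophobicityScale}.
#' @param thresholdDg report segments with dG_app at or below this value
#'   (kcal/mol; default 0).
#' @param keepAll return all non-overlapping local minima.
#' @return \link[IRanges]{IRanges} sorted by start with a \code{dg_app}
#'   metadata column; empty (with a warning) if the sequence is shorter
#'   than \code{Lmin}.
#' @examples
#' sc <- defaultScale()
#' scanSegments(paste(rep(c("G", "L"), c(30, 21)), collapse = ""), sc)
#' @export
scanSegments <- function(x, scale, thresholdDg = 0, keepAll = FALSE) {
    s <- .asSeqString(x)
    if (nchar(s) < scale@Lmin) {
        warning("sequence shorter than the minimum helix length (",
                scale@Lmin, "); returning no segments")
        return(IRanges())
    }
    wins <- .allWindows(s, scale)
    if (!keepAll)
        wins <- wins[wins$dg <= thresholdDg, , drop = FALSE]
    sel <- .greedySelect(wins)
    sel <- sel[order(sel$start), , drop = FALSE]
    out <- IRanges(start = sel$start, width = sel$len)
    mcols(out) <- DataFrame(dg_app = round(sel$dg, 3L))
    out
}

# Best (lowest-dG) single window whose start lies in [from, to]; NULL if
# no window fits. Used by the screen's rescue step.
.bestWindowIn <- function(s, scale, from, to, avoid = IRanges()) {
    wins <- .allWindows(s, scale)
    wins <- wins[wins$start >= from & wins$start <= to, , drop = FALSE]
    if (length(avoid) && nrow(wins)) {
        en <- wins$start + wins$len - 1L
        ok <- vapply(seq_len(nrow(wins)), function(k) {
            all(en[k] < start(avoid) | wins$start[k] > end(avoid))
        }, logical(1L))
        wins <- wins[ok, , drop = FALSE]
    }
    if (!nrow(wins))
        return(NULL)
    wins <- wins[order(wins$dg, wins$start, wins$len), , drop = FALSE]
    out <- IRanges(start = wins$start[1L], width = wins$len[1L])
    mcols(out) <- DataFrame(dg_app = round(wins$dg[1L], 3L))
    out
}

#' Parse substitution strings like "S179L"
#'
#' @param x character vector (elements may themselves be comma-separated),
#'   each substitution \code{<wt><pos><new>}; the wildtype letter is checked
#'   against the sequence when applied.
#' @return data.frame with columns \code{wt}, \code{pos}, \code{new}.
#' @export
parseSubstitutions <- function(x) {
    toks <- unlist(strsplit(x, ",", fixed = TRUE))
    toks <- trimws(toks)
    m <- regmatches(toks, regexec("^([A-Za-z])(\\d+)([A-Za-z])$", toks))
    bad <- vapply(m, length, integer(1L)) != 4L
    if (any(bad))
        stop("cannot parse substitution(s): ",
             paste(toks[bad], collapse = ", "))
    data.frame(wt = toupper(vapply(m, `[`, character(1L), 2L)),
               pos = as.integer(vapply(m, `[`, character(1L), 3L)),
               new = toupper(vapply(m, `[`, character(1L), 4L)),
               stringsAsFactors = FALSE)
}

.applySubstitutions <- function(s, subs) {
    n <- nchar(s)
    for (k in seq_len(nrow(subs))) {
        p <- subs$pos[k]
        if (is.na(p) || p < 1L || p > n)
            stop("substitution position ", p,
                 " outside the sequence (length ", n, ")")
        if (!subs$new[k] %in% .AA_ALLOWED)
            stop("invalid replacement residue '", subs$new[k], "'")
        have <- substr(s, p, p)
        if (!is.na(subs$wt[k]) && nzchar(subs$wt[k]) && have != subs$wt[k])
            stop("substitution ", subs$wt[k], p, subs$new[k],
                 ": sequence has '", have, "' at position ", p)
        substr(s, p, p) <- subs$new[k]
    }
    s
}

#' What-if dG_app of a substituted span
#'
#' Scores a span before and after applying point substitutions. Because a
#' substitution can shift where a scanner would place the helix, the variant
#' is reported both over the fixed original span and over a re-scanned span
#' (the best window of allowed lengths overlapping the original span by at
#' least half the window length). \code{delta = dg_wildtype - dg_variant}
#' (fixed span): positive means the variant is more insertion-favourable.
#'
#' @param x sequence (as in [segmentDG()]).
#' @param substitutions data.frame from [parseSubstitutions()], or a
#'   character vector like \code{"S179L"} / \code{c("G234L", "S235L")}.
#' @param start,end span to score, 1-based inclusive.
#' @param scale a \linkS4class{HydrophobicityScale}.
#' @param lengthCorrection as in [segmentDG()].
#' @param rescan also report the re-scanned variant span (default TRUE).
#' @return list with \code{dg_wildtype}, \code{dg_variant}, \code{delta},
#'   and (if \code{rescan}) \code{dg_variant_rescan} and
#'   \code{rescan_span}.
#' @examples
#' sc <- defaultScale()
#' s <- paste(rep(c("G", "L", "G"), c(5, 21, 5)), collapse = "")
#' variantDG(s, "G3L", 6, 26, sc)$delta  # substitution outside span: 0
#' @export
variantDG <- function(x, substitutions, start, end, scale,
                      lengthCorrection = TRUE, rescan = TRUE) {
    s <- .asSeqString(x)
    if (is.character(substitutions))
        substitutions <- parseSubstitutions(substitutions)
    sv <- .applySubstitutions(s, substitutions)
    dg_wt <- dgApp(segmentDG(s, start, end, scale, lengthCorrection))
    dg_var <- dgApp(segmentDG(sv, start, end, scale, lengthCorrection))
    out <- list(dg_wildtype = dg_wt, dg_variant = dg_var,
                delta = round(dg_wt - dg_var, 3L))
    if (rescan) {
        wins <- .allWindows(sv, scale, lengthCorrection)
        if (nrow(wins)) {
            en <- wins$start + wins$len - 1L
            ov <- pmin(en, end) - pmax(wins$start, start) + 1L
            wins <- wins[ov >= wins$len / 2, , drop = FALSE]
        }
        if (nrow(wins)) {
            wins <- wins[order(wins$dg, wins$start, wins$len), ,
                         drop = FALSE]
            out$dg_variant_rescan <- round(wins$dg[1L], 3L)
            out$rescan_span <- c(wins$start[1L],
                                 wins$start[1L] + wins$len[1L] - 1L)
        } else {
            out$dg_variant_rescan <- NA_real_
            out$rescan_span <- c(NA_integer_, NA_integer_)
        }
    }
    out
}
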