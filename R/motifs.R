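## motifs module: canonical GTPase motif scanning and WG-relative annotation.

.REGION_PRIORITY <- c("G1", "G2", "G3", "G4", "G5",
                      "trans_loop1", "alpha4", "beta_meander")

## patterns as per-position allowed-letter sets (NULL = any residue)
.MOTIF_PATTERNS <- list(
    G1 = list("G", NULL, NULL, NULL, NULL, "G", "K", c("S", "T")),
    G3 = list("D", NULL, NULL, "G"),
    G4 = list(c("A", "G", "N", "T"), "K", NULL, "D"),
    G5 = list(c("S", "A"), "A", c("K", "L", "R")))

## sliding mismatch-tolerant scan; returns (start, mismatches) of the best
## hit (fewest mismatches, then leftmost) or NULL
.scanPattern <- function(chars, pattern, maxMismatch, from = 1L) {
    L <- length(pattern); n <- length(chars)
    if (from > n - L + 1L) return(NULL)
    best <- NULL
    for (s in from:(n - L + 1L)) {
        mm <- 0L
        for (k in seq_len(L)) {
            allowed <- pattern[[k]]
            if (!is.null(allowed) && !(chars[s + k - 1L] %in% allowed))
                mm <- mm + 1L
            if (mm > maxMismatch) break
        }
        if (mm <= maxMismatch && (is.null(best) || mm < best$mismatches)) {
            best <- list(start = s, mismatches = mm)
            if (mm == 0L) break
        }
    }
    best
}

.checkAASeq <- function(sequence) {
    if (length(sequence) == 1L && nchar(sequence[1]) > 1L)
        sequence <- strsplit(unname(sequence), "")[[1]]
    s <- toupper(unname(sequence))
    bad <- setdiff(unique(s), c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"))
    if (length(bad))
        stop("non-amino-acid character(s) in sequence: ",
             paste(bad, collapse = ", "))
    s
}

#' Scan a sequence for canonical GTPase / septin motifs
#'
#' Locates the motif cores by degenerate patterns: G1 (P-loop) as
#' `GxxxxGK[S/T]`, G3 (Switch II) as `DxxG`, G4 as `[A/G/N/T]KxD`, G5 as
#' `[S/A]A[K/L/R]`, each allowing up to `maxMismatch` mismatches (reported),
#' and the Sep4 "WG" anchor as a literal `WG` downstream of G5. The
#' beta-meander range is centred on the WG Trp (WG-6 .. WG+12), and the
#' config-style trans loop 1 and alpha-4 helix ranges are anchored relative
#' to G4 (tl1 just N-terminal, alpha-4 C-terminal). Regions that cannot be
#' located are flagged absent rather than failing, so degenerate motifs in
#' pseudoGTPases still scan. Overlaps between derived ranges are resolved by
#' fixed priority (G1 > G2 > G3 > G4 > G5 > tl1 > alpha4 > beta_meander).
#'
#' @param sequence amino-acid string (>= 100 residues) or character vector;
#'   names, when present, are taken as author residue numbers.
#' @param maxMismatch mismatches tolerated per motif (default 1).
#' @return a [MotifDefinition].
#' @export
scanMotifs <- function(sequence, maxMismatch = 1L) {
    resnos <- if (!is.null(names(sequence))) as.integer(names(sequence)) else NULL
    chars <- .checkAASeq(sequence)
    n <- length(chars)
    if (n < 100L) stop("sequence too short for a GTPase domain (need >= 100)")
    if (is.null(resnos)) resnos <- seq_len(n)

    hits <- list(); absent <- character()
    from <- 1L
    for (m in c("G1", "G3", "G4", "G5")) {
        ## G5 is short and degenerate; it is only meaningful (and only
        ## scanned) downstream of a located G4
        if (m == "G5" && is.null(hits$G4)) { absent <- c(absent, m); next }
        h <- .scanPattern(chars, .MOTIF_PATTERNS[[m]], maxMismatch, from = from)
        if (is.null(h)) { absent <- c(absent, m); next }
        hits[[m]] <- c(start = h$start,
                       end = h$start + length(.MOTIF_PATTERNS[[m]]) - 1L,
                       mismatches = h$mismatches)
        from <- h$start + length(.MOTIF_PATTERNS[[m]])
    }
    absent <- c(absent, "G2")  # switch I has no reliable sequence signature
    ## WG anchor: literal, downstream of G5 (or G4, or mid-sequence)
    wgFrom <- if (!is.null(hits$G5)) hits$G5["end"] + 1L
              else if (!is.null(hits$G4)) hits$G4["end"] + 1L else 1L
    wg <- NULL
    for (s in wgFrom:(n - 1L))
        if (chars[s] == "W" && chars[s + 1L] == "G") { wg <- s; break }
    if (is.null(wg)) absent <- c(absent, "beta_meander")

    rows <- list()
    addRange <- function(region, start, end, mismatches, source) {
        rows[[length(rows) + 1L]] <<- data.frame(
            region = region, start = max(1L, start), end = min(n, end),
            mismatches = mismatches, source = source, stringsAsFactors = FALSE)
    }
    for (m in names(hits))
        addRange(m, hits[[m]]["start"], hits[[m]]["end"],
                 hits[[m]]["mismatches"], "regex_scan")
    if (!is.null(hits$G4)) {
        addRange("trans_loop1", hits$G4["start"] - 9L, hits$G4["start"] - 4L,
                 NA_integer_, "config")
        addRange("alpha4", hits$G4["end"] + 4L, hits$G4["end"] + 15L,
                 NA_integer_, "config")
    } else absent <- c(absent, "trans_loop1", "alpha4")
    if (!is.null(wg))
        addRange("beta_meander", wg - 6L, wg + 12L, NA_integer_, "config")

    def <- .resolveOverlaps(do.call(rbind, rows))
    ## convert scan positions to author numbering
    if (!is.null(def) && nrow(def)) {
        def$start <- resnos[def$start]
        def$end <- resnos[def$end]
    }
    new("MotifDefinition", protein = NA_character_,
        ranges = if (is.null(def)) data.frame() else def,
        anchors = list(wg = if (is.null(wg)) NULL else resnos[wg]),
        absent = unique(absent))
}

## assign positions in priority order, then rebuild contiguous ranges
.resolveOverlaps <- function(ranges) {
    if (is.null(ranges) || nrow(ranges) == 0L) return(ranges)
    maxpos <- max(ranges$end)
    owner <- rep(NA_character_, maxpos)
    ranges$prio <- match(ranges$region, .REGION_PRIORITY)
    ranges <- ranges[order(ranges$prio, ranges$start), ]
    out <- list()
    for (i in seq_len(nrow(ranges))) {
        span <- ranges$start[i]:ranges$end[i]
        span <- span[is.na(owner[span])]
        if (!length(span)) next
        owner[span] <- ranges$region[i]
        ## contiguous runs
        breaks <- c(0L, which(diff(span) != 1L), length(span))
        for (b in seq_len(length(breaks) - 1L)) {
            seg <- span[(breaks[b] + 1L):breaks[b + 1L]]
            out[[length(out) + 1L]] <- data.frame(
                region = ranges$region[i], start = min(seg), end = max(seg),
                mismatches = ranges$mismatches[i], source = ranges$source[i],
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    res <- res[order(res$start), ]
    rownames(res) <- NULL
    res
}

#' Build a MotifDefinition from explicit ranges
#'
#' @param protein protein name.
#' @param regions named list/vector, region -> "start-end" (author numbering)
#'   or integer c(start, end).
#' @param wg position of the WG Trp (required when a beta_meander range is
#'   given and offsets are wanted).
#' @param catalyticThr optional position of the catalytic Thr.
#' @return a [MotifDefinition] (source "config").
#' @export
motifDefinition <- function(protein, regions, wg = NULL, catalyticThr = NULL) {
    rows <- lapply(names(regions), function(rg) {
        v <- regions[[rg]]
        if (is.character(v)) v <- as.integer(strsplit(v, "-")[[1]])
        if (!rg %in% .REGION_PRIORITY)
            stop("unknown region label: ", rg)
        data.frame(region = rg, start = v[1], end = v[2],
                   mismatches = NA_integer_, source = "config",
                   stringsAsFactors = FALSE)
    })
    ranges <- if (length(rows)) .resolveOverlaps(do.call(rbind, rows))
              else data.frame()
    new("MotifDefinition", protein = protein, ranges = ranges,
        anchors = list(wg = wg, catalytic_thr = catalyticThr),
        absent = character())
}

#' Read motif definitions from a YAML config
#'
#' Layout: top-level protein names, each with optional `wg` and
#' `catalytic_thr` anchors and a `regions` map of region -> "start-end"
#' in author numbering. A curated example for the yeast Cdc3/Cdc10 G dimer
#' ships at `system.file("extdata", "motif_config_yeast.yaml", package =
#' "septG")`.
#'
#' @param path YAML file path.
#' @return named list of [MotifDefinition] objects.
#' @export
readMotifConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    out <- lapply(names(cfg), function(p) {
        entry <- cfg[[p]]
        motifDefinition(p, entry$regions %||% list(),
                        wg = entry$wg, catalyticThr = entry$catalytic_thr)
    })
    setNames(out, names(cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Annotate residues with G-interface regions and WG-relative offsets
#'
#' Residues outside every range are labelled "other". For beta-meander
#' residues the signed offset relative to the WG Trp is reported (the WG Trp
#' itself has offset 0); offsets are computed from author numbering and are
#' therefore translation-invariant under renumbering.
#'
#' @param sequence amino-acid string or named character vector (names =
#'   author residue numbers); alternatively a [StructureModel] together with
#'   `chain`.
#' @param definition a [MotifDefinition].
#' @param chain chain id, when `sequence` is a model.
#' @return a [MotifAnnotation].
#' @export
annotateMotifs <- function(sequence, definition, chain = NULL) {
    stopifnot(is(definition, "MotifDefinition"))
    if (is(sequence, "StructureModel")) {
        if (is.null(chain)) chain <- chainIds(sequence)[1]
        sequence <- chainSequence(sequence, chain)
    }
    resnos <- if (!is.null(names(sequence))) as.integer(names(sequence)) else NULL
    chars <- .checkAASeq(sequence)
    if (is.null(resnos)) resnos <- seq_along(chars)

    rg <- motifRanges(definition)
    if (nrow(rg)) {
        if (any(rg$start < min(resnos)) || any(rg$end > max(resnos)))
            stop("definition ranges fall outside the sequence numbering")
    }
    region <- rep("other", length(chars))
    for (i in seq_len(nrow(rg)))
        region[resnos >= rg$start[i] & resnos <= rg$end[i]] <- rg$region[i]

    wg <- motifAnchors(definition)$wg
    if (any(region == "beta_meander") && is.null(wg))
        stop("beta_meander range present but no WG anchor in the definition")
    wg_offset <- rep(NA_integer_, length(chars))
    if (!is.null(wg))
        wg_offset[region == "beta_meander"] <-
            resnos[region == "beta_meander"] - as.integer(wg)
    if (!is.null(wg) && any(resnos == wg) && chars[resnos == wg] != "W" &&
        nrow(rg) && any(rg$source == "regex_scan"))
        warning("WG anchor residue is not Trp")

    tab <- data.frame(resno = resnos, aa = chars, region = region,
                      wg_offset = wg_offset, stringsAsFactors = FALSE)
    new("MotifAnnotation", table = tab, anchors = motifAnchors(definition),
        protein = definition@protein)
}

#' Presence of the catalytic Thr relative to a reference
#'
#' Globally aligns the query to a reference whose catalytic-Thr position is
#' known, and reports the query residue aligned to that column. The residue
#' is "absent" whenever it is not Thr; a gap at the catalytic column yields
#' status "unalignable" rather than a guess.
#'
#' @param query,reference amino-acid strings (or named vectors).
#' @param refThrPos position of the catalytic Thr in the reference
#'   (1-based, ungapped).
#' @param ... passed to [globalAlign()].
#' @return list(status = "present"/"absent"/"unalignable", residue, column).
#' @export
catalyticThrStatus <- function(query, reference, refThrPos, ...) {
    refChars <- .checkAASeq(reference)
    if (refThrPos < 1L || refThrPos > length(refChars))
        stop("refThrPos outside the reference sequence")
    if (refChars[refThrPos] != "T")
        warning("reference residue at the declared catalytic position is not Thr")
    aln <- globalAlign(paste(refChars, collapse = ""),
                       paste(.checkAASeq(query), collapse = ""), ...)
    ga <- strsplit(aln@alignedA, "")[[1]]
    gb <- strsplit(aln@alignedB, "")[[1]]
    col <- which(cumsum(ga != "-") == refThrPos & ga != "-")[1]
    res <- gb[col]
    if (res == "-")
        return(list(status = "unalignable", residue = NA_character_, column = col))
    list(status = if (res == "T") "present" else "absent",
         residue = res, column = col)
}

#' Write a MotifAnnotation as TSV
#' @param annotation a [MotifAnnotation].
#' @param path output path.
#' @export
writeAnnotationTsv <- function(annotation, path) {
    write.table(annotationTable(annotation), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
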