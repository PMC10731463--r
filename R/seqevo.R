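## seqevo module: pairwise identity, marker covariation, NJ trees.

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment (via Biostrings) under BLOSUM62 with
#' affine gap penalties; defaults are gap open 10, gap extend 0.5. Traceback
#' is deterministic.
#'
#' @param a,b amino-acid strings or named character vectors; standard 20
#'   letters plus X.
#' @param substitutionMatrix scoring matrix name or matrix (default
#'   "BLOSUM62").
#' @param gapOpening,gapExtension affine gap penalties (non-negative costs).
#' @param ids optional character(2) identifiers for display.
#' @return a [GlobalAlignment].
#' @export
globalAlign <- function(a, b, substitutionMatrix = "BLOSUM62",
                        gapOpening = 10, gapExtension = 0.5, ids = NULL) {
    sa <- paste(.checkAASeq(a), collapse = "")
    sb <- paste(.checkAASeq(b), collapse = "")
    if (!nzchar(sa) || !nzchar(sb)) stop("sequences must be non-empty")
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(sa), Biostrings::AAString(sb), type = "global",
        substitutionMatrix = substitutionMatrix,
        gapOpening = gapOpening, gapExtension = gapExtension)
    if (is.null(ids))
        ids <- c(if (length(a) == 1L && !is.null(names(a))) names(a) else "seqA",
                 if (length(b) == 1L && !is.null(names(b))) names(b) else "seqB")
    new("GlobalAlignment",
        alignedA = as.character(Biostrings::alignedPattern(pa)),
        alignedB = as.character(Biostrings::alignedSubject(pa)),
        score = Biostrings::score(pa), ids = ids,
        params = list(substitutionMatrix = if (is.character(substitutionMatrix))
                          substitutionMatrix else "custom",
                      gapOpening = gapOpening, gapExtension = gapExtension))
}

#' Percent identity of a pairwise alignment
#'
#' 100 x identical columns / denominator. The default denominator is the
#' alignment length (gapped columns count against identity); "shorter_seq"
#' divides by the shorter ungapped sequence instead. Symmetric in the two
#' sequences under both conventions.
#'
#' @param alignment a [GlobalAlignment], or a sequence (then `b` must be
#'   given and the pair is aligned first).
#' @param b optional second sequence.
#' @param denominator "alignment_length" (default) or "shorter_seq".
#' @param ... passed to [globalAlign()] when aligning.
#' @return percentage in `[0, 100]`.
#' @export
percentIdentity <- function(alignment, b = NULL,
                            denominator = c("alignment_length", "shorter_seq"),
                            ...) {
    denominator <- match.arg(denominator)
    if (!is(alignment, "GlobalAlignment")) {
        stopifnot(!is.null(b))
        alignment <- globalAlign(alignment, b, ...)
    }
    ga <- strsplit(alignment@alignedA, "")[[1]]
    gb <- strsplit(alignment@alignedB, "")[[1]]
    if (!length(ga)) stop("zero-length alignment")
    ident <- sum(ga == gb & ga != "-")
    den <- switch(denominator,
                  alignment_length = length(ga),
                  shorter_seq = min(sum(ga != "-"), sum(gb != "-")))
    100 * ident / den
}

## coerce MSA-ish input to a character matrix (rows = sequences)
.msaMatrix <- function(msa) {
    if (is(msa, "AAMultipleAlignment"))
        msa <- as.character(Biostrings::unmasked(msa))
    if (is(msa, "AAStringSet")) msa <- as.character(msa)
    if (is.matrix(msa)) return(msa)
    if (is.character(msa)) {
        if (length(unique(nchar(msa))) != 1L)
            stop("aligned sequences must have equal length")
        m <- do.call(rbind, strsplit(toupper(msa), ""))
        rownames(m) <- names(msa)
        return(m)
    }
    stop("unsupported MSA input")
}

#' Columns covarying with a binary marker (catalytic-Thr absence)
#'
#' The marker vector is TRUE for sequences whose residue at `markerColumn`
#' differs from `markerResidue` (Thr by default). For every other column the
#' residue identities are partitioned into two blocks in every possible way,
#' and the best matching coefficient -- the fraction of sequences on which
#' the partition indicator equals the marker -- is reported. Columns whose
#' coefficient is exactly 1 are listed as perfect. Constant columns are
#' excluded as uninformative; sequences gapped at a column are excluded from
#' that column's denominator, and sequences gapped at the marker column are
#' excluded throughout.
#'
#' @param msa an `AAMultipleAlignment`, aligned `AAStringSet`, character
#'   matrix, or character vector of equal-length gapped strings.
#' @param markerColumn column index of the marker (e.g. the catalytic-Thr
#'   column).
#' @param markerResidue single residue letter (default "T").
#' @return a [CovariationReport].
#' @export
covaryWithMarker <- function(msa, markerColumn, markerResidue = "T") {
    m <- .msaMatrix(msa)
    if (nrow(m) < 4L) stop("need at least 4 sequences")
    if (markerColumn < 1L || markerColumn > ncol(m))
        stop("marker column outside the alignment")
    mk <- m[, markerColumn]
    usable <- mk != "-"
    if (!any(usable)) stop("marker column is all gaps")
    marker <- mk != markerResidue
    marker[!usable] <- NA
    mUse <- marker[usable]
    if (length(unique(mUse)) < 2L) {
        return(new("CovariationReport", markerColumn = as.integer(markerColumn),
                   markerResidue = markerResidue, marker = marker,
                   columns = data.frame(), perfect = integer(),
                   degenerate = TRUE))
    }
    cols <- setdiff(seq_len(ncol(m)), markerColumn)
    rows <- lapply(cols, function(j) {
        res <- m[usable, j]
        ok <- res != "-"
        if (sum(ok) < 2L)
            return(data.frame(column = j, coefficient = NA_real_,
                              n_used = sum(ok), classes_true = NA_character_,
                              classes_false = NA_character_, excluded = TRUE,
                              reason = "too few ungapped sequences"))
        r <- res[ok]; mm <- mUse[ok]
        classes <- sort(unique(r))
        k <- length(classes)
        if (k < 2L)
            return(data.frame(column = j, coefficient = NA_real_,
                              n_used = length(r), classes_true = NA_character_,
                              classes_false = NA_character_, excluded = TRUE,
                              reason = "constant column"))
        best <- -1; bestSet <- NULL
        for (mask in seq_len(2L^k - 2L)) {
            inSet <- classes[bitwAnd(mask, 2L^(seq_len(k) - 1L)) > 0L]
            coeff <- mean((r %in% inSet) == mm)
            if (coeff > best + 1e-12) { best <- coeff; bestSet <- inSet }
        }
        data.frame(column = j, coefficient = best, n_used = length(r),
                   classes_true = paste(bestSet, collapse = ""),
                   classes_false = paste(setdiff(classes, bestSet), collapse = ""),
                   excluded = FALSE, reason = "", stringsAsFactors = FALSE)
    })
    columns <- do.call(rbind, rows)
    perfect <- columns$column[!columns$excluded &
                              abs(columns$coefficient - 1) < 1e-12]
    new("CovariationReport", markerColumn = as.integer(markerColumn),
        markerResidue = markerResidue, marker = marker, columns = columns,
        perfect = as.integer(perfect), degenerate = FALSE)
}

#' Pairwise distance matrix from global-alignment identity
#'
#' Distance is 1 minus fractional identity from [globalAlign()] /
#' [percentIdentity()].
#'
#' @param sequences named character vector or `AAStringSet` (unique ids
#'   required, at least 3 sequences).
#' @param ... passed to [percentIdentity()] (e.g. `denominator`).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distanceMatrix <- function(sequences, ...) {
    if (is(sequences, "AAStringSet")) sequences <- as.character(sequences)
    ids <- names(sequences)
    if (is.null(ids) || any(!nzchar(ids))) stop("sequences must be named")
    if (anyDuplicated(ids)) stop("duplicate sequence ids")
    n <- length(sequences)
    if (n < 3L) stop("need at least 3 sequences")
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        pid <- percentIdentity(sequences[[i]], sequences[[j]], ...)
        D[i, j] <- D[j, i] <- 1 - pid / 100
    }
    D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration with deterministic tie-breaking:
#' among minimal-Q pairs, the pair whose clusters contain the
#' lexicographically smallest labels is joined. Negative branch lengths are
#' clamped to 0 with a warning. The result is an unrooted `phylo` tree
#' (ape), so newick round-trips via [writeNewick()] / `ape::read.tree`.
#'
#' @param D symmetric distance matrix with labelled dimnames, n >= 3, no
#'   NAs.
#' @return an `ape::phylo` object.
#' @export
njTree <- function(D) {
    if (any(is.na(D))) stop("NA/NaN distances are not allowed")
    if (is.null(rownames(D))) stop("distance matrix must have labels")
    n <- nrow(D)
    if (n < 3L) stop("need at least 3 taxa")
    if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
    labels <- rownames(D)
    nwk <- labels            # newick substring per active cluster
    rep_ <- labels           # representative (smallest) label per cluster
    act <- seq_len(n)
    Dm <- D
    clamped <- FALSE
    fmt <- function(x) sprintf("%.10g", x)
    clamp <- function(x) {
        if (x < -1e-12) clamped <<- TRUE
        if (x < 1e-12) 0 else x
    }
    while (length(act) > 3L) {
        nn <- length(act)
        r <- rowSums(Dm)
        Q <- (nn - 2) * Dm - outer(r, r, "+")
        diag(Q) <- Inf
        qmin <- min(Q)
        cand <- which(Q - qmin <= 1e-12, arr.ind = TRUE)
        cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
        ## deterministic tie-break: smallest representative labels
        keyA <- pmin(rep_[cand[, 1]], rep_[cand[, 2]])
        keyB <- pmax(rep_[cand[, 1]], rep_[cand[, 2]])
        pick <- order(keyA, keyB)[1]
        i <- cand[pick, 1]; j <- cand[pick, 2]
        li <- clamp(Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2)))
        lj <- clamp(Dm[i, j] - (Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))))
        newNwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
        newRep <- min(rep_[i], rep_[j])
        dNew <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
        keep <- setdiff(seq_len(nn), c(i, j))
        Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dNew[keep]),
                    c(dNew[keep], 0))
        nwk <- c(nwk[keep], newNwk)
        rep_ <- c(rep_[keep], newRep)
        act <- seq_len(nn - 1L)
        rownames(Dm) <- colnames(Dm) <- NULL
    }
    ## final trifurcation (three-point formulas)
    d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
    l1 <- clamp((d12 + d13 - d23) / 2)
    l2 <- clamp((d12 + d23 - d13) / 2)
    l3 <- clamp((d13 + d23 - d12) / 2)
    if (clamped) warning("negative branch length(s) clamped to 0")
    txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(l1), nwk[2], fmt(l2),
                   nwk[3], fmt(l3))
    ape::read.tree(text = txt)
}

#' Write a tree in newick format
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @export
writeNewick <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}

#' Read protein sequences from FASTA
#' @param path FASTA file.
#' @return named character vector.
#' @export
readSequences <- function(path) {
    x <- Biostrings::readAAStringSet(path)
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    out
}

#' Read a multiple sequence alignment
#' @param path file path.
#' @param format "auto" (by extension), "fasta" or "clustal".
#' @return character matrix (rows = sequences).
#' @export
readMsa <- function(path, format = c("auto", "fasta", "clustal")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- if (ext %in% c("aln", "clustal", "clw")) "clustal" else "fasta"
    }
    msa <- Biostrings::readAAMultipleAlignment(path, format = format)
    .msaMatrix(msa)
}

#' Progressive (center-star) multiple alignment
#'
#' Aligns every sequence to the center sequence (the one minimising total
#' pairwise distance) and merges the pairwise alignments under the
#' "once a gap, always a gap" rule. Adequate for the small (around a dozen
#' sequences) alignments this package targets; use a dedicated MSA tool for
#' anything larger.
#'
#' @param sequences named character vector (>= 2 sequences).
#' @param ... passed to [globalAlign()].
#' @return character matrix of gapped sequences (rows = input order).
#' @export
alignSequences <- function(sequences, ...) {
    n <- length(sequences)
    stopifnot(n >= 2L, !is.null(names(sequences)))
    if (n == 2L) {
        aln <- globalAlign(sequences[[1]], sequences[[2]], ...)
        return(.msaMatrix(setNames(c(aln@alignedA, aln@alignedB),
                                   names(sequences))))
    }
    D <- distanceMatrix(sequences, ...)
    center <- which.min(rowSums(D))
    L <- nchar(sequences[[center]])
    others <- setdiff(seq_len(n), center)
    alns <- lapply(others, function(i)
        globalAlign(sequences[[center]], sequences[[i]], ...))
    ## gaps inserted before each center residue (positions 1..L, plus trailing)
    gapsBefore <- function(aln) {
        gc <- strsplit(aln@alignedA, "")[[1]]
        gb <- integer(L + 1L); k <- 1L; run <- 0L
        for (ch in gc) {
            if (ch == "-") run <- run + 1L
            else { gb[k] <- run; run <- 0L; k <- k + 1L }
        }
        gb[L + 1L] <- run
        gb
    }
    gbs <- lapply(alns, gapsBefore)
    master <- Reduce(pmax, gbs, accumulate = FALSE)
    padRow <- function(aln, gb) {
        gc <- strsplit(aln@alignedA, "")[[1]]
        gs <- strsplit(aln@alignedB, "")[[1]]
        out <- character(0); col <- 1L
        for (k in seq_len(L + 1L)) {
            out <- c(out, rep("-", master[k] - gb[k]))
            take <- gb[k] + (k <= L)  # gap block plus the center-residue column
            if (take > 0L) {
                out <- c(out, gs[col:(col + take - 1L)])
                col <- col + take
            }
        }
        paste(out, collapse = "")
    }
    centerRow <- {
        cc <- strsplit(sequences[[center]], "")[[1]]
        out <- character(0)
        for (k in seq_len(L + 1L)) {
            out <- c(out, rep("-", master[k]))
            if (k <= L) out <- c(out, cc[k])
        }
        paste(out, collapse = "")
    }
    rowsOut <- character(n)
    rowsOut[center] <- centerRow
    for (t in seq_along(others)) rowsOut[others[t]] <- padRow(alns[[t]], gbs[[t]])
    .msaMatrix(setNames(rowsOut, names(sequences)))
}

#' Distinct species among accession records
#'
#' Counts distinct organism names in an accession metadata table (e.g. the
#' per-accession organism annotations retrieved from a sequence database).
#'
#' @param metadata data.frame with columns `accession` and `organism`, or a
#'   path to a TSV file with those columns.
#' @return list(n_accessions, n_species, species).
#' @export
countDistinctSpecies <- function(metadata) {
    if (is.character(metadata)) metadata <- read.delim(metadata)
    stopifnot(all(c("accession", "organism") %in% names(metadata)))
    sp <- sort(unique(trimws(metadata$organism)))
    list(n_accessions = length(unique(metadata$accession)),
         n_species = length(sp), species = sp)
}
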