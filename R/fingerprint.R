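## fingerprint module: region x region contact matrices, interface diffs,
## Kabsch superposition and residue-residue distances.

#' Aggregate cross-chain hydrogen bonds into a region-by-region matrix
#'
#' Each cross-chain bond increments exactly one cell: (region of the residue
#' in the first chain) x (region of the residue in the second chain). Bond
#' input order does not affect the result. Bonds referencing residues not
#' covered by the annotations raise an error listing them; residues the
#' annotation labels "other" count in the "other" margin.
#'
#' @param hbonds bond table from [detectHBonds()].
#' @param annotA,annotB [MotifAnnotation] for the two chains.
#' @param chains character(2): chain ids of `annotA` and `annotB`.
#' @return a [ContactMatrix].
#' @export
buildFingerprint <- function(hbonds, annotA, annotB, chains) {
    stopifnot(is(annotA, "MotifAnnotation"), is(annotB, "MotifAnnotation"),
              length(chains) == 2L)
    b <- hbonds[hbonds$cross_chain &
                ((hbonds$donor_chain == chains[1] & hbonds$acceptor_chain == chains[2]) |
                 (hbonds$donor_chain == chains[2] & hbonds$acceptor_chain == chains[1])), ,
                drop = FALSE]
    lv <- .REGION_LEVELS
    counts <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
    lookup <- function(annot, resno) {
        t <- annotationTable(annot)
        i <- match(resno, t$resno)
        if (anyNA(i))
            stop("bond residue(s) absent from annotation: ",
                 paste(unique(resno[is.na(i)]), collapse = ", "))
        t$region[i]
    }
    pairs <- data.frame(resno_a = integer(), resname_a = character(),
                        region_a = character(), resno_b = integer(),
                        resname_b = character(), region_b = character())
    if (nrow(b)) {
        aFirst <- b$donor_chain == chains[1]
        resno_a <- ifelse(aFirst, b$donor_resno, b$acceptor_resno)
        resname_a <- ifelse(aFirst, b$donor_resname, b$acceptor_resname)
        resno_b <- ifelse(aFirst, b$acceptor_resno, b$donor_resno)
        resname_b <- ifelse(aFirst, b$acceptor_resname, b$donor_resname)
        region_a <- lookup(annotA, resno_a)
        region_b <- lookup(annotB, resno_b)
        for (i in seq_along(resno_a))
            counts[region_a[i], region_b[i]] <- counts[region_a[i], region_b[i]] + 1L
        pairs <- data.frame(resno_a = resno_a, resname_a = resname_a,
                            region_a = region_a, resno_b = resno_b,
                            resname_b = resname_b, region_b = region_b,
                            stringsAsFactors = FALSE)
        pairs <- pairs[order(pairs$resno_a, pairs$resno_b), ]
        rownames(pairs) <- NULL
    }
    new("ContactMatrix", counts = counts, pairs = pairs,
        chains = as.character(chains))
}

#' Residue correspondence between two sequences via global alignment
#'
#' Bijective on aligned non-gap columns; gapped positions are unmapped.
#' Substitutions are flagged rather than breaking the map, so point mutants
#' (e.g. a D182N structure) map residue-for-residue onto the wild type.
#'
#' @param seqA,seqB amino-acid strings or named vectors (names = author
#'   residue numbers).
#' @param warnIdentity warn when percent identity falls below this value
#'   (default 30), as a guard against aligning non-homologs.
#' @param ... passed to [globalAlign()].
#' @return data.frame(pos_a, pos_b, aa_a, aa_b, identical); positions are in
#'   each sequence's own numbering.
#' @export
correspondenceMap <- function(seqA, seqB, warnIdentity = 30, ...) {
    numA <- if (!is.null(names(seqA))) as.integer(names(seqA)) else NULL
    numB <- if (!is.null(names(seqB))) as.integer(names(seqB)) else NULL
    a <- paste(.checkAASeq(seqA), collapse = "")
    b <- paste(.checkAASeq(seqB), collapse = "")
    if (is.null(numA)) numA <- seq_len(nchar(a))
    if (is.null(numB)) numB <- seq_len(nchar(b))
    aln <- globalAlign(a, b, ...)
    if (percentIdentity(aln) < warnIdentity)
        warning(sprintf("sequences are only %.1f%% identical; the map may be unreliable",
                        percentIdentity(aln)))
    ga <- strsplit(aln@alignedA, "")[[1]]
    gb <- strsplit(aln@alignedB, "")[[1]]
    ia <- cumsum(ga != "-"); ib <- cumsum(gb != "-")
    keep <- ga != "-" & gb != "-"
    data.frame(pos_a = numA[ia[keep]], pos_b = numB[ib[keep]],
               aa_a = ga[keep], aa_b = gb[keep],
               identical = ga[keep] == gb[keep])
}

.bondKeys <- function(bonds, granularity) {
    if (nrow(bonds) == 0L) return(character())
    if (granularity == "atom") {
        e1 <- paste(bonds$donor_chain, bonds$donor_resno, bonds$donor_atom)
        e2 <- paste(bonds$acceptor_chain, bonds$acceptor_resno, bonds$acceptor_atom)
    } else {
        e1 <- paste(bonds$donor_chain, bonds$donor_resno)
        e2 <- paste(bonds$acceptor_chain, bonds$acceptor_resno)
    }
    ## unordered endpoint pair, robust to donor/acceptor swaps between models
    paste(pmin(e1, e2), pmax(e1, e2), sep = " | ")
}

## remap residue numbers of a bond table through chain-wise correspondence
.remapBonds <- function(bonds, map) {
    if (is.null(map) || nrow(bonds) == 0L) return(list(bonds = bonds, unmapped = bonds[0, ]))
    if (is.data.frame(map)) map <- list(map)  # same map for all chains
    remapCol <- function(chain, resno) {
        out <- rep(NA_integer_, length(resno))
        for (ch in unique(chain)) {
            m <- if (!is.null(names(map)) && ch %in% names(map)) map[[ch]]
                 else map[[1]]
            sel <- chain == ch
            out[sel] <- m$pos_b[match(resno[sel], m$pos_a)]
        }
        out
    }
    dn <- remapCol(bonds$donor_chain, bonds$donor_resno)
    an <- remapCol(bonds$acceptor_chain, bonds$acceptor_resno)
    unmapped <- bonds[is.na(dn) | is.na(an), , drop = FALSE]
    ok <- !(is.na(dn) | is.na(an))
    b <- bonds[ok, , drop = FALSE]
    b$donor_resno <- dn[ok]; b$acceptor_resno <- an[ok]
    list(bonds = b, unmapped = unmapped)
}

#' Differential interface contacts between two bond sets
#'
#' Contacts are compared at residue-pair granularity by default (atom
#' identity ignored), after remapping the first set's residue numbers into
#' the second set's numbering through `map`. A contact is "unchanged" iff
#' its (mapped) unordered residue pair occurs in both sets; otherwise it is
#' lost (only in A) or gained (only in B). `diffFingerprints(a, b)` mirrors
#' `diffFingerprints(b, a)` with gained and lost swapped.
#'
#' @param bondsA,bondsB bond tables from [detectHBonds()].
#' @param map optional correspondence from [correspondenceMap()] (A -> B
#'   numbering); a named list of maps keyed by chain id, or a single map
#'   applied to every chain; NULL for identical numbering. Bonds whose
#'   residues are unmappable are reported in the `unmapped` attribute.
#' @param granularity "residue" (default) or "atom".
#' @return a [ContactDiff].
#' @export
diffFingerprints <- function(bondsA, bondsB, map = NULL,
                             granularity = c("residue", "atom")) {
    granularity <- match.arg(granularity)
    rm <- .remapBonds(bondsA, map)
    keysA <- .bondKeys(rm$bonds, granularity)
    keysB <- .bondKeys(bondsB, granularity)
    uA <- !duplicated(keysA); uB <- !duplicated(keysB)
    bA <- rm$bonds[uA, , drop = FALSE]; kA <- keysA[uA]
    bB <- bondsB[uB, , drop = FALSE]; kB <- keysB[uB]
    lost <- bA[!(kA %in% kB), , drop = FALSE]
    gained <- bB[!(kB %in% kA), , drop = FALSE]
    rownames(lost) <- rownames(gained) <- NULL
    out <- new("ContactDiff", gained = gained, lost = lost,
               unchanged = sum(kA %in% kB), granularity = granularity)
    attr(out, "unmapped") <- rm$unmapped
    out
}

## Kabsch: optimal rotation/translation of P onto Q (n x 3 matrices)
.kabsch <- function(P, Q) {
    cp <- colMeans(P); cq <- colMeans(Q)
    H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
    s <- svd(H)
    d <- sign(det(tcrossprod(s$v, s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    list(R = R, t = cq - as.vector(R %*% cp))
}

#' Superpose one model onto another (Kabsch least squares)
#'
#' Pairs atoms of the fit selection (CA by default) between the two models
#' by chain, residue number and atom name -- optionally after remapping
#' model A residue numbers through a [correspondenceMap()] -- and finds the
#' rigid rotation/translation minimising RMSD over that selection. The fit
#' is then applied to ALL atoms of model A, and per-residue displacements
#' against model B (maximum heavy-atom displacement and side-chain centroid
#' displacement) are reported for every residue with matched atoms.
#'
#' @param modelA,modelB [StructureModel]s.
#' @param selection atom names used for the fit (default "CA").
#' @param chains optional chain ids restricting the fit selection.
#' @param map optional correspondence (A -> B numbering), as in
#'   [diffFingerprints()].
#' @return a [SuperpositionResult].
#' @export
superpose <- function(modelA, modelB, selection = "CA", chains = NULL,
                      map = NULL) {
    stopifnot(is(modelA, "StructureModel"), is(modelB, "StructureModel"))
    a <- atoms(modelA); b <- atoms(modelB)
    if (!is.null(map)) {
        if (is.data.frame(map)) map <- list(map)
        for (ch in unique(a$chain)) {
            m <- if (!is.null(names(map)) && ch %in% names(map)) map[[ch]]
                 else map[[1]]
            sel <- a$chain == ch
            a$resno[sel] <- m$pos_b[match(a$resno[sel], m$pos_a)]
        }
        a <- a[!is.na(a$resno), , drop = FALSE]
    }
    akey <- paste(a$chain, a$resno, a$insert, a$name, sep = "\r")
    bkey <- paste(b$chain, b$resno, b$insert, b$name, sep = "\r")
    fitA <- a$name %in% selection & a$elem != "H"
    if (!is.null(chains)) fitA <- fitA & a$chain %in% chains
    common <- intersect(akey[fitA], bkey)
    if (length(common) < 3L)
        stop("need at least 3 paired atoms for a superposition, got ",
             length(common))
    P <- as.matrix(a[match(common, akey), c("x", "y", "z")])
    Q <- as.matrix(b[match(common, bkey), c("x", "y", "z")])
    fit <- .kabsch(P, Q)
    Pfit <- sweep(tcrossprod(P, fit$R), 2, fit$t, "+")
    rmsd <- sqrt(mean(rowSums((Pfit - Q)^2)))

    ## displacements for all matched atoms after applying the fit
    matched <- akey %in% bkey & a$elem != "H"
    A <- as.matrix(a[matched, c("x", "y", "z")])
    Afit <- sweep(tcrossprod(A, fit$R), 2, fit$t, "+")
    B <- as.matrix(b[match(akey[matched], bkey), c("x", "y", "z")])
    disp <- sqrt(rowSums((Afit - B)^2))
    am <- a[matched, ]
    am$disp <- disp
    am$side <- !(am$name %in% .BACKBONE)
    key <- paste(am$chain, am$resno, am$insert, sep = "\r")
    rows <- lapply(split(am, factor(key, levels = unique(key))), function(g) {
        sc <- g[g$side, , drop = FALSE]
        scDisp <- NA_real_
        if (nrow(sc)) {
            i <- match(paste(sc$chain, sc$resno, sc$insert, sc$name, sep = "\r"),
                       akey[matched])
            c1 <- colMeans(Afit[i, , drop = FALSE])
            c2 <- colMeans(B[i, , drop = FALSE])
            scDisp <- sqrt(sum((c1 - c2)^2))
        }
        data.frame(chain = g$chain[1], resno = g$resno[1],
                   resname = g$resname[1], max_heavy = max(g$disp),
                   sidechain_centroid = scDisp, stringsAsFactors = FALSE)
    })
    dtab <- do.call(rbind, rows)
    rownames(dtab) <- NULL
    new("SuperpositionResult", rotation = fit$R, translation = fit$t,
        rmsd = rmsd, displacements = dtab)
}

#' Minimum heavy-atom distance between two residues
#'
#' @param model a [StructureModel].
#' @param resA,resB lists with `chain` and `resno` (and optional `insert`).
#' @param mode "min_heavy" (all heavy atoms) or "sidechain_min" (side-chain
#'   heavy atoms; falls back to min_heavy with a warning when a residue has
#'   no side chain).
#' @return distance in Angstrom.
#' @export
residueDistance <- function(model, resA, resB,
                            mode = c("min_heavy", "sidechain_min")) {
    mode <- match.arg(mode)
    a <- atoms(model)
    pick <- function(r) {
        ins <- r$insert %||% ""
        sel <- a[a$chain == r$chain & a$resno == r$resno &
                 (a$insert == ins | (!nzchar(ins))) & a$elem != "H", ,
                 drop = FALSE]
        if (nrow(sel) == 0L)
            stop(sprintf("residue %s:%s not found or has no heavy atoms",
                         r$chain, r$resno))
        if (mode == "sidechain_min") {
            sc <- sel[!(sel$name %in% .BACKBONE), , drop = FALSE]
            if (nrow(sc) == 0L)
                warning(sprintf("residue %s:%s has no side chain; using all heavy atoms",
                                r$chain, r$resno))
            else sel <- sc
        }
        as.matrix(sel[, c("x", "y", "z")])
    }
    A <- pick(resA); B <- pick(resB)
    min(sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2 +
             outer(A[, 3], B[, 3], "-")^2))
}

#' Export a ContactMatrix as TSV and/or JSON
#'
#' @param x a [ContactMatrix].
#' @param tsv,json optional output paths.
#' @param dropEmpty drop all-zero rows/columns in the TSV.
#' @export
writeFingerprint <- function(x, tsv = NULL, json = NULL, dropEmpty = TRUE) {
    stopifnot(is(x, "ContactMatrix"))
    if (!is.null(tsv)) {
        m <- contactCounts(x)
        if (dropEmpty && sum(m) > 0) {
            m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
        }
        write.table(cbind(region = rownames(m), as.data.frame(m)), tsv,
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(json))
        jsonlite::write_json(
            list(chains = x@chains, counts = contactCounts(x),
                 pairs = contactPairs(x)),
            json, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    invisible(x)
}
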