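## synthetic_data module: seeded fixtures with machine-checkable ground truth.
## Residue geometry is idealized (no rotamer library): the detectors consume
## only distances and angles, so chemically plausible internal coordinates
## are sufficient.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.glyBackbone <- function(resno, chain, x0, y0, resname = "GLY") {
    data.frame(name = c("N", "CA", "C", "O"),
               resname = resname, chain = chain, resno = resno,
               x = c(x0 - 1.0, x0, x0 + 1.0, x0 + 1.0),
               y = c(y0 - 1.0, y0, y0 - 1.0, y0 - 2.2),
               z = 0, het = FALSE, stringsAsFactors = FALSE)
}

#' Synthetic dimer with planted inter-chain hydrogen bonds
#'
#' Two chains (A and B) of minimal-geometry residues facing each other
#' across a wide gap. At `k` seeded positions a Ser OG donor (chain A) and
#' an Asp OD1 acceptor (chain B) are placed at a donor-acceptor distance of
#' 2.9 A with a linear (180 deg) acceptor-antecedent proxy angle, optionally
#' perturbed by Gaussian noise of standard deviation `sigma`. Every
#' inter-chain heavy-atom pair not belonging to a planted donor/acceptor
#' group is farther than 6 A (the acceptor's covalent antecedent necessarily
#' sits within ~4.5 A of the donor; it is neither a donor nor an acceptor,
#' so the planted bond list remains the exact detector ground truth).
#'
#' @param k number of planted bonds (<= nResidues).
#' @param nResidues residues per chain.
#' @param sigma coordinate noise on the planted donor/acceptor atoms, A.
#' @param seed integer seed; the fixture is bit-reproducible under it.
#' @param pdbPath optional path; when given the model is also written as PDB.
#' @return list(model = [StructureModel], truth = list(bonds, seed, k,
#'   sigma)); `truth$bonds` has one row per planted bond.
#' @export
makeHbondDimer <- function(k, nResidues = 20L, sigma = 0, seed = 1L,
                           pdbPath = NULL) {
    if (k > nResidues)
        stop("cannot pack ", k, " bonds into ", nResidues,
             " residues per chain; increase nResidues")
    stopifnot(sigma >= 0)
    set.seed(seed)
    planted <- sort(sample.int(nResidues, k))
    rows <- list()
    for (i in seq_len(nResidues)) {
        x0 <- 10 * i
        isP <- i %in% planted
        a <- .glyBackbone(i, "A", x0, 0, if (isP) "SER" else "GLY")
        b <- .glyBackbone(i, "B", x0, 9.5, if (isP) "ASP" else "GLY")
        b$y <- 19 - b$y  # mirror chain B so carbonyls point away from the gap
        if (isP) {
            a <- rbind(a, data.frame(name = c("CB", "OG"), resname = "SER",
                                     chain = "A", resno = i,
                                     x = x0, y = c(1.5, 3.2), z = 0,
                                     het = FALSE))
            b <- rbind(b, data.frame(name = c("CB", "CG", "OD1"),
                                     resname = "ASP", chain = "B", resno = i,
                                     x = x0, y = c(8.4, 7.6, 6.1), z = 0,
                                     het = FALSE))
        }
        rows[[length(rows) + 1L]] <- a
        rows[[length(rows) + 1L]] <- b
    }
    a <- do.call(rbind, rows)
    if (sigma > 0) {
        pert <- a$name %in% c("OG", "OD1")
        a[pert, c("x", "y", "z")] <- a[pert, c("x", "y", "z")] +
            matrix(rnorm(3 * sum(pert), 0, sigma), ncol = 3)
    }
    model <- structureModel(a, metadata = list(source = "makeHbondDimer",
                                               seed = seed))
    truth <- list(bonds = data.frame(donor_chain = rep("A", k),
                                     donor_resno = planted,
                                     donor_atom = rep("OG", k),
                                     acceptor_chain = rep("B", k),
                                     acceptor_resno = planted,
                                     acceptor_atom = rep("OD1", k)),
                  k = k, sigma = sigma, seed = seed)
    if (!is.null(pdbPath)) {
        writeStructure(model, pdbPath)
        jsonlite::write_json(truth, paste0(pdbPath, ".truth.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    list(model = model, truth = truth)
}

#' Synthetic ligand pocket with planted contact distances
#'
#' A single-atom guanine-nucleotide ligand at the origin surrounded by
#' minimal residues on a spherical spiral: each listed contact residue's
#' nearest heavy atom (CA) is placed exactly at its specified distance from
#' the ligand; all other residues sit at 6 A (beyond a 4.5-A exclusion
#' shell).
#'
#' @param contactResidues integer residue numbers to plant as contacts.
#' @param distances one distance (A) per contact residue, in (0, 4).
#' @param nResidues total residues (>= max(contactResidues)).
#' @param seed integer seed.
#' @param pdbPath optional PDB output path (+ JSON truth sidecar).
#' @return list(model, ligand = [LigandPose], truth).
#' @export
makeLigandPocket <- function(contactResidues, distances,
                             nResidues = max(c(contactResidues, 6L)) + 4L,
                             seed = 1L, pdbPath = NULL) {
    stopifnot(length(contactResidues) == length(distances))
    if (length(distances) && (any(distances <= 0) || any(distances >= 4)))
        stop("planted contact distances must lie in (0, 4) A")
    if (anyDuplicated(contactResidues)) stop("duplicate contact residues")
    set.seed(seed)
    n <- nResidues
    ## deterministic golden-angle spiral directions
    idx <- seq_len(n)
    zc <- 1 - 2 * (idx - 0.5) / n
    th <- pi * (1 + sqrt(5)) * idx
    dirs <- cbind(sqrt(1 - zc^2) * cos(th), sqrt(1 - zc^2) * sin(th), zc)
    r <- rep(6.0, n)
    r[contactResidues] <- distances
    rows <- lapply(idx, function(i) {
        ca <- r[i] * dirs[i, ]
        out <- ca + 1.4 * dirs[i, ]  # N, C, O strictly farther out
        data.frame(name = c("CA", "N", "C", "O"), resname = "GLY",
                   chain = "A", resno = i,
                   x = c(ca[1], out[1] + 0.4, out[1] - 0.4, out[1]),
                   y = c(ca[2], out[2], out[2], out[2] + 0.8),
                   z = c(ca[3], out[3], out[3], out[3] - 0.8),
                   het = FALSE, stringsAsFactors = FALSE)
    })
    lig <- data.frame(name = "PA", resname = "GTP", chain = "L", resno = 999L,
                      x = 0, y = 0, z = 0, het = TRUE, elem = "P",
                      stringsAsFactors = FALSE)
    prot <- do.call(rbind, rows)
    prot$elem <- guessElement(prot$name)
    model <- structureModel(rbind(prot, lig),
                            metadata = list(source = "makeLigandPocket",
                                            seed = seed))
    truth <- list(contacts = data.frame(resno = contactResidues,
                                        distance = distances),
                  seed = seed)
    if (!is.null(pdbPath)) {
        writeStructure(model, pdbPath)
        jsonlite::write_json(truth, paste0(pdbPath, ".truth.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    list(model = model, ligand = ligands(model)[[1]], truth = truth)
}

## does a column's residue partition reproduce the marker exactly?
## (independent of the covariation scanner: a column is perfect iff every
## residue class is homogeneous with respect to the marker)
.columnPerfect <- function(col, marker) {
    if (length(unique(col)) < 2L) return(FALSE)
    all(vapply(split(marker, col), function(v) length(unique(v)) == 1L,
               logical(1)))
}

#' Synthetic MSA with planted marker covariation
#'
#' Builds an ungapped alignment with a marker column (Thr present/absent), a
#' set of planted perfectly covarying columns, optional noisy columns where
#' a stated number of sequences is flipped, and uniformly random background
#' columns (re-drawn if they accidentally covary perfectly or mirror the
#' planted flips).
#'
#' @param nSeq number of sequences (>= 4).
#' @param nCol number of columns.
#' @param thrAbsent logical vector (length nSeq) or indices: which sequences
#'   lack the catalytic Thr.
#' @param markerColumn column index of the marker (default 5).
#' @param perfectColumns indices of planted perfectly covarying columns.
#' @param noisyColumns named integer vector: column index -> number of
#'   flipped sequences (each flip count must be < nSeq).
#' @param seed integer seed.
#' @param fastaPath optional FASTA output path (+ JSON truth sidecar).
#' @return list(msa = character matrix, truth).
#' @export
makeCovaryingMSA <- function(nSeq = 12L, nCol = 40L, thrAbsent,
                             markerColumn = 5L, perfectColumns = integer(),
                             noisyColumns = integer(), seed = 1L,
                             fastaPath = NULL) {
    if (nSeq < 4L) stop("need at least 4 sequences")
    if (is.numeric(thrAbsent) && !is.logical(thrAbsent))
        thrAbsent <- seq_len(nSeq) %in% thrAbsent
    stopifnot(length(thrAbsent) == nSeq)
    noisyIdx <- if (length(noisyColumns)) as.integer(names(noisyColumns))
                else integer()
    if (length(noisyColumns) && any(noisyColumns >= nSeq))
        stop("flip count must be smaller than the number of sequences")
    special <- c(markerColumn, perfectColumns, noisyIdx)
    if (anyDuplicated(special)) stop("marker/perfect/noisy columns overlap")
    if (any(special > nCol)) stop("column index beyond nCol")
    set.seed(seed)
    m <- matrix("", nSeq, nCol,
                dimnames = list(sprintf("seq%02d", seq_len(nSeq)), NULL))
    nonThr <- setdiff(.AA20, "T")
    m[, markerColumn] <- ifelse(thrAbsent, sample(c("R", "Q", "S"), nSeq,
                                                  replace = TRUE), "T")
    twoLetters <- function() sample(nonThr, 2L)
    plant <- function(col) {
        ab <- twoLetters()
        m[, col] <<- ifelse(thrAbsent, ab[1], ab[2])
        ab
    }
    for (col in perfectColumns) plant(col)
    flips <- list()
    for (t in seq_along(noisyIdx)) {
        col <- noisyIdx[t]; f <- noisyColumns[t]
        ab <- plant(col)
        fl <- sample.int(nSeq, f)
        m[fl, col] <- ifelse(m[fl, col] == ab[1], ab[2], ab[1])
        flips[[as.character(col)]] <- sort(fl)
    }
    background <- setdiff(seq_len(nCol), special)
    for (col in background) {
        repeat {
            v <- sample(nonThr, nSeq, replace = TRUE)
            if (!.columnPerfect(v, thrAbsent) &&
                (length(unique(v)) != 2L ||
                 !any(vapply(flips, function(fl)
                     .columnPerfect(v, xor(thrAbsent, seq_len(nSeq) %in% fl)),
                     logical(1)))))
                break
        }
        m[, col] <- v
    }
    truth <- list(markerColumn = markerColumn, thrAbsent = thrAbsent,
                  perfectColumns = sort(as.integer(perfectColumns)),
                  noisyColumns = if (length(noisyIdx))
                      data.frame(column = noisyIdx,
                                 flips = as.integer(noisyColumns),
                                 coefficient = pmax(noisyColumns,
                                                    nSeq - noisyColumns) / nSeq)
                      else data.frame(),
                  seed = seed)
    if (!is.null(fastaPath)) {
        seqs <- apply(m, 1L, paste, collapse = "")
        writeLines(paste0(">", names(seqs), "\n", seqs), fastaPath)
        jsonlite::write_json(truth, paste0(fastaPath, ".truth.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    list(msa = m, truth = truth)
}

#' Sequence pair with a specified percent identity
#'
#' The second sequence is the first with `round((1 - target/100) * length)`
#' substitutions at seeded positions; no indels, so a global alignment is
#' gapless and the realised identity is exact.
#'
#' @param length sequence length.
#' @param targetIdentity percent identity in (0, 100].
#' @param seed integer seed.
#' @return list(sequences = named character(2), truth = list(positions,
#'   n_substitutions, expected_identity, seed)).
#' @export
makeIdentityPair <- function(length = 100L, targetIdentity = 80, seed = 1L) {
    stopifnot(targetIdentity > 0, targetIdentity <= 100)
    set.seed(seed)
    s1 <- sample(.AA20, length, replace = TRUE)
    nSub <- round((1 - targetIdentity / 100) * length)
    pos <- if (nSub) sort(sample.int(length, nSub)) else integer()
    s2 <- s1
    for (p in pos) s2[p] <- sample(setdiff(.AA20, s1[p]), 1L)
    list(sequences = c(a = paste(s1, collapse = ""),
                       b = paste(s2, collapse = "")),
         truth = list(positions = pos, n_substitutions = nSub,
                      expected_identity = 100 * (length - nSub) / length,
                      seed = seed))
}
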