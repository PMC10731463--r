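## Independent oracles used across the suite. These deliberately re-derive
## results by the most naive route available (double loops, exhaustive
## enumeration, score-only dynamic programming) so that they share no code
## path with the package implementations they check.

## ---- brute-force hydrogen-bond evaluation --------------------------------

bruteForceHBonds <- function(model, criteria = hbondCriteria()) {
    a <- atoms(model)
    tab <- donorAcceptorTable()
    dmax <- criteria@baseDaMax + criteria@distanceTolerance
    dhaMin <- criteria@baseDhaMin - criteria@angleTolerance
    daaMin <- criteria@baseDaaMin - criteria@angleTolerance
    angle <- function(p, v, q) {
        u1 <- p - v; u2 <- q - v
        acos(min(1, max(-1, sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))))) * 180 / pi
    }
    ## plain vectors: data.frame row access is far too slow in a double loop
    chain <- a$chain; resno <- a$resno; insert <- a$insert; name <- a$name
    resname <- a$resname; elem <- a$elem; X <- a$x; Y <- a$y; Z <- a$z
    n <- length(chain)
    key2 <- function(r, at) paste(r, at, sep = "\r")
    donKeys <- key2(tab$resname[tab$role == "donor"],
                    tab$atom[tab$role == "donor"])
    accTab <- tab[tab$role == "acceptor", ]
    accIdx <- match(key2(resname, name), key2(accTab$resname, accTab$atom))
    isDon <- key2(resname, name) %in% donKeys & elem != "H"
    isAcc <- !is.na(accIdx) & elem != "H"
    keys <- character()
    for (i in which(isDon)) {
        hsel <- which(elem == "H" & chain == chain[i] & resno == resno[i] &
                      insert == insert[i])
        if (length(hsel)) {
            hd <- sqrt((X[hsel] - X[i])^2 + (Y[hsel] - Y[i])^2 +
                       (Z[hsel] - Z[i])^2)
            hsel <- hsel[hd <= 1.25]
        }
        dp <- c(X[i], Y[i], Z[i])
        for (j in which(isAcc)) {
            if (chain[i] == chain[j] && resno[i] == resno[j] &&
                insert[i] == insert[j]) next
            if (chain[i] == chain[j] && abs(resno[i] - resno[j]) == 1L &&
                name[i] == "N" && name[j] == "O") next
            d <- sqrt((X[i] - X[j])^2 + (Y[i] - Y[j])^2 + (Z[i] - Z[j])^2)
            if (d > dmax || d < 1.8) next
            ap <- c(X[j], Y[j], Z[j])
            ok <- TRUE
            if (length(hsel)) {
                best <- max(vapply(hsel, function(k)
                    angle(dp, c(X[k], Y[k], Z[k]), ap), numeric(1)))
                ok <- best >= dhaMin
            } else {
                anteName <- accTab$antecedent[accIdx[j]]
                ak <- which(chain == chain[j] & resno == resno[j] &
                            insert == insert[j] & name == anteName)
                if (length(ak) == 1L)
                    ok <- angle(dp, ap, c(X[ak], Y[ak], Z[ak])) >= daaMin
            }
            if (ok)
                keys <- c(keys, paste(chain[i], resno[i], name[i], "->",
                                      chain[j], resno[j], name[j]))
        }
    }
    sort(keys)
}

hbondKeys <- function(bonds) {
    if (nrow(bonds) == 0L) return(character())
    sort(paste(bonds$donor_chain, bonds$donor_resno, bonds$donor_atom, "->",
               bonds$acceptor_chain, bonds$acceptor_resno, bonds$acceptor_atom))
}

## random two-chain model built from template residues at random positions
randomContactModel <- function(seed, nPerChain = 12L, box = 18) {
    set.seed(seed)
    templates <- list(
        SER = c("N", "CA", "C", "O", "CB", "OG"),
        ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
        LYS = c("N", "CA", "C", "O", "CE", "NZ"),
        ARG = c("N", "CA", "C", "O", "NE", "NH1", "NH2"),
        GLY = c("N", "CA", "C", "O"))
    rows <- list()
    for (ch in c("A", "B")) {
        off <- if (ch == "A") 0 else runif(1, 2, 6)
        for (i in seq_len(nPerChain)) {
            rn <- sample(names(templates), 1L)
            ctr <- runif(3, 0, box) + c(off, 0, 0)
            nm <- templates[[rn]]
            xyz <- matrix(rnorm(3 * length(nm), 0, 1.6), ncol = 3) +
                rep(ctr, each = length(nm))
            df <- data.frame(name = nm, resname = rn, chain = ch, resno = i,
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                             het = FALSE, stringsAsFactors = FALSE)
            ## occasionally give the backbone amide an explicit hydrogen
            if (runif(1) < 0.3) {
                np <- as.numeric(df[df$name == "N", c("x", "y", "z")])
                u <- rnorm(3); u <- u / sqrt(sum(u^2))
                df <- rbind(df, data.frame(name = "H", resname = rn,
                                           chain = ch, resno = i,
                                           x = np[1] + u[1], y = np[2] + u[2],
                                           z = np[3] + u[3], het = FALSE))
            }
            rows[[length(rows) + 1L]] <- df
        }
    }
    a <- do.call(rbind, rows)
    a$elem <- ifelse(a$name == "H", "H", guessElement(a$name))
    structureModel(a)
}

## ---- score-only affine-gap global alignment (Gotoh) ----------------------

gotohScore <- function(a, b, gapOpen = 10, gapExt = 0.5) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    S <- get("BLOSUM62", envir = environment())
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    NEG <- -1e9
    M <- matrix(NEG, n + 1, m + 1); Ix <- matrix(NEG, n + 1, m + 1)
    Iy <- matrix(NEG, n + 1, m + 1)
    M[1, 1] <- 0
    for (i in 2:(n + 1)) Ix[i, 1] <- -gapOpen - (i - 1) * gapExt
    for (j in 2:(m + 1)) Iy[1, j] <- -gapOpen - (j - 1) * gapExt
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
        M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) +
            S[A[i - 1], B[j - 1]]
        Ix[i, j] <- max(M[i - 1, j] - gapOpen - gapExt, Ix[i - 1, j] - gapExt)
        Iy[i, j] <- max(M[i, j - 1] - gapOpen - gapExt, Iy[i, j - 1] - gapExt)
    }
    max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

## ---- exhaustive covariation partition search -----------------------------

covariationOracle <- function(column, marker) {
    ok <- column != "-"
    r <- column[ok]; m <- marker[ok]
    classes <- sort(unique(r))
    if (length(classes) < 2L) return(NA_real_)
    best <- -1
    for (sz in seq_len(length(classes) - 1L)) {
        sets <- combn(classes, sz, simplify = FALSE)
        for (S in sets)
            best <- max(best, mean((r %in% S) == m))
    }
    best
}

## ---- misc ----------------------------------------------------------------

randomRotation <- function() {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
}

## background alphabet free of the letters the motif patterns key on, so a
## planted motif is the unique exact hit
motifFreeBackground <- function(n) {
    ## no G/K/S/T/D/W (motif letters) and no A/L/R (G4/G5 wildcard-position
    ## letters), so planted motifs are the unique minimal-mismatch hits
    sample(c("E", "F", "H", "I", "M", "P", "Q", "V", "Y", "C"),
           n, replace = TRUE)
}

plantMotifs <- function(seed, len = 160L) {
    set.seed(seed)
    s <- motifFreeBackground(len)
    pos <- list(G1 = 30L + sample.int(6L, 1L), G3 = 70L + sample.int(6L, 1L),
                G4 = 95L + sample.int(6L, 1L), G5 = 115L + sample.int(6L, 1L),
                WG = 130L + sample.int(6L, 1L))
    s[pos$G1:(pos$G1 + 7L)] <- strsplit("GAGESGKS", "")[[1]]
    s[pos$G3:(pos$G3 + 3L)] <- strsplit("DTAG", "")[[1]]
    s[pos$G4:(pos$G4 + 3L)] <- strsplit("AKVD", "")[[1]]
    s[pos$G5:(pos$G5 + 2L)] <- strsplit("SAK", "")[[1]]
    s[pos$WG:(pos$WG + 1L)] <- c("W", "G")
    list(seq = paste(s, collapse = ""), pos = pos)
}
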