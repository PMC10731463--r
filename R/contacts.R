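## contacts module: geometric hydrogen bonds, ligand proximity, vdW clashes.

#' Hydrogen-bond acceptance criteria
#'
#' Defaults combine a conventional geometric base (donor-acceptor <= 3.3 A,
#' donor-H-acceptor >= 120 deg, donor-acceptor-antecedent >= 90 deg) with the
#' relaxations used throughout the package's interface analyses: +1.0 A on
#' the distance ceiling and -20 deg on the angle floors. All five values are
#' exposed so other conventions can be matched.
#'
#' @param baseDaMax donor-acceptor heavy-atom distance ceiling (A).
#' @param baseDhaMin donor-H-acceptor angle floor (deg), used when the donor
#'   has an attached hydrogen.
#' @param baseDaaMin donor-acceptor-antecedent proxy angle floor (deg), used
#'   for hydrogen-free structures.
#' @param distanceTolerance relaxation added to `baseDaMax` (A).
#' @param angleTolerance relaxation subtracted from the angle floors (deg).
#' @return an [HBondCriteria] object.
#' @export
hbondCriteria <- function(baseDaMax = 3.3, baseDhaMin = 120, baseDaaMin = 90,
                          distanceTolerance = 1.0, angleTolerance = 20.0) {
    new("HBondCriteria", baseDaMax = baseDaMax, baseDhaMin = baseDhaMin,
        baseDaaMin = baseDaaMin, distanceTolerance = distanceTolerance,
        angleTolerance = angleTolerance)
}

.daRow <- function(resname, atom, role, antecedent = NA_character_) {
    data.frame(resname = resname, atom = atom, role = role,
               antecedent = antecedent, stringsAsFactors = FALSE)
}

#' Donor/acceptor template table
#'
#' One row per (residue, atom, role). Covers the 20 standard amino acids
#' (backbone amide donor -- except proline -- and carbonyl acceptor, plus
#' side-chain donors/acceptors) and the guanine/inosine/xanthosine nucleotide
#' ligands (phosphate and ribose oxygens as acceptors, base N1/N2 and ribose
#' hydroxyls as donors). Atoms listed in the template but absent from a given
#' residue (e.g. the gamma-phosphate oxygens of GDP) are simply never
#' matched.
#'
#' @return data.frame(resname, atom, role, antecedent); `antecedent` is the
#'   covalently attached heavy atom used for the acceptor-side proxy angle.
#' @export
donorAcceptorTable <- function() {
    aa <- names(.AA321)
    rows <- list()
    ## backbone: amide N donates (except Pro), carbonyl O accepts
    for (r in aa) {
        if (r != "PRO") rows[[length(rows) + 1L]] <- .daRow(r, "N", "donor")
        rows[[length(rows) + 1L]] <- .daRow(r, "O", "acceptor", "C")
        rows[[length(rows) + 1L]] <- .daRow(r, "OXT", "acceptor", "C")
    }
    side <- list(
        SER = list(d = c(OG = NA),  a = c(OG = "CB")),
        THR = list(d = c(OG1 = NA), a = c(OG1 = "CB")),
        TYR = list(d = c(OH = NA),  a = c(OH = "CZ")),
        CYS = list(d = c(SG = NA),  a = NULL),
        ASN = list(d = c(ND2 = NA), a = c(OD1 = "CG")),
        GLN = list(d = c(NE2 = NA), a = c(OE1 = "CD")),
        ASP = list(d = NULL,        a = c(OD1 = "CG", OD2 = "CG")),
        GLU = list(d = NULL,        a = c(OE1 = "CD", OE2 = "CD")),
        HIS = list(d = c(ND1 = NA, NE2 = NA),
                   a = c(ND1 = "CG", NE2 = "CD2")),
        LYS = list(d = c(NZ = NA),  a = NULL),
        ARG = list(d = c(NE = NA, NH1 = NA, NH2 = NA), a = NULL),
        TRP = list(d = c(NE1 = NA), a = NULL),
        MET = list(d = NULL,        a = c(SD = "CG")))
    for (r in names(side)) {
        for (at in names(side[[r]]$d))
            rows[[length(rows) + 1L]] <- .daRow(r, at, "donor")
        a <- side[[r]]$a
        for (at in names(a))
            rows[[length(rows) + 1L]] <- .daRow(r, at, "acceptor", unname(a[at]))
    }
    ## guanine-style nucleotides (one template reused across the series)
    nuc <- c("GTP", "GDP", "GMP", "5GP", "GNP", "GCP", "G", "GSN",
             "IMP", "IDP", "ITP", "NOS", "XMP", "XDP", "XTP")
    nucAcc <- c(O6 = "C6", N7 = "C5", N3 = "C4", "O4'" = "C4'",
                "O2'" = "C2'", "O3'" = "C3'", "O5'" = "C5'",
                O1A = "PA", O2A = "PA", O3A = "PA",
                O1B = "PB", O2B = "PB", O3B = "PB",
                O1G = "PG", O2G = "PG", O3G = "PG")
    nucDon <- c("N1", "N2", "O2'", "O3'")
    for (r in nuc) {
        for (at in names(nucAcc))
            rows[[length(rows) + 1L]] <- .daRow(r, at, "acceptor", unname(nucAcc[at]))
        for (at in nucDon)
            rows[[length(rows) + 1L]] <- .daRow(r, at, "donor")
    }
    do.call(rbind, rows)
}

#' Tag model atoms with donor/acceptor roles
#'
#' Residue names absent from the template are reported with a warning (once,
#' listing the names) and excluded rather than silently skipped.
#'
#' @param model a [StructureModel].
#' @param table template from [donorAcceptorTable()].
#' @return list with data.frames `donors` and `acceptors`; both carry atom
#'   coordinates, `acceptors` also carries antecedent coordinates (NA when
#'   the antecedent atom is missing).
#' @export
assignDonorsAcceptors <- function(model, table = donorAcceptorTable()) {
    a <- atoms(model)
    unknown <- setdiff(unique(a$resname[a$elem != "H"]), unique(table$resname))
    unknown <- setdiff(unknown, c("HOH", "WAT", "MG", "NA", "CL", "K", "ZN", "CA"))
    if (length(unknown))
        warning("residue name(s) without donor/acceptor template, excluded: ",
                paste(unknown, collapse = ", "))
    a$row <- seq_len(nrow(a))
    key <- function(res, at) paste(res, at, sep = "\r")
    tab <- table
    don <- tab[tab$role == "donor", ]
    acc <- tab[tab$role == "acceptor", ]
    donors <- a[key(a$resname, a$name) %in% key(don$resname, don$atom), ]
    acceptors <- a[key(a$resname, a$name) %in% key(acc$resname, acc$atom), ]
    ## antecedent lookup for acceptors
    if (nrow(acceptors)) {
        ante <- acc$antecedent[match(key(acceptors$resname, acceptors$name),
                                     key(acc$resname, acc$atom))]
        reskey <- paste(a$chain, a$resno, a$insert, a$name, sep = "\r")
        idx <- match(paste(acceptors$chain, acceptors$resno, acceptors$insert,
                           ante, sep = "\r"), reskey)
        acceptors$ante_name <- ante
        acceptors$ax <- a$x[idx]; acceptors$ay <- a$y[idx]; acceptors$az <- a$z[idx]
    }
    ## attached hydrogens for donors (same residue, within 1.25 A)
    donors$has_h <- rep(FALSE, nrow(donors))
    hyd <- a[a$elem == "H", ]
    hlist <- vector("list", nrow(donors))
    if (nrow(hyd) && nrow(donors)) {
        for (i in seq_len(nrow(donors))) {
            d <- donors[i, ]
            cand <- hyd[hyd$chain == d$chain & hyd$resno == d$resno &
                        hyd$insert == d$insert, , drop = FALSE]
            if (nrow(cand)) {
                dd <- sqrt((cand$x - d$x)^2 + (cand$y - d$y)^2 + (cand$z - d$z)^2)
                cand <- cand[dd <= 1.25, , drop = FALSE]
                if (nrow(cand)) {
                    donors$has_h[i] <- TRUE
                    hlist[[i]] <- cand[, c("x", "y", "z")]
                }
            }
        }
    }
    list(donors = donors, acceptors = acceptors, hydrogens = hlist)
}

.angleDeg <- function(a, v, b) {
    ## angle at vertex v between points a and b, degrees
    u1 <- a - v; u2 <- b - v
    cosang <- sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))
    acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect hydrogen bonds from geometry
#'
#' A donor-acceptor pair is reported iff the heavy-atom distance is at most
#' `baseDaMax + distanceTolerance` and the angle test passes: donor-H-acceptor
#' >= `baseDhaMin - angleTolerance` when the donor carries a hydrogen,
#' otherwise the donor-acceptor-antecedent proxy angle >=
#' `baseDaaMin - angleTolerance` (structures without hydrogens, e.g.
#' predicted models, use only the proxy). Pairs within one residue, and
#' backbone amide-to-carbonyl pairs of sequence-adjacent residues (covalently
#' constrained), are excluded. Output is deterministically ordered by
#' (donor, acceptor).
#'
#' @param model a [StructureModel].
#' @param criteria an [HBondCriteria].
#' @param chains optional chain pair; only bonds between these two chains
#'   are returned.
#' @param crossOnly return only inter-chain bonds.
#' @param table donor/acceptor template.
#' @return data.frame with one row per bond: donor_chain, donor_resno,
#'   donor_insert, donor_resname, donor_atom, acceptor_* likewise,
#'   distance, angle, angle_kind ("dha" or "proxy" or "none"), cross_chain.
#' @export
detectHBonds <- function(model, criteria = hbondCriteria(), chains = NULL,
                         crossOnly = FALSE, table = donorAcceptorTable()) {
    stopifnot(is(model, "StructureModel"), is(criteria, "HBondCriteria"))
    validObject(criteria)
    da <- assignDonorsAcceptors(model, table)
    don <- da$donors; acc <- da$acceptors
    empty <- data.frame(donor_chain = character(), donor_resno = integer(),
                        donor_insert = character(), donor_resname = character(),
                        donor_atom = character(), acceptor_chain = character(),
                        acceptor_resno = integer(), acceptor_insert = character(),
                        acceptor_resname = character(), acceptor_atom = character(),
                        distance = numeric(), angle = numeric(),
                        angle_kind = character(), cross_chain = logical())
    if (nrow(don) == 0L || nrow(acc) == 0L) return(empty)
    dmax <- criteria@baseDaMax + criteria@distanceTolerance
    dhaMin <- criteria@baseDhaMin - criteria@angleTolerance
    daaMin <- criteria@baseDaaMin - criteria@angleTolerance
    ## all donor x acceptor distances (sizes here are modest)
    dx <- outer(don$x, acc$x, "-"); dy <- outer(don$y, acc$y, "-")
    dz <- outer(don$z, acc$z, "-")
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    hits <- which(dist <= dmax & dist >= 1.8, arr.ind = TRUE)
    if (nrow(hits) == 0L) return(empty)
    out <- vector("list", nrow(hits))
    for (h in seq_len(nrow(hits))) {
        i <- hits[h, 1]; j <- hits[h, 2]
        d <- don[i, ]; ac <- acc[j, ]
        sameRes <- d$chain == ac$chain & d$resno == ac$resno & d$insert == ac$insert
        if (sameRes) next
        ## covalently constrained neighbours: backbone N(i+1)...O(i) etc.
        if (d$chain == ac$chain && abs(d$resno - ac$resno) == 1L &&
            d$name == "N" && ac$name == "O") next
        dp <- c(d$x, d$y, d$z); ap <- c(ac$x, ac$y, ac$z)
        ang <- NA_real_; kind <- "none"; ok <- TRUE
        if (d$has_h) {
            hs <- da$hydrogens[[i]]
            angs <- apply(as.matrix(hs), 1L,
                          function(hxyz) .angleDeg(dp, hxyz, ap))
            ang <- max(angs); kind <- "dha"
            ok <- ang >= dhaMin
        } else if (!is.na(ac$ax)) {
            ang <- .angleDeg(dp, ap, c(ac$ax, ac$ay, ac$az))
            kind <- "proxy"
            ok <- ang >= daaMin
        }  ## no H and no antecedent: accept on distance alone
        if (!ok) next
        out[[h]] <- data.frame(
            donor_chain = d$chain, donor_resno = d$resno,
            donor_insert = d$insert, donor_resname = d$resname,
            donor_atom = d$name,
            acceptor_chain = ac$chain, acceptor_resno = ac$resno,
            acceptor_insert = ac$insert, acceptor_resname = ac$resname,
            acceptor_atom = ac$name,
            distance = dist[i, j], angle = ang, angle_kind = kind,
            cross_chain = d$chain != ac$chain, stringsAsFactors = FALSE)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    if (!is.null(chains)) {
        stopifnot(length(chains) == 2L)
        res <- res[(res$donor_chain == chains[1] & res$acceptor_chain == chains[2]) |
                   (res$donor_chain == chains[2] & res$acceptor_chain == chains[1]), ]
    }
    if (crossOnly) res <- res[res$cross_chain, ]
    res <- res[order(res$donor_chain, res$donor_resno, res$donor_insert,
                     res$donor_atom, res$acceptor_chain, res$acceptor_resno,
                     res$acceptor_insert, res$acceptor_atom), ]
    rownames(res) <- NULL
    attr(res, "criteria") <- criteria
    res
}

## resolve a ligand argument (LigandPose or name) against a model
.resolveLigand <- function(model, ligand) {
    if (is(ligand, "LigandPose")) return(ligand)
    ll <- ligands(model)
    if (is.character(ligand)) ll <- Filter(function(l) l@ligandName == ligand, ll)
    if (!length(ll)) stop("no matching ligand found in model")
    ll[[1]]
}

#' Residues contacting a ligand within a distance cutoff
#'
#' One record per residue with any heavy atom within `cutoff` of any ligand
#' heavy atom. `kind` is "hbond" when the geometric detector also reports a
#' hydrogen bond between that residue and the ligand, else "proximity".
#'
#' @param model a [StructureModel] (may contain the ligand as HETATM).
#' @param ligand a [LigandPose], or a ligand name to look up in `model`.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.0).
#' @param criteria [HBondCriteria] used for the `kind` classification.
#' @return data.frame(chain, resno, insert, resname, min_distance, kind),
#'   ordered by chain/resno.
#' @export
ligandContacts <- function(model, ligand, cutoff = 4.0,
                           criteria = hbondCriteria()) {
    stopifnot(is(model, "StructureModel"))
    lig <- .resolveLigand(model, ligand)
    la <- atoms(lig); la <- la[la$elem != "H", , drop = FALSE]
    if (nrow(la) == 0L) stop("ligand has no heavy atoms")
    a <- atoms(model)
    ## drop the ligand's own residue from the environment
    own <- a$chain == lig@parent$chain & a$resno == lig@parent$resno &
        a$insert == lig@parent$insert & a$resname == lig@ligandName
    env <- a[!own & a$elem != "H", , drop = FALSE]
    out <- data.frame(chain = character(), resno = integer(),
                      insert = character(), resname = character(),
                      min_distance = numeric(), kind = character())
    if (nrow(env) == 0L || cutoff <= 0) return(out)
    d <- sqrt(outer(env$x, la$x, "-")^2 + outer(env$y, la$y, "-")^2 +
              outer(env$z, la$z, "-")^2)
    mind <- apply(d, 1L, min)
    env$mind <- mind
    hit <- env[env$mind <= cutoff, , drop = FALSE]
    if (nrow(hit) == 0L) return(out)
    key <- paste(hit$chain, hit$resno, hit$insert, sep = "\r")
    per <- lapply(split(hit, factor(key, levels = unique(key))), function(g)
        data.frame(chain = g$chain[1], resno = g$resno[1], insert = g$insert[1],
                   resname = g$resname[1], min_distance = min(g$mind),
                   stringsAsFactors = FALSE))
    res <- do.call(rbind, per)
    ## classify: does the detector report residue--ligand hydrogen bonds?
    comp <- structureModel(rbind(a[!own, , drop = FALSE], atoms(lig)),
                           metadata = modelMetadata(model))
    hb <- detectHBonds(comp, criteria = criteria)
    ligSide <- function(ch, rn, ins)
        ch == lig@parent$chain & rn == lig@parent$resno & ins == lig@parent$insert
    hbres <- character()
    if (nrow(hb)) {
        dl <- ligSide(hb$donor_chain, hb$donor_resno, hb$donor_insert)
        al <- ligSide(hb$acceptor_chain, hb$acceptor_resno, hb$acceptor_insert)
        hbres <- c(paste(hb$acceptor_chain, hb$acceptor_resno,
                         hb$acceptor_insert, sep = "\r")[dl],
                   paste(hb$donor_chain, hb$donor_resno,
                         hb$donor_insert, sep = "\r")[al])
    }
    res$kind <- ifelse(paste(res$chain, res$resno, res$insert, sep = "\r") %in%
                       hbres, "hbond", "proximity")
    res <- res[order(res$chain, res$resno, res$insert), ]
    rownames(res) <- NULL
    res
}

#' Van der Waals radii (Bondi-style)
#'
#' @return named numeric vector, element symbol to radius in Angstrom.
#' @export
vdwRadii <- function() {
    c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
      F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, MG = 1.73, NA. = 2.27,
      K = 2.75, CA = 2.31, ZN = 1.39, FE = 1.63, MN = 1.73, SE = 1.90)
}

#' Steric clashes between a model and a ligand pose
#'
#' A clash is a (protein heavy atom, ligand heavy atom) pair whose distance
#' is smaller than the sum of van der Waals radii minus `overlapThreshold`.
#'
#' @param model a [StructureModel].
#' @param ligand a [LigandPose] or ligand name present in the model.
#' @param overlapThreshold minimum overlap (vdW sum - distance) in Angstrom
#'   reported as a clash; default 0.4.
#' @param radii element radius table.
#' @return data.frame(chain, resno, insert, resname, atom, ligand_atom,
#'   distance, overlap) sorted by overlap, largest first.
#' @export
clashCheck <- function(model, ligand, overlapThreshold = 0.4,
                       radii = vdwRadii()) {
    stopifnot(is(model, "StructureModel"))
    lig <- .resolveLigand(model, ligand)
    la <- atoms(lig); la <- la[la$elem != "H", , drop = FALSE]
    a <- atoms(model)
    own <- a$chain == lig@parent$chain & a$resno == lig@parent$resno &
        a$insert == lig@parent$insert & a$resname == lig@ligandName
    env <- a[!own & a$elem != "H", , drop = FALSE]
    names(radii)[names(radii) == "NA."] <- "NA"
    unknown <- setdiff(unique(c(env$elem, la$elem)), names(radii))
    if (length(unknown))
        stop("no van der Waals radius for element(s): ",
             paste(unknown, collapse = ", "))
    out <- data.frame(chain = character(), resno = integer(),
                      insert = character(), resname = character(),
                      atom = character(), ligand_atom = character(),
                      distance = numeric(), overlap = numeric())
    if (nrow(env) == 0L) return(out)
    d <- sqrt(outer(env$x, la$x, "-")^2 + outer(env$y, la$y, "-")^2 +
              outer(env$z, la$z, "-")^2)
    vsum <- outer(unname(radii[env$elem]), unname(radii[la$elem]), "+")
    ov <- vsum - d
    hits <- which(ov >= overlapThreshold, arr.ind = TRUE)
    if (nrow(hits) == 0L) return(out)
    res <- data.frame(chain = env$chain[hits[, 1]], resno = env$resno[hits[, 1]],
                      insert = env$insert[hits[, 1]],
                      resname = env$resname[hits[, 1]],
                      atom = env$name[hits[, 1]], ligand_atom = la$name[hits[, 2]],
                      distance = d[hits], overlap = ov[hits],
                      stringsAsFactors = FALSE)
    res <- res[order(-res$overlap, res$chain, res$resno, res$atom), ]
    rownames(res) <- NULL
    res
}

#' Write a bond table as TSV
#'
#' Fixed 6-decimal formatting so that repeated runs are byte-identical.
#'
#' @param bonds data.frame from [detectHBonds()].
#' @param path output path.
#' @export
writeContactsTsv <- function(bonds, path) {
    b <- bonds
    for (cc in c("distance", "angle"))
        b[[cc]] <- formatC(b[[cc]], format = "f", digits = 6)
    write.table(b, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
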