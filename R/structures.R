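## structures module: parse, represent, select from and write models.

.BACKBONE <- c("N", "CA", "C", "O", "OXT")

#' Construct a StructureModel from an atom table
#'
#' Mostly used internally and by the synthetic-data generators; end users
#' normally call [readStructure()].
#'
#' @param atoms data.frame with (at least) name, resname, chain, resno and
#'   x/y/z columns; serial, alt, insert, elem, het, occ are filled in when
#'   missing (elements are derived from atom names).
#' @param metadata named list stored alongside the atoms.
#' @return a [StructureModel].
#' @export
structureModel <- function(atoms, metadata = list()) {
    if (!is.data.frame(atoms) || nrow(atoms) == 0L)
        stop("empty structure: an atom table with at least one row is required")
    a <- atoms
    if (is.null(a$serial)) a$serial <- seq_len(nrow(a))
    if (is.null(a$alt)) a$alt <- ""
    if (is.null(a$insert)) a$insert <- ""
    if (is.null(a$elem)) a$elem <- guessElement(a$name)
    if (is.null(a$het)) a$het <- FALSE
    if (is.null(a$occ)) a$occ <- 1
    a$resno <- as.integer(a$resno)
    a$serial <- as.integer(a$serial)
    a <- a[, .ATOM_COLS]
    rownames(a) <- NULL
    new("StructureModel", atoms = a, metadata = metadata)
}

#' Guess the element symbol from a PDB atom name
#'
#' Handles the common protein/nucleotide heavy atoms and hydrogens; two-letter
#' elements must be supplied explicitly via the `elem` column.
#'
#' @param name character vector of atom names (e.g. "CA", "OD1", "PG").
#' @return character vector of element symbols.
#' @export
guessElement <- function(name) {
    nm <- toupper(trimws(name))
    first <- substring(gsub("^[0-9']+", "", nm), 1L, 1L)
    ifelse(first %in% c("C", "N", "O", "S", "P", "H"), first, first)
}

#' Known small-molecule ligand codes
#'
#' The guanine-nucleotide series and related nucleosides/nucleotides that the
#' package recognises as ligands when extracting [LigandPose] objects from a
#' parsed structure, plus a few aliases. HETATM residues outside this set
#' (waters, ions) are kept in the model but not exposed as ligands.
#'
#' @return character vector of three-letter (or shorter) residue codes.
#' @export
ligandDictionary <- function() {
    c("GTP", "GDP", "GMP", "5GP", "GSN", "GNP", "GCP", "G",
      "IMP", "IDP", "ITP", "NOS", "XMP", "XDP", "XTP",
      "ATP", "ADP", "AMP", "CTP", "CDP", "LIG")
}

## collapse alternate locations: keep highest occupancy, ties by alphabetical
## alt-loc id
.collapseAltLocs <- function(a) {
    if (all(a$alt %in% c("", " "))) return(a)
    key <- paste(a$chain, a$resno, a$insert, a$name, sep = "\r")
    ord <- order(key, -a$occ, a$alt)
    a <- a[ord, ]
    a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$name, sep = "\r")), ]
    a[order(a$serial), ]
}

#' Read a structure from a PDB or mmCIF file
#'
#' Parses all ATOM and HETATM records (first model of multi-model files).
#' Alternate locations are collapsed to the highest-occupancy conformer
#' (ties broken by alphabetical alt-loc id); insertion codes are preserved;
#' hydrogens are kept if present but never required. HETATM residues whose
#' code appears in [ligandDictionary()] are retrievable as [LigandPose]
#' objects via [ligands()].
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (by file extension).
#' @param keepAltLocs keep all alternate locations instead of collapsing.
#' @return a [StructureModel].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          keepAltLocs = FALSE) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
    }
    parsed <- tryCatch(
        if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                             verbose = FALSE)
        else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
        error = function(e) stop(sprintf("cannot parse '%s' as %s: %s",
                                         path, format, conditionMessage(e)),
                                 call. = FALSE))
    at <- parsed$atom
    if (is.null(at) || nrow(at) == 0L)
        stop("empty structure: no ATOM/HETATM records in ", path)
    blank <- function(v) { v <- as.character(v); v[is.na(v)] <- ""; v }
    elem <- blank(at$elesy)
    elem[!nzchar(elem)] <- guessElement(at$elety[!nzchar(elem)])
    a <- data.frame(serial = as.integer(at$eleno),
                    name = as.character(at$elety),
                    alt = blank(at$alt),
                    resname = as.character(at$resid),
                    chain = blank(at$chain),
                    resno = as.integer(at$resno),
                    insert = blank(at$insert),
                    elem = toupper(elem),
                    x = at$x, y = at$y, z = at$z,
                    het = at$type == "HETATM",
                    occ = ifelse(is.na(at$o), 1, at$o),
                    stringsAsFactors = FALSE)
    a$chain[!nzchar(a$chain)] <- " "
    if (!keepAltLocs) a <- .collapseAltLocs(a)
    if (anyDuplicated(a$serial)) a$serial <- seq_len(nrow(a))
    structureModel(a, metadata = list(source = path, format = format,
                                      title = paste(parsed$header, collapse = " ")))
}

#' Write a StructureModel to a PDB file
#'
#' Round-trips through [readStructure()] to coordinate precision (1e-3 A,
#' the PDB fixed-width format).
#'
#' @param model a [StructureModel].
#' @param path output file path.
#' @param format only "pdb" is supported.
#' @return invisibly, `path`.
#' @export
writeStructure <- function(model, path, format = "pdb") {
    stopifnot(is(model, "StructureModel"))
    format <- match.arg(format, "pdb")
    a <- atoms(model)
    if (nrow(a) == 0L) stop("refusing to write an empty model")
    if (nrow(a) > 99999L)
        stop("PDB format overflow: ", nrow(a), " atoms exceed the 99999 limit")
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = ifelse(a$het, "HETATM", "ATOM"),
                     resno = a$resno, resid = a$resname,
                     eleno = seq_len(nrow(a)), elety = a$name,
                     chain = ifelse(nzchar(trimws(a$chain)), a$chain, " "),
                     insert = ifelse(nzchar(a$insert), a$insert, ""),
                     alt = ifelse(nzchar(a$alt), a$alt, ""),
                     o = a$occ, b = rep(0, nrow(a)),
                     elesy = a$elem)
    invisible(path)
}

#' Select a sub-model by chain, residue range and/or atom names
#'
#' Selecting everything returns an identical model; selection is idempotent.
#'
#' @param model a [StructureModel].
#' @param chains optional character vector of chain ids (error if unknown).
#' @param resno optional integer vector of residue numbers to keep (author
#'   numbering), applied per selected chain.
#' @param atomNames optional character vector of atom names, or one of the
#'   shorthands "backbone" / "sidechain" / "heavy".
#' @param het keep HETATM records (default TRUE).
#' @return a [StructureModel] containing the selected atoms.
#' @export
selectAtoms <- function(model, chains = NULL, resno = NULL, atomNames = NULL,
                        het = TRUE) {
    stopifnot(is(model, "StructureModel"))
    a <- atoms(model)
    keep <- rep(TRUE, nrow(a))
    if (!is.null(chains)) {
        unknown <- setdiff(chains, unique(a$chain))
        if (length(unknown))
            stop(sprintf("unknown chain id(s) %s; available: %s",
                         paste(unknown, collapse = ","),
                         paste(unique(a$chain), collapse = ",")))
        keep <- keep & a$chain %in% chains
    }
    if (!is.null(resno)) keep <- keep & a$resno %in% resno
    if (!is.null(atomNames)) {
        keep <- keep & switch(atomNames[1],
            backbone  = a$name %in% .BACKBONE,
            sidechain = !(a$name %in% .BACKBONE) & a$elem != "H",
            heavy     = a$elem != "H",
            a$name %in% atomNames)
    }
    if (!het) keep <- keep & !a$het
    if (!any(keep)) stop("selection is empty")
    structureModel(a[keep, , drop = FALSE], metadata = modelMetadata(model))
}

#' Extract ligand poses from a model
#'
#' @param model a [StructureModel].
#' @param dictionary residue codes treated as ligands.
#' @return list of [LigandPose] objects (possibly empty).
#' @export
ligands <- function(model, dictionary = ligandDictionary()) {
    a <- atoms(model)
    lig <- a[a$het & a$resname %in% dictionary, , drop = FALSE]
    if (nrow(lig) == 0L) return(list())
    key <- paste(lig$chain, lig$resno, lig$insert, lig$resname, sep = "\r")
    lapply(split(lig, factor(key, levels = unique(key))), function(g) {
        new("LigandPose", ligandName = g$resname[1], atoms = g,
            parent = list(chain = g$chain[1], resno = g$resno[1],
                          insert = g$insert[1]))
    }) |> unname()
}

.AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")

.AA123 <- setNames(names(.AA321), .AA321)

#' One-letter sequence of a chain
#'
#' @param model a [StructureModel].
#' @param chain chain id.
#' @return named character vector of one-letter codes ("X" for non-standard
#'   residues), names are author residue numbers.
#' @export
chainSequence <- function(model, chain) {
    r <- residues(selectAtoms(model, chains = chain, het = FALSE))
    aa <- unname(.AA321[r$resname])
    aa[is.na(aa)] <- "X"
    setNames(aa, r$resno)
}
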