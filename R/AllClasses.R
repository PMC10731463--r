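#' @import methods
#' @importFrom stats setNames rnorm runif sd
#' @importFrom utils combn head read.delim write.table
NULL

## canonical column layout of the atom table used throughout the package
.ATOM_COLS <- c("serial", "name", "alt", "resname", "chain", "resno",
                "insert", "elem", "x", "y", "z", "het", "occ")

.REGION_LEVELS <- c("G1", "G2", "G3", "G4", "G5",
                    "trans_loop1", "alpha4", "beta_meander", "other")

#' StructureModel: chains/residues/atoms with 3-D coordinates
#'
#' A light S4 container for a macromolecular model. Atoms live in a single
#' data.frame (one row per atom) with author chain ids and residue numbers;
#' coordinates are in Angstrom. Use [readStructure()] to create one from a
#' PDB/mmCIF file and [atoms()], [chainIds()], [ligands()] to access it.
#'
#' @slot atoms data.frame with columns serial, name, alt, resname, chain,
#'   resno, insert, elem, x, y, z, het, occ.
#' @slot metadata list; typically `source` (file or id) and `title`.
#' @export
setClass("StructureModel",
         representation(atoms = "data.frame", metadata = "list"),
         prototype(metadata = list()))

setValidity("StructureModel", function(object) {
    a <- object@atoms
    msg <- character()
    if (!all(.ATOM_COLS %in% names(a)))
        msg <- c(msg, paste("atom table must have columns:",
                            paste(setdiff(.ATOM_COLS, names(a)), collapse = ", ")))
    else {
        if (nrow(a) < 1L) msg <- c(msg, "empty structure: no atoms")
        if (nrow(a) > 0L && !all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
            msg <- c(msg, "non-finite coordinates")
        if (anyDuplicated(a$serial)) msg <- c(msg, "duplicate atom serial numbers")
        if (nrow(a) > 0L && any(!nzchar(a$elem)))
            msg <- c(msg, "empty element symbols")
    }
    if (length(msg)) msg else TRUE
})

#' LigandPose: a small-molecule ligand and its atoms
#'
#' @slot ligandName identifier drawn from [ligandDictionary()] (e.g. "GTP").
#' @slot atoms atom table (same layout as [StructureModel]).
#' @slot parent list with `chain`, `resno`, `insert` of the parent residue.
#' @export
setClass("LigandPose",
         representation(ligandName = "character", atoms = "data.frame",
                        parent = "list"))

setValidity("LigandPose", function(object) {
    if (nrow(object@atoms) < 1L) return("ligand must have at least one atom")
    if (!nzchar(object@ligandName)) return("empty ligand name")
    TRUE
})

#' HBondCriteria: geometric hydrogen-bond acceptance criteria
#'
#' Base criteria plus the relaxation tolerances applied on top of them. A
#' donor--acceptor pair is accepted when the heavy-atom distance is at most
#' `baseDaMax + distanceTolerance` and the angle test passes: donor-H-acceptor
#' at least `baseDhaMin - angleTolerance` when an attached hydrogen exists,
#' otherwise the donor-acceptor-antecedent proxy angle at least
#' `baseDaaMin - angleTolerance`.
#'
#' @slot baseDaMax donor-acceptor heavy-atom distance ceiling, Angstrom.
#' @slot baseDhaMin donor-H-acceptor angle floor, degrees (H present).
#' @slot baseDaaMin donor-acceptor-antecedent proxy angle floor, degrees.
#' @slot distanceTolerance Angstrom added to `baseDaMax` (default 1.0).
#' @slot angleTolerance degrees subtracted from the angle floors (default 20).
#' @export
setClass("HBondCriteria",
         representation(baseDaMax = "numeric", baseDhaMin = "numeric",
                        baseDaaMin = "numeric", distanceTolerance = "numeric",
                        angleTolerance = "numeric"))

setValidity("HBondCriteria", function(object) {
    v <- c(object@baseDaMax, object@baseDhaMin, object@baseDaaMin,
           object@distanceTolerance, object@angleTolerance)
    if (length(v) != 5L || any(!is.finite(v)))
        return("all criteria fields must be finite numbers")
    if (object@baseDaMax <= 0 || object@baseDhaMin <= 0 || object@baseDaaMin <= 0)
        return("base criteria must be positive")
    if (object@distanceTolerance < 0 || object@angleTolerance < 0)
        return("tolerances must be non-negative")
    TRUE
})

#' MotifDefinition: residue ranges of G-interface regions for one protein
#'
#' @slot protein protein name the ranges refer to.
#' @slot ranges data.frame(region, start, end, mismatches, source) in author
#'   numbering; `source` is "regex_scan" or "config".
#' @slot anchors list; `wg` (position of the WG Trp) and optionally
#'   `catalytic_thr`.
#' @slot absent character vector of regions that were scanned for but not
#'   found.
#' @export
setClass("MotifDefinition",
         representation(protein = "character", ranges = "data.frame",
                        anchors = "list", absent = "character"),
         prototype(protein = NA_character_, anchors = list(),
                   absent = character()))

setValidity("MotifDefinition", function(object) {
    r <- object@ranges
    if (nrow(r) == 0L) return(TRUE)
    if (!all(c("region", "start", "end") %in% names(r)))
        return("ranges must have region/start/end columns")
    if (any(r$end < r$start)) return("ranges must span at least one residue")
    ## non-overlap across regions
    pos <- unlist(Map(seq.int, r$start, r$end))
    if (anyDuplicated(pos)) return("region ranges overlap")
    TRUE
})

#' MotifAnnotation: per-residue region assignment with WG-relative offsets
#'
#' @slot table data.frame(resno, aa, region, wg_offset); `wg_offset` is the
#'   signed position relative to the WG Trp, defined only for beta_meander
#'   residues.
#' @slot anchors list carried over from the definition.
#' @slot protein protein name.
#' @export
setClass("MotifAnnotation",
         representation(table = "data.frame", anchors = "list",
                        protein = "character"),
         prototype(anchors = list(), protein = NA_character_))

setValidity("MotifAnnotation", function(object) {
    t <- object@table
    if (!all(c("resno", "aa", "region", "wg_offset") %in% names(t)))
        return("annotation table must have resno/aa/region/wg_offset")
    if (!all(t$region %in% .REGION_LEVELS))
        return("unknown region label in annotation")
    bad <- !is.na(t$wg_offset) & t$region != "beta_meander"
    if (any(bad)) return("wg_offset defined outside beta_meander")
    TRUE
})

#' ContactMatrix: region-by-region counts of cross-chain hydrogen bonds
#'
#' @slot counts integer matrix; rows are regions of the first chain, columns
#'   regions of the second.
#' @slot pairs data.frame backing list of contributing bonds (one row per
#'   bond with both residues and regions).
#' @slot chains character(2): the chain pair aggregated.
#' @export
setClass("ContactMatrix",
         representation(counts = "matrix", pairs = "data.frame",
                        chains = "character"))

setValidity("ContactMatrix", function(object) {
    if (any(object@counts < 0)) return("negative cell count")
    if (sum(object@counts) != nrow(object@pairs))
        return("cell total must equal number of backing bonds")
    TRUE
})

#' ContactDiff: gained/lost/unchanged interface contacts between two models
#'
#' @slot gained data.frame of contacts present only in the second bond set.
#' @slot lost data.frame of contacts present only in the first bond set.
#' @slot unchanged integer count of shared contacts.
#' @slot granularity "residue" or "atom".
#' @export
setClass("ContactDiff",
         representation(gained = "data.frame", lost = "data.frame",
                        unchanged = "integer", granularity = "character"))

#' SuperpositionResult: Kabsch fit of one model onto another
#'
#' @slot rotation 3x3 orthonormal matrix (det +1).
#' @slot translation length-3 vector, Angstrom.
#' @slot rmsd root-mean-square deviation over the fitted selection, Angstrom.
#' @slot displacements data.frame(chain, resno, resname, max_heavy,
#'   sidechain_centroid) of per-residue displacements after the fit.
#' @export
setClass("SuperpositionResult",
         representation(rotation = "matrix", translation = "numeric",
                        rmsd = "numeric", displacements = "data.frame"))

setValidity("SuperpositionResult", function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
    if (abs(det(R) - 1) > 1e-6) return("rotation determinant must be +1")
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
        return("rotation must be orthonormal")
    if (object@rmsd < 0) return("rmsd must be non-negative")
    TRUE
})

#' GlobalAlignment: an affine-gap global pairwise alignment
#'
#' @slot alignedA,alignedB gapped strings of equal length.
#' @slot score alignment score.
#' @slot ids character(2) sequence identifiers.
#' @slot params scoring parameters used.
#' @export
setClass("GlobalAlignment",
         representation(alignedA = "character", alignedB = "character",
                        score = "numeric", ids = "character",
                        params = "list"))

setValidity("GlobalAlignment", function(object) {
    if (nchar(object@alignedA) != nchar(object@alignedB))
        return("gapped strings must have equal length")
    TRUE
})

#' CovariationReport: MSA columns whose partitions match a binary marker
#'
#' @slot markerColumn index of the marker column in the alignment.
#' @slot markerResidue residue whose absence defines the marker (default Thr).
#' @slot marker logical per sequence: TRUE where the marker residue is absent.
#' @slot columns data.frame per scanned column: column, coefficient, n_used,
#'   classes_true, classes_false, excluded, reason.
#' @slot perfect integer vector of columns with coefficient exactly 1.
#' @slot degenerate TRUE when the marker itself is constant (no scan done).
#' @export
setClass("CovariationReport",
         representation(markerColumn = "integer", markerResidue = "character",
                        marker = "logical", columns = "data.frame",
                        perfect = "integer", degenerate = "logical"),
         prototype(degenerate = FALSE))

setValidity("CovariationReport", function(object) {
    co <- object@columns$coefficient
    co <- co[!is.na(co)]
    if (length(co) && (min(co) < 0 || max(co) > 1))
        return("coefficient must lie in [0, 1]")
    TRUE
})

#' OctamerModel: subunit slots with GTP-bound fractions
#'
#' Represents a septin hetero-oligomer as a set of slots, each filled by one
#' subunit (or an alternative mixture, e.g. terminal Cdc11:Shs1), with a
#' GTP-bound fraction per subunit and 1:1 nucleotide:protein pocket
#' occupancy.
#'
#' @slot subunits data.frame(slot, subunit, copies, weight, gtp_fraction);
#'   `weight` is the within-slot mixture weight (1 for unmixed slots).
#' @slot size integer complex size (8 for the yeast octamer).
#' @export
setClass("OctamerModel",
         representation(subunits = "data.frame", size = "integer"))

setValidity("OctamerModel", function(object) {
    s <- object@subunits
    need <- c("slot", "subunit", "copies", "weight", "gtp_fraction")
    if (!all(need %in% names(s)))
        return(paste("subunits must have columns:", paste(need, collapse = ", ")))
    if (any(s$copies <= 0) || any(s$copies != round(s$copies)))
        return("copies must be positive integers")
    if (any(s$weight <= 0)) return("mixture weights must be positive")
    if (any(s$gtp_fraction < 0 | s$gtp_fraction > 1))
        return("gtp fractions must lie in [0, 1]")
    ## per-slot copies consistent and weights summing to 1 per slot
    for (sl in unique(s$slot)) {
        rows <- s[s$slot == sl, ]
        if (length(unique(rows$copies)) != 1L)
            return(sprintf("slot '%s': inconsistent copy numbers", sl))
        if (abs(sum(rows$weight) - 1) > 1e-9)
            return(sprintf("slot '%s': mixture weights must sum to 1", sl))
    }
    tot <- sum(vapply(split(s, s$slot), function(r) r$copies[1], numeric(1)))
    if (tot != object@size)
        return(sprintf("slot copies sum to %d, not the complex size %d",
                       as.integer(tot), object@size))
    TRUE
})
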