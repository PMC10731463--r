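#' Access the atom table of a model or ligand
#' @param x a [StructureModel] or [LigandPose].
#' @return data.frame of atoms (one row per atom).
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "LigandPose", function(x) x@atoms)

#' Chain identifiers of a model
#' @param x a [StructureModel].
#' @return character vector of chain ids in file order.
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname chainIds
#' @export
setMethod("chainIds", "StructureModel", function(x) unique(x@atoms$chain))

#' Number of atoms
#' @param x a [StructureModel] or [LigandPose].
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "StructureModel", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "LigandPose", function(x) nrow(x@atoms))

#' Residue table of a model
#' @param x a [StructureModel].
#' @return data.frame(chain, resno, insert, resname, het), one row per
#'   residue in file order.
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname residues
#' @export
setMethod("residues", "StructureModel", function(x) {
    a <- x@atoms
    key <- paste(a$chain, a$resno, a$insert, sep = "\r")
    keep <- !duplicated(key)
    out <- a[keep, c("chain", "resno", "insert", "resname", "het")]
    rownames(out) <- NULL
    out
})

#' Metadata list of a model
#' @param x a [StructureModel].
#' @export
setGeneric("modelMetadata", function(x) standardGeneric("modelMetadata"))

#' @rdname modelMetadata
#' @export
setMethod("modelMetadata", "StructureModel", function(x) x@metadata)

#' Counts matrix of a ContactMatrix
#' @param x a [ContactMatrix].
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

#' @rdname contactCounts
#' @export
setMethod("contactCounts", "ContactMatrix", function(x) x@counts)

#' Backing residue-pair list of a ContactMatrix
#' @param x a [ContactMatrix].
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' @rdname contactPairs
#' @export
setMethod("contactPairs", "ContactMatrix", function(x) x@pairs)

#' Per-residue annotation table
#' @param x a [MotifAnnotation].
#' @export
setGeneric("annotationTable", function(x) standardGeneric("annotationTable"))

#' @rdname annotationTable
#' @export
setMethod("annotationTable", "MotifAnnotation", function(x) x@table)

#' Motif anchors (WG Trp, catalytic Thr)
#' @param x a [MotifAnnotation] or [MotifDefinition].
#' @export
setGeneric("motifAnchors", function(x) standardGeneric("motifAnchors"))

#' @rdname motifAnchors
#' @export
setMethod("motifAnchors", "MotifAnnotation", function(x) x@anchors)

#' @rdname motifAnchors
#' @export
setMethod("motifAnchors", "MotifDefinition", function(x) x@anchors)

#' Region ranges of a MotifDefinition
#' @param x a [MotifDefinition].
#' @export
setGeneric("motifRanges", function(x) standardGeneric("motifRanges"))

#' @rdname motifRanges
#' @export
setMethod("motifRanges", "MotifDefinition", function(x) x@ranges)

## ---- show methods ---------------------------------------------------------

setMethod("show", "StructureModel", function(object) {
    a <- object@atoms
    r <- residues(object)
    cat(sprintf("StructureModel: %d atoms, %d residues, %d chain(s) [%s]\n",
                nrow(a), nrow(r), length(unique(a$chain)),
                paste(unique(a$chain), collapse = ",")))
    if (!is.null(object@metadata$source))
        cat("  source:", object@metadata$source, "\n")
    nhet <- sum(r$het)
    if (nhet) cat(sprintf("  hetero residues: %d (%s)\n", nhet,
                          paste(unique(r$resname[r$het]), collapse = ", ")))
})

setMethod("show", "LigandPose", function(object) {
    cat(sprintf("LigandPose '%s': %d atoms (chain %s resno %s)\n",
                object@ligandName, nrow(object@atoms),
                object@parent$chain, object@parent$resno))
})

setMethod("show", "HBondCriteria", function(object) {
    cat(sprintf(paste0("HBondCriteria: D-A <= %.2f + %.2f A; ",
                       "D-H-A >= %.0f - %.0f deg; D-A-antecedent >= %.0f - %.0f deg\n"),
                object@baseDaMax, object@distanceTolerance,
                object@baseDhaMin, object@angleTolerance,
                object@baseDaaMin, object@angleTolerance))
})

setMethod("show", "MotifDefinition", function(object) {
    cat(sprintf("MotifDefinition for '%s': %d region(s)\n",
                object@protein, nrow(object@ranges)))
    if (nrow(object@ranges)) {
        r <- object@ranges
        cat(paste(sprintf("  %-12s %4d-%-4d (%s%s)", r$region, r$start, r$end,
                          r$source,
                          ifelse(is.na(r$mismatches) | r$mismatches == 0, "",
                                 sprintf(", %d mismatch", r$mismatches))),
                  collapse = "\n"), "\n")
    }
    if (length(object@absent))
        cat("  absent:", paste(object@absent, collapse = ", "), "\n")
    if (!is.null(object@anchors$wg))
        cat("  WG anchor at", object@anchors$wg, "\n")
})

setMethod("show", "MotifAnnotation", function(object) {
    tab <- table(object@table$region)
    tab <- tab[tab > 0]
    cat(sprintf("MotifAnnotation ('%s'): %d residues; %s\n", object@protein,
                nrow(object@table),
                paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
})

setMethod("show", "ContactMatrix", function(object) {
    cat(sprintf("ContactMatrix (%s x %s): %d cross-chain bond(s)\n",
                object@chains[1], object@chains[2], sum(object@counts)))
    m <- object@counts
    keep_r <- rowSums(m) > 0
    keep_c <- colSums(m) > 0
    if (any(keep_r) && any(keep_c))
        print(m[keep_r, keep_c, drop = FALSE])
})

setMethod("show", "ContactDiff", function(object) {
    cat(sprintf("ContactDiff (%s granularity): %d gained, %d lost, %d unchanged\n",
                object@granularity, nrow(object@gained), nrow(object@lost),
                object@unchanged))
})

setMethod("show", "SuperpositionResult", function(object) {
    cat(sprintf("SuperpositionResult: rmsd %.4f A over fit selection; %d residue displacement(s)\n",
                object@rmsd, nrow(object@displacements)))
})

setMethod("show", "GlobalAlignment", function(object) {
    cat(sprintf("GlobalAlignment %s vs %s: score %.1f, length %d\n",
                object@ids[1], object@ids[2], object@score,
                nchar(object@alignedA)))
})

setMethod("show", "CovariationReport", function(object) {
    if (object@degenerate) {
        cat("CovariationReport: degenerate marker (single state), no scan\n")
        return(invisible(NULL))
    }
    cat(sprintf("CovariationReport: marker column %d (non-%s in %d/%d sequences); %d perfect column(s)\n",
                object@markerColumn, object@markerResidue,
                sum(object@marker), length(object@marker),
                length(object@perfect)))
    if (length(object@perfect))
        cat("  perfect:", paste(object@perfect, collapse = ", "), "\n")
})

setMethod("show", "OctamerModel", function(object) {
    cat(sprintf("OctamerModel: %d subunits\n", object@size))
    s <- object@subunits
    cat(paste(sprintf("  %-10s %s x%d (weight %.3f, GTP fraction %.2f)",
                      s$slot, s$subunit, s$copies, s$weight, s$gtp_fraction),
              collapse = "\n"), "\n")
})
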