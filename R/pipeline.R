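## cli_pipeline module: configuration, orchestration, report bundles.

#' Build and validate a run configuration
#'
#' Defaults reproduce the package's standard interface-analysis settings:
#' hydrogen-bond relaxation of +1.0 A / -20 deg on top of the base criteria
#' and a 4.0 A ligand-contact cutoff.
#'
#' @param structures character vector of 1-2 structure paths (interface
#'   analysis).
#' @param chains optional chain pair, e.g. c("A", "B").
#' @param sequences optional FASTA path (evolution analysis).
#' @param msa optional MSA path (FASTA/Clustal).
#' @param markerColumn optional marker column for covariation.
#' @param markerResidue marker residue (default "T").
#' @param motifConfig optional motif-definition YAML path.
#' @param ligand optional ligand name for pocket contacts.
#' @param ligandCutoff contact cutoff, A (default 4).
#' @param distanceTolerance,angleTolerance,baseDaMax,baseDhaMin,baseDaaMin
#'   hydrogen-bond criteria (see [hbondCriteria()]).
#' @param outputDir output directory (created if needed).
#' @param seed integer seed recorded in the log and used by any stochastic
#'   stage.
#' @param verbose logical.
#' @return validated config list (class "septgConfig").
#' @export
runConfig <- function(structures = character(), chains = NULL,
                      sequences = NULL, msa = NULL, markerColumn = NULL,
                      markerResidue = "T", motifConfig = NULL, ligand = NULL,
                      ligandCutoff = 4.0, distanceTolerance = 1.0,
                      angleTolerance = 20.0, baseDaMax = 3.3,
                      baseDhaMin = 120, baseDaaMin = 90,
                      outputDir = "septg_out", seed = 1L, verbose = FALSE) {
    cfg <- list(structures = structures, chains = chains,
                sequences = sequences, msa = msa,
                markerColumn = markerColumn, markerResidue = markerResidue,
                motifConfig = motifConfig, ligand = ligand,
                ligandCutoff = ligandCutoff,
                criteria = hbondCriteria(baseDaMax = baseDaMax,
                                         baseDhaMin = baseDhaMin,
                                         baseDaaMin = baseDaaMin,
                                         distanceTolerance = distanceTolerance,
                                         angleTolerance = angleTolerance),
                outputDir = outputDir, seed = as.integer(seed),
                verbose = isTRUE(verbose))
    for (p in c(cfg$structures, cfg$sequences, cfg$msa, cfg$motifConfig))
        if (!is.null(p) && !file.exists(p)) stop("input not found: ", p)
    if (length(cfg$structures) > 2L)
        stop("supply 1 or 2 structures")
    if (cfg$ligandCutoff <= 0) stop("ligand cutoff must be positive")
    class(cfg) <- "septgConfig"
    cfg
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match [runConfig()] arguments.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
    do.call(runConfig, yaml::read_yaml(path))
}

## write via a temp file in the same directory, then rename (atomic-ish)
.atomicWrite <- function(writer, path) {
    tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    writer(tmp)
    file.rename(tmp, path)
    path
}

.logLines <- function(cfg, extra = character()) {
    cr <- cfg$criteria
    c("septG run log",
      sprintf("seed: %d", cfg$seed),
      sprintf("hbond criteria: base_da_max=%.3f distance_tolerance=%.3f base_dha_min=%.1f base_daa_min=%.1f angle_tolerance=%.1f",
              cr@baseDaMax, cr@distanceTolerance, cr@baseDhaMin,
              cr@baseDaaMin, cr@angleTolerance),
      sprintf("ligand cutoff: %.3f", cfg$ligandCutoff),
      extra)
}

## annotate a chain, falling back to an all-"other" annotation when the
## chain is too short/degenerate for a motif scan (e.g. synthetic fixtures)
.annotateChain <- function(model, chain, defs) {
    seq <- chainSequence(model, chain)
    if (!is.null(defs) && chain %in% names(defs))
        return(annotateMotifs(seq, defs[[chain]]))
    def <- tryCatch(scanMotifs(seq),
                    error = function(e) motifDefinition(chain, list()))
    def@protein <- chain
    annotateMotifs(seq, def)
}

#' Run the structure/interface stage pipeline
#'
#' Reads 1-2 structures, detects hydrogen bonds, annotates the interface
#' chains, and writes a report bundle into the configured output directory:
#' `contacts.tsv` (and `contacts_2.tsv`), `fingerprint.json`, optional
#' `ligand_contacts.tsv`, `diff.tsv` when two structures are supplied, and
#' `run.log`. All files are written atomically, with fixed 6-decimal number
#' formatting so reruns are byte-identical; nothing is written when any
#' stage fails.
#'
#' @param config from [runConfig()] / [readRunConfig()].
#' @return (invisibly) list with the bond tables, fingerprint, optional
#'   diff, and output paths.
#' @export
runInterfaceAnalysis <- function(config) {
    stopifnot(inherits(config, "septgConfig"))
    if (length(config$structures) < 1L)
        stop("interface analysis: at least one structure is required")
    note <- function(...) if (config$verbose) message(sprintf(...))

    ## compute everything first; write only on full success
    models <- lapply(config$structures, readStructure)
    chains <- config$chains %||% head(chainIds(models[[1]]), 2L)
    if (length(chains) < 2L)
        stop("interface analysis: the structure has fewer than two chains")
    defs <- if (!is.null(config$motifConfig)) readMotifConfig(config$motifConfig)
    bonds <- lapply(models, detectHBonds, criteria = config$criteria,
                    chains = chains, crossOnly = TRUE)
    note("structure 1: %d cross-chain bonds", nrow(bonds[[1]]))
    annotA <- .annotateChain(models[[1]], chains[1], defs)
    annotB <- .annotateChain(models[[1]], chains[2], defs)
    fp <- buildFingerprint(bonds[[1]], annotA, annotB, chains)
    lc <- if (!is.null(config$ligand))
        ligandContacts(models[[1]], config$ligand, cutoff = config$ligandCutoff,
                       criteria = config$criteria)
    diff <- NULL
    if (length(models) == 2L) {
        maps <- setNames(lapply(chains, function(ch)
            correspondenceMap(chainSequence(models[[1]], ch),
                              chainSequence(models[[2]], ch))), chains)
        diff <- diffFingerprints(bonds[[1]], bonds[[2]], map = maps)
    }

    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    out <- setNames(file.path(config$outputDir,
                              c("contacts.tsv", "fingerprint.json", "run.log")),
                    c("contacts", "fingerprint", "log"))
    .atomicWrite(function(p) writeContactsTsv(bonds[[1]], p), out[["contacts"]])
    .atomicWrite(function(p) writeFingerprint(fp, json = p), out[["fingerprint"]])
    if (length(models) == 2L) {
        out[["contacts_2"]] <- file.path(config$outputDir, "contacts_2.tsv")
        .atomicWrite(function(p) writeContactsTsv(bonds[[2]], p),
                     out[["contacts_2"]])
        out[["diff"]] <- file.path(config$outputDir, "diff.tsv")
        .atomicWrite(function(p) {
            gained <- diff@gained; lost <- diff@lost
            gained$change <- if (nrow(gained)) "gained" else character()
            lost$change <- if (nrow(lost)) "lost" else character()
            tab <- rbind(gained, lost)
            for (cc in c("distance", "angle"))
                tab[[cc]] <- formatC(tab[[cc]], format = "f", digits = 6)
            write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
        }, out[["diff"]])
    }
    if (!is.null(lc)) {
        out[["ligand_contacts"]] <- file.path(config$outputDir,
                                              "ligand_contacts.tsv")
        .atomicWrite(function(p) {
            l <- lc
            l$min_distance <- formatC(l$min_distance, format = "f", digits = 6)
            write.table(l, p, sep = "\t", quote = FALSE, row.names = FALSE)
        }, out[["ligand_contacts"]])
    }
    .atomicWrite(function(p) writeLines(.logLines(config, c(
        sprintf("structures: %s", paste(config$structures, collapse = ", ")),
        sprintf("chains: %s", paste(chains, collapse = ",")),
        sprintf("cross-chain bonds: %s",
                paste(vapply(bonds, nrow, integer(1)), collapse = ", ")),
        if (!is.null(diff)) sprintf("diff: %d gained, %d lost, %d unchanged",
                                    nrow(diff@gained), nrow(diff@lost),
                                    diff@unchanged))), p), out[["log"]])
    invisible(list(bonds = bonds, fingerprint = fp, ligand_contacts = lc,
                   diff = diff, paths = out))
}

#' Run the sequence-evolution stage pipeline
#'
#' Computes all pairwise identities from a FASTA set, the covariation report
#' from an MSA (when a marker column is configured), and a neighbor-joining
#' tree (>= 3 sequences), writing `identity.tsv`, `covariation.tsv`,
#' `tree.newick` and `run.log` into the output directory.
#'
#' @param config from [runConfig()].
#' @return (invisibly) list with the identity table, report, tree and paths.
#' @export
runEvolutionAnalysis <- function(config) {
    stopifnot(inherits(config, "septgConfig"))
    if (is.null(config$sequences) && is.null(config$msa))
        stop("evolution analysis: sequences or an MSA are required")
    seqs <- NULL; idTab <- NULL; tree <- NULL; rep <- NULL
    if (!is.null(config$sequences)) {
        seqs <- readSequences(config$sequences)
        ids <- names(seqs)
        pairs <- if (length(seqs) >= 2L) t(combn(length(seqs), 2L)) else
            matrix(integer(), ncol = 2L)
        idTab <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
            i <- pairs[r, 1]; j <- pairs[r, 2]
            data.frame(id_a = ids[i], id_b = ids[j],
                       percent_identity = percentIdentity(seqs[[i]], seqs[[j]]),
                       stringsAsFactors = FALSE)
        }))
        if (length(seqs) >= 3L) tree <- njTree(distanceMatrix(seqs))
    }
    if (!is.null(config$msa) && !is.null(config$markerColumn)) {
        m <- readMsa(config$msa)
        rep <- covaryWithMarker(m, config$markerColumn, config$markerResidue)
    }
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    out <- c(log = file.path(config$outputDir, "run.log"))
    if (!is.null(idTab)) {
        out[["identity"]] <- file.path(config$outputDir, "identity.tsv")
        .atomicWrite(function(p) {
            t <- idTab
            t$percent_identity <- formatC(t$percent_identity, format = "f",
                                          digits = 6)
            write.table(t, p, sep = "\t", quote = FALSE, row.names = FALSE)
        }, out[["identity"]])
    }
    if (!is.null(rep)) {
        out[["covariation"]] <- file.path(config$outputDir, "covariation.tsv")
        .atomicWrite(function(p) {
            t <- rep@columns
            if (nrow(t)) t$coefficient <- formatC(t$coefficient, format = "f",
                                                  digits = 6)
            write.table(t, p, sep = "\t", quote = FALSE, row.names = FALSE)
        }, out[["covariation"]])
    }
    if (!is.null(tree)) {
        out[["tree"]] <- file.path(config$outputDir, "tree.newick")
        .atomicWrite(function(p) writeNewick(tree, p), out[["tree"]])
    }
    .atomicWrite(function(p) writeLines(.logLines(config, c(
        if (!is.null(seqs)) sprintf("sequences: %d", length(seqs)),
        if (!is.null(rep)) sprintf("perfect covarying columns: %s",
                                   paste(rep@perfect, collapse = ",")))), p),
        out[["log"]])
    invisible(list(identity = idTab, covariation = rep, tree = tree,
                   paths = out))
}
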