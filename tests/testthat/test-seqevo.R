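test_that("global alignment: identical sequences, single gap, validation", {
    aln <- globalAlign("ACDEFGHIK", "ACDEFGHIK")
    expect_false(grepl("-", aln@alignedA))
    expect_false(grepl("-", aln@alignedB))

    aln2 <- globalAlign("ACDEFG", "ACDFG")
    gaps <- gregexpr("-", aln2@alignedB)[[1]]
    expect_length(gaps[gaps > 0], 1L)
    expect_equal(nchar(aln2@alignedA), 6L)

    expect_error(globalAlign("AC1DE", "ACDE"), "non-amino-acid")
    expect_error(globalAlign("", "ACDE"), "non-empty|non-amino")
})

test_that("alignment scores equal a score-only Gotoh oracle on random 8-mers", {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    set.seed(77)
    for (i in 1:100) {
        a <- paste(sample(aa, 8, replace = TRUE), collapse = "")
        b <- paste(sample(aa, 8, replace = TRUE), collapse = "")
        expect_equal(globalAlign(a, b)@score, gotohScore(a, b),
                     tolerance = 1e-9, info = paste(a, b))
    }
})

test_that("percent identity: arithmetic, denominators, symmetry", {
    expect_equal(percentIdentity("AAAA", "AAAA"), 100)
    expect_equal(percentIdentity("AAAA", "AAAT"), 75)
    expect_error(percentIdentity(new("GlobalAlignment", alignedA = "",
                                     alignedB = "", score = 0,
                                     ids = c("a", "b"), params = list())),
                 "zero-length")
    set.seed(31)
    for (i in 1:10) {
        p <- makeIdentityPair(60, sample(c(50, 70, 90), 1), seed = i)
        ab <- percentIdentity(p$sequences[["a"]], p$sequences[["b"]])
        ba <- percentIdentity(p$sequences[["b"]], p$sequences[["a"]])
        expect_equal(ab, ba)
        abS <- percentIdentity(p$sequences[["a"]], p$sequences[["b"]],
                               denominator = "shorter_seq")
        baS <- percentIdentity(p$sequences[["b"]], p$sequences[["a"]],
                               denominator = "shorter_seq")
        expect_equal(abS, baS)
    }
})

test_that("covariation: planted perfect columns score 1.0, flips score (n-f)/n", {
    fx <- makeCovaryingMSA(12, 40, thrAbsent = c(1, 4, 6, 9, 11),
                           markerColumn = 5, perfectColumns = c(12, 25),
                           noisyColumns = c(`33` = 2), seed = 19)
    rep <- covaryWithMarker(fx$msa, 5)
    expect_equal(rep@perfect, c(12L, 25L))
    expect_equal(rep@columns$coefficient[rep@columns$column == 33], 10 / 12)
    ## marker vector is "Thr absent"
    expect_equal(which(unname(rep@marker)), c(1L, 4L, 6L, 9L, 11L))
})

test_that("covariation coefficients equal the exhaustive-partition oracle", {
    fx <- makeCovaryingMSA(10, 30, thrAbsent = c(2, 3, 7, 8),
                           markerColumn = 3, perfectColumns = c(10),
                           noisyColumns = c(`20` = 1, `21` = 3), seed = 23)
    rep <- covaryWithMarker(fx$msa, 3)
    marker <- fx$msa[, 3] != "T"
    for (j in setdiff(seq_len(30), 3)) {
        want <- covariationOracle(fx$msa[, j], marker)
        got <- rep@columns$coefficient[rep@columns$column == j]
        if (is.na(want)) expect_true(rep@columns$excluded[rep@columns$column == j])
        else expect_equal(got, want, info = paste("column", j))
    }
})

test_that("constant columns are excluded; gapped sequences leave the denominator", {
    m <- rbind(c("T", "A", "G", "L"),
               c("T", "A", "G", "L"),
               c("R", "A", "S", "L"),
               c("R", "A", "S", "-"))
    rownames(m) <- paste0("s", 1:4)
    rep <- covaryWithMarker(m, 1)
    cols <- rep@columns
    expect_true(cols$excluded[cols$column == 2])   # constant
    expect_match(cols$reason[cols$column == 2], "constant")
    expect_equal(cols$coefficient[cols$column == 3], 1)
    expect_equal(cols$n_used[cols$column == 4], 3L) # gap excluded
    expect_true(cols$excluded[cols$column == 4])    # constant among ungapped
})

test_that("degenerate markers are reported, not scanned", {
    m <- matrix("T", 4, 6, dimnames = list(paste0("s", 1:4), NULL))
    rep <- covaryWithMarker(m, 2)
    expect_true(rep@degenerate)
    expect_equal(nrow(rep@columns), 0L)
})

test_that("distance matrix is symmetric with zero diagonal and matches recomputation", {
    seqs <- c(a = makeIdentityPair(50, 90, seed = 1)$sequences[["a"]])
    seqs <- c(seqs,
              b = makeIdentityPair(50, 90, seed = 1)$sequences[["b"]],
              c = makeIdentityPair(50, 70, seed = 2)$sequences[["b"]])
    D <- distanceMatrix(seqs)
    expect_equal(diag(D), c(a = 0, b = 0, c = 0))
    expect_equal(D, t(D))
    expect_equal(D["a", "b"], 1 - percentIdentity(seqs[["a"]], seqs[["b"]]) / 100)
    expect_equal(D["a", "b"], 0.10, tolerance = 1e-9)
    expect_error(distanceMatrix(setNames(seqs, c("a", "a", "c"))), "duplicate")
})

test_that("3-taxon NJ solves the three-point formulas", {
    D <- matrix(c(0, 0.3, 0.4, 0.3, 0, 0.5, 0.4, 0.5, 0), 3, 3,
                dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
    tr <- njTree(D)
    expect_setequal(tr$tip.label, c("x", "y", "z"))
    cd <- ape::cophenetic.phylo(tr)[c("x", "y", "z"), c("x", "y", "z")]
    expect_equal(cd, D, tolerance = 1e-9)
    ## closed form: l_x = (d_xy + d_xz - d_yz)/2 = 0.1
    lx <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "x")]
    expect_equal(lx, 0.1, tolerance = 1e-9)
})

test_that("NJ exactly recovers random additive trees and their branch lengths", {
    set.seed(55)
    for (i in 1:50) {
        n <- sample(5:8, 1)
        tr <- ape::rtree(n, rooted = FALSE)
        D <- ape::cophenetic.phylo(tr)
        ord <- sample(rownames(D))          # input order must not matter
        rec <- njTree(D[ord, ord])
        expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), rec)), 0,
                     info = paste("trial", i))
        expect_lt(max(abs(ape::cophenetic.phylo(rec)[rownames(D), colnames(D)] -
                          D)), 1e-8)
    }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
    set.seed(8)
    n <- 7
    D <- as.matrix(dist(matrix(runif(n * 3), ncol = 3)))
    dimnames(D) <- list(letters[1:n], letters[1:n])
    mine <- njTree(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(as.numeric(ape::dist.topo(mine, ref)), 0)
})

test_that("NJ input validation and negative-branch clamping", {
    D <- matrix(c(0, NA, 1, NA, 0, 1, 1, 1, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
    expect_error(njTree(D), "NA")
    ## violated triangle: negative three-point solution gets clamped
    D2 <- matrix(c(0, 1, 0.1, 1, 0, 2, 0.1, 2, 0), 3, 3,
                 dimnames = list(letters[1:3], letters[1:3]))
    expect_warning(tr <- njTree(D2), "clamped")
    expect_true(all(tr$edge.length >= 0))
})

test_that("newick output round-trips", {
    fx <- lapply(1:4, function(i) makeIdentityPair(40, 75, seed = i))
    seqs <- setNames(vapply(fx, function(p) p$sequences[["b"]], character(1)),
                     paste0("t", 1:4))
    tr <- njTree(distanceMatrix(seqs))
    tf <- tempfile(fileext = ".nwk")
    writeNewick(tr, tf)
    tr2 <- ape::read.tree(tf)
    expect_setequal(tr2$tip.label, names(seqs))
    expect_equal(as.numeric(ape::dist.topo(tr, tr2)), 0)
})

test_that("center-star progressive alignment handles indels", {
    seqs <- c(s1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
              s2 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
              s3 = "MKTAYIAKQISFVKSHFSRQLEERLGLIEVQ",   # 2-residue deletion
              s4 = "MKTAYIAKQRQISFVKSHFSRQLEERLG")      # truncated
    m <- alignSequences(seqs)
    expect_equal(nrow(m), 4L)
    expect_equal(length(unique(apply(m, 1, length))), 1L)
    ## degapped rows recover the inputs
    for (i in 1:4)
        expect_equal(paste(m[i, ][m[i, ] != "-"], collapse = ""),
                     unname(seqs[i]))
})

test_that("FASTA and Clustal readers feed the same downstream analyses", {
    fx <- makeCovaryingMSA(6, 12, thrAbsent = c(1, 2), markerColumn = 2,
                           perfectColumns = 7, seed = 3)
    ff <- tempfile(fileext = ".fasta")
    seqs <- apply(fx$msa, 1, paste, collapse = "")
    writeLines(paste0(">", names(seqs), "\n", seqs), ff)
    mFasta <- readMsa(ff)
    expect_equal(unname(mFasta), unname(fx$msa))
    cf <- tempfile(fileext = ".aln")
    writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
                 paste0(formatC(names(seqs), width = -16), seqs),
                 paste0(strrep(" ", 16), strrep("*", ncol(fx$msa))), ""), cf)
    mClustal <- readMsa(cf)
    expect_equal(unname(mClustal), unname(fx$msa))
    rep <- covaryWithMarker(mClustal, 2)
    expect_equal(rep@perfect, 7L)
})
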