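test_that("donor/acceptor templates carry the expected chemistry", {
    tab <- donorAcceptorTable()
    gly <- tab[tab$resname == "GLY", ]
    expect_setequal(gly$atom[gly$role == "donor"], "N")
    expect_setequal(gly$atom[gly$role == "acceptor"], c("O", "OXT"))
    arg <- tab[tab$resname == "ARG" & tab$role == "donor", ]
    expect_true(all(c("NE", "NH1", "NH2", "N") %in% arg$atom))
    gtp <- tab[tab$resname == "GTP", ]
    expect_true(all(c("O1A", "O1B", "O1G", "O6") %in%
                    gtp$atom[gtp$role == "acceptor"]))
    expect_true(all(c("N1", "N2") %in% gtp$atom[gtp$role == "donor"]))
    ## proline backbone amide cannot donate
    expect_false(any(tab$resname == "PRO" & tab$atom == "N" &
                     tab$role == "donor"))
})

test_that("unknown residues are reported, not silently dropped", {
    a <- data.frame(name = c("CA", "X1"), resname = c("GLY", "UNK"),
                    chain = "A", resno = c(1, 2), x = c(0, 50), y = 0, z = 0,
                    het = c(FALSE, TRUE))
    m <- structureModel(a)
    expect_warning(assignDonorsAcceptors(m), "UNK")
})

test_that("distant chains yield no bonds; planted bonds are recovered exactly", {
    far <- makeHbondDimer(0, 10, seed = 3)
    expect_equal(nrow(detectHBonds(far$model)), 0L)

    fx <- makeHbondDimer(5, 20, seed = 17)
    hb <- detectHBonds(fx$model)
    expect_equal(nrow(hb), 5L)
    expect_true(all(hb$cross_chain))
    expect_equal(hb$donor_resno, fx$truth$bonds$donor_resno)
    expect_equal(hb$distance, rep(2.9, 5), tolerance = 1e-6)

    ## tightening below the planted distance removes everything
    tight <- hbondCriteria(baseDaMax = 2.8, distanceTolerance = 0,
                           angleTolerance = 0)
    expect_equal(nrow(detectHBonds(fx$model, criteria = tight)), 0L)
})

test_that("invalid criteria are rejected", {
    expect_error(hbondCriteria(baseDaMax = -1), "positive")
    expect_error(hbondCriteria(distanceTolerance = -0.5), "non-negative")
})

test_that("detector equals a brute-force all-pairs oracle on random models", {
    for (seed in 1:12) {
        m <- randomContactModel(seed)
        got <- hbondKeys(detectHBonds(m))
        want <- bruteForceHBonds(m)
        expect_equal(got, want, info = paste("seed", seed))
    }
})

test_that("bond set grows monotonically with either tolerance", {
    m <- randomContactModel(99)
    prev <- character()
    for (dt in c(0, 0.5, 1, 1.5)) {
        cur <- hbondKeys(detectHBonds(m, hbondCriteria(distanceTolerance = dt)))
        expect_true(all(prev %in% cur))
        prev <- cur
    }
    prev <- character()
    for (at in c(0, 10, 20, 40)) {
        cur <- hbondKeys(detectHBonds(m, hbondCriteria(angleTolerance = at)))
        expect_true(all(prev %in% cur))
        prev <- cur
    }
})

test_that("cross-chain bonds are invariant to chain order", {
    fx <- makeHbondDimer(4, 15, seed = 23)
    a <- atoms(fx$model)
    rev <- structureModel(a[order(match(a$chain, c("B", "A")), a$serial), ])
    expect_equal(hbondKeys(detectHBonds(fx$model, crossOnly = TRUE)),
                 hbondKeys(detectHBonds(rev, crossOnly = TRUE)))
})

test_that("ligand contacts recover planted residues at the 4 A cutoff", {
    planted <- c(2, 5, 8, 11, 14, 17)
    d <- c(3.2, 3.3, 3.5, 3.6, 3.8, 3.9)
    fx <- makeLigandPocket(planted, d, seed = 31)
    lc <- ligandContacts(fx$model, fx$ligand)
    expect_equal(lc$resno, planted)
    expect_equal(lc$min_distance, d, tolerance = 0.05)

    ## displaced ligand: nothing within reach
    a <- atoms(fx$model)
    a[a$het, c("x", "y", "z")] <- a[a$het, c("x", "y", "z")] + 50
    m2 <- structureModel(a)
    expect_equal(nrow(ligandContacts(m2, ligands(m2)[[1]])), 0L)

    ## degenerate cutoff
    expect_equal(nrow(ligandContacts(fx$model, fx$ligand, cutoff = 0)), 0L)
})

test_that("ligand hydrogen bonds are classified as kind = hbond", {
    ## Ser OG donor 2.9 A from a GTP phosphate oxygen with linear proxy angle
    a <- rbind(
        data.frame(name = c("N", "CA", "CB", "OG"), resname = "SER",
                   chain = "A", resno = 1,
                   x = c(-8, -7, -5.5, -2.9), y = 0, z = 0, het = FALSE),
        data.frame(name = c("O1A", "PA"), resname = "GTP", chain = "L",
                   resno = 90, x = c(0, 1.5), y = 0, z = 0, het = TRUE))
    m <- structureModel(a)
    lc <- ligandContacts(m, "GTP")
    expect_equal(nrow(lc), 1L)
    expect_equal(lc$kind, "hbond")
})

test_that("clash detection matches van der Waals arithmetic", {
    ## ligand carbon 1.0 A from a protein carbon: overlap = 3.4 - 1.0 = 2.4
    a <- rbind(
        data.frame(name = "CA", resname = "GLY", chain = "A", resno = 1,
                   x = 0, y = 0, z = 0, het = FALSE),
        data.frame(name = "C8", resname = "GTP", chain = "L", resno = 9,
                   x = 1.0, y = 0, z = 0, het = TRUE))
    m <- structureModel(a)
    cl <- clashCheck(m, "GTP")
    expect_equal(nrow(cl), 1L)
    expect_equal(cl$overlap, 2.4, tolerance = 1e-9)

    ## far ligand: no clash; huge threshold: no clash
    expect_equal(nrow(clashCheck(makeLigandPocket(1, 3.9, seed = 1)$model,
                                 "GTP")), 0L)
    expect_equal(nrow(clashCheck(m, "GTP", overlapThreshold = 5)), 0L)
})

test_that("clash check names unknown elements", {
    a <- rbind(
        data.frame(name = "XX", resname = "GLY", chain = "A", resno = 1,
                   x = 0, y = 0, z = 0, het = FALSE, elem = "QQ"),
        data.frame(name = "C8", resname = "GTP", chain = "L", resno = 9,
                   x = 1, y = 0, z = 0, het = TRUE, elem = "C"))
    expect_error(clashCheck(structureModel(a), "GTP"), "QQ")
})

test_that("clashes sort by overlap, largest first", {
    a <- rbind(
        data.frame(name = c("CA", "CB"), resname = "GLY", chain = "A",
                   resno = 1:2, x = c(1.0, 2.0), y = 0, z = 0, het = FALSE),
        data.frame(name = "C8", resname = "GTP", chain = "L", resno = 9,
                   x = 0, y = 0, z = 0, het = TRUE))
    cl <- clashCheck(structureModel(a), "GTP")
    expect_equal(nrow(cl), 2L)
    expect_true(all(diff(cl$overlap) <= 0))
})
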