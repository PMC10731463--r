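## helper: annotation assigning a fixed region to every residue of a chain
flatAnnotation <- function(resnos, region, protein = "x") {
    def <- motifDefinition(protein, setNames(
        list(sprintf("%d-%d", min(resnos), max(resnos))), region),
        wg = if (region == "beta_meander") max(resnos) else NULL)
    annotateMotifs(setNames(rep("A", length(resnos)), resnos), def)
}

test_that("fingerprint cells count cross-chain bonds and conserve the total", {
    fx <- makeHbondDimer(5, 20, seed = 41)
    hb <- detectHBonds(fx$model, crossOnly = TRUE)
    annA <- flatAnnotation(1:20, "G1")
    annB <- flatAnnotation(1:20, "G4")
    fp <- buildFingerprint(hb, annA, annB, c("A", "B"))
    expect_equal(contactCounts(fp)["G1", "G4"], 5L)
    expect_equal(sum(contactCounts(fp)), 5L)            # total conservation
    expect_equal(sum(contactCounts(fp)), nrow(hb))
    expect_equal(nrow(contactPairs(fp)), 5L)

    ## empty bond list: all-zero matrix
    fp0 <- buildFingerprint(hb[0, ], annA, annB, c("A", "B"))
    expect_equal(sum(contactCounts(fp0)), 0L)

    ## shuffled input order: identical matrix
    set.seed(1)
    fpS <- buildFingerprint(hb[sample(nrow(hb)), ], annA, annB, c("A", "B"))
    expect_identical(contactCounts(fpS), contactCounts(fp))
})

test_that("bonds outside the annotation raise an error naming the residues", {
    fx <- makeHbondDimer(2, 10, seed = 6)
    hb <- detectHBonds(fx$model, crossOnly = TRUE)
    annShort <- flatAnnotation(1:3, "G1")
    expect_error(buildFingerprint(hb, annShort, flatAnnotation(1:10, "G4"),
                                  c("A", "B")),
                 "absent from annotation")
})

test_that("matrix total equals cross-chain bond count on random fixtures", {
    for (seed in c(2, 13, 27)) {
        k <- sample(0:6, 1)
        fx <- makeHbondDimer(k, 15, seed = seed)
        hb <- detectHBonds(fx$model, crossOnly = TRUE)
        fp <- buildFingerprint(hb, flatAnnotation(1:15, "G2"),
                               flatAnnotation(1:15, "alpha4"), c("A", "B"))
        expect_equal(sum(contactCounts(fp)), nrow(hb))
    }
})

test_that("correspondence map: identity, substitution flag, insertion offset", {
    s <- "MSTNPKPQRKTKRNTNRRPQDVKFPGG"
    m <- correspondenceMap(s, s)
    expect_equal(m$pos_a, m$pos_b)
    expect_true(all(m$identical))

    sub <- s; substr(sub, 10, 10) <- "A"
    m2 <- correspondenceMap(s, sub)
    expect_equal(m2$pos_a, m2$pos_b)        # still an identity map
    expect_equal(sum(!m2$identical), 1L)    # with the substitution flagged
    expect_equal(m2$pos_a[!m2$identical], 10L)

    ins <- paste0(substr(s, 1, 12), "GGG", substr(s, 13, nchar(s)))
    m3 <- suppressWarnings(correspondenceMap(s, ins))
    expect_equal(m3$pos_b[m3$pos_a == 12], 12L)
    expect_equal(m3$pos_b[m3$pos_a == 13], 16L)  # downstream offset by 3
})

test_that("diff: identical sets, planted gains/losses, antisymmetry", {
    fx <- makeHbondDimer(4, 16, seed = 51)
    hb <- detectHBonds(fx$model, crossOnly = TRUE)
    d0 <- diffFingerprints(hb, hb)
    expect_equal(nrow(d0@gained), 0L)
    expect_equal(nrow(d0@lost), 0L)
    expect_equal(d0@unchanged, 4L)

    ## remove 2 planted bonds, add 1 new one, by editing coordinates
    a <- atoms(fx$model)
    drop <- fx$truth$bonds$donor_resno[1:2]
    a$y[a$chain == "A" & a$resno %in% drop & a$name == "OG"] <- 1.6
    free <- setdiff(1:16, fx$truth$bonds$donor_resno)[1]
    newSer <- a[a$chain == "A" & a$resno == fx$truth$bonds$donor_resno[3] &
                a$name %in% c("CB", "OG"), ]
    newAsp <- a[a$chain == "B" & a$resno == fx$truth$bonds$acceptor_resno[3] &
                a$name %in% c("CB", "CG", "OD1"), ]
    newSer$resno <- free; newSer$x <- 10 * free
    newAsp$resno <- free; newAsp$x <- 10 * free
    a$resname[a$chain == "A" & a$resno == free] <- "SER"
    a$resname[a$chain == "B" & a$resno == free] <- "ASP"
    a <- rbind(a, newSer, newAsp)
    a$serial <- seq_len(nrow(a))
    hb2 <- detectHBonds(structureModel(a), crossOnly = TRUE)
    d <- diffFingerprints(hb, hb2)
    expect_equal(nrow(d@lost), 2L)
    expect_equal(nrow(d@gained), 1L)
    expect_equal(d@unchanged, 2L)

    ## antisymmetry
    dRev <- diffFingerprints(hb2, hb)
    expect_equal(nrow(dRev@gained), nrow(d@lost))
    expect_equal(nrow(dRev@lost), nrow(d@gained))
    expect_equal(dRev@unchanged, d@unchanged)
})

test_that("diff consistency through an intermediate bond set", {
    fx <- makeHbondDimer(6, 20, seed = 71)
    hb <- detectHBonds(fx$model, crossOnly = TRUE)
    subsetBonds <- function(b, keep) b[b$donor_resno %in% keep, , drop = FALSE]
    A <- subsetBonds(hb, fx$truth$bonds$donor_resno[1:5])
    B <- subsetBonds(hb, fx$truth$bonds$donor_resno[2:6])
    C <- subsetBonds(hb, fx$truth$bonds$donor_resno[3:6])
    dAC <- diffFingerprints(A, C)
    dAB <- diffFingerprints(A, B)
    dBC <- diffFingerprints(B, C)
    expect_lte(nrow(dAC@gained) + nrow(dAC@lost),
               nrow(dAB@gained) + nrow(dAB@lost) +
               nrow(dBC@gained) + nrow(dBC@lost))
})

test_that("diff honours a correspondence map with renumbering", {
    fx <- makeHbondDimer(3, 12, seed = 81)
    hb <- detectHBonds(fx$model, crossOnly = TRUE)
    shifted <- hb
    shifted$donor_resno <- shifted$donor_resno + 7L
    shifted$acceptor_resno <- shifted$acceptor_resno + 7L
    map <- data.frame(pos_a = 1:12, pos_b = 8:19)
    d <- diffFingerprints(hb, shifted, map = map)
    expect_equal(d@unchanged, 3L)
    expect_equal(nrow(d@gained) + nrow(d@lost), 0L)
})

test_that("superposing a model on itself and on rigid copies gives rmsd ~ 0", {
    fx <- makeHbondDimer(3, 15, seed = 2)
    spSelf <- superpose(fx$model, fx$model)
    expect_lt(spSelf@rmsd, 1e-12)
    expect_true(all(spSelf@displacements$max_heavy < 1e-12))

    set.seed(4)
    R <- randomRotation()
    a <- atoms(fx$model)
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
    a$x <- xyz[, 1] + 12; a$y <- xyz[, 2] - 4; a$z <- xyz[, 3] + 3
    sp <- superpose(fx$model, structureModel(a))
    expect_lt(sp@rmsd, 1e-6)
    expect_equal(det(sp@rotation), 1, tolerance = 1e-9)
})

test_that("a 7 A side-chain displacement is recovered after a CA-only fit", {
    fx <- makeHbondDimer(3, 15, seed = 2)
    pr <- fx$truth$bonds$donor_resno[1]
    b <- atoms(fx$model)
    sel <- b$chain == "A" & b$resno == pr & b$name %in% c("CB", "OG")
    b$z[sel] <- b$z[sel] + 7
    sp <- superpose(fx$model, structureModel(b), selection = "CA")
    d <- sp@displacements
    moved <- d[d$chain == "A" & d$resno == pr, ]
    expect_equal(moved$max_heavy, 7, tolerance = 0.01)
    expect_equal(moved$sidechain_centroid, 7, tolerance = 0.01)
    others <- d[!(d$chain == "A" & d$resno == pr), ]
    expect_true(all(others$max_heavy < 0.01))
})

test_that("Kabsch fit beats 1000 random rigid transforms (Monte-Carlo bound)", {
    set.seed(123)
    P <- matrix(rnorm(30, sd = 4), ncol = 3)
    R0 <- randomRotation()
    Q <- P %*% t(R0) + matrix(rnorm(30, sd = 0.3), ncol = 3)
    mk <- function(X) structureModel(data.frame(
        name = "CA", resname = "GLY", chain = "A", resno = 1:10,
        x = X[, 1], y = X[, 2], z = X[, 3], het = FALSE))
    fit <- superpose(mk(P), mk(Q))
    rmsdOf <- function(X) sqrt(mean(rowSums((X - Q)^2)))
    for (i in 1:1000) {
        Rr <- randomRotation()
        cand <- sweep(sweep(P, 2, colMeans(P)) %*% t(Rr), 2, colMeans(Q), "+")
        cand <- cand + matrix(rnorm(3, sd = 0.5), nrow = 10, ncol = 3,
                              byrow = TRUE)
        expect_gte(rmsdOf(cand), fit@rmsd - 1e-9)
    }
})

test_that("superposition with too few paired atoms errors", {
    a <- structureModel(data.frame(name = "CA", resname = "GLY", chain = "A",
                                   resno = 1:2, x = 1:2, y = 0, z = 0,
                                   het = FALSE))
    expect_error(superpose(a, a), "at least 3")
})

test_that("residue distances: self, constructed CA pair, side-chain fallback", {
    a <- data.frame(name = "CA", resname = "GLY", chain = "A", resno = c(1, 2),
                    x = c(0, 9), y = 0, z = 0, het = FALSE)
    m <- structureModel(a)
    expect_equal(residueDistance(m, list(chain = "A", resno = 1),
                                 list(chain = "A", resno = 1)), 0)
    expect_equal(residueDistance(m, list(chain = "A", resno = 1),
                                 list(chain = "A", resno = 2)), 9)
    expect_warning(
        d <- residueDistance(m, list(chain = "A", resno = 1),
                             list(chain = "A", resno = 2),
                             mode = "sidechain_min"),
        "no side chain")
    expect_equal(d, 9)
})
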