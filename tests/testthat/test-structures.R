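test_that("a minimal PDB fixture parses into chains/residues/atoms", {
    tf <- tempfile(fileext = ".pdb")
    writeLines(c(
        "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
        "ATOM      2  CA  ALA A   1       2.400   2.000   3.000  1.00  0.00           C",
        "END"), tf)
    m <- readStructure(tf)
    expect_s4_class(m, "StructureModel")
    expect_equal(nAtoms(m), 2L)
    expect_equal(chainIds(m), "A")
    expect_equal(nrow(residues(m)), 1L)
    expect_equal(atoms(m)$elem, c("N", "C"))
    expect_equal(atoms(m)$x, c(1, 2.4))
})

test_that("write/read round-trips preserve atoms and coordinates to PDB precision", {
    fx <- makeHbondDimer(4, 25, seed = 11)
    tf <- tempfile(fileext = ".pdb")
    writeStructure(fx$model, tf)
    m2 <- readStructure(tf)
    expect_equal(nAtoms(m2), nAtoms(fx$model))
    dev <- abs(as.matrix(atoms(fx$model)[, c("x", "y", "z")]) -
               as.matrix(atoms(m2)[, c("x", "y", "z")]))
    expect_lte(max(dev), 1e-3)
    expect_equal(atoms(m2)$name, atoms(fx$model)$name)
    expect_equal(atoms(m2)$resname, atoms(fx$model)$resname)

    ## random 50-residue model: same property
    set.seed(42)
    a <- data.frame(name = rep(c("N", "CA", "C", "O"), 50),
                    resname = "ALA", chain = "A",
                    resno = rep(seq_len(50), each = 4),
                    x = round(runif(200, -99, 99), 3),
                    y = round(runif(200, -99, 99), 3),
                    z = round(runif(200, -99, 99), 3), het = FALSE)
    m <- structureModel(a)
    tf2 <- tempfile(fileext = ".pdb")
    writeStructure(m, tf2)
    m3 <- readStructure(tf2)
    expect_lte(max(abs(as.matrix(atoms(m)[, c("x", "y", "z")]) -
                       as.matrix(atoms(m3)[, c("x", "y", "z")]))), 1e-3)
})

test_that("mmCIF files parse through the same interface", {
    cif <- c("data_fix", "loop_", "_atom_site.group_PDB", "_atom_site.id",
             "_atom_site.type_symbol", "_atom_site.label_atom_id",
             "_atom_site.label_alt_id", "_atom_site.label_comp_id",
             "_atom_site.label_asym_id", "_atom_site.label_entity_id",
             "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
             "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
             "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
             "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
             "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
             "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
             "ATOM 1 N N . GLY A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 5 GLY A N 1",
             "ATOM 2 C CA . GLY A 1 1 ? 2.400 2.000 3.000 1.00 0.00 ? 5 GLY A CA 1",
             "#")
    tf <- tempfile(fileext = ".cif")
    writeLines(cif, tf)
    m <- readStructure(tf)
    expect_equal(nAtoms(m), 2L)
    expect_equal(unique(atoms(m)$resno), 5L)  # author numbering kept
})

test_that("parse errors and empty models are reported explicitly", {
    tf <- tempfile(fileext = ".pdb")
    writeLines(c("REMARK nothing here", "END"), tf)
    expect_error(readStructure(tf), "empty structure|cannot parse")
    expect_error(readStructure(tempfile(fileext = ".pdb")), "not found")
    expect_error(structureModel(data.frame()), "empty structure")
})

test_that("alternate locations collapse to highest occupancy, ties alphabetical", {
    tf <- tempfile(fileext = ".pdb")
    writeLines(c(
        "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
        "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60  0.00           C",
        "ATOM      3  CB AALA A   2       0.000   0.000   0.000  0.50  0.00           C",
        "ATOM      4  CB BALA A   2       9.000   0.000   0.000  0.50  0.00           C",
        "END"), tf)
    m <- readStructure(tf)
    a <- atoms(m)
    expect_equal(nrow(a), 2L)
    expect_equal(a$x[a$resno == 1], 5.0)   # higher occupancy wins
    expect_equal(a$x[a$resno == 2], 0.0)   # tie: alphabetical alt-loc "A"
})

test_that("selection: identity, chains, residues, side-chain predicate", {
    fx <- makeHbondDimer(3, 12, seed = 5)
    m <- fx$model
    expect_equal(atoms(selectAtoms(m)), atoms(m))
    onlyA <- selectAtoms(m, chains = "A")
    expect_equal(unique(atoms(onlyA)$chain), "A")
    ## idempotent
    expect_equal(atoms(selectAtoms(onlyA, chains = "A")), atoms(onlyA))
    ## side-chain selection excludes backbone names
    pr <- fx$truth$bonds$donor_resno[1]
    sc <- selectAtoms(m, chains = "A", resno = pr, atomNames = "sidechain")
    expect_true(all(!atoms(sc)$name %in% c("N", "CA", "C", "O")))
    expect_setequal(atoms(sc)$name, c("CB", "OG"))
    expect_error(selectAtoms(m, chains = "Q"), "unknown chain.*available")
})

test_that("selection commutes with chain reordering", {
    fx <- makeHbondDimer(2, 8, seed = 9)
    a <- atoms(fx$model)
    rev <- structureModel(a[order(a$chain, decreasing = TRUE), ])
    s1 <- atoms(selectAtoms(fx$model, chains = "B"))
    s2 <- atoms(selectAtoms(rev, chains = "B"))
    expect_equal(s1[order(s1$serial), names(s1) != "serial"],
                 s2[order(s2$serial), names(s2) != "serial"],
                 ignore_attr = TRUE)
})

test_that("writing rejects empty and oversized models", {
    expect_error(writeStructure(structureModel(
        data.frame(name = "CA", resname = "GLY", chain = "A", resno = 1,
                   x = 0, y = 0, z = 0)[0, ]), tempfile()),
        "empty")
    fx <- makeHbondDimer(1, 5, seed = 1)
    big <- atoms(fx$model)[rep(1, 1e5 + 1), ]
    big$serial <- seq_len(nrow(big))
    m <- structureModel(big)
    expect_error(writeStructure(m, tempfile()), "overflow|99999")
})

test_that("HETATM ligands are exposed as LigandPose objects", {
    fx <- makeLigandPocket(c(1, 3), c(3.1, 3.9), seed = 2)
    ll <- ligands(fx$model)
    expect_length(ll, 1L)
    expect_equal(ll[[1]]@ligandName, "GTP")
    expect_equal(nAtoms(ll[[1]]), 1L)
})
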