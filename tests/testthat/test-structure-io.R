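test_that("a minimal dipeptide parses into residues with no waters", {
  f <- write_fixture(dipeptide_lines())
  s <- read_pdb(f)
  rt <- residue_table(s)
  expect_s3_class(s, "ncistruct")
  expect_equal(nrow(rt), 2)
  expect_equal(rt$resname, c("GLY", "ALA"))
  expect_false(any(s$atoms$is_water))
})

test_that("MODEL blocks become separate snapshots with increasing index", {
  body <- dipeptide_lines()
  lines <- c("MODEL     1", body, "ENDMDL",
             "MODEL     2", body, "ENDMDL",
             "MODEL     3", body, "ENDMDL")
  f <- write_fixture(lines)
  out <- read_pdb(f)
  expect_length(out, 3)
  expect_equal(vapply(out, `[[`, 0L, "snapshot_index"), 0:2)
})

test_that("alt-locs resolve to the highest-occupancy conformer, ties to A", {
  base <- dipeptide_lines()
  # duplicate the GLY CA with two conformers: A at 0.3, B at 0.7
  ca <- grep(" CA  GLY", base, value = TRUE)[1]
  xa <- pdb_line(99, "CA", "GLY", "A", 1, 9, 9, 9, occ = 0.3, alt = "A")
  xb <- pdb_line(98, "CA", "GLY", "A", 1, 7, 7, 7, occ = 0.7, alt = "B")
  f <- write_fixture(c(setdiff(base, ca), xa, xb))
  s <- read_pdb(f)
  ca_row <- s$atoms[s$atoms$name == "CA" & s$atoms$resno == 1, ]
  expect_equal(nrow(ca_row), 1)
  expect_equal(as.numeric(ca_row[, c("x", "y", "z")]), c(7, 7, 7))
  # tie: equal occupancy keeps altLoc A
  xb2 <- pdb_line(98, "CA", "GLY", "A", 1, 7, 7, 7, occ = 0.3, alt = "B")
  s2 <- read_pdb(write_fixture(c(setdiff(base, ca), xa, xb2)))
  ca2 <- s2$atoms[s2$atoms$name == "CA" & s2$atoms$resno == 1, ]
  expect_equal(as.numeric(ca2[, c("x", "y", "z")]), c(9, 9, 9))
})

test_that("write/read round trip preserves atoms to PDB precision", {
  s <- build_peptide("alpha_helix", n_res = 6)
  f <- tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f)
  expect_equal(nrow(s$atoms), nrow(s2$atoms))
  expect_equal(s$atoms$name, s2$atoms$name)
  expect_lt(max(abs(as.matrix(s$atoms[, c("x", "y", "z")]) -
                      as.matrix(s2$atoms[, c("x", "y", "z")]))), 5e-4 + 1e-9)
  # multi-model
  ens <- perturb_ensemble(s, 0.1, 3, seed = 5)
  f2 <- tempfile(fileext = ".pdb")
  write_pdb(ens, f2)
  back <- read_pdb(f2)
  expect_length(back, 3)
  expect_lt(max(abs(back[[2]]$atoms$x - ens[[2]]$atoms$x)), 5e-4 + 1e-9)
})

test_that("malformed coordinates raise a parse error naming the file", {
  bad <- dipeptide_lines()
  substr(bad[2], 31, 38) <- "   xx.yy"
  f <- write_fixture(bad)
  expect_error(read_pdb(f), "coordinates|parse")
})

test_that("donor enumeration on a Gly-Ala dipeptide", {
  f <- write_fixture(dipeptide_lines())
  s <- read_pdb(f)
  dn <- identify_donors(s)
  # one backbone NH (residue 2; residue 1 is the unprotonated N-terminus)
  expect_equal(sum(dn$category == "NH_bb"), 1)
  expect_equal(dn$resno[dn$category == "NH_bb"], 2)
  # glycine: one CaH group carrying both alpha hydrogens
  gly_ca <- dn[dn$category == "CaH" & dn$resno == 1, ]
  expect_equal(nrow(gly_ca), 1)
  expect_length(gly_ca$hyd[[1]], 2)
  # alanine: one CaH (1 H) and one CH_X (methyl, 3 H)
  ala_ca <- dn[dn$category == "CaH" & dn$resno == 2, ]
  expect_length(ala_ca$hyd[[1]], 1)
  ala_cb <- dn[dn$category == "CH_X" & dn$resno == 2, ]
  expect_equal(nrow(ala_cb), 1)
  expect_length(ala_cb$hyd[[1]], 3)
  # every donor hydrogen is covalently close to its heavy atom
  for (i in seq_len(nrow(dn))) {
    heavy <- as.numeric(s$atoms[dn$heavy[i], c("x", "y", "z")])
    for (h in dn$hyd[[i]]) {
      expect_lte(atom_distance(heavy,
                               as.numeric(s$atoms[h, c("x", "y", "z")])), 1.2)
    }
  }
})

test_that("proline contributes no backbone NH donor", {
  base <- dipeptide_lines()
  pro <- sub("ALA", "PRO", base[grep("ALA", base)])
  pro <- pro[!grepl(" H   PRO", pro)]  # proline has no amide H
  f <- write_fixture(c(base[grep("GLY", base)], pro))
  dn <- identify_donors(read_pdb(f))
  expect_equal(sum(dn$category == "NH_bb"), 0)
})

test_that("waters donate only with explicit hydrogens", {
  base <- dipeptide_lines()
  wat <- c(pdb_line(50, "O", "HOH", "W", 100, 10, 10, 10, het = TRUE),
           pdb_line(51, "H1", "HOH", "W", 100, 10.9, 10.2, 10, het = TRUE),
           pdb_line(52, "H2", "HOH", "W", 100, 9.7, 10.8, 10.4, het = TRUE),
           pdb_line(53, "O", "HOH", "W", 101, 20, 20, 20, het = TRUE))
  s <- read_pdb(write_fixture(c(base, wat)))
  dn <- identify_donors(s)
  hoh <- dn[dn$category == "HOH", ]
  expect_equal(nrow(hoh), 1)
  expect_length(hoh$hyd[[1]], 2)
  expect_equal(attr(dn, "waters_without_h"), 1L)
})

test_that("carbonyl sites: terminal exclusion, Asn side chain, empty input", {
  s <- build_peptide("alpha_helix", n_res = 10)
  sites <- identify_carbonyls(s)
  expect_equal(nrow(sites), 9)  # chain-terminal carboxylate excluded
  expect_true(all(sites$kind == "mainchain"))
  expect_equal(nrow(identify_carbonyls(s, include_terminal = TRUE)), 10)
  # an Asn residue adds a side-chain amide site
  base <- dipeptide_lines()
  gly <- base[grep("GLY", base)]
  asn <- sub("ALA", "ASN", base[grep("ALA", base)])
  s2 <- read_pdb(write_fixture(c(gly, asn)))
  cb <- as.numeric(s2$atoms[s2$atoms$name == "CB", c("x", "y", "z")])
  extra <- c(pdb_line(60, "CG", "ASN", "A", 2, cb[1] + 1.5, cb[2], cb[3]),
             pdb_line(61, "OD1", "ASN", "A", 2, cb[1] + 1.5, cb[2] + 1.23, cb[3]),
             pdb_line(62, "ND2", "ASN", "A", 2, cb[1] + 2.8, cb[2] - 0.5, cb[3]))
  s3 <- read_pdb(write_fixture(c(gly, asn[!grepl("HB", asn)], extra)))
  sites3 <- identify_carbonyls(s3, include_terminal = TRUE)
  expect_equal(sum(sites3$kind == "sidechain" & sites3$resname == "ASN"), 1)
  # empty structure
  empty <- new_structure("empty", data.frame(
    serial = integer(), name = character(), element = character(),
    alt = character(), resname = character(), chain = character(),
    resno = integer(), insert = character(), x = numeric(), y = numeric(),
    z = numeric(), occ = numeric()))
  expect_equal(nrow(identify_carbonyls(empty)), 0)
  expect_equal(nrow(identify_donors(empty)), 0)
})

test_that("identification is pure and topology pinning reproduces it", {
  s <- build_peptide("alpha_helix", n_res = 8)
  expect_identical(identify_carbonyls(s), identify_carbonyls(s))
  d1 <- identify_donors(s)
  d2 <- identify_donors(s)
  expect_identical(d1$heavy, d2$heavy)
  topo <- structure_topology(s)
  c_by_topo <- identify_carbonyls(s, topology = topo)
  expect_equal(c_by_topo$O, identify_carbonyls(s)$O)
  d_by_topo <- identify_donors(s, topology = topo)
  expect_equal(d_by_topo$heavy, d1$heavy)
})
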