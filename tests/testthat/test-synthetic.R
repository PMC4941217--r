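test_that("the built alpha helix matches textbook helix parameters", {
  s <- build_peptide("alpha_helix", n_res = 12)
  ca <- as.matrix(s$atoms[s$atoms$name == "CA", c("x", "y", "z")])
  pc <- stats::prcomp(ca)
  rise <- mean(diff(ca %*% pc$rotation[, 1]))
  expect_equal(abs(rise), 1.50, tolerance = 0.1 / 1.5)
  axis <- pc$rotation[, 1]
  rel <- sweep(ca, 2, colMeans(ca))
  perp <- rel - (rel %*% axis) %*% t(axis)
  ang <- vapply(seq_len(nrow(ca) - 1), function(i) {
    u <- perp[i, ] / sqrt(sum(perp[i, ]^2))
    v <- perp[i + 1, ] / sqrt(sum(perp[i + 1, ]^2))
    acos(max(-1, min(1, sum(u * v)))) * 180 / pi
  }, 0)
  expect_equal(360 / mean(ang), 3.6, tolerance = 0.1)
})

test_that("built internal coordinates hit the ideal values", {
  s <- build_peptide("alpha_helix", n_res = 8)
  a <- s$atoms
  g <- function(i, nm) as.numeric(a[a$resno == i & a$name == nm, c("x", "y", "z")])
  for (i in 3:6) {
    expect_equal(atom_distance(g(i, "N"), g(i, "CA")), 1.46, tolerance = 1e-6)
    expect_equal(atom_distance(g(i, "CA"), g(i, "C")), 1.52, tolerance = 1e-6)
    expect_equal(atom_distance(g(i, "C"), g(i, "O")), 1.23, tolerance = 1e-6)
    expect_equal(atom_distance(g(i, "C"), g(i + 1, "N")), 1.33, tolerance = 1e-6)
    expect_equal(bond_angle(g(i, "N"), g(i, "CA"), g(i, "C")), 111,
                 tolerance = 1e-6)
    # omega is trans
    expect_equal(dihedral_angle(g(i, "CA"), g(i, "C"), g(i + 1, "N"),
                                g(i + 1, "CA")), 180, tolerance = 1e-6)
  }
})

test_that("generation is deterministic for identical specs and seeds", {
  s1 <- build_peptide(build_spec("alpha_helix", n_res = 9,
                                 solvation = "exposed_carbonyls", seed = 4))
  s2 <- build_peptide(build_spec("alpha_helix", n_res = 9,
                                 solvation = "exposed_carbonyls", seed = 4))
  expect_identical(s1$atoms, s2$atoms)
  e1 <- perturb_ensemble(s1, 0.2, 4, seed = 9)
  e2 <- perturb_ensemble(s2, 0.2, 4, seed = 9)
  for (k in 1:4) expect_identical(e1[[k]]$atoms, e2[[k]]$atoms)
  # a different seed perturbs differently
  e3 <- perturb_ensemble(s1, 0.2, 4, seed = 10)
  expect_false(identical(e1[[1]]$atoms$x, e3[[1]]$atoms$x))
})

test_that("sigma = 0 snapshots are identical to the input", {
  s <- build_peptide("extended", n_res = 5)
  snaps <- perturb_ensemble(s, 0, 3, seed = 1)
  for (k in 1:3)
    expect_identical(snaps[[k]]$atoms[, c("x", "y", "z")],
                     s$atoms[, c("x", "y", "z")])
  expect_equal(vapply(snaps, `[[`, 0L, "snapshot_index"), 0:2)
})

test_that("single-residue build yields no NCIs downstream", {
  s <- build_peptide("alpha_helix", n_res = 1)
  expect_equal(nrow(residue_table(s)), 1)
  inv <- inventory_structure(s)
  expect_equal(nrow(inv$records), 0)
})

test_that("designed-NCI recovery on every template", {
  # helix: NH_bb(i+4) + n->pi*(i+1) on interior residues
  h <- inventory_structure(build_peptide("alpha_helix", n_res = 16))
  for (u in paste0("A|", 3:10, "|"))
    expect_equal(sort(h$records$nci_type[h$records$res_uid == u]),
                 c("NH_bb", "npistar"))
  # 3-10 helix: NH_bb(i+3)
  g <- inventory_structure(build_peptide("three10_helix", n_res = 12))
  g_nh <- g$records[g$records$nci_type == "NH_bb", ]
  expect_true(all(g_nh$seqsep == "3"))
  expect_gt(nrow(g_nh), 3)
  # antiparallel sheet: cross-strand NH_bb on the hydrogen-bonded pairs
  sh <- inventory_structure(build_peptide("antiparallel_sheet", n_res = 8))
  nh <- sh$records[sh$records$nci_type == "NH_bb", ]
  expect_gte(nrow(nh), 6)
  expect_true(all(abs(as.integer(nh$seqsep)) > 4))  # cross-strand, not local
  # parallel sheet: cross-strand NH_bb as well
  pl <- inventory_structure(build_peptide("parallel_sheet", n_res = 8))
  nhp <- pl$records[pl$records$nci_type == "NH_bb", ]
  expect_gte(nrow(nhp), 4)
  expect_true(all(abs(as.integer(nhp$seqsep)) > 4))
  # solvated extended peptide: two waters per carbonyl by construction
  w <- build_peptide(build_spec("extended", n_res = 6,
                                solvation = "exposed_carbonyls"))
  iw <- inventory_structure(w)
  expect_true(all(iw$residues$raw_count == 2))
  expect_true(all(vapply(split(iw$records$nci_type, iw$records$res_uid),
                         function(x) all(x == "HOH"), TRUE)))
})

test_that("solvation respects per_site and placed waters all qualify", {
  s <- build_peptide("extended", n_res = 5)
  expect_identical(solvate_carbonyls(s, per_site = 0), s)
  s2 <- solvate_carbonyls(s, per_site = 2, seed = 3)
  inv <- inventory_structure(s2, water_rule = FALSE)
  expect_true(all(inv$residues$raw_count == 2))
  hoh <- inv$records[inv$records$nci_type == "HOH", ]
  th <- nci_thresholds()
  expect_true(all(hoh$d <= th$d_OH_max))
  expect_true(all(hoh$omega >= th$omega_min & hoh$rho >= th$rho_min))
})

test_that("large noise strictly lowers the mean reported count", {
  s <- build_peptide("alpha_helix", n_res = 14)
  topo <- structure_topology(s)
  mean_count <- function(sig, seed) {
    snaps <- perturb_ensemble(s, sig, 4, seed = seed)
    mean(vapply(snaps, function(x)
      mean(inventory_structure(x, topology = topo)$residues$reported_count), 0))
  }
  m0 <- mean_count(0, 1)
  for (seed in 1:3) expect_lt(mean_count(1.0, seed), m0)
})
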