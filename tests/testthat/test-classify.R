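test_that("hydrogen-bond thresholds are applied as printed (inclusive)", {
  th <- nci_thresholds()
  # good geometry inside all cutoffs
  tc <- toy_hbond(2.0, 150, 120)
  expect_equal(bond_angle(as.numeric(tc$s$atoms[4, c("x", "y", "z")]),
                          as.numeric(tc$s$atoms[5, c("x", "y", "z")]),
                          c(0, 0, 0)), 150, tolerance = 1e-6)
  rec <- classify_hbond(tc$s, tc$site, tc$donor, th)
  expect_false(is.null(rec))
  expect_equal(rec$nci_type, "NH_bb")
  expect_equal(rec$d, 2.0, tolerance = 1e-9)
  # distance just over the NH cutoff
  expect_null(with(toy_hbond(2.50, 150, 120), classify_hbond(s, site, donor, th)))
  # exactly at the cutoff is accepted
  expect_false(is.null(with(toy_hbond(2.44, 150, 120),
                            classify_hbond(s, site, donor, th))))
  # omega and rho below 90 reject
  expect_null(with(toy_hbond(2.0, 85, 120), classify_hbond(s, site, donor, th)))
  expect_null(with(toy_hbond(2.0, 150, 85), classify_hbond(s, site, donor, th)))
  # OH cutoff is tighter than NH: 2.40 passes NH but fails OH/HOH
  expect_false(is.null(with(toy_hbond(2.40, 150, 120, "NH_sc"),
                            classify_hbond(s, site, donor, th))))
  expect_null(with(toy_hbond(2.40, 150, 120, "HOH"),
                   classify_hbond(s, site, donor, th)))
  # CH donors: wider distance window but an elevation limit
  expect_false(is.null(with(toy_hbond(2.60, 150, 120, "CH_X"),
                            classify_hbond(s, site, donor, th))))
  expect_null(with(toy_hbond(2.60, 150, 120, "CH_X", elev_out = TRUE),
                   classify_hbond(s, site, donor, th)))
  # out-of-plane placement does not matter for an NH donor
  expect_false(is.null(with(toy_hbond(2.0, 150, 120, elev_out = TRUE),
                            classify_hbond(s, site, donor, th))))
})

test_that("n->pi* thresholds: distance, Burgi-Dunitz window and planarity", {
  th <- nci_thresholds()
  ok <- toy_npistar(3.0, 110, 150)
  rec <- classify_npistar(ok$s, ok$donor_site, ok$acceptor_site, th)
  expect_false(is.null(rec))
  expect_equal(rec$nci_type, "npistar")
  expect_equal(rec$d, 3.0, tolerance = 1e-9)
  expect_equal(rec$theta, 110, tolerance = 1e-6)
  expect_null(with(toy_npistar(3.30, 110, 150),
                   classify_npistar(s, donor_site, acceptor_site, th)))
  expect_null(with(toy_npistar(3.0, 90, 150),
                   classify_npistar(s, donor_site, acceptor_site, th)))
  expect_null(with(toy_npistar(3.0, 130, 150),
                   classify_npistar(s, donor_site, acceptor_site, th)))
  expect_null(with(toy_npistar(3.0, 110, 60),
                   classify_npistar(s, donor_site, acceptor_site, th)))
  # a site never donates to itself
  expect_null(classify_npistar(ok$s, ok$donor_site, ok$donor_site, th))
})

test_that("ideal helix recovers the canonical NH_bb(i+4) + n->pi*(i+1) pair", {
  s <- build_peptide("alpha_helix", n_res = 20)
  inv <- inventory_structure(s)
  interior <- paste0("A|", 2:15, "|")
  for (u in interior) {
    r <- inv$records[inv$records$res_uid == u, ]
    expect_equal(sort(r$nci_type), c("NH_bb", "npistar"))
    expect_equal(r$seqsep[r$nci_type == "NH_bb"], "4")
    expect_equal(r$seqsep[r$nci_type == "npistar"], "1")
  }
  expect_true(all(inv$residues$reported_count[
    inv$residues$res_uid %in% interior] == 2))
})

test_that("the water-saturation rule reports exactly two for water-only sites", {
  for (ps in 1:3) {
    s <- solvate_carbonyls(build_peptide("extended", n_res = 6), per_site = ps,
                           seed = 11)
    inv <- inventory_structure(s)
    expect_true(all(inv$residues$raw_count == ps))
    expect_true(all(inv$residues$reported_count == 2))
    expect_true(all(inv$residues$water_only))
  }
  # dry structure: no water, counts unchanged, rule does not fire
  dry <- inventory_structure(build_peptide("extended", n_res = 6))
  expect_true(all(dry$residues$reported_count == 0))
  expect_false(any(dry$residues$water_only))
})

test_that("the water rule leaves mixed protein+water inventories alone", {
  inv <- structure(list(
    structure_id = "hand", snapshot_index = 0L,
    records = data.frame(res_uid = c("A|1|", "A|1|", "A|2|"),
                         nci_type = c("HOH", "NH_bb", "HOH"),
                         stringsAsFactors = FALSE),
    residues = data.frame(res_uid = c("A|1|", "A|2|", "A|3|"),
                          chain = "A", resno = 1:3, insert = "",
                          resname = "ALA", raw_count = c(2L, 1L, 0L),
                          water_near = c(TRUE, TRUE, FALSE),
                          water_only = FALSE, reported_count = c(2L, 1L, 0L),
                          stringsAsFactors = FALSE)),
    class = "nci_inventory")
  out <- apply_water_rule(inv)
  # mixed set keeps the raw count; water-only set snaps to 2; a buried
  # empty set stays 0
  expect_equal(out$residues$reported_count, c(2L, 2L, 0L))
  expect_equal(out$residues$water_only, c(FALSE, TRUE, FALSE))
})

test_that("classification is pure and rigid-motion invariant", {
  s <- solvate_carbonyls(build_peptide("alpha_helix", n_res = 10),
                         per_site = 1, seed = 2)
  k1 <- inventory_keys(inventory_structure(s))
  k2 <- inventory_keys(inventory_structure(s))
  expect_identical(k1, k2)
  for (seed in 1:3) {
    km <- inventory_keys(inventory_structure(rigid_motion(s, seed)))
    expect_identical(k1, km)
  }
})

test_that("every stored record re-checks against its thresholds", {
  th <- nci_thresholds()
  s <- random_structure(99)
  inv <- inventory_structure(s, th)
  r <- inv$records
  hb <- r[!r$nci_type %in% c("npistar", "npistar_sc"), ]
  if (nrow(hb)) {
    cut <- ifelse(hb$nci_type %in% c("NH_bb", "NH_sc"), th$d_NH_max,
                  ifelse(hb$nci_type %in% c("OH_sc", "HOH"), th$d_OH_max,
                         th$d_CH_max))
    expect_true(all(hb$d <= cut))
    expect_true(all(hb$omega >= th$omega_min))
    expect_true(all(hb$rho >= th$rho_min))
    ch <- hb[hb$nci_type %in% c("CaH", "CH_X"), ]
    if (nrow(ch)) expect_true(all(ch$elevation < th$elevation_max))
  }
  np <- r[r$nci_type %in% c("npistar", "npistar_sc"), ]
  if (nrow(np)) {
    expect_true(all(np$d <= th$d_npistar_max))
    expect_true(all(np$theta >= th$theta_min & np$theta <= th$theta_max))
    expect_true(all(is.na(np$chi) | np$chi >= th$chi_min))
  }
})

test_that("the prefilter radius dominates every distance cutoff", {
  th <- nci_thresholds()
  expect_gt(th$prefilter,
            max(th$d_NH_max, th$d_OH_max, th$d_CH_max) + 1.2)
  expect_error(nci_thresholds(prefilter = 3), "prefilter")
})

test_that("prefiltered classifier equals the brute-force double loop", {
  # small sweep here; the full 50-structure sweep runs in the acceptance
  # suite
  for (seed in 1:10) {
    s <- random_structure(seed)
    expect_identical(inventory_keys(inventory_structure(s)),
                     brute_force_keys(s), label = paste("seed", seed))
  }
})
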