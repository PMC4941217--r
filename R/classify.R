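# Operational classification of backbone-carbonyl NCIs. Every (carbonyl,
# donor) pair within a generous prefilter is measured and accepted or
# rejected against the geometric thresholds; the per-residue inventory then
# applies the water-saturation rule.

#' Geometric thresholds for NCI classification
#'
#' Defaults are the operational cutoffs used throughout: hydrogen bonds
#' require d(H...O) below a donor-class cutoff (NH 2.44 A, OH/water 2.31 A,
#' CH 2.68 A) with donor linearity omega >= 90 deg and acceptor approach
#' rho >= 90 deg; CH donors additionally require the hydrogen to approach
#' within 50 deg of the sp2 carbonyl plane. n->pi* contacts require
#' d(O...C) <= 3.22 A, a Burgi-Dunitz-type angle theta in [95, 125] deg and
#' a planarity torsion chi >= 120 deg about the donor C=O bond
#' (`chi_mode = "donor_plane"`: Ca-C-O(donor)...C(acceptor); the historical
#' alternative `"acceptor_amide_h"` uses the donor residue's amide H as the
#' fourth atom). All cutoffs are inclusive.
#'
#' @param d_NH_max,d_OH_max,d_CH_max Hydrogen-bond distance cutoffs (A).
#' @param omega_min,rho_min Angular cutoffs (degrees).
#' @param elevation_max Out-of-plane limit for CH donors (degrees).
#' @param d_npistar_max,theta_min,theta_max,chi_min n->pi* cutoffs.
#' @param chi_mode Atom choice for the chi torsion (see Details).
#' @param water_contact_max Water-exposure radius for the water rule (A).
#' @param prefilter Heavy-atom prefilter radius for candidate pairs (A).
#' @return A list of class `nci_thresholds`.
#' @export
nci_thresholds <- function(d_NH_max = 2.44, d_OH_max = 2.31, d_CH_max = 2.68,
                           omega_min = 90, rho_min = 90, elevation_max = 50,
                           d_npistar_max = 3.22, theta_min = 95,
                           theta_max = 125, chi_min = 120,
                           chi_mode = c("donor_plane", "acceptor_amide_h"),
                           water_contact_max = 3.5, prefilter = 5) {
  chi_mode <- match.arg(chi_mode)
  th <- list(d_NH_max = d_NH_max, d_OH_max = d_OH_max, d_CH_max = d_CH_max,
             omega_min = omega_min, rho_min = rho_min,
             elevation_max = elevation_max, d_npistar_max = d_npistar_max,
             theta_min = theta_min, theta_max = theta_max, chi_min = chi_min,
             chi_mode = chi_mode, water_contact_max = water_contact_max,
             prefilter = prefilter)
  num <- vapply(th[setdiff(names(th), "chi_mode")], is.numeric, TRUE)
  if (!all(num)) stop("thresholds must be numeric")
  if (any(unlist(th[setdiff(names(th), "chi_mode")]) <= 0))
    stop("thresholds must be positive")
  if (th$theta_min >= th$theta_max) stop("theta_min must be < theta_max")
  # the prefilter must dominate every distance cutoff plus the covalent
  # X-H offset, so prefiltering can never drop a qualifying pair
  if (th$prefilter < max(d_NH_max, d_OH_max, d_CH_max) + 1.2)
    stop("prefilter radius too small for the distance cutoffs")
  class(th) <- "nci_thresholds"
  th
}

.h_cutoff <- function(category, th) {
  switch(category,
         NH_bb = th$d_NH_max, NH_sc = th$d_NH_max,
         OH_sc = th$d_OH_max, HOH = th$d_OH_max,
         CaH = th$d_CH_max, CH_X = th$d_CH_max,
         stop("unknown donor category: ", category))
}

.empty_records <- function() {
  data.frame(res_uid = character(), nci_type = character(),
             partner_uid = character(), partner_atom = character(),
             partner_resname = character(), partner_chain = character(),
             partner_resno = integer(), d = numeric(), omega = numeric(),
             rho = numeric(), theta = numeric(), chi = numeric(),
             elevation = numeric(), seqsep = character(),
             stringsAsFactors = FALSE)
}

#' Classify a potential hydrogen bond to a carbonyl oxygen
#'
#' Measures every hydrogen of the donor group against the carbonyl oxygen:
#' d(H...O), omega (angle donor-heavy - H ... O), rho (angle H ... O = C),
#' and for CH donors the elevation of H above the sp2 carbonyl plane. The
#' best (smallest-d) qualifying hydrogen yields the record. The donor NH of
#' the carbonyl's own peptide unit (the following residue's backbone NH) is
#' a covalent neighbour, not an interaction, and is rejected.
#'
#' @param s An `ncistruct`.
#' @param site One row of [identify_carbonyls()].
#' @param donor One row of [identify_donors()].
#' @param th An [nci_thresholds()].
#' @return A one-row record data.frame, or `NULL` if no hydrogen qualifies.
#' @export
classify_hbond <- function(s, site, donor, th = nci_thresholds()) {
  a <- s$atoms
  # self-pair: the backbone NH bonded to this carbonyl's peptide unit
  if (donor$category == "NH_bb" && site$kind == "mainchain" &&
      donor$chain == site$chain) {
    dN <- as.numeric(a[donor$heavy, c("x", "y", "z")])
    Cc <- as.numeric(a[site$C, c("x", "y", "z")])
    if (atom_distance(dN, Cc) <= 1.8) return(NULL)
  }
  hyd <- donor$hyd[[1]]
  if (!length(hyd)) return(NULL)
  O <- as.numeric(a[site$O, c("x", "y", "z")])
  C <- as.numeric(a[site$C, c("x", "y", "z")])
  CAx <- as.numeric(a[site$CAx, c("x", "y", "z")])
  heavy <- as.numeric(a[donor$heavy, c("x", "y", "z")])
  cutoff <- .h_cutoff(donor$category, th)
  best <- NULL
  for (h in hyd) {
    H <- as.numeric(a[h, c("x", "y", "z")])
    d <- atom_distance(H, O)
    if (d > cutoff) next
    omega <- bond_angle(heavy, H, O)
    if (omega < th$omega_min) next
    rho <- bond_angle(H, O, C)
    if (rho < th$rho_min) next
    elev <- NA_real_
    if (donor$category %in% c("CaH", "CH_X")) {
      elev <- elevation_angle(H, CAx, C, O)
      if (elev >= th$elevation_max) next
    }
    if (is.null(best) || d < best$d) {
      best <- data.frame(
        res_uid = site$res_uid, nci_type = donor$category,
        partner_uid = donor$res_uid, partner_atom = a$name[h],
        partner_resname = donor$resname, partner_chain = donor$chain,
        partner_resno = donor$resno, d = d, omega = omega, rho = rho,
        theta = NA_real_, chi = NA_real_, elevation = elev,
        seqsep = if (donor$category == "HOH") "water"
                 else if (donor$chain != site$chain) "interchain"
                 else as.character(donor$resno - site$resno),
        stringsAsFactors = FALSE)
    }
  }
  best
}

#' Classify a potential n->pi* carbonyl-carbonyl interaction
#'
#' The donor carbonyl's oxygen lone pair is donated into the pi* orbital of
#' the acceptor carbonyl carbon. Measured: d = d(O_donor, C_acceptor),
#' theta = angle O_donor ... C_acceptor = O_acceptor, and the planarity
#' torsion chi (see [nci_thresholds()]). The record is attributed to the
#' donor carbonyl's residue: it is that oxygen's lone pair being satisfied.
#'
#' @param s An `ncistruct`.
#' @param donor_site,acceptor_site Rows of [identify_carbonyls()].
#' @param th An [nci_thresholds()].
#' @return A one-row record data.frame, or `NULL`.
#' @export
classify_npistar <- function(s, donor_site, acceptor_site,
                             th = nci_thresholds()) {
  if (donor_site$res_uid == acceptor_site$res_uid &&
      donor_site$kind == acceptor_site$kind) return(NULL)
  a <- s$atoms
  Od <- as.numeric(a[donor_site$O, c("x", "y", "z")])
  Ca <- as.numeric(a[acceptor_site$C, c("x", "y", "z")])
  d <- atom_distance(Od, Ca)
  if (d > th$d_npistar_max || d < 1.5) return(NULL)
  Oa <- as.numeric(a[acceptor_site$O, c("x", "y", "z")])
  theta <- bond_angle(Od, Ca, Oa)
  if (theta < th$theta_min || theta > th$theta_max) return(NULL)
  chi <- .npistar_chi(s, donor_site, acceptor_site, th)
  if (!is.na(chi) && chi < th$chi_min) return(NULL)
  data.frame(
    res_uid = donor_site$res_uid,
    nci_type = if (acceptor_site$kind == "sidechain") "npistar_sc" else "npistar",
    partner_uid = acceptor_site$res_uid,
    partner_atom = s$atoms$name[acceptor_site$C],
    partner_resname = acceptor_site$resname,
    partner_chain = acceptor_site$chain,
    partner_resno = acceptor_site$resno,
    d = d, omega = NA_real_, rho = NA_real_, theta = theta, chi = chi,
    elevation = NA_real_,
    seqsep = if (acceptor_site$chain != donor_site$chain) "interchain"
             else as.character(acceptor_site$resno - donor_site$resno),
    stringsAsFactors = FALSE)
}

.npistar_chi <- function(s, donor_site, acceptor_site, th) {
  a <- s$atoms
  if (th$chi_mode == "donor_plane") {
    dihedral_angle(as.numeric(a[donor_site$CAx, c("x", "y", "z")]),
                   as.numeric(a[donor_site$C, c("x", "y", "z")]),
                   as.numeric(a[donor_site$O, c("x", "y", "z")]),
                   as.numeric(a[acceptor_site$C, c("x", "y", "z")]))
  } else {
    h <- .atom_idx(a, donor_site$res_uid, "H")
    if (is.na(h)) return(NA_real_)  # Pro / N-terminus: treated as passing
    dihedral_angle(as.numeric(a[acceptor_site$CAx, c("x", "y", "z")]),
                   as.numeric(a[acceptor_site$C, c("x", "y", "z")]),
                   as.numeric(a[donor_site$O, c("x", "y", "z")]),
                   as.numeric(a[h, c("x", "y", "z")]))
  }
}

#' Inventory all carbonyl NCIs of a structure
#'
#' Tests every mainchain carbonyl against every donor group within a
#' heavy-atom prefilter and every other carbonyl site (as n->pi* acceptor)
#' within the n->pi* cutoff plus 1 A, producing one inventory row per
#' mainchain carbonyl with the water-saturation rule applied.
#'
#' @param s An `ncistruct`.
#' @param th An [nci_thresholds()].
#' @param water_rule Apply the water-saturation rule (default TRUE).
#' @param topology Optional [structure_topology()] of the reference
#'   structure; use it when inventorying ensemble snapshots so connectivity
#'   is pinned across snapshots.
#' @return An object of class `nci_inventory`: list with `records` (one row
#'   per classified interaction) and `residues` (per-carbonyl counts:
#'   raw_count, reported_count, water_only, water_near).
#' @export
inventory_structure <- function(s, th = nci_thresholds(),
                                water_rule = TRUE, topology = NULL) {
  sites <- identify_carbonyls(s, topology = topology)
  donors <- identify_donors(s, topology = topology)
  a <- s$atoms
  main <- sites[sites$kind == "mainchain", , drop = FALSE]
  recs <- list()
  if (nrow(main)) {
    O_xyz <- .xyz(a, main$O)
    if (nrow(donors)) {
      don_xyz <- .xyz(a, donors$heavy)
      for (i in seq_len(nrow(main))) {
        dd <- atom_distance(don_xyz, matrix(O_xyz[i, ], nrow(donors), 3,
                                            byrow = TRUE))
        for (j in which(dd <= th$prefilter)) {
          r <- classify_hbond(s, main[i, ], donors[j, ], th)
          if (!is.null(r)) recs[[length(recs) + 1L]] <- r
        }
      }
    }
    if (nrow(sites) > 1) {
      acc_C <- .xyz(a, sites$C)
      for (i in seq_len(nrow(main))) {
        dd <- atom_distance(acc_C, matrix(O_xyz[i, ], nrow(sites), 3,
                                          byrow = TRUE))
        for (j in which(dd <= th$d_npistar_max + 1)) {
          r <- classify_npistar(s, main[i, ], sites[j, ], th)
          if (!is.null(r)) recs[[length(recs) + 1L]] <- r
        }
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else .empty_records()
  rownames(records) <- NULL
  res <- main[, c("res_uid", "chain", "resno", "insert", "resname")]
  res$raw_count <- vapply(res$res_uid, function(u)
    sum(records$res_uid == u), 0L)
  # water exposure: any water oxygen within the contact radius of the
  # carbonyl O (used by the saturation rule)
  wat_o <- which(a$is_water & a$element == "O")
  res$water_near <- logical(nrow(res))
  if (length(wat_o) && nrow(res)) {
    w_xyz <- .xyz(a, wat_o)
    for (i in seq_len(nrow(res))) {
      d <- atom_distance(w_xyz, matrix(as.numeric(a[main$O[i], c("x", "y", "z")]),
                                       length(wat_o), 3, byrow = TRUE))
      res$water_near[i] <- any(d <= th$water_contact_max)
    }
  }
  res$water_only <- logical(nrow(res))
  res$reported_count <- res$raw_count
  rownames(res) <- NULL
  inv <- structure(list(structure_id = s$id, snapshot_index = s$snapshot_index,
                        records = records, residues = res, thresholds = th),
                   class = "nci_inventory")
  if (water_rule) apply_water_rule(inv) else inv
}

#' Apply the water-saturation rule
#'
#' A carbonyl whose only qualifying NCIs are to water is taken to be fully
#' exposed and is assigned a reported count of exactly 2 (one hydrogen bond
#' per lone pair), provided at least one water oxygen lies within the
#' exposure radius of the carbonyl oxygen. Residues with any protein NCI
#' keep their raw count.
#'
#' @param inv An `nci_inventory`.
#' @return The inventory with `reported_count` and `water_only` updated.
#' @export
apply_water_rule <- function(inv) {
  stopifnot(inherits(inv, "nci_inventory"))
  res <- inv$residues
  for (i in seq_len(nrow(res))) {
    u <- res$res_uid[i]
    types <- inv$records$nci_type[inv$records$res_uid == u]
    all_water <- all(types == "HOH")  # TRUE also for zero records
    if (all_water && res$water_near[i]) {
      res$water_only[i] <- TRUE
      res$reported_count[i] <- 2L
    } else {
      res$water_only[i] <- FALSE
      res$reported_count[i] <- res$raw_count[i]
    }
  }
  inv$residues <- res
  inv
}

#' @export
print.nci_inventory <- function(x, ...) {
  cat(sprintf("<nci_inventory> %s snapshot %d: %d carbonyls, %d records\n",
              x$structure_id, x$snapshot_index, nrow(x$residues),
              nrow(x$records)))
  if (nrow(x$records))
    print(table(x$records$nci_type))
  invisible(x)
}

#' @export
summary.nci_inventory <- function(object, ...) {
  res <- object$residues
  list(structure_id = object$structure_id,
       n_carbonyls = nrow(res),
       count_distribution = table(res$reported_count),
       n_water_only = sum(res$water_only),
       types = table(object$records$nci_type))
}

#' Export an inventory as a TSV table
#'
#' One row per classified interaction (with its geometry) plus one summary
#' row per carbonyl residue.
#'
#' @param inv An `nci_inventory`.
#' @param path Output TSV path.
#' @return Invisibly, the exported data.frame.
#' @export
write_inventory_tsv <- function(inv, path) {
  res <- inv$residues
  rec <- inv$records
  rec_rows <- merge(rec, res[, c("res_uid", "resname", "raw_count",
                                 "reported_count", "water_only")],
                    by = "res_uid")
  sum_rows <- res
  sum_rows$nci_type <- "SUMMARY"
  out <- data.frame(structure_id = inv$structure_id,
                    snapshot = inv$snapshot_index,
                    res_uid = c(rec_rows$res_uid, sum_rows$res_uid),
                    resname = c(rec_rows$resname, sum_rows$resname),
                    nci_type = c(rec_rows$nci_type, sum_rows$nci_type),
                    partner_uid = c(rec_rows$partner_uid,
                                    rep(NA, nrow(sum_rows))),
                    partner_atom = c(rec_rows$partner_atom,
                                     rep(NA, nrow(sum_rows))),
                    d = c(rec_rows$d, rep(NA, nrow(sum_rows))),
                    omega = c(rec_rows$omega, rep(NA, nrow(sum_rows))),
                    rho = c(rec_rows$rho, rep(NA, nrow(sum_rows))),
                    theta = c(rec_rows$theta, rep(NA, nrow(sum_rows))),
                    chi = c(rec_rows$chi, rep(NA, nrow(sum_rows))),
                    elevation = c(rec_rows$elevation, rep(NA, nrow(sum_rows))),
                    seqsep = c(rec_rows$seqsep, rep(NA, nrow(sum_rows))),
                    raw_count = c(rec_rows$raw_count, sum_rows$raw_count),
                    reported_count = c(rec_rows$reported_count,
                                       sum_rows$reported_count),
                    water_only = c(rec_rows$water_only, sum_rows$water_only),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
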