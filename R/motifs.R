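# Mining of sustained under-/over-satisfied carbonyls: the named 3-NCI
# helix clusters, bifurcated hydrogen bonds, sequence profiles around motif
# anchors, and an optional sub-van-der-Waals contact scan for 1-NCI
# residues.

.MOTIF_DEFS <- list(
  M1_helix_NHbb_npistar_CHX = list(combo = c("CH_X", "NH_bb", "npistar"),
                                   ss = "alpha_helix"),
  M2_Nterm_2NHbb_npistar = list(combo = c("NH_bb", "NH_bb", "npistar"),
                                ss = "alpha_helix"),
  M3_Cterm_NHbb_OHsc_npistar = list(combo = c("NH_bb", "OH_sc", "npistar"),
                                    ss = "alpha_helix"),
  M4_strand_NHbb_CaH_HOH = list(combo = c("CaH", "HOH", "NH_bb"),
                                ss = "beta_strand"))

#' Residues sustaining a given NCI count
#'
#' Residues whose modal count equals `target_count` and whose occupancy at
#' the mode is at least `min_occupancy` -- sustained states, not ephemeral
#' fluctuations.
#'
#' @param ei An `nci_ensemble`.
#' @param target_count Target NCI count.
#' @param min_occupancy Occupancy threshold (default 0.5, inclusive).
#' @return Character vector of residue ids.
#' @export
find_sustained <- function(ei, target_count, min_occupancy = 0.5) {
  stopifnot(inherits(ei, "nci_ensemble"))
  modal <- apply(ei$counts, 1, modal_count)
  occ <- apply(ei$counts, 1, occupancy_at_mode)
  ei$residues[modal == target_count & occ >= min_occupancy]
}

# most frequent combination multiset among the snapshots at the modal
# count; ties resolved to the lexicographically smallest key
.modal_combo <- function(ei, i) {
  m <- modal_count(ei$counts[i, ])
  ks <- vapply(which(ei$counts[i, ] == m),
               function(k) .combo_key(ei$combos[[i, k]]), "")
  tab <- table(ks)
  names(tab)[tab == max(tab)][1]
}

# position of a residue within its (collapsed) helix run: "N" first turn,
# "C" last turn, "mid" otherwise, NA if not helical
.helix_side <- function(ei, i) {
  if (is.null(ei$ss)) return(NA_character_)
  helix <- ei$ss == "alpha_helix"
  if (!isTRUE(helix[i])) return(NA_character_)
  r <- rle(helix)
  ends <- cumsum(r$lengths); starts <- c(1, utils::head(ends, -1) + 1)
  k <- which(starts <= i & ends >= i & r$values)
  a <- starts[k]; b <- ends[k]
  if (i <= a + 3 && i >= b - 3) "NC"
  else if (i <= a + 3) "N"
  else if (i >= b - 3) "C"
  else "mid"
}

#' Classify the sustained-NCI motif of a residue
#'
#' Matches the residue's modal NCI combination against the named clusters:
#' M1 (helix; NH_bb + n->pi* + CH_X), M2 (helix N-terminal turn; 2 x NH_bb
#' from the i+3 and i+4 amides, forming a bifurcated pair, + n->pi*), M3
#' (helix C-terminal turn; NH_bb + Ser/Thr OH_sc + n->pi*), M4 (strand;
#' NH_bb + CaH + water). A sustained 1-NCI residue is reported as
#' `undersatisfied_1NCI`; anything else sustained at 3 yields motif
#' `"none"`.
#'
#' @param ei An `nci_ensemble` built with records (see
#'   [ensemble_from_inventories()]).
#' @param residue Residue id (element of `ei$residues`).
#' @param min_occupancy Occupancy threshold (default 0.5).
#' @return One-row data.frame (residue, motif, occupancy,
#'   snapshots_matching, ss_class, little_h, helix_side, modal_combo), or
#'   NULL when the residue sustains neither 1 nor 3 NCIs.
#' @export
classify_motif <- function(ei, residue, min_occupancy = 0.5) {
  stopifnot(inherits(ei, "nci_ensemble"))
  i <- match(residue, ei$residues)
  if (is.na(i)) stop("unknown residue: ", residue)
  series <- ei$counts[i, ]
  m <- modal_count(series)
  occ <- occupancy_at_mode(series)
  if (!(m %in% c(1L, 3L)) || occ < min_occupancy) return(NULL)
  key <- .modal_combo(ei, i)
  types <- if (key == "(none)") character() else strsplit(key, "+", fixed = TRUE)[[1]]
  ssc <- if (is.null(ei$ss)) NA_character_ else ei$ss[i]
  lit <- if (!is.null(ei$ss_table)) {
    isTRUE(ei$ss_table$little_h[match(residue, ei$ss_table$res_uid)])
  } else NA
  side <- .helix_side(ei, i)
  n_match <- sum(vapply(seq_len(ncol(ei$counts)), function(k)
    .combo_key(ei$combos[[i, k]]) == key, TRUE))
  motif <- "none"
  if (m == 1L) {
    motif <- "undersatisfied_1NCI"
  } else {
    for (nm in names(.MOTIF_DEFS)) {
      def <- .MOTIF_DEFS[[nm]]
      if (!identical(sort(types), sort(def$combo))) next
      if (!is.na(ssc) && ssc != def$ss) next
      if (nm == "M2_Nterm_2NHbb_npistar") {
        if (!is.na(side) && !side %in% c("N", "NC")) next
        if (!.check_m2_donors(ei, residue)) next
      }
      if (nm == "M3_Cterm_NHbb_OHsc_npistar") {
        if (!is.na(side) && !side %in% c("C", "NC")) next
        if (!.check_m3_donor(ei, residue)) next
      }
      motif <- nm
      break
    }
  }
  data.frame(residue = residue, motif = motif, occupancy = occ,
             snapshots_matching = n_match, ss_class = ssc, little_h = lit,
             helix_side = side, modal_combo = key, stringsAsFactors = FALSE)
}

# M2: the two NH_bb donors must be the i+3 and i+4 amides (the bifurcated
# helix pair, read from the donor side as i-3/i-4)
.check_m2_donors <- function(ei, residue) {
  if (is.null(ei$records)) return(TRUE)
  for (rec in ei$records) {
    seps <- rec$seqsep[rec$res_uid == residue & rec$nci_type == "NH_bb"]
    if (length(seps) >= 2 && all(c("3", "4") %in% seps)) return(TRUE)
  }
  FALSE
}

# M3: the hydroxyl donor must come from Ser or Thr
.check_m3_donor <- function(ei, residue) {
  if (is.null(ei$records)) return(TRUE)
  for (rec in ei$records) {
    rn <- rec$partner_resname[rec$res_uid == residue & rec$nci_type == "OH_sc"]
    if (length(rn) && any(rn %in% c("SER", "THR"))) return(TRUE)
  }
  FALSE
}

#' Find all sustained motif hits in an ensemble
#'
#' Runs [classify_motif()] over the sustained 1- and 3-NCI residue sets.
#'
#' @param ei An `nci_ensemble`.
#' @param min_occupancy Occupancy threshold.
#' @return data.frame of motif hits (possibly empty).
#' @export
find_motifs <- function(ei, min_occupancy = 0.5) {
  res <- c(find_sustained(ei, 1L, min_occupancy),
           find_sustained(ei, 3L, min_occupancy))
  hits <- lapply(res, function(u) classify_motif(ei, u, min_occupancy))
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (!length(hits)) {
    return(data.frame(residue = character(), motif = character(),
                      occupancy = numeric(), snapshots_matching = integer(),
                      ss_class = character(), little_h = logical(),
                      helix_side = character(), modal_combo = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Fraction of backbone-NH hydrogen bonds that are bifurcated
#'
#' A backbone amide NH is bifurcated when it donates qualifying hydrogen
#' bonds to two different carbonyl acceptors in the same snapshot. The
#' default pools records over snapshots: numerator = NH_bb records whose
#' donor also bonds a second acceptor in that snapshot, denominator = all
#' NH_bb records. `mode = "unique"` counts distinct (donor, acceptor) bonds
#' over the whole ensemble instead.
#'
#' @param ei An `nci_ensemble` built with records.
#' @param mode "pooled" (default) or "unique".
#' @return Fraction in [0, 1], or NA if there are no NH_bb records.
#' @export
bifurcation_fraction <- function(ei, mode = c("pooled", "unique")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ei, "nci_ensemble"))
  if (is.null(ei$records)) stop("ensemble has no record data")
  if (mode == "pooled") {
    num <- 0L; den <- 0L
    for (rec in ei$records) {
      nh <- rec[rec$nci_type == "NH_bb", , drop = FALSE]
      if (!nrow(nh)) next
      den <- den + nrow(nh)
      acc_per_donor <- tapply(nh$res_uid, nh$partner_uid,
                              function(x) length(unique(x)))
      bif <- names(acc_per_donor)[acc_per_donor >= 2]
      num <- num + sum(nh$partner_uid %in% bif)
    }
    if (den == 0L) return(NA_real_)
    num / den
  } else {
    bonds <- unique(do.call(rbind, lapply(ei$records, function(rec)
      rec[rec$nci_type == "NH_bb", c("partner_uid", "res_uid")])))
    if (is.null(bonds) || !nrow(bonds)) return(NA_real_)
    acc_per_donor <- tapply(bonds$res_uid, bonds$partner_uid,
                            function(x) length(unique(x)))
    bif <- names(acc_per_donor)[acc_per_donor >= 2]
    sum(bonds$partner_uid %in% bif) / nrow(bonds)
  }
}

#' Amino-acid frequency profile around motif anchors
#'
#' Per-position residue-type frequencies in a window around each motif
#' anchor residue (the plain-table equivalent of a sequence logo).
#'
#' @param hits Motif hit data.frame ([find_motifs()]), sharing one motif
#'   label.
#' @param ei The `nci_ensemble` the hits came from (provides the residue
#'   order and names).
#' @param flank Number of positions either side of the anchor.
#' @return Matrix positions x amino acids; rows sum to 1 (ignoring
#'   positions that fall outside the chain).
#' @export
sequence_profile <- function(hits, ei, flank = 2) {
  stopifnot(inherits(ei, "nci_ensemble"))
  if (is.null(ei$resnames)) stop("ensemble has no residue names")
  pos <- (-flank):flank
  aas <- sort(unique(ei$resnames))
  m <- matrix(0, length(pos), length(aas),
              dimnames = list(as.character(pos), aas))
  for (r in hits$residue) {
    i <- match(r, ei$residues)
    for (p in seq_along(pos)) {
      j <- i + pos[p]
      if (j < 1 || j > length(ei$resnames)) next
      m[p, ei$resnames[j]] <- m[p, ei$resnames[j]] + 1
    }
  }
  sw <- rowSums(m)
  m[sw > 0, ] <- m[sw > 0, ] / sw[sw > 0]
  m
}

#' Sub-van-der-Waals contact scan for under-satisfied carbonyls
#'
#' For each sustained 1-NCI residue, measures the undocumented close
#' contacts of its carbonyl oxygen: to the backbone amide proton of the
#' same residue and to the alpha proton of the following residue (minimum
#' over the two HA of glycine), and flags distances below the O...H
#' van-der-Waals sum.
#'
#' @param s Reference `ncistruct` (coordinates).
#' @param residues Residue ids to scan (e.g. `find_sustained(ei, 1)`).
#' @param cutoff O...H van-der-Waals sum, default 2.72 A (1.52 + 1.20).
#' @return data.frame: residue, d_NH_same, d_CaH_next, below_cutoff flags
#'   (NA where the hydrogen is absent).
#' @export
subvdw_scan <- function(s, residues, cutoff = 2.72) {
  a <- s$atoms
  rt <- residue_table(s)
  out <- lapply(residues, function(u) {
    i <- match(u, rt$res_uid)
    O <- .atom_idx(a, u, "O")
    d1 <- d2 <- NA_real_
    if (!is.na(O)) {
      Oxyz <- as.numeric(a[O, c("x", "y", "z")])
      h <- .atom_idx(a, u, "H")
      if (!is.na(h)) d1 <- atom_distance(Oxyz, as.numeric(a[h, c("x", "y", "z")]))
      if (!is.na(i) && i < nrow(rt) && rt$chain[i + 1] == rt$chain[i]) {
        u2 <- rt$res_uid[i + 1]
        has <- which(a$res_uid == u2 & a$name %in% c("HA", "HA2", "HA3"))
        if (length(has)) {
          d2 <- min(atom_distance(.xyz(a, has),
                                  matrix(Oxyz, length(has), 3, byrow = TRUE)))
        }
      }
    }
    data.frame(residue = u, d_NH_same = d1, d_CaH_next = d2,
               NH_below = !is.na(d1) & d1 < cutoff,
               CaH_below = !is.na(d2) & d2 < cutoff,
               stringsAsFactors = FALSE)
  })
  if (!length(out)) {
    return(data.frame(residue = character(), d_NH_same = numeric(),
                      d_CaH_next = numeric(), NH_below = logical(),
                      CaH_below = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
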