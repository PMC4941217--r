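# Ideal-geometry peptide builder and pseudo-ensemble generator. Stands in
# for solvated molecular-dynamics snapshots: structures are built from
# canonical phi/psi with ideal bond lengths and angles, optionally solvated
# at exposed carbonyls, and perturbed with seeded Gaussian coordinate noise.

# Ideal internal coordinates (Angstroms / degrees)
.BOND <- c(N_CA = 1.46, CA_C = 1.52, C_N = 1.33, C_O = 1.23, N_H = 1.01,
           C_H = 1.09, O_H = 0.96, CB_OG = 1.417)
.ANG <- c(N_CA_C = 111.0, CA_C_N = 116.5, C_N_CA = 121.7, CA_C_O = 120.5,
          TET = 109.47, CA_CB_OG = 110.5)

.TEMPLATES <- list(alpha_helix = c(-57, -47),
                   three10_helix = c(-49, -26),
                   antiparallel_sheet = c(-139, 135),
                   parallel_sheet = c(-119, 113),
                   extended = c(-139, 135))

#' Specification for a synthetic structure
#'
#' Bundles the parameters of the synthetic generator: a backbone template
#' (canonical phi/psi: alpha -57/-47, 3-10 -49/-26, antiparallel -139/135,
#' parallel -119/113), chain length, sequence, solvation of exposed
#' carbonyls, and the Gaussian jitter that turns one structure into a
#' pseudo-ensemble of snapshots.
#'
#' @param template One of "alpha_helix", "three10_helix",
#'   "antiparallel_sheet", "parallel_sheet", "extended", or "custom".
#' @param n_res Residues per chain segment (per strand for sheet templates).
#' @param sequence One-letter sequence (default poly-Ala). Supported letters:
#'   G, A, S, T; others are built with an alanine side chain.
#' @param phi_psi For `template = "custom"`: a 2-column matrix of phi/psi in
#'   degrees, one row per residue (recycled if a single row).
#' @param solvation "none" or "exposed_carbonyls".
#' @param waters_per_site Waters placed per carbonyl when solvating (0-3).
#' @param noise_sigma Gaussian coordinate jitter, Angstroms.
#' @param n_snapshots Number of ensemble snapshots.
#' @param seed Integer seed for water jitter and ensemble noise.
#' @return A list of class `build_spec`.
#' @export
build_spec <- function(template = "alpha_helix", n_res = 12L, sequence = NULL,
                       phi_psi = NULL, solvation = c("none", "exposed_carbonyls"),
                       waters_per_site = 2L, noise_sigma = 0, n_snapshots = 1L,
                       seed = 1L) {
  solvation <- match.arg(solvation)
  if (!template %in% c(names(.TEMPLATES), "custom"))
    stop("unknown template: ", template)
  stopifnot(n_res >= 1, noise_sigma >= 0, n_snapshots >= 1,
            waters_per_site %in% 0:3)
  if (is.null(sequence)) sequence <- paste(rep("A", n_res), collapse = "")
  if (nchar(sequence) != n_res) stop("sequence length != n_res")
  structure(list(template = template, n_res = as.integer(n_res),
                 sequence = sequence, phi_psi = phi_psi,
                 solvation = solvation,
                 waters_per_site = as.integer(waters_per_site),
                 noise_sigma = noise_sigma,
                 n_snapshots = as.integer(n_snapshots),
                 seed = as.integer(seed)),
            class = "build_spec")
}

# --- low-level single-strand builder -----------------------------------------

# Tetrahedral substituent directions on a centre with two existing bonds
# b1, b2 (unit vectors away from the centre). Returns the two remaining
# directions; [,1] is the L-configuration beta-carbon direction when
# (b1, b2) = (N - CA, C - CA).
.tet_dirs <- function(b1, b2) {
  bis <- (b1 + b2); bis <- bis / sqrt(sum(bis * bis))
  perp <- c(b1[2] * b2[3] - b1[3] * b2[2],
            b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
  perp <- perp / sqrt(sum(perp * perp))
  gamma <- acos(sum(b1 * b2))
  alpha <- cos(.ANG[["TET"]] * pi / 180) / cos(gamma / 2)
  beta <- sqrt(max(0, 1 - alpha^2))
  u1 <- alpha * bis + beta * perp
  u2 <- alpha * bis - beta * perp
  cbind(u1 / sqrt(sum(u1 * u1)), u2 / sqrt(sum(u2 * u2)))
}

# Build one strand (single chain segment) from phi/psi. Returns an atom
# data.frame (new_structure columns), residues numbered resno_start..,
# chain `chain`.
.build_strand <- function(phi, psi, sequence, chain = "A", resno_start = 1L) {
  n <- length(phi)
  seq1 <- strsplit(sequence, "")[[1]]
  stopifnot(length(seq1) == n, length(psi) == n)
  res3 <- c(G = "GLY", A = "ALA", S = "SER", T = "THR")[seq1]
  res3[is.na(res3)] <- "ALA"
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  # first residue frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BOND[["N_CA"]], 0, 0)
  C[1, ] <- .place_atom(c(0, 1, 0), N[1, ], CA[1, ], .BOND[["CA_C"]],
                        .ANG[["N_CA_C"]], phi[1] + 60)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], .BOND[["C_N"]],
                            .ANG[["CA_C_N"]], psi[i - 1])
      CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], .BOND[["N_CA"]],
                             .ANG[["C_N_CA"]], 180)
      C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ], .BOND[["CA_C"]],
                            .ANG[["N_CA_C"]], phi[i])
    }
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], .BOND[["C_O"]],
                          .ANG[["CA_C_O"]], psi[i] + 180)
  }
  atoms <- list()
  emit <- function(i, name, el, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      serial = 0L, name = name, element = el, alt = "", resname = res3[i],
      chain = chain, resno = resno_start + i - 1L, insert = "",
      x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    emit(i, "N", "N", N[i, ])
    emit(i, "CA", "C", CA[i, ])
    emit(i, "C", "C", C[i, ])
    emit(i, "O", "O", O[i, ])
    if (i > 1 && res3[i] != "PRO") {
      # amide H in the peptide plane, anti to the carbonyl O of i-1
      u1 <- C[i - 1, ] - N[i, ]; u1 <- u1 / sqrt(sum(u1 * u1))
      u2 <- CA[i, ] - N[i, ]; u2 <- u2 / sqrt(sum(u2 * u2))
      hd <- -(u1 + u2); hd <- hd / sqrt(sum(hd * hd))
      emit(i, "H", "H", N[i, ] + .BOND[["N_H"]] * hd)
    }
    b1 <- N[i, ] - CA[i, ]; b1 <- b1 / sqrt(sum(b1 * b1))
    b2 <- C[i, ] - CA[i, ]; b2 <- b2 / sqrt(sum(b2 * b2))
    td <- .tet_dirs(b1, b2)
    cb_dir <- td[, 1]; ha_dir <- td[, 2]
    if (res3[i] == "GLY") {
      emit(i, "HA2", "H", CA[i, ] + .BOND[["C_H"]] * cb_dir)
      emit(i, "HA3", "H", CA[i, ] + .BOND[["C_H"]] * ha_dir)
    } else {
      emit(i, "HA", "H", CA[i, ] + .BOND[["C_H"]] * ha_dir)
      CB <- CA[i, ] + 1.53 * cb_dir
      emit(i, "CB", "C", CB)
      if (res3[i] == "ALA") {
        # provisional stagger; methyl rotamers are re-optimised on the
        # assembled structure (see .optimize_methyls)
        for (k in 1:3) {
          h <- .place_atom(N[i, ], CA[i, ], CB, .BOND[["C_H"]], .ANG[["TET"]],
                           60 + 120 * (k - 1))
          emit(i, paste0("HB", k), "H", h)
        }
      } else if (res3[i] %in% c("SER", "THR")) {
        og_name <- if (res3[i] == "SER") "OG" else "OG1"
        hg_name <- if (res3[i] == "SER") "HG" else "HG1"
        OG <- .place_atom(N[i, ], CA[i, ], CB, .BOND[["CB_OG"]],
                          .ANG[["CA_CB_OG"]], 180)
        emit(i, og_name, "O", OG)
        if (res3[i] == "SER") {
          emit(i, "HB2", "H", .place_atom(N[i, ], CA[i, ], CB, .BOND[["C_H"]],
                                          .ANG[["TET"]], 60))
          emit(i, "HB3", "H", .place_atom(N[i, ], CA[i, ], CB, .BOND[["C_H"]],
                                          .ANG[["TET"]], -60))
        } else {
          emit(i, "HB", "H", .place_atom(N[i, ], CA[i, ], CB, .BOND[["C_H"]],
                                         .ANG[["TET"]], 60))
        }
        emit(i, hg_name, "H", .place_atom(CA[i, ], CB, OG, .BOND[["O_H"]],
                                          .ANG[["TET"]], 180))
        if (res3[i] == "THR") {
          CG2 <- .place_atom(N[i, ], CA[i, ], CB, 1.53, .ANG[["TET"]], -60)
          emit(i, "CG2", "C", CG2)
          for (k in 1:3)
            emit(i, paste0("HG2", k), "H",
                 .place_atom(CA[i, ], CB, CG2, .BOND[["C_H"]], .ANG[["TET"]],
                             60 + 120 * (k - 1)))
        }
      }
    }
  }
  out <- do.call(rbind, atoms)
  out$serial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Re-orient methyl rotors on the assembled structure: for each methyl the
# torsion offset is chosen (5-degree grid, deterministic) to maximise the
# minimum distance from its hydrogens to any carbonyl/hydroxyl oxygen, i.e.
# the non-interacting rotamer. Methyl rotors are nearly free, so this is a
# legitimate degree of freedom of an idealised fixture.
.optimize_methyls <- function(atoms) {
  if (is.null(atoms$res_uid))
    atoms$res_uid <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  o_idx <- which(atoms$element == "O")
  if (!length(o_idx)) return(atoms)
  O_xyz <- as.matrix(atoms[o_idx, c("x", "y", "z")])
  methyls <- list(c("CB", "HB1", "HB2", "HB3", "N", "CA"),
                  c("CG2", "HG21", "HG22", "HG23", "CA", "CB"))
  for (u in unique(atoms$res_uid[atoms$resname %in% c("ALA", "THR")])) {
    ri <- which(atoms$res_uid == u)
    for (m in methyls) {
      idx <- vapply(m, function(nm) {
        j <- ri[atoms$name[ri] == nm]
        if (length(j)) j[1] else NA_integer_
      }, 1L)
      if (anyNA(idx)) next
      Cm <- as.numeric(atoms[idx[1], c("x", "y", "z")])
      A <- as.numeric(atoms[idx[5], c("x", "y", "z")])
      B <- as.numeric(atoms[idx[6], c("x", "y", "z")])
      near <- which(sqrt(rowSums((O_xyz - matrix(Cm, nrow(O_xyz), 3,
                                                 byrow = TRUE))^2)) < 4.5)
      near <- setdiff(near, match(intersect(o_idx, ri), o_idx))
      if (!length(near)) next
      Onear <- O_xyz[near, , drop = FALSE]
      best_off <- 60; best_val <- -Inf
      for (off in seq(0, 115, by = 5)) {
        dmin <- Inf
        for (k in 0:2) {
          H <- .place_atom(A, B, Cm, .BOND[["C_H"]], .ANG[["TET"]],
                           off + 120 * k)
          dmin <- min(dmin, sqrt(rowSums((Onear - matrix(H, nrow(Onear), 3,
                                                         byrow = TRUE))^2)))
        }
        if (dmin > best_val) { best_val <- dmin; best_off <- off }
      }
      for (k in 0:2) {
        H <- .place_atom(A, B, Cm, .BOND[["C_H"]], .ANG[["TET"]],
                         best_off + 120 * k)
        atoms[idx[2 + k], c("x", "y", "z")] <- as.list(H)
      }
    }
  }
  atoms
}

# session cache for fitted sheet strand placements (deterministic; keyed by
# template, strand length and sequence)
.sheet_cache <- new.env(parent = emptyenv())

# rigid transform helpers for sheet assembly
.rot_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, 3, byrow = TRUE)
}
.rot_y <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
}
.rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
.apply_rigid <- function(atoms, R, t) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + t[1]; atoms$y <- xyz[, 2] + t[2]; atoms$z <- xyz[, 3] + t[3]
  atoms
}

# Place strand B against strand A to realise a designed hydrogen-bond
# registry: `pairs` is a data.frame with columns donor_strand ("A"/"B"),
# donor_resno, acceptor_resno; the rigid placement of B is optimised so each
# designed N-H...O=C contact reaches d(H, O) ~ 1.95 A with good linearity.
.fit_strand_b <- function(a_atoms, b_atoms, pairs, par0) {
  get <- function(atoms, resno, name) {
    i <- which(atoms$resno == resno & atoms$name == name)
    as.numeric(atoms[i[1], c("x", "y", "z")])
  }
  obj <- function(p) {
    R <- .rot_z(p[4]) %*% .rot_y(p[5]) %*% .rot_x(p[6])
    b <- .apply_rigid(b_atoms, R, p[1:3])
    err <- 0
    for (k in seq_len(nrow(pairs))) {
      don <- if (pairs$donor_strand[k] == "A") a_atoms else b
      acc <- if (pairs$donor_strand[k] == "A") b else a_atoms
      H <- get(don, pairs$donor_resno[k], "H")
      Nn <- get(don, pairs$donor_resno[k], "N")
      Oo <- get(acc, pairs$acceptor_resno[k], "O")
      dHO <- sqrt(sum((H - Oo)^2))
      omega <- bond_angle(Nn, H, Oo)
      err <- err + (dHO - 1.95)^2 + ((180 - omega) / 60)^2
    }
    # soft clash penalty between heavy atoms of the two strands
    ah <- as.matrix(a_atoms[a_atoms$element != "H", c("x", "y", "z")])
    bh <- as.matrix(b[b$element != "H", c("x", "y", "z")])
    dmin <- sqrt(outer(rowSums(ah^2), rowSums(bh^2), "+") - 2 * ah %*% t(bh))
    err + sum(pmax(0, 2.8 - dmin)^2)
  }
  if (!is.list(par0)) par0 <- list(par0)
  best <- NULL
  for (p0 in par0) {
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 1500, reltol = 1e-10))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 1500, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < 0.05 * nrow(pairs)) break  # good enough: stop early
  }
  R <- .rot_z(best$par[4]) %*% .rot_y(best$par[5]) %*% .rot_x(best$par[6])
  .apply_rigid(b_atoms, R, best$par[1:3])
}

#' Build an ideal-geometry peptide structure
#'
#' Constructs a backbone from ideal internal coordinates (N-CA 1.46, CA-C
#' 1.52, C-N 1.33, C=O 1.23 A, omega = 180 deg) at the template's canonical
#' phi/psi, with amide hydrogens in the peptide plane anti to the carbonyl
#' and tetrahedral HA/side-chain hydrogens. Sheet templates build two
#' strands of `n_res` residues each on one chain (residue numbering leaves a
#' gap), with the second strand rigidly placed to realise the canonical
#' inter-strand hydrogen-bond registry.
#'
#' @param spec A [build_spec()] (or a template name, for convenience).
#' @param ... When `spec` is a template name, forwarded to [build_spec()].
#' @return An `ncistruct`.
#' @export
build_peptide <- function(spec, ...) {
  if (is.character(spec)) spec <- build_spec(template = spec, ...)
  stopifnot(inherits(spec, "build_spec"))
  n <- spec$n_res
  if (spec$template == "custom") {
    pp <- spec$phi_psi
    if (is.null(pp)) stop("custom template requires phi_psi")
    pp <- matrix(pp, ncol = 2)
    if (nrow(pp) == 1) pp <- pp[rep(1, n), , drop = FALSE]
    stopifnot(nrow(pp) == n)
    phi <- pp[, 1]; psi <- pp[, 2]
    atoms <- .build_strand(phi, psi, spec$sequence)
  } else if (spec$template %in% c("antiparallel_sheet", "parallel_sheet")) {
    tpl <- .TEMPLATES[[spec$template]]
    phi <- rep(tpl[1], n); psi <- rep(tpl[2], n)
    a_atoms <- .build_strand(phi, psi, spec$sequence, resno_start = 1L)
    b_atoms <- .build_strand(phi, psi, spec$sequence,
                             resno_start = n + 11L)
    if (spec$template == "antiparallel_sheet") {
      b_atoms <- .apply_rigid(b_atoms, .rot_y(180), c(0, 0, 0))
      ii <- seq(2, n - 1, by = 2)
      pairs <- rbind(
        data.frame(donor_strand = "A", donor_resno = ii,
                   acceptor_resno = n + 11L + (n - ii)),
        data.frame(donor_strand = "B", donor_resno = n + 11L + (n - ii),
                   acceptor_resno = ii))
      par0 <- c(0, 4.9, 0, 0, 0, 0)
    } else {
      # parallel registry: residue i of A pairs with j of B; bonds
      # NH(A_i) -> O(B_{j-1}) and NH(B_{j+1}) -> O(A_i); the pleat means
      # only alternate residues face the partner strand
      ii <- seq(2, n - 2, by = 2)
      pairs <- rbind(
        data.frame(donor_strand = "A", donor_resno = ii,
                   acceptor_resno = n + 11L + (ii - 2L)),
        data.frame(donor_strand = "B", donor_resno = n + 11L + ii,
                   acceptor_resno = ii))
      par0 <- c(0, 4.9, 0, 0, 0, 0)
    }
    starts <- if (spec$template == "antiparallel_sheet") list(par0) else
      lapply(c(0, -1.7, 1.7, -3.4, 3.4), function(dx) replace(par0, 1, dx))
    key <- paste(spec$template, n, spec$sequence, sep = "/")
    if (is.null(.sheet_cache[[key]])) {
      .sheet_cache[[key]] <- .fit_strand_b(a_atoms, b_atoms, pairs, starts)
    }
    b_atoms <- .sheet_cache[[key]]
    atoms <- rbind(a_atoms, b_atoms)
    atoms$serial <- seq_len(nrow(atoms))
  } else {
    tpl <- .TEMPLATES[[spec$template]]
    atoms <- .build_strand(rep(tpl[1], n), rep(tpl[2], n), spec$sequence)
  }
  atoms <- .optimize_methyls(atoms)
  s <- new_structure(paste0("synth_", spec$template), atoms)
  if (spec$solvation == "exposed_carbonyls")
    s <- solvate_carbonyls(s, per_site = spec$waters_per_site,
                           seed = spec$seed)
  s
}

#' Add idealised waters hydrogen-bonded to carbonyl oxygens
#'
#' For each mainchain carbonyl, places up to `per_site` water molecules with
#' one hydrogen pointing at the carbonyl O (d(H...O) = 1.9 A, donor angle
#' ~165 deg), in the sp2 carbonyl plane at +/-60 deg from the C=O axis (a
#' third water, if requested, approaches along the C=O axis). Placements
#' clashing with existing heavy atoms (< 2.4 A) are skipped.
#'
#' @param s An `ncistruct`.
#' @param per_site Waters per carbonyl site, 0-3.
#' @param seed Integer seed for the small angular jitter.
#' @param jitter_deg Standard deviation of the angular jitter (degrees).
#' @return A new `ncistruct` including the waters.
#' @export
solvate_carbonyls <- function(s, per_site = 2L, seed = 1L, jitter_deg = 2) {
  stopifnot(per_site %in% 0:3)
  if (per_site == 0L) return(s)
  set.seed(seed)
  sites <- identify_carbonyls(s)
  sites <- sites[sites$kind == "mainchain", , drop = FALSE]
  a <- s$atoms
  heavy <- as.matrix(a[a$element != "H", c("x", "y", "z")])
  new_rows <- list()
  wat_no <- max(c(0L, a$resno)) + 1000L
  n_skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    C <- as.numeric(a[sites$C[i], c("x", "y", "z")])
    O <- as.numeric(a[sites$O[i], c("x", "y", "z")])
    CAx <- as.numeric(a[sites$CAx[i], c("x", "y", "z")])
    co <- O - C; co <- co / sqrt(sum(co * co))
    nrm <- .row_cross(matrix(CAx - C, 1), matrix(O - C, 1))[1, ]
    nrm <- nrm / sqrt(sum(nrm * nrm))
    inplane <- .row_cross(matrix(nrm, 1), matrix(co, 1))[1, ]
    dirs <- list()
    for (sgn in c(1, -1)) {
      th <- (60 + stats::rnorm(1, 0, jitter_deg)) * pi / 180
      dirs[[length(dirs) + 1L]] <- cos(th) * co + sgn * sin(th) * inplane
    }
    dirs[[3]] <- co  # along the C=O axis for a third water
    placed <- 0L
    for (k in seq_along(dirs)) {
      if (placed >= per_site) break
      u <- dirs[[k]]
      H1 <- O + 1.9 * u
      # water O set so the donor angle Ow-H1-O(carbonyl) is ~165 deg
      tilt <- 15 * pi / 180
      w <- cos(tilt) * u + sin(tilt) * nrm
      Ow <- H1 + 0.957 * w
      dmin <- min(sqrt(rowSums((heavy - matrix(Ow, nrow(heavy), 3,
                                               byrow = TRUE))^2)))
      if (dmin < 2.4) { n_skipped <- n_skipped + 1L; next }
      # second water hydrogen, ~104.5 deg from the first O-H bond
      v2 <- -sin(tilt + 104.5 * pi / 180) * nrm +
        cos(tilt + 104.5 * pi / 180) * u
      H2 <- Ow + 0.957 * (v2 / sqrt(sum(v2 * v2)))
      wat_no <- wat_no + 1L
      mk <- function(nm, el, p) data.frame(
        serial = 0L, name = nm, element = el, alt = "", resname = "HOH",
        chain = "W", resno = wat_no, insert = "", x = p[1], y = p[2],
        z = p[3], occ = 1, stringsAsFactors = FALSE)
      new_rows[[length(new_rows) + 1L]] <- rbind(mk("O", "O", Ow),
                                                 mk("H1", "H", H1),
                                                 mk("H2", "H", H2))
      heavy <- rbind(heavy, Ow)
      placed <- placed + 1L
    }
  }
  if (length(new_rows)) {
    add <- do.call(rbind, new_rows)
    all_atoms <- rbind(a[, names(add)], add)
    all_atoms$serial <- seq_len(nrow(all_atoms))
    s2 <- new_structure(s$id, all_atoms, s$snapshot_index)
  } else s2 <- s
  attr(s2, "n_sites_skipped") <- n_skipped
  s2
}

#' Perturb a structure into a pseudo-ensemble
#'
#' Returns `n` copies of the structure with i.i.d. Gaussian displacement
#' (standard deviation `sigma` Angstroms) added to every coordinate;
#' snapshots are numbered 0..n-1 and the generation is reproducible for a
#' given seed.
#'
#' @param s An `ncistruct`.
#' @param sigma Coordinate noise, Angstroms (>= 0).
#' @param n Number of snapshots (>= 1).
#' @param seed Integer seed.
#' @return List of `ncistruct` snapshots.
#' @export
perturb_ensemble <- function(s, sigma, n, seed = 1L) {
  stopifnot(sigma >= 0, n >= 1)
  set.seed(seed)
  out <- vector("list", n)
  na <- nrow(s$atoms)
  for (k in seq_len(n)) {
    sk <- s
    if (sigma > 0) {
      sk$atoms$x <- sk$atoms$x + stats::rnorm(na, 0, sigma)
      sk$atoms$y <- sk$atoms$y + stats::rnorm(na, 0, sigma)
      sk$atoms$z <- sk$atoms$z + stats::rnorm(na, 0, sigma)
    }
    sk$snapshot_index <- k - 1L
    out[[k]] <- sk
  }
  out
}

# --- motif fixtures ----------------------------------------------------------

# replace named atoms of one residue with new coordinates
.patch_atoms <- function(s, resno, coords) {
  a <- s$atoms
  for (nm in names(coords)) {
    i <- which(a$resno == resno & a$name == nm & !a$is_water)
    if (!length(i)) stop("no atom ", nm, " in residue ", resno)
    a[i[1], c("x", "y", "z")] <- as.list(coords[[nm]])
  }
  s$atoms <- a
  s
}

.fixture_m3 <- function() {
  n <- 10L; t <- 6L
  s <- build_peptide(build_spec("alpha_helix", n_res = n,
                                sequence = "AAAAAAAAAS"))
  a <- s$atoms
  g <- function(i, nm) as.numeric(a[a$resno == i & a$name == nm & !a$is_water,
                                    c("x", "y", "z")])
  O <- g(t, "O"); C <- g(t, "C")
  N <- g(n, "N"); CA <- g(n, "CA"); CB <- g(n, "CB")
  o_all <- .xyz(a, which(a$element == "O" & a$resno != t))
  # serine rotamer search: hydroxyl must reach the i-4 carbonyl oxygen and
  # nothing else
  for (chi1 in seq(-180, 175, 5)) {
    OG <- .place_atom(N, CA, CB, .BOND[["CB_OG"]], .ANG[["CA_CB_OG"]], chi1)
    if (atom_distance(OG, O) > 3.3) next
    for (chi2 in seq(-180, 175, 5)) {
      HG <- .place_atom(CA, CB, OG, .BOND[["O_H"]], .ANG[["TET"]], chi2)
      d <- atom_distance(HG, O)
      if (d < 1.8 || d > 2.31) next
      if (bond_angle(OG, HG, O) < 95 || bond_angle(HG, O, C) < 95) next
      d_others <- atom_distance(o_all, matrix(HG, nrow(o_all), 3, byrow = TRUE))
      if (min(d_others) < 2.6) next
      out <- .patch_atoms(s, n, list(OG = OG, HG = HG))
      attr(out, "target_residues") <- paste0("A|", t, "|")
      return(out)
    }
  }
  stop("no serine capping rotamer found")  # nocov
}

.fixture_m1 <- function() {
  n <- 14L; t <- 7L; don <- t + 3L
  seq1 <- paste0(strrep("A", don - 1), "T", strrep("A", n - don))
  s <- build_peptide(build_spec("alpha_helix", n_res = n, sequence = seq1))
  a <- s$atoms
  g <- function(i, nm) as.numeric(a[a$resno == i & a$name == nm & !a$is_water,
                                    c("x", "y", "z")])
  O <- g(t, "O"); C <- g(t, "C"); CAt <- g(t, "CA")
  N <- g(don, "N"); CA <- g(don, "CA"); CB <- g(don, "CB")
  # every oxygen except the threonine's own hydroxyl (stale position)
  o_all <- .xyz(a, which(a$element == "O" &
                           !(a$resno == don & a$name == "OG1")))
  for (tm in seq(-180, 175, 5)) {       # CG2 torsion
    CG2 <- .place_atom(N, CA, CB, 1.53, .ANG[["TET"]], tm)
    if (atom_distance(CG2, O) > 3.7 || atom_distance(CG2, O) < 3.0) next
    OG1 <- .place_atom(N, CA, CB, .BOND[["CB_OG"]], .ANG[["CA_CB_OG"]],
                       tm + 120)
    HB <- .place_atom(N, CA, CB, .BOND[["C_H"]], .ANG[["TET"]], tm - 120)
    for (off in seq(0, 115, 5)) {       # methyl rotation
      H3 <- lapply(0:2, function(k)
        .place_atom(CA, CB, CG2, .BOND[["C_H"]], .ANG[["TET"]], off + 120 * k))
      q <- vapply(H3, function(H) {
        d <- atom_distance(H, O)
        d >= 2.2 && d <= 2.68 && bond_angle(CG2, H, O) >= 95 &&
          bond_angle(H, O, C) >= 95 && elevation_angle(H, CAt, C, O) < 45
      }, TRUE)
      if (sum(q) != 1) next
      # hydroxyl proton pointed away from every carbonyl oxygen
      best_hg <- NULL; best_d <- 0
      for (chi2 in seq(-180, 175, 15)) {
        HG1 <- .place_atom(CA, CB, OG1, .BOND[["O_H"]], .ANG[["TET"]], chi2)
        dmin <- min(atom_distance(o_all, matrix(HG1, nrow(o_all), 3,
                                                byrow = TRUE)))
        if (dmin > best_d) { best_d <- dmin; best_hg <- HG1 }
      }
      if (best_d <= 2.5) next
      coords <- list(OG1 = OG1, CG2 = CG2, HB = HB, HG1 = best_hg,
                     HG21 = H3[[1]], HG22 = H3[[2]], HG23 = H3[[3]])
      out <- .patch_atoms(s, don, coords)
      attr(out, "target_residues") <- paste0("A|", t, "|")
      return(out)
    }
  }
  stop("no methyl rotamer found for the over-satisfied helix fixture")  # nocov
}

.fixture_m2 <- function() {
  # slight uniform crankshaft off the canonical helix: both the i+3 and
  # i+4 amides reach the carbonyl (bifurcated pair) while the i+1 n->pi*
  # persists
  s <- build_peptide(build_spec("custom", n_res = 10,
                                phi_psi = c(-49, -50)))
  s$id <- "synth_m2_bifurcated"
  attr(s, "target_residues") <- "A|2|"
  s
}

#' Build a structure guaranteeing a named carbonyl motif
#'
#' Hand-tuned ideal geometry for closed-loop testing of motif detection:
#' `M1` (mid-helix carbonyl with NH_bb + n->pi* + a threonine-methyl CH_X),
#' `M2_bifurcated` (crankshafted helix whose N-terminal carbonyl accepts
#' NH_bb from both i+3 and i+4 plus the i+1 n->pi*), `M3_capping` (helix
#' C-terminal carbonyl with NH_bb + serine OH_sc + n->pi*), `water_only`
#' (solvated extended peptide: every carbonyl sees only water) and
#' `undersatisfied` (dry short helix whose C-terminal carbonyls keep a
#' single NCI). The designed residue ids are in
#' `attr(, "target_residues")`.
#'
#' @param motif One of "M1", "M2_bifurcated", "M3_capping", "water_only",
#'   "undersatisfied".
#' @return An `ncistruct` with attribute `target_residues`.
#' @export
build_motif_fixture <- function(motif = c("M1", "M2_bifurcated", "M3_capping",
                                          "water_only", "undersatisfied")) {
  motif <- match.arg(motif)
  switch(motif,
         M1 = .fixture_m1(),
         M2_bifurcated = .fixture_m2(),
         M3_capping = .fixture_m3(),
         water_only = {
           s <- build_peptide(build_spec("extended", n_res = 6,
                                         solvation = "exposed_carbonyls",
                                         waters_per_site = 2L))
           s$id <- "synth_water_only"
           attr(s, "target_residues") <- paste0("A|", 1:5, "|")
           s
         },
         undersatisfied = {
           s <- build_peptide(build_spec("alpha_helix", n_res = 8))
           s$id <- "synth_undersatisfied"
           attr(s, "target_residues") <- paste0("A|", 5:6, "|")
           s
         })
}
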