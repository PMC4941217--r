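# Shared fixtures and an independent brute-force classifier used as the
# oracle for the prefiltered implementation.

# -- PDB text fixtures (built in code, written to tempfiles on demand) --------

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, alt = "", element = NULL, het = FALSE,
                     insert = "") {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, nm, alt, resname, chain,
          resno, insert, x, y, z, occ, 0, element)
}

write_fixture <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

# Gly-Ala dipeptide with hydrogens, trans peptide, arbitrary but sane
# coordinates (taken from an ideal extended build)
dipeptide_lines <- function() {
  s <- build_peptide(build_spec("extended", n_res = 2, sequence = "GA"))
  a <- s$atoms
  vapply(seq_len(nrow(a)), function(i)
    pdb_line(i, a$name[i], a$resname[i], a$chain[i], a$resno[i],
             a$x[i], a$y[i], a$z[i]), "")
}

# -- independent brute-force classifier ---------------------------------------
# Same thresholds, no prefilter, different arithmetic: distances by explicit
# sums of squares, angles by the law of cosines, elevation by projection
# onto the plane normal. Returns a sorted key set "owner|type|partner|atom".

bf_dist <- function(p, q) sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2 + (p[3] - q[3])^2)

bf_angle <- function(p, v, q) {
  d1 <- bf_dist(p, v); d2 <- bf_dist(q, v); d3 <- bf_dist(p, q)
  acos(min(1, max(-1, (d1^2 + d2^2 - d3^2) / (2 * d1 * d2)))) * 180 / pi
}

bf_elevation <- function(p, a, b, c, origin) {
  u <- b - a; v <- c - a
  n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  n <- n / bf_dist(n, c(0, 0, 0))
  w <- p - origin
  w <- w / bf_dist(w, c(0, 0, 0))
  asin(min(1, max(-1, abs(sum(w * n))))) * 180 / pi
}

bf_dihedral <- function(p1, p2, p3, p4) {
  # projection construction (Gram-Schmidt), distinct from the atan2 route
  b1 <- p1 - p2; b2 <- p3 - p2; b3 <- p4 - p3
  u <- b2 / bf_dist(b2, c(0, 0, 0))
  v <- b1 - sum(b1 * u) * u
  w <- b3 - sum(b3 * u) * u
  acos(min(1, max(-1, sum(v * w) / (bf_dist(v, c(0, 0, 0)) *
                                      bf_dist(w, c(0, 0, 0)))))) * 180 / pi
}

brute_force_keys <- function(s, th = nci_thresholds()) {
  a <- s$atoms
  sites <- identify_carbonyls(s)
  donors <- identify_donors(s)
  main <- sites[sites$kind == "mainchain", , drop = FALSE]
  xyz <- function(i) as.numeric(a[i, c("x", "y", "z")])
  keys <- character()
  for (i in seq_len(nrow(main))) {
    O <- xyz(main$O[i]); C <- xyz(main$C[i]); CAx <- xyz(main$CAx[i])
    for (j in seq_len(nrow(donors))) {
      don <- donors[j, ]
      if (don$category == "NH_bb" && don$chain == main$chain[i] &&
          bf_dist(xyz(don$heavy), C) <= 1.8) next
      cutoff <- switch(don$category, NH_bb = , NH_sc = th$d_NH_max,
                       OH_sc = , HOH = th$d_OH_max, th$d_CH_max)
      best_d <- Inf; best_h <- NA
      for (h in don$hyd[[1]]) {
        H <- xyz(h)
        d <- bf_dist(H, O)
        if (d > cutoff) next
        if (bf_angle(xyz(don$heavy), H, O) < th$omega_min) next
        if (bf_angle(H, O, C) < th$rho_min) next
        if (don$category %in% c("CaH", "CH_X") &&
            bf_elevation(H, CAx, C, O, O) >= th$elevation_max) next
        if (d < best_d) { best_d <- d; best_h <- h }
      }
      if (is.finite(best_d))
        keys <- c(keys, paste(main$res_uid[i], don$category, don$res_uid,
                              a$name[best_h], sep = "|"))
    }
    # n->pi*: this O as electron donor against every other site
    for (j in seq_len(nrow(sites))) {
      if (sites$res_uid[j] == main$res_uid[i] &&
          sites$kind[j] == "mainchain") next
      Cj <- xyz(sites$C[j]); Oj <- xyz(sites$O[j])
      d <- bf_dist(O, Cj)
      if (d > th$d_npistar_max || d < 1.5) next
      theta <- bf_angle(O, Cj, Oj)
      if (theta < th$theta_min || theta > th$theta_max) next
      chi <- bf_dihedral(CAx, C, O, Cj)
      if (chi < th$chi_min) next
      ty <- if (sites$kind[j] == "sidechain") "npistar_sc" else "npistar"
      keys <- c(keys, paste(main$res_uid[i], ty, sites$res_uid[j],
                            a$name[sites$C[j]], sep = "|"))
    }
  }
  sort(keys)
}

inventory_keys <- function(inv) {
  r <- inv$records
  sort(paste(r$res_uid, r$nci_type, r$partner_uid, r$partner_atom, sep = "|"))
}

# random small structure generator for the oracle sweep
random_structure <- function(seed) {
  set.seed(seed)
  template <- sample(c("alpha_helix", "three10_helix", "antiparallel_sheet",
                       "extended", "custom"), 1)
  n <- sample(4:14, 1)
  # sheet strand placement is optimised and cached per size: draw from a
  # small size set so the cache is reused across the sweep
  if (template == "antiparallel_sheet") n <- sample(c(6L, 8L, 10L), 1)
  spec <- if (template == "custom") {
    build_spec("custom", n_res = n,
               phi_psi = cbind(runif(n, -160, -50), runif(n, -60, 160)))
  } else build_spec(template, n_res = n)
  s <- build_peptide(spec)
  if (runif(1) < 0.5)
    s <- solvate_carbonyls(s, per_site = sample(0:2, 1), seed = seed)
  snaps <- perturb_ensemble(s, sigma = runif(1, 0, 0.25), n = 1, seed = seed)
  snaps[[1]]
}

rigid_motion <- function(s, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(M))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t <- rnorm(3, 0, 10)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- xyz[, 1] + t[1]
  s$atoms$y <- xyz[, 2] + t[2]
  s$atoms$z <- xyz[, 3] + t[3]
  s
}

# toy single hydrogen-bond geometry with prescribed d(H..O), omega, rho;
# returns the structure plus site/donor rows ready for classify_hbond
toy_hbond <- function(d, omega, rho, category = "NH_bb", elev_out = FALSE) {
  O <- c(0, 0, 0)
  C <- c(-1.23, 0, 0)
  CA <- C + 1.52 * c(cos(pi * (180 - 120.5) / 180), sin(pi * (180 - 120.5) / 180), 0)
  # H at angle rho from the O->C direction, in the carbonyl plane
  dirH <- c(cos(pi * (180 - rho) / 180), sin(pi * (180 - rho) / 180), 0)
  if (elev_out) {  # push H out of plane, keeping rho
    dirH <- c(cos(pi * (180 - rho) / 180), 0, sin(pi * (180 - rho) / 180))
  }
  H <- O + d * dirH
  # heavy atom at angle omega from the H->O direction
  u <- (O - H) / sqrt(sum((O - H)^2))
  perp <- c(-u[2], u[1], 0)
  if (sum(perp^2) < 1e-8) perp <- c(0, 1, 0)
  perp <- perp / sqrt(sum(perp^2))
  w <- cos(pi * omega / 180) * u + sin(pi * omega / 180) * perp
  heavy_el <- switch(category, NH_bb = "N", NH_sc = "N", OH_sc = "O",
                     HOH = "O", "C")
  bond <- if (heavy_el == "N") 1.01 else if (heavy_el == "O") 0.96 else 1.09
  HV <- H + bond * w
  atoms <- data.frame(
    serial = 1:5,
    name = c("C", "O", "CA", if (category == "HOH") "OW" else "NZ", "HX"),
    element = c("C", "O", "C", heavy_el, "H"), alt = "",
    resname = c("ALA", "ALA", "ALA", if (category == "HOH") "HOH" else "LYS",
                if (category == "HOH") "HOH" else "LYS"),
    chain = c("A", "A", "A", "B", "B"), resno = c(1L, 1L, 1L, 9L, 9L),
    insert = "", x = c(C[1], O[1], CA[1], HV[1], H[1]),
    y = c(C[2], O[2], CA[2], HV[2], H[2]),
    z = c(C[3], O[3], CA[3], HV[3], H[3]), occ = 1,
    stringsAsFactors = FALSE)
  s <- new_structure("toy", atoms)
  a <- s$atoms
  site <- data.frame(res_uid = "A|1|", chain = "A", resno = 1L, insert = "",
                     resname = "ALA", kind = "mainchain",
                     C = which(a$name == "C"), O = which(a$name == "O"),
                     CAx = which(a$name == "CA"), stringsAsFactors = FALSE)
  donor <- data.frame(category = category,
                      res_uid = a$res_uid[a$name == "HX"],
                      chain = "B", resno = 9L, insert = "",
                      resname = a$resname[a$name == "HX"],
                      heavy = which(a$name %in% c("OW", "NZ")),
                      heavy_name = a$name[a$name %in% c("OW", "NZ")],
                      hyd = I(list(which(a$name == "HX"))),
                      stringsAsFactors = FALSE)
  list(s = s, site = site, donor = donor)
}

# two carbonyl sites with prescribed n->pi* geometry (d, theta, chi)
toy_npistar <- function(d, theta, chi) {
  O <- c(0, 0, 0)
  C <- c(-1.23, 0, 0)
  CA <- C + 1.52 * c(cos(pi * (180 - 120.5) / 180),
                     sin(pi * (180 - 120.5) / 180), 0)
  # acceptor C on a cone about the C=O axis at torsion chi from CA
  ax <- c(1, 0, 0)  # O - C direction
  r <- sin(pi * 30 / 180); h <- cos(pi * 30 / 180)  # 30 deg off-axis
  dir <- h * ax + r * c(0, cos(pi * chi / 180), sin(pi * chi / 180))
  Cacc <- O + d * dir
  # acceptor O at angle theta from the (O_donor - C_acc) direction
  v <- (O - Cacc) / d
  perp <- c(0, -v[3], v[2]); perp <- perp / sqrt(sum(perp^2))
  w <- cos(pi * theta / 180) * v + sin(pi * theta / 180) * perp
  Oacc <- Cacc + 1.23 * w
  CAacc <- Cacc + 1.52 * c(0, 0, 1)
  atoms <- data.frame(
    serial = 1:6, name = c("C", "O", "CA", "C", "O", "CA"),
    element = c("C", "O", "C", "C", "O", "C"), alt = "",
    resname = "ALA", chain = "A", resno = c(1L, 1L, 1L, 5L, 5L, 5L),
    insert = "",
    x = c(C[1], O[1], CA[1], Cacc[1], Oacc[1], CAacc[1]),
    y = c(C[2], O[2], CA[2], Cacc[2], Oacc[2], CAacc[2]),
    z = c(C[3], O[3], CA[3], Cacc[3], Oacc[3], CAacc[3]), occ = 1,
    stringsAsFactors = FALSE)
  s <- new_structure("toy_npi", atoms)
  a <- s$atoms
  mk <- function(resno) data.frame(
    res_uid = paste0("A|", resno, "|"), chain = "A", resno = resno,
    insert = "", resname = "ALA", kind = "mainchain",
    C = which(a$resno == resno & a$name == "C"),
    O = which(a$resno == resno & a$name == "O"),
    CAx = which(a$resno == resno & a$name == "CA"), stringsAsFactors = FALSE)
  list(s = s, donor_site = mk(1), acceptor_site = mk(5))
}
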