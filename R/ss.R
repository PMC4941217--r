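# Secondary-structure assignment: a Kabsch-Sander hydrogen-bond-energy core
# with the usual turn/helix/bridge/ladder logic, collapsed into six classes
# (alpha-helix, beta-strand, 3-10/pi-helix, turn, bend, none).

.KS_Q <- 0.084 * 332  # electrostatic prefactor, kcal/mol * A

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic energy of a backbone N-H...O=C contact,
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol.
#' A hydrogen bond is assigned when E < -0.5 kcal/mol. Donors lacking an
#' amide hydrogen (proline, N-termini without H) return +Inf.
#'
#' @param N,H Donor backbone N and amide H coordinates (3-vectors, A).
#'   `H` may be NULL/NA for donors without an amide hydrogen.
#' @param C,O Acceptor backbone C and O coordinates.
#' @return Energy in kcal/mol.
#' @export
ks_energy <- function(N, H, C, O) {
  if (is.null(H) || anyNA(H)) return(Inf)
  r_on <- atom_distance(O, N); r_ch <- atom_distance(C, H)
  r_oh <- atom_distance(O, H); r_cn <- atom_distance(C, N)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(Inf)  # clash / overlap
  .KS_Q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# Backbone coordinate arrays for one chain (rows = residues)
.bb_coords <- function(s, rt) {
  a <- s$atoms
  get1 <- function(u, nm) {
    i <- .atom_idx(a, u, nm)
    if (is.na(i)) rep(NA_real_, 3) else as.numeric(a[i, c("x", "y", "z")])
  }
  n <- nrow(rt)
  out <- list(N = matrix(NA_real_, n, 3), H = matrix(NA_real_, n, 3),
              CA = matrix(NA_real_, n, 3), C = matrix(NA_real_, n, 3),
              O = matrix(NA_real_, n, 3))
  for (i in seq_len(n)) {
    u <- rt$res_uid[i]
    out$N[i, ] <- get1(u, "N"); out$CA[i, ] <- get1(u, "CA")
    out$C[i, ] <- get1(u, "C"); out$O[i, ] <- get1(u, "O")
    if (rt$resname[i] != "PRO") out$H[i, ] <- get1(u, "H")
  }
  out
}

#' Assign secondary structure
#'
#' Kabsch-Sander-style assignment from backbone hydrogen bonds: n-turns
#' (i -> i+3/4/5) give G/H/I helices when two consecutive turns are present,
#' inter-strand hydrogen bonds give bridges (B) and ladders (E), remaining
#' turn positions give T, and backbone curvature above 70 degrees gives a
#' bend (S). Priority H > E > B > G > I > T > S. The `little_h` flag marks
#' the first and last turn (4 residues) of each helical segment.
#'
#' @param s An `ncistruct`.
#' @param e_cut Hydrogen-bond energy cutoff, kcal/mol (default -0.5).
#' @return data.frame: res_uid, chain, resno, resname, raw, collapsed,
#'   little_h.
#' @export
assign_ss <- function(s, e_cut = -0.5) {
  rt <- residue_table(s)
  n <- nrow(rt)
  out <- data.frame(res_uid = rt$res_uid, chain = rt$chain, resno = rt$resno,
                    resname = rt$resname, raw = rep("-", n),
                    collapsed = rep("none", n), little_h = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  if (n < 3) {
    out$collapsed <- rep("none", n)
    return(out)
  }
  bb <- .bb_coords(s, rt)
  # chain-break bookkeeping: j follows i only if peptide-bonded
  bonded <- rep(FALSE, n)  # bonded[i]: residue i bonded to i+1
  for (i in seq_len(n - 1)) {
    if (rt$chain[i] == rt$chain[i + 1] &&
        all(is.finite(bb$C[i, ])) && all(is.finite(bb$N[i + 1, ]))) {
      bonded[i] <- atom_distance(bb$C[i, ], bb$N[i + 1, ]) <= 1.8
    }
  }
  contiguous <- function(i, j) {
    if (i > j) return(contiguous(j, i))
    i < j && all(bonded[i:(j - 1)])
  }
  # hydrogen-bond matrix: hb[i, j] = donor NH of i bonded to C=O of j
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (!all(is.finite(bb$N[i, ])) || !all(is.finite(bb$H[i, ]))) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 && rt$chain[i] == rt$chain[j]) next
      if (!all(is.finite(bb$C[j, ])) || !all(is.finite(bb$O[j, ]))) next
      if (atom_distance(bb$N[i, ], bb$O[j, ]) > 5.2) next
      e <- ks_energy(bb$N[i, ], bb$H[i, ], bb$C[j, ], bb$O[j, ])
      hb[i, j] <- e < e_cut
    }
  }
  # n-turns: turn_k[i] TRUE when NH(i+k) -> C=O(i)
  turn <- list()
  for (k in 3:5) {
    tk <- rep(FALSE, n)
    for (i in seq_len(max(0, n - k)))
      if (contiguous(i, i + k) && hb[i + k, i]) tk[i] <- TRUE
    turn[[as.character(k)]] <- tk
  }
  raw <- rep("-", n)
  # helices: two consecutive n-turns make a minimal helix at i..i+k-1
  mark_helix <- function(raw, tk, k, code) {
    if (n - k < 2) return(raw)
    for (i in 2:(n - k)) {
      if (tk[i - 1] && tk[i]) {
        idx <- i:(i + k - 1)
        if (code == "H") raw[idx] <- "H"
        else if (all(raw[idx] %in% c("-", code))) raw[idx] <- code
      }
    }
    raw
  }
  raw <- mark_helix(raw, turn[["4"]], 4, "H")
  # bridges and ladders
  bridge <- matrix(FALSE, n, n)
  if (n >= 4) for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) < 3 && rt$chain[i] == rt$chain[j]) next
      para <- (hb[i, j - 1] && hb[j + 1, i]) || (hb[j, i - 1] && hb[i + 1, j])
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (para || anti) bridge[i, j] <- TRUE
    }
  }
  is_bridge <- apply(bridge, 1, any)
  # ladders: a bridge residue adjacent (in sequence) to another bridge
  # residue extends to E; isolated bridges stay B
  for (i in which(is_bridge)) {
    nb <- FALSE
    for (j in which(bridge[i, ])) {
      if ((i > 1 && any(bridge[i - 1, pmax(1, j - 1):pmin(n, j + 1)])) ||
          (i < n && any(bridge[i + 1, pmax(1, j - 1):pmin(n, j + 1)])))
        nb <- TRUE
    }
    code <- if (nb) "E" else "B"
    if (raw[i] == "-") raw[i] <- code
    else if (raw[i] != "H" && code == "E") raw[i] <- "E"
  }
  raw <- mark_helix(raw, turn[["3"]], 3, "G")
  raw <- mark_helix(raw, turn[["5"]], 5, "I")
  # turns: residues spanned by an n-turn (i+1 .. i+k-1)
  for (k in 3:5) {
    tk <- turn[[as.character(k)]]
    for (i in which(tk)) {
      idx <- (i + 1):(i + k - 1)
      raw[idx][raw[idx] == "-"] <- "T"
    }
  }
  # bends: curvature of the CA trace above 70 degrees
  # (180 minus the angle CA(i-2)-CA(i)-CA(i+2))
  if (n >= 5) for (i in 3:(n - 2)) {
    if (!contiguous(i - 2, i + 2)) next
    if (any(!is.finite(bb$CA[c(i - 2, i, i + 2), ]))) next
    curv <- 180 - bond_angle(bb$CA[i - 2, ], bb$CA[i, ], bb$CA[i + 2, ])
    if (curv > 70 && raw[i] == "-") raw[i] <- "S"
  }
  out$raw <- raw
  out$collapsed <- c(H = "alpha_helix", E = "beta_strand", B = "beta_strand",
                     G = "three10_pi", I = "three10_pi", T = "turn",
                     S = "bend", "-" = "none")[raw]
  # little h: first and last 4 residues of each maximal H run
  r <- rle(raw == "H")
  pos <- cumsum(r$lengths)
  start <- c(1, head(pos, -1) + 1)
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    idx <- start[k]:pos[k]
    lit <- unique(c(utils::head(idx, 4), utils::tail(idx, 4)))
    out$little_h[lit] <- TRUE
  }
  out
}

#' Collapse secondary-structure labels into class counts
#'
#' @param ss Output of [assign_ss()] (or a character vector of collapsed
#'   labels).
#' @return Named integer vector over the six classes; sums to the residue
#'   count.
#' @export
collapse_ss <- function(ss) {
  lab <- if (is.data.frame(ss)) ss$collapsed else ss
  classes <- c("alpha_helix", "beta_strand", "three10_pi", "turn", "bend",
               "none")
  tab <- table(factor(lab, levels = classes))
  out <- as.integer(tab)
  names(out) <- classes
  out
}
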