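# Structure container and PDB input/output. Parsing and writing of the PDB
# format itself is delegated to bio3d; this module owns alt-loc resolution,
# water bookkeeping, residue indexing and the identification of carbonyl
# acceptor sites and donor groups.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")

.WATER_NAMES <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "H2O")

.AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O")

.infer_element <- function(name, resname) {
  # strip digits and leading whitespace; PDB v2 hydrogens can be "1HB2"
  el <- sub("^[0-9 ]*", "", name)
  el <- substr(el, 1, 1)
  el[el == ""] <- "X"
  el
}

#' Construct a structure object
#'
#' An atom table (one row per atom, coordinates in Angstroms) tagged with a
#' structure id and a snapshot index. Protein atoms are ordered by
#' (chain, residue number, insertion code); waters follow.
#'
#' @param id Structure identifier string.
#' @param atoms data.frame with columns serial, name, element, alt, resname,
#'   chain, resno, insert, x, y, z, occ.
#' @param snapshot_index Non-negative integer; 0 for a static structure.
#' @return An object of class `ncistruct`.
#' @export
new_structure <- function(id, atoms, snapshot_index = 0L) {
  need <- c("serial", "name", "element", "alt", "resname", "chain", "resno",
            "insert", "x", "y", "z", "occ")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  atoms$is_water <- toupper(atoms$resname) %in% .WATER_NAMES
  atoms$res_uid <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  prot <- atoms[!atoms$is_water, , drop = FALSE]
  wat <- atoms[atoms$is_water, , drop = FALSE]
  if (nrow(prot)) {
    ord <- order(prot$chain, prot$resno, prot$insert)
    prot <- prot[ord, , drop = FALSE]
  }
  atoms <- rbind(prot, wat)
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms,
                 snapshot_index = as.integer(snapshot_index)),
            class = "ncistruct")
}

#' @export
print.ncistruct <- function(x, ...) {
  rt <- residue_table(x)
  nw <- length(unique(x$atoms$res_uid[x$atoms$is_water]))
  cat(sprintf("<ncistruct> %s (snapshot %d): %d residues, %d atoms, %d waters\n",
              x$id, x$snapshot_index, nrow(rt), nrow(x$atoms), nw))
  invisible(x)
}

# Resolve alt-locs: keep the highest-occupancy conformer per
# (residue, atom name); ties broken towards altLoc "A" (then alphabetical).
.resolve_altloc <- function(atoms) {
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "\r")
  dup <- key %in% key[duplicated(key)]
  if (!any(dup)) return(atoms)
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[dup])) {
    i <- which(key == k)
    occ <- atoms$occ[i]
    occ[is.na(occ)] <- 1
    best <- i[order(-occ, alt[i])][1]
    keep[i] <- FALSE
    keep[best] <- TRUE
  }
  atoms[keep, , drop = FALSE]
}

#' Read a PDB file
#'
#' Reads ATOM/HETATM records (PDB v3.3 columns) via bio3d. Waters (HOH, WAT,
#' TIP3, SOL) are retained and flagged. Alternate locations are resolved to
#' the highest-occupancy conformer (ties to altLoc "A"). Files containing
#' several MODEL blocks yield one structure per model with increasing
#' `snapshot_index`.
#'
#' @param path Path to a PDB file.
#' @param id Structure id; defaults to the file name without extension.
#' @return A single `ncistruct`, or a list of them when the file holds
#'   multiple MODELs.
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  el <- at$elesy
  bad <- is.na(el) | el == "" | el == " "
  el[bad] <- .infer_element(at$elety[bad], at$resid[bad])
  base <- data.frame(serial = at$eleno, name = at$elety, element = toupper(el),
                     alt = ifelse(is.na(at$alt), "", at$alt),
                     resname = toupper(at$resid),
                     chain = ifelse(is.na(at$chain), "A", at$chain),
                     resno = at$resno,
                     insert = ifelse(is.na(at$insert), "", at$insert),
                     occ = ifelse(is.na(at$o), 1, at$o),
                     stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  out <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    a <- base
    a$x <- xyz[m, seq(1, ncol(xyz), 3)]
    a$y <- xyz[m, seq(2, ncol(xyz), 3)]
    a$z <- xyz[m, seq(3, ncol(xyz), 3)]
    if (anyNA(a$x) || anyNA(a$y) || anyNA(a$z)) {
      bad <- which(is.na(a$x) | is.na(a$y) | is.na(a$z))[1]
      stop("malformed coordinates in '", path, "' at atom serial ",
           a$serial[bad])
    }
    a <- .resolve_altloc(a)
    out[[m]] <- new_structure(id, a, snapshot_index = m - 1L)
  }
  if (n_models == 1L) out[[1]] else out
}

#' Write one or more structures to a PDB file
#'
#' A single structure is written as a plain coordinate file; a list of
#' structures is written as a multi-MODEL file (one MODEL block per
#' snapshot). Coordinates are written at standard PDB precision (3 decimals).
#'
#' @param s An `ncistruct` or a list of them (shared atom ordering).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(s, path) {
  models <- if (inherits(s, "ncistruct")) list(s) else s
  stopifnot(length(models) >= 1, all(vapply(models, inherits, TRUE, "ncistruct")))
  multi <- length(models) > 1L
  if (file.exists(path)) file.remove(path)
  for (m in seq_along(models)) {
    a <- models[[m]]$atoms
    if (multi) cat(sprintf("MODEL     %4d\n", m), file = path, append = TRUE)
    bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = ifelse(a$is_water, "HETATM", "ATOM"),
                     resno = a$resno, resid = a$resname, eleno = a$serial,
                     elety = a$name, chain = a$chain,
                     insert = ifelse(a$insert == "", NA, a$insert),
                     alt = ifelse(a$alt == "", NA, a$alt),
                     o = a$occ, b = rep(0, nrow(a)), elesy = a$element,
                     append = TRUE, end = FALSE, verbose = FALSE)
    if (multi) cat("ENDMDL\n", file = path, append = TRUE)
  }
  cat("END   \n", file = path, append = TRUE)
  invisible(path)
}

#' Residue table of a structure
#'
#' One row per protein residue in structure order, with completeness of the
#' backbone (N, CA, C, O) and whether the residue is the final residue of its
#' chain (no peptide bond C_i-N_(i+1) <= 1.8 A to a successor).
#'
#' @param s An `ncistruct`.
#' @return data.frame with columns res_uid, chain, resno, insert, resname,
#'   complete, is_cterm.
#' @export
residue_table <- function(s) {
  a <- s$atoms[!s$atoms$is_water & toupper(s$atoms$resname) %in% .AA3, , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(res_uid = character(), chain = character(),
                      resno = integer(), insert = character(),
                      resname = character(), complete = logical(),
                      is_cterm = logical(), stringsAsFactors = FALSE))
  }
  uid <- unique(a$res_uid)
  first <- match(uid, a$res_uid)
  rt <- data.frame(res_uid = uid, chain = a$chain[first], resno = a$resno[first],
                   insert = a$insert[first], resname = a$resname[first],
                   stringsAsFactors = FALSE)
  has <- function(nm) vapply(uid, function(u)
    any(a$res_uid == u & a$name == nm), TRUE)
  rt$complete <- has("N") & has("CA") & has("C") & has("O")
  rt$is_cterm <- TRUE
  for (i in seq_len(nrow(rt) - 1)) {
    if (rt$chain[i] != rt$chain[i + 1]) next
    ci <- which(a$res_uid == rt$res_uid[i] & a$name == "C")
    nj <- which(a$res_uid == rt$res_uid[i + 1] & a$name == "N")
    if (length(ci) && length(nj)) {
      d <- atom_distance(as.numeric(a[ci[1], c("x", "y", "z")]),
                         as.numeric(a[nj[1], c("x", "y", "z")]))
      if (d <= 1.8) rt$is_cterm[i] <- FALSE
    }
  }
  rt
}

# coordinates of atom table rows as a matrix
.xyz <- function(atoms, idx) {
  as.matrix(atoms[idx, c("x", "y", "z"), drop = FALSE])
}

# index of a named atom within a residue (first match), NA if absent
.atom_idx <- function(atoms, uid, name) {
  i <- which(atoms$res_uid == uid & atoms$name == name & !atoms$is_water)
  if (length(i)) i[1] else NA_integer_
}

# hydrogens covalently bonded (<= 1.2 A) to a given heavy atom, searched
# within the same residue; bond inference is by distance, not by name, so
# both PDB v3 (HB2) and v2 (1HB) hydrogen dialects work.
.bonded_h <- function(atoms, heavy_idx) {
  uid <- atoms$res_uid[heavy_idx]
  wat <- atoms$is_water[heavy_idx]
  cand <- which(atoms$res_uid == uid & atoms$element == "H" &
                  atoms$is_water == wat)
  if (!length(cand)) return(integer())
  d <- atom_distance(.xyz(atoms, cand),
                     matrix(as.numeric(atoms[heavy_idx, c("x", "y", "z")]),
                            nrow = length(cand), ncol = 3, byrow = TRUE))
  cand[d <= 1.2]
}

#' Identify carbonyl acceptor sites
#'
#' One mainchain site per protein residue with a complete backbone; the
#' C-terminal carboxylate is excluded by default because the inventory
#' concerns amide carbonyls. Asn (CG/OD1) and Gln (CD/OE1) side-chain amide
#' carbonyls are emitted as `sidechain` sites. The `CAx` column holds the
#' third atom of the sp2 carbonyl plane (CA for mainchain, CB for Asn, CG
#' for Gln).
#'
#' @param s An `ncistruct`.
#' @param include_terminal Include the chain-terminal carbonyl (default FALSE).
#' @param topology Optional [structure_topology()] from a reference
#'   structure: atom roles are then resolved by name, with no geometric
#'   sanity checks, so every snapshot of an ensemble yields the same site
#'   list regardless of coordinate noise.
#' @return data.frame of sites: res_uid, chain, resno, insert, resname, kind,
#'   C, O, CAx (atom row indices into `s$atoms`).
#' @export
identify_carbonyls <- function(s, include_terminal = FALSE, topology = NULL) {
  a <- s$atoms
  if (!is.null(topology)) {
    tp <- topology$sites
    idx <- function(u, nm) vapply(seq_along(u), function(i) {
      j <- which(a$res_uid == u[i] & a$name == nm[i] & !a$is_water)
      if (length(j)) j[1] else NA_integer_
    }, 1L)
    out <- data.frame(res_uid = tp$res_uid, chain = tp$chain,
                      resno = tp$resno, insert = tp$insert,
                      resname = tp$resname, kind = tp$kind,
                      C = idx(tp$res_uid, tp$C_name),
                      O = idx(tp$res_uid, tp$O_name),
                      CAx = idx(tp$res_uid, tp$CAx_name),
                      stringsAsFactors = FALSE)
    if (anyNA(out$C) || anyNA(out$O) || anyNA(out$CAx))
      stop("topology does not match structure ", s$id)
    return(out)
  }
  rt <- residue_table(s)
  rows <- list()
  for (i in seq_len(nrow(rt))) {
    u <- rt$res_uid[i]
    if (rt$complete[i] && (include_terminal || !rt$is_cterm[i])) {
      C <- .atom_idx(a, u, "C"); O <- .atom_idx(a, u, "O"); CA <- .atom_idx(a, u, "CA")
      dco <- atom_distance(as.numeric(a[C, c("x", "y", "z")]),
                           as.numeric(a[O, c("x", "y", "z")]))
      if (dco >= 1.1 && dco <= 1.4) {
        rows[[length(rows) + 1L]] <- data.frame(
          res_uid = u, chain = rt$chain[i], resno = rt$resno[i],
          insert = rt$insert[i], resname = rt$resname[i], kind = "mainchain",
          C = C, O = O, CAx = CA, stringsAsFactors = FALSE)
      }
    }
    sc <- switch(rt$resname[i],
                 ASN = c("CG", "OD1", "CB"),
                 GLN = c("CD", "OE1", "CG"),
                 NULL)
    if (!is.null(sc)) {
      C <- .atom_idx(a, u, sc[1]); O <- .atom_idx(a, u, sc[2]); X <- .atom_idx(a, u, sc[3])
      if (!anyNA(c(C, O, X))) {
        dco <- atom_distance(as.numeric(a[C, c("x", "y", "z")]),
                             as.numeric(a[O, c("x", "y", "z")]))
        if (dco >= 1.1 && dco <= 1.4) {
          rows[[length(rows) + 1L]] <- data.frame(
            res_uid = u, chain = rt$chain[i], resno = rt$resno[i],
            insert = rt$insert[i], resname = rt$resname[i], kind = "sidechain",
            C = C, O = O, CAx = X, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(res_uid = character(), chain = character(),
                      resno = integer(), insert = character(),
                      resname = character(), kind = character(),
                      C = integer(), O = integer(), CAx = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Identify donor groups
#'
#' Enumerates every typed donor group: backbone amide NH (`NH_bb`, absent for
#' proline), side-chain NH (`NH_sc`: Lys, Arg, Asn, Gln, His, Trp),
#' side-chain hydroxyl (`OH_sc`: Ser, Thr, Tyr), alpha-carbon H (`CaH`),
#' side-chain carbons bearing at least one hydrogen (`CH_X`) and waters with
#' explicit hydrogens (`HOH`). Hydrogens are attached to their heavy atom by
#' distance (<= 1.2 A). Waters lacking hydrogens are excluded from the HOH
#' donors; their count is available as `attr(, "waters_without_h")`.
#'
#' @param s An `ncistruct`.
#' @param topology Optional [structure_topology()]; donor groups are then
#'   resolved by atom name with no distance-based bond inference.
#' @return data.frame of donor groups: category, res_uid, chain, resno,
#'   insert, resname, heavy (atom row index), heavy_name, and a list-column
#'   `hyd` of hydrogen row indices.
#' @export
identify_donors <- function(s, topology = NULL) {
  a <- s$atoms
  if (!is.null(topology)) {
    tp <- topology$donors
    out <- tp
    out$heavy <- NA_integer_
    out$hyd <- vector("list", nrow(tp))
    for (i in seq_len(nrow(tp))) {
      wat <- tp$category[i] == "HOH"
      j <- which(a$res_uid == tp$res_uid[i] & a$name == tp$heavy_name[i] &
                   a$is_water == wat)
      if (!length(j)) stop("topology does not match structure ", s$id)
      out$heavy[i] <- j[1]
      out$hyd[[i]] <- vapply(tp$hyd_names[[i]], function(nm) {
        k <- which(a$res_uid == tp$res_uid[i] & a$name == nm &
                     a$is_water == wat)
        if (length(k)) k[1] else NA_integer_
      }, 1L)
      if (anyNA(out$hyd[[i]]))
        stop("topology does not match structure ", s$id)
    }
    out$hyd_names <- NULL
    out$hyd <- I(out$hyd)
    attr(out, "waters_without_h") <- attr(topology, "waters_without_h") %||% 0L
    return(out)
  }
  rows <- list()
  add <- function(category, heavy, hyd) {
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, res_uid = a$res_uid[heavy], chain = a$chain[heavy],
      resno = a$resno[heavy], insert = a$insert[heavy],
      resname = a$resname[heavy], heavy = heavy, heavy_name = a$name[heavy],
      hyd = I(list(hyd)), stringsAsFactors = FALSE)
  }
  prot <- which(!a$is_water & a$resname %in% .AA3)
  for (u in unique(a$res_uid[prot])) {
    ri <- which(a$res_uid == u & !a$is_water)
    resname <- a$resname[ri[1]]
    for (j in ri) {
      el <- a$element[j]
      nm <- a$name[j]
      if (!el %in% c("N", "O", "C")) next
      h <- .bonded_h(a, j)
      if (!length(h)) next
      if (el == "N") {
        if (nm == "N") {
          if (resname != "PRO") add("NH_bb", j, h)
        } else add("NH_sc", j, h)
      } else if (el == "O") {
        if (nm != "O" && nm != "OXT") add("OH_sc", j, h)
      } else {
        if (nm == "CA") add("CaH", j, h)
        else if (nm != "C") add("CH_X", j, h)
      }
    }
  }
  n_dry <- 0L
  wat_o <- which(a$is_water & a$element == "O")
  for (j in wat_o) {
    h <- .bonded_h(a, j)
    if (length(h)) add("HOH", j, h) else n_dry <- n_dry + 1L
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(), res_uid = character(),
               chain = character(), resno = integer(), insert = character(),
               resname = character(), heavy = integer(),
               heavy_name = character(), hyd = I(list()),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "waters_without_h") <- n_dry
  out
}

#' Summarise a structure
#'
#' Counts of residues, donor groups by category and waters with/without
#' explicit hydrogens, suitable for JSON export.
#'
#' @param s An `ncistruct`.
#' @return A named list.
#' @export
structure_summary <- function(s) {
  rt <- residue_table(s)
  dn <- identify_donors(s)
  list(id = s$id, snapshot_index = s$snapshot_index,
       n_residues = nrow(rt), n_complete = sum(rt$complete),
       n_atoms = nrow(s$atoms),
       donors = as.list(table(dn$category)),
       n_waters_with_h = sum(dn$category == "HOH"),
       n_waters_without_h = attr(dn, "waters_without_h"))
}

#' Capture the interaction topology of a reference structure
#'
#' Records, by atom name, the carbonyl sites and donor groups identified on
#' a reference structure. Passing the result to [identify_carbonyls()],
#' [identify_donors()] or [inventory_structure()] for snapshots of the same
#' molecule pins the connectivity: coordinate noise can then never add or
#' remove sites, only change which interactions their geometry satisfies
#' (molecular-dynamics snapshots preserve topology; so does this pipeline).
#'
#' @param s The reference `ncistruct`.
#' @param include_terminal Passed to [identify_carbonyls()].
#' @return A list of class `nci_topology` with `sites` and `donors` tables.
#' @export
structure_topology <- function(s, include_terminal = FALSE) {
  a <- s$atoms
  sites <- identify_carbonyls(s, include_terminal)
  sites$C_name <- a$name[sites$C]
  sites$O_name <- a$name[sites$O]
  sites$CAx_name <- a$name[sites$CAx]
  sites$C <- sites$O <- sites$CAx <- NULL
  donors <- identify_donors(s)
  donors$hyd_names <- I(lapply(donors$hyd, function(h) a$name[h]))
  nwoh <- attr(donors, "waters_without_h")
  donors$heavy <- NULL
  donors$hyd <- NULL
  out <- structure(list(sites = sites, donors = donors),
                   class = "nci_topology")
  attr(out, "waters_without_h") <- nwoh
  out
}
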