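# Ensemble statistics over snapshot inventories: the count-distribution
# modes, modal averages and occupancies, secondary-structure-resolved
# tables, NCI-combination frequencies and per-residue densities.

.HB_TYPES <- c("NH_bb", "NH_sc", "OH_sc", "HOH")

#' Construct an ensemble inventory
#'
#' Low-level constructor from a residue x snapshot count matrix, optionally
#' with per-cell NCI-combination multisets and per-residue secondary
#' structure. Used directly in tests and by [ensemble_from_inventories()].
#'
#' @param counts Integer matrix, residues x snapshots (reported counts).
#' @param combos Optional list-matrix of the same shape; each cell a
#'   character vector of nci_type values (the cell's multiset).
#' @param ss Optional per-residue collapsed class (character vector) or the
#'   data.frame returned by [assign_ss()].
#' @param residues Residue identifiers (defaults to rownames or R1..Rn).
#' @param records Optional list (per snapshot) of record data.frames.
#' @param resnames Optional per-residue 3-letter codes.
#' @return An object of class `nci_ensemble`.
#' @export
ensemble_inventory <- function(counts, combos = NULL, ss = NULL,
                               residues = NULL, records = NULL,
                               resnames = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(residues))
    residues <- if (!is.null(rownames(counts))) rownames(counts)
                else paste0("R", seq_len(nrow(counts)))
  ss_df <- NULL
  if (is.data.frame(ss)) { ss_df <- ss; ss <- ss$collapsed[match(residues, ss$res_uid)] }
  if (!is.null(combos)) {
    stopifnot(is.matrix(combos) || is.list(combos))
    combos <- matrix(combos, nrow(counts), ncol(counts))
  }
  structure(list(residues = residues,
                 snapshots = seq_len(ncol(counts)) - 1L,
                 counts = counts, combos = combos,
                 ss = ss, ss_table = ss_df,
                 resnames = resnames, records = records),
            class = "nci_ensemble")
}

#' Build an ensemble inventory from per-snapshot inventories
#'
#' @param invs List of `nci_inventory` objects over the same residue set
#'   (e.g. one per snapshot of a trajectory or pseudo-ensemble).
#' @param ss Optional [assign_ss()] table from the reference structure;
#'   by convention secondary structure is assigned once on the reference
#'   and reused across snapshots.
#' @return An `nci_ensemble`.
#' @export
ensemble_from_inventories <- function(invs, ss = NULL) {
  stopifnot(length(invs) >= 1, all(vapply(invs, inherits, TRUE, "nci_inventory")))
  ref <- invs[[1]]$residues$res_uid
  for (k in seq_along(invs)) {
    uk <- invs[[k]]$residues$res_uid
    if (!identical(uk, ref)) {
      bad <- c(setdiff(uk, ref), setdiff(ref, uk), "order")[1]
      stop("snapshot ", k - 1, " residue set mismatch at residue: ", bad)
    }
  }
  n <- length(ref); m <- length(invs)
  counts <- matrix(0L, n, m, dimnames = list(ref, NULL))
  combos <- matrix(vector("list", n * m), n, m)
  for (k in seq_len(m)) {
    res <- invs[[k]]$residues
    counts[, k] <- res$reported_count
    for (i in seq_len(n)) {
      if (res$water_only[i]) {
        combos[[i, k]] <- c("HOH", "HOH")
      } else {
        ty <- invs[[k]]$records$nci_type[invs[[k]]$records$res_uid == ref[i]]
        combos[[i, k]] <- sort(ty)
      }
    }
  }
  ensemble_inventory(counts, combos = combos, ss = ss, residues = ref,
                     records = lapply(invs, `[[`, "records"),
                     resnames = invs[[1]]$residues$resname)
}

#' @export
print.nci_ensemble <- function(x, ...) {
  cat(sprintf("<nci_ensemble> %d residues x %d snapshots; mean count %.2f\n",
              nrow(x$counts), ncol(x$counts), mean(x$counts)))
  invisible(x)
}

#' Modal count of a series
#'
#' Most frequent value; ties are broken to the smallest tied value so that
#' over-satisfaction is never inflated by a tie.
#'
#' @param series Non-empty integer vector.
#' @return The modal value.
#' @export
modal_count <- function(series) {
  if (!length(series)) stop("empty series")
  tab <- table(series)
  vals <- as.integer(names(tab))
  min(vals[tab == max(tab)])
}

#' Occupancy at the modal count
#'
#' Fraction of the series spent at [modal_count()].
#'
#' @param series Non-empty integer vector.
#' @return Fraction in (0, 1].
#' @export
occupancy_at_mode <- function(series) {
  if (!length(series)) stop("empty series")
  mean(series == modal_count(series))
}

.hist_pct <- function(x, levels) {
  tab <- table(factor(x, levels = levels))
  100 * as.numeric(tab) / max(1, length(x))
}

#' The four count distributions
#'
#' Percentages of carbonyls making x NCIs, measured four ways: over the
#' static structures; over all residue-snapshot cells of the ensemble; over
#' the per-residue modal averages; and over the cells of only those
#' residues that spend at least half of the ensemble at their modal count.
#'
#' @param ei An `nci_ensemble`.
#' @param static_counts Integer vector of static reported counts (or an
#'   `nci_inventory`); must cover the same residue set.
#' @param min_occupancy Occupancy threshold for the filtered mode
#'   (default 0.5, inclusive).
#' @return A list of class `nci_distributions` with elements `static`,
#'   `per_snapshot`, `modal`, `modal_occupancy_filtered`: named percentage
#'   vectors each summing to 100.
#' @export
nci_distributions <- function(ei, static_counts = NULL, min_occupancy = 0.5) {
  stopifnot(inherits(ei, "nci_ensemble"))
  if (inherits(static_counts, "nci_inventory")) {
    if (!identical(static_counts$residues$res_uid, ei$residues))
      stop("static inventory residue set mismatch: ",
           paste(utils::head(setdiff(static_counts$residues$res_uid,
                                     ei$residues), 3), collapse = ", "))
    static_counts <- static_counts$residues$reported_count
  }
  if (is.null(static_counts)) static_counts <- ei$counts[, 1]
  if (length(static_counts) != nrow(ei$counts))
    stop("static counts length does not match ensemble residues")
  modal <- apply(ei$counts, 1, modal_count)
  occ <- apply(ei$counts, 1, occupancy_at_mode)
  lev <- 0:max(ei$counts, static_counts, modal)
  keep <- occ >= min_occupancy
  out <- list(static = .hist_pct(static_counts, lev),
              per_snapshot = .hist_pct(as.vector(ei$counts), lev),
              modal = .hist_pct(modal, lev),
              modal_occupancy_filtered =
                .hist_pct(as.vector(ei$counts[keep, , drop = FALSE]), lev))
  for (k in seq_along(out)) names(out[[k]]) <- as.character(lev)
  structure(out, class = "nci_distributions")
}

#' @export
print.nci_distributions <- function(x, ...) {
  m <- do.call(rbind, x)
  cat("Percentage of carbonyls making x NCIs:\n")
  print(round(m, 1))
  invisible(x)
}

.combo_key <- function(types) {
  if (!length(types)) "(none)" else paste(sort(types), collapse = "+")
}

#' NCI combination frequencies by secondary structure
#'
#' Tabulates the unordered multisets of NCI types made by carbonyls with a
#' given count, resolved by secondary-structure class. For `n_target = 2`
#' the default pools all residue-snapshot cells at that count; for the
#' under-/over-satisfied counts (1 and 3) the convention is to keep only
#' residues whose modal count equals the target with occupancy >= 0.5, then
#' pool their matching cells.
#'
#' @param ei An `nci_ensemble` with combos and ss populated.
#' @param n_target Target NCI count.
#' @param occupancy_filter Apply the modal+occupancy filter (default TRUE
#'   for n_target 1 and 3, FALSE for 2).
#' @param min_occupancy Occupancy threshold (default 0.5).
#' @return data.frame: ss_class, combo, n, pct (percentages normalised
#'   within each ss_class).
#' @export
combo_frequencies <- function(ei, n_target,
                              occupancy_filter = n_target != 2,
                              min_occupancy = 0.5) {
  stopifnot(inherits(ei, "nci_ensemble"))
  if (is.null(ei$combos)) stop("ensemble has no combination data")
  ss <- if (is.null(ei$ss)) rep("all", nrow(ei$counts)) else ei$ss
  rows <- list()
  if (occupancy_filter) {
    modal <- apply(ei$counts, 1, modal_count)
    occ <- apply(ei$counts, 1, occupancy_at_mode)
    use_res <- which(modal == n_target & occ >= min_occupancy)
  } else use_res <- seq_len(nrow(ei$counts))
  for (i in use_res) {
    for (k in which(ei$counts[i, ] == n_target)) {
      rows[[length(rows) + 1L]] <- c(ss[i], .combo_key(ei$combos[[i, k]]))
    }
  }
  if (!length(rows)) {
    return(data.frame(ss_class = character(), combo = character(),
                      n = integer(), pct = numeric(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rows)
  tab <- as.data.frame(table(ss_class = m[, 1], combo = m[, 2]),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  names(tab)[3] <- "n"
  tot <- tapply(tab$n, tab$ss_class, sum)
  tab$pct <- 100 * tab$n / as.numeric(tot[tab$ss_class])
  rownames(tab) <- NULL
  tab[order(tab$ss_class, -tab$n), ]
}

#' Mean NCI density per residue
#'
#' Mean reported count over all residue-snapshot cells, optionally
#' restricted to one secondary-structure class.
#'
#' @param ei An `nci_ensemble`.
#' @param ss_class Optional class name (e.g. "alpha_helix").
#' @return Mean count.
#' @export
nci_density <- function(ei, ss_class = NULL) {
  stopifnot(inherits(ei, "nci_ensemble"))
  sel <- seq_len(nrow(ei$counts))
  if (!is.null(ss_class)) {
    if (is.null(ei$ss)) stop("ensemble has no secondary structure")
    sel <- which(ei$ss == ss_class)
  }
  mean(ei$counts[sel, , drop = FALSE])
}

#' Mean hydrogen bonds per residue
#'
#' As [nci_density()] but counting only conventional hydrogen-bond donors
#' (NH_bb, NH_sc, OH_sc, HOH); weak C-H bonds and n->pi* contacts are
#' excluded.
#'
#' @param ei An `nci_ensemble` with combos populated.
#' @param ss_class Optional class restriction.
#' @return Mean hydrogen-bond count per residue-snapshot.
#' @export
hbonds_per_residue <- function(ei, ss_class = NULL) {
  stopifnot(inherits(ei, "nci_ensemble"))
  if (is.null(ei$combos)) stop("ensemble has no combination data")
  sel <- seq_len(nrow(ei$counts))
  if (!is.null(ss_class)) {
    if (is.null(ei$ss)) stop("ensemble has no secondary structure")
    sel <- which(ei$ss == ss_class)
  }
  if (!length(sel)) return(NaN)
  vals <- vapply(sel, function(i)
    mean(vapply(seq_len(ncol(ei$counts)), function(k)
      sum(ei$combos[[i, k]] %in% .HB_TYPES), 0)), 0)
  mean(vals)
}

#' Secondary-structure x count summary table
#'
#' For each class and count value x: the mean (over snapshots) number of
#' residues making x NCIs, and the number of residues whose modal count is
#' x.
#'
#' @param ei An `nci_ensemble` with ss populated.
#' @return list with `mean` and `modal` matrices (class x count).
#' @export
ss_count_table <- function(ei) {
  stopifnot(inherits(ei, "nci_ensemble"))
  ss <- if (is.null(ei$ss)) rep("all", nrow(ei$counts)) else ei$ss
  classes <- unique(ss)
  lev <- 0:max(ei$counts)
  mean_m <- matrix(0, length(classes), length(lev),
                   dimnames = list(classes, as.character(lev)))
  modal_m <- mean_m
  modal <- apply(ei$counts, 1, modal_count)
  for (ci in seq_along(classes)) {
    rows <- which(ss == classes[ci])
    per_snap <- vapply(lev, function(x)
      mean(colSums(ei$counts[rows, , drop = FALSE] == x)), 0)
    mean_m[ci, ] <- per_snap
    modal_m[ci, ] <- vapply(lev, function(x) sum(modal[rows] == x), 0)
  }
  list(mean = mean_m, modal = modal_m)
}
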