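# End-to-end orchestration: static inventories and full ensemble reports
# with machine-readable TSV/JSON outputs and a content-hash manifest.

.load_inputs <- function(input) {
  if (inherits(input, "ncistruct")) return(list(input))
  if (is.list(input) && all(vapply(input, inherits, TRUE, "ncistruct")))
    return(input)
  if (is.character(input)) {
    paths <- input
    if (length(paths) == 1 && dir.exists(paths))
      paths <- sort(list.files(paths, pattern = "\\.(pdb|ent)$",
                               full.names = TRUE, ignore.case = TRUE))
    if (!length(paths)) stop("no inputs")
    out <- list()
    for (p in paths) {
      s <- read_pdb(p)
      out <- c(out, if (inherits(s, "ncistruct")) list(s) else s)
    }
    return(out)
  }
  stop("unsupported input type")
}

.write_manifest <- function(out_dir, files) {
  files <- files[file.exists(files)]
  manifest <- list(files = lapply(files, function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, jf, auto_unbox = TRUE, pretty = TRUE)
  invisible(jf)
}

#' Run the static inventory pipeline
#'
#' Reads one or more structures, inventories every backbone carbonyl,
#' assigns secondary structure and writes per-structure inventory and
#' secondary-structure TSVs plus a summary JSON (static count
#' distribution, class-resolved count table, per-structure summaries) and
#' a manifest with content hashes.
#'
#' @param input PDB path(s), a directory of PDB files, an `ncistruct` or a
#'   list of them.
#' @param out_dir Output directory (created if needed).
#' @param th An [nci_thresholds()].
#' @return Invisibly, a list with the computed tables.
#' @export
run_static <- function(input, out_dir, th = nci_thresholds()) {
  structs <- .load_inputs(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  all_counts <- integer()
  class_tab <- list()
  summaries <- list()
  for (s in structs) {
    inv <- inventory_structure(s, th)
    ss <- assign_ss(s)
    f1 <- file.path(out_dir, paste0(s$id, "_inventory.tsv"))
    write_inventory_tsv(inv, f1)
    f2 <- file.path(out_dir, paste0(s$id, "_ss.tsv"))
    utils::write.table(ss, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f1, f2)
    all_counts <- c(all_counts, inv$residues$reported_count)
    cls <- ss$collapsed[match(inv$residues$res_uid, ss$res_uid)]
    for (i in seq_along(cls)) {
      key <- paste(cls[i], inv$residues$reported_count[i])
      class_tab[[key]] <- (class_tab[[key]] %||% 0L) + 1L
    }
    summaries[[s$id]] <- structure_summary(s)
  }
  lev <- 0:max(all_counts, 0)
  dist <- .hist_pct(all_counts, lev)
  names(dist) <- as.character(lev)
  report <- list(n_structures = length(structs),
                 static_distribution_pct = as.list(dist),
                 class_count_table = class_tab,
                 structures = summaries)
  fj <- file.path(out_dir, "static_report.json")
  jsonlite::write_json(report, fj, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, fj)
  .write_manifest(out_dir, files)
  invisible(list(distribution = dist, class_count_table = class_tab,
                 report = report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the ensemble pipeline
#'
#' Loads a snapshot ensemble (multi-MODEL PDB, directory of PDB snapshots
#' or a list of structures), inventories every snapshot, and writes the
#' full report: the four count distributions, combination-frequency tables
#' for counts 1/2/3, NCI densities and hydrogen bonds per residue (overall
#' and per secondary-structure class), motif hits and the
#' bifurcated-hydrogen-bond fraction.
#'
#' @param input Ensemble input (see above).
#' @param out_dir Output directory.
#' @param th An [nci_thresholds()].
#' @param static_input Optional separate static structure for the static
#'   distribution (defaults to the first snapshot).
#' @param ss_mode "reference" (assign secondary structure once, on the
#'   first snapshot; the default) or "per_snapshot" (reassign on every
#'   snapshot and use each residue's modal class).
#' @param min_occupancy Occupancy threshold for modal statistics.
#' @return Invisibly, a list with the ensemble object and computed
#'   statistics.
#' @export
run_ensemble <- function(input, out_dir, th = nci_thresholds(),
                         static_input = NULL, ss_mode = c("reference",
                                                          "per_snapshot"),
                         min_occupancy = 0.5) {
  ss_mode <- match.arg(ss_mode)
  snaps <- .load_inputs(input)
  if (!length(snaps)) stop("no inputs")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref_res <- residue_table(snaps[[1]])$res_uid
  for (k in seq_along(snaps)[-1]) {
    rk <- residue_table(snaps[[k]])$res_uid
    if (!identical(rk, ref_res)) {
      bad <- c(setdiff(rk, ref_res), setdiff(ref_res, rk), "(order)")[1]
      stop("snapshot ", k - 1, " residue set mismatch at residue: ", bad)
    }
  }
  topo <- structure_topology(snaps[[1]])
  invs <- lapply(snaps, inventory_structure, th = th, topology = topo)
  ss <- assign_ss(snaps[[1]])
  if (ss_mode == "per_snapshot" && length(snaps) > 1) {
    labs <- vapply(snaps, function(s) assign_ss(s)$collapsed,
                   character(nrow(ss)))
    ss$collapsed <- apply(labs, 1, function(x) names(sort(table(x),
                                                          decreasing = TRUE))[1])
  }
  ei <- ensemble_from_inventories(invs, ss = ss)
  static_counts <- if (is.null(static_input)) NULL else
    inventory_structure(.load_inputs(static_input)[[1]], th)
  dist <- nci_distributions(ei, static_counts, min_occupancy)
  combos <- lapply(c(1, 2, 3), function(k) combo_frequencies(ei, k))
  names(combos) <- paste0("n", 1:3)
  classes <- unique(ei$ss %||% "all")
  dens <- c(list(all = nci_density(ei)),
            stats::setNames(lapply(classes, function(cl)
              nci_density(ei, cl)), classes))
  hbs <- c(list(all = hbonds_per_residue(ei)),
           stats::setNames(lapply(classes, function(cl)
             hbonds_per_residue(ei, cl)), classes))
  motifs <- find_motifs(ei, min_occupancy)
  bif <- bifurcation_fraction(ei)
  files <- character()
  fm <- file.path(out_dir, "motifs.tsv")
  utils::write.table(motifs, fm, sep = "\t", quote = FALSE, row.names = FALSE)
  for (k in names(combos)) {
    fk <- file.path(out_dir, paste0("combos_", k, ".tsv"))
    utils::write.table(combos[[k]], fk, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, fk)
  }
  tab <- ss_count_table(ei)
  report <- list(n_snapshots = length(snaps),
                 n_residues = nrow(ei$counts),
                 distributions = lapply(unclass(dist), as.list),
                 nci_density = dens,
                 hbonds_per_residue = hbs,
                 bifurcation_fraction = bif,
                 ss_count_table = list(mean = as.data.frame(tab$mean),
                                       modal = as.data.frame(tab$modal)),
                 n_motif_hits = nrow(motifs))
  fj <- file.path(out_dir, "ensemble_report.json")
  jsonlite::write_json(report, fj, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, fm, fj)
  .write_manifest(out_dir, files)
  invisible(list(ensemble = ei, distributions = dist, combos = combos,
                 densities = dens, hbonds = hbs, motifs = motifs,
                 bifurcation = bif, report = report))
}
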