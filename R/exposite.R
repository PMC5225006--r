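# The decision layer: flag residues whose exposure changes strongly in
# low-frequency modes, take the centroid of their C-alpha positions as the
# predicted active site, and rank geometric pockets by proximity to it.

#' Pipeline configuration
#'
#' Bundles every tunable of the prediction pipeline with its default.
#' Defaults follow the trained operating point: the 10 lowest non-trivial
#' modes and a per-residue |dSAS| window of 20-40 Angstrom^2 (below ~10
#' Angstrom^2 ordinary exposure fluctuations dominate; far above 40 the
#' tip effect at flexible termini does).
#'
#' @param n_modes number of non-trivial low-frequency modes sampled.
#' @param dsas_min,dsas_max flagging window for per-residue |dSAS|
#'   (Angstrom^2).
#' @param dsas_ceiling optional hard upper cutoff on |dSAS| applied on top
#'   of the window (safety valve against flexible-termini artifacts);
#'   `NULL` disables it.
#' @param amplitude inter-extreme C-alpha RMSD of each mode deformation
#'   (Angstrom).
#' @param enm_cutoff elastic-network contact cutoff (Angstrom).
#' @param n_sphere_points SASA lattice points per atom.
#' @param grid_spacing,grid_margin pocket grid geometry (Angstrom).
#' @param min_psp minimum protein-solvent-protein directions (of 7).
#' @param pocket_min_volume pocket volume floor (Angstrom^3).
#' @param keep_pockets maximum number of pockets retained.
#' @param aggregate `"union"` flags a residue qualifying in any mode;
#'   `"max"` applies the window to the residue's maximum |dSAS| over modes.
#' @param centroid_cutoff success cutoff for the centroid criterion
#'   (Angstrom, strict `<`).
#' @param ligand_cutoff success cutoff for the ligand criterion (Angstrom,
#'   inclusive `<=`).
#' @return an `exposite_config` list.
#' @export
exposite_config <- function(n_modes = 10L, dsas_min = 20, dsas_max = 40,
                            dsas_ceiling = NULL, amplitude = 2.0,
                            enm_cutoff = 12, n_sphere_points = 960L,
                            grid_spacing = 1.0, grid_margin = 4.0,
                            min_psp = 3L, pocket_min_volume = 7.0,
                            keep_pockets = 10L,
                            aggregate = c("union", "max"),
                            centroid_cutoff = 12, ligand_cutoff = 4) {
  stopifnot(dsas_min >= 0, dsas_min < dsas_max, amplitude > 0,
            enm_cutoff > 0, centroid_cutoff > 0, ligand_cutoff > 0)
  structure(list(n_modes = as.integer(n_modes), dsas_min = dsas_min,
                 dsas_max = dsas_max, dsas_ceiling = dsas_ceiling,
                 amplitude = amplitude, enm_cutoff = enm_cutoff,
                 n_sphere_points = as.integer(n_sphere_points),
                 grid_spacing = grid_spacing, grid_margin = grid_margin,
                 min_psp = as.integer(min_psp),
                 pocket_min_volume = pocket_min_volume,
                 keep_pockets = as.integer(keep_pockets),
                 aggregate = match.arg(aggregate),
                 centroid_cutoff = centroid_cutoff,
                 ligand_cutoff = ligand_cutoff),
            class = "exposite_config")
}

no_signal_error <- function(msg) {
  stop(structure(class = c("exposite_no_signal", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Flag residues by the |dSAS| window
#'
#' A residue is flagged when its per-residue |dSAS| falls inside
#' `[dsas_min, dsas_max]` for at least one sampled mode (union over modes;
#' with `aggregate = "max"` the window is applied to the per-residue
#' maximum over modes instead). Each flag records the qualifying
#' (mode, |dSAS|) pairs.
#'
#' @param profiles list of `dsas_profile`s, one per mode, over a common
#'   residue set.
#' @param config an [exposite_config()].
#' @return data frame with columns `residue`, `mode`, `dsas` (one row per
#'   qualifying residue-mode pair). Raises a no-signal condition when no
#'   residue qualifies.
#' @export
flag_exposed_residues <- function(profiles, config = exposite_config()) {
  stopifnot(length(profiles) >= 1)
  res <- names(profiles[[1]]$value)
  for (p in profiles)
    if (!identical(names(p$value), res))
      stop("mode profiles cover different residue sets", call. = FALSE)
  tab <- do.call(rbind, lapply(profiles, function(p)
    data.frame(residue = res, mode = p$mode_index,
               dsas = as.numeric(p$value), stringsAsFactors = FALSE)))
  if (!is.null(config$dsas_ceiling))
    tab <- tab[tab$dsas <= config$dsas_ceiling, , drop = FALSE]
  if (config$aggregate == "max") {
    mx <- tapply(tab$dsas, tab$residue, max)
    keep_res <- names(mx)[mx >= config$dsas_min & mx <= config$dsas_max]
    hits <- tab[tab$residue %in% keep_res &
                  tab$dsas >= config$dsas_min & tab$dsas <= config$dsas_max, ,
                drop = FALSE]
  } else {
    hits <- tab[tab$dsas >= config$dsas_min & tab$dsas <= config$dsas_max, ,
                drop = FALSE]
  }
  if (nrow(hits) == 0)
    no_signal_error(sprintf(
      "no residue has |dSAS| in [%g, %g] Angstrom^2 in any of %d modes; consider widening the window",
      config$dsas_min, config$dsas_max, length(profiles)))
  rownames(hits) <- NULL
  hits
}

#' Per-mode |dSAS| profiles of a structure
#'
#' Runs the mode engine and SASA stages: elastic network on the C-alpha
#' trace, the `n_modes` lowest non-trivial modes, a pair of opposite
#' extreme conformers per mode, and the per-residue |dSAS| between them.
#'
#' @param structure an `exposite_structure`.
#' @param config an [exposite_config()].
#' @return list of `dsas_profile`s, one per mode.
#' @export
dsas_profiles <- function(structure, config = exposite_config()) {
  net <- elastic_network(structure, cutoff = config$enm_cutoff)
  modes <- suppressWarnings(compute_modes(build_hessian(net), config$n_modes))
  radii <- radii_table()
  lapply(seq_along(modes$values), function(k) {
    pair <- generate_extremes(structure, modes, k, config$amplitude)
    delta_sas(shrake_rupley(pair$plus, radii, config$n_sphere_points),
              shrake_rupley(pair$minus, radii, config$n_sphere_points),
              mode_index = k)
  })
}

#' Predict the active site of a structure
#'
#' The full pipeline: normal modes on the C-alpha elastic network, per-mode
#' extreme conformers, per-residue |dSAS|, window flagging, and the
#' exposure centroid — the unweighted mean of the flagged residues'
#' C-alpha coordinates — as the predicted site. Geometric pockets are
#' detected on the undeformed structure and ranked by ascending distance
#' of their centre to the predicted site.
#'
#' @param structure an `exposite_structure`.
#' @param config an [exposite_config()].
#' @return an `exposite_prediction`: `site` (predicted coordinate),
#'   `flagged` (residue/mode/|dSAS| table), `ranked_pockets` (pockets with
#'   `dist_to_site`, ascending), `baseline_site` (EnSite-style pocket
#'   choice, `NULL` when no pockets), `config`.
#' @export
predict_active_site <- function(structure, config = exposite_config()) {
  profiles <- dsas_profiles(structure, config)
  flagged <- flag_exposed_residues(profiles, config)
  site <- ca_centroid(structure, unique(flagged$residue))
  pockets <- find_pockets(structure,
                          spacing = config$grid_spacing,
                          margin = config$grid_margin,
                          min_psp = config$min_psp,
                          min_volume = config$pocket_min_volume,
                          keep = config$keep_pockets)
  if (length(pockets) > 0) {
    d <- vapply(pockets, function(p) sqrt(sum((p$center - site)^2)),
                numeric(1))
    ord <- order(d)
    pockets <- pockets[ord]
    for (i in seq_along(pockets)) pockets[[i]]$dist_to_site <- d[ord][i]
    baseline <- baseline_ensite(structure, pockets)
  } else {
    baseline <- NULL
  }
  structure(list(site = site, flagged = flagged, ranked_pockets = pockets,
                 baseline_site = baseline, profiles = profiles,
                 config = config, id = structure$id),
            class = "exposite_prediction")
}

#' @export
print.exposite_prediction <- function(x, ...) {
  cat(sprintf("<exposite_prediction> %s\n", x$id))
  cat(sprintf("  predicted site: (%.2f, %.2f, %.2f)\n",
              x$site[1], x$site[2], x$site[3]))
  cat(sprintf("  flagged residues: %d (%d residue-mode hits)\n",
              length(unique(x$flagged$residue)), nrow(x$flagged)))
  cat(sprintf("  pockets: %d", length(x$ranked_pockets)))
  if (length(x$ranked_pockets) > 0)
    cat(sprintf("; nearest at %.1f A, %.0f A^3",
                x$ranked_pockets[[1]]$dist_to_site,
                x$ranked_pockets[[1]]$volume))
  cat("\n")
  invisible(x)
}

#' Evaluate a prediction against known catalytic residues
#'
#' The observed site is the centroid of the C-alpha coordinates of the
#' annotated residues; the prediction succeeds when the predicted-observed
#' distance is strictly below `cutoff` (default 12 Angstrom).
#'
#' @param prediction an `exposite_prediction` (or any list with `site`).
#' @param observed_residues character vector of residue identifiers.
#' @param structure the structure the residues refer to.
#' @param cutoff success cutoff in Angstrom.
#' @return an `exposite_evaluation`: `distance`, `success`, `criterion`.
#' @export
evaluate_centroid <- function(prediction, observed_residues, structure,
                              cutoff = 12) {
  observed <- ca_centroid(structure, observed_residues)
  d <- sqrt(sum((prediction$site - observed)^2))
  structure(list(distance = d, success = d < cutoff,
                 criterion = "centroid_12A", cutoff = cutoff,
                 observed_site = observed),
            class = "exposite_evaluation")
}

#' Evaluate a prediction against a bound ligand
#'
#' Succeeds when any ligand atom lies within `cutoff` (default 4 Angstrom,
#' inclusive) of the predicted site.
#'
#' @param prediction an `exposite_prediction`.
#' @param ligand_atoms atom table (e.g. `structure$ligand`) with x/y/z
#'   columns.
#' @param cutoff success cutoff in Angstrom.
#' @return an `exposite_evaluation`: `distance` (minimum site-to-atom
#'   distance), `success`, `criterion`.
#' @export
evaluate_ligand <- function(prediction, ligand_atoms, cutoff = 4) {
  if (is.null(ligand_atoms) || nrow(ligand_atoms) == 0)
    stop("no ligand atoms to evaluate against", call. = FALSE)
  xyz <- as.matrix(ligand_atoms[, c("x", "y", "z")])
  d <- min(sqrt(rowSums((xyz - matrix(prediction$site, nrow(xyz), 3,
                                      byrow = TRUE))^2)))
  structure(list(distance = d, success = d <= cutoff,
                 criterion = "ligand_4A", cutoff = cutoff),
            class = "exposite_evaluation")
}

#' @export
print.exposite_evaluation <- function(x, ...) {
  cat(sprintf("<exposite_evaluation> %s: distance %.2f A -> %s\n",
              x$criterion, x$distance,
              if (x$success) "success" else "failure"))
  invisible(x)
}

#' EnSite-style baseline: pocket nearest the molecular centroid
#'
#' Purely geometric reference predictor: among the detected pockets,
#' return the centre of the one whose centre is nearest the molecular
#' centroid.
#'
#' @param structure an `exposite_structure`.
#' @param pockets non-empty list of pockets.
#' @return numeric length-3 coordinate.
#' @export
baseline_ensite <- function(structure, pockets) {
  if (length(pockets) == 0) stop("no pockets to rank", call. = FALSE)
  mc <- molecular_centroid(structure)
  d <- vapply(pockets, function(p) sqrt(sum((p$center - mc)^2)), numeric(1))
  pockets[[which.min(d)]]$center
}

#' Sweep the |dSAS| window and mode count over an evaluation set
#'
#' Re-evaluates the centroid criterion over a grid of flagging windows and
#' mode counts. The expensive stages (modes, SASA) are computed once per
#' structure at the largest requested mode count; each grid cell only
#' re-applies the window.
#'
#' @param structures list of `exposite_structure`s.
#' @param truths list of residue-identifier vectors (observed sites), or a
#'   list of length-3 coordinates, aligned with `structures`.
#' @param dsas_grid list of `c(min, max)` windows.
#' @param modes_grid integer vector of mode counts.
#' @param config base [exposite_config()] for the fixed parameters.
#' @return data frame: `dsas_min`, `dsas_max`, `n_modes`, `success_rate`,
#'   `n`.
#' @export
sweep_thresholds <- function(structures, truths, dsas_grid,
                             modes_grid = NULL, config = exposite_config()) {
  stopifnot(length(structures) >= 1, length(structures) == length(truths))
  if (is.null(modes_grid)) modes_grid <- config$n_modes
  max_modes <- max(modes_grid)
  cfg_full <- config
  cfg_full$n_modes <- as.integer(max_modes)
  all_profiles <- lapply(structures, dsas_profiles, config = cfg_full)
  observed <- lapply(seq_along(truths), function(i) {
    if (is.character(truths[[i]])) ca_centroid(structures[[i]], truths[[i]])
    else as.numeric(truths[[i]])
  })
  rows <- list()
  for (m in modes_grid) for (w in dsas_grid) {
    cfg <- config
    cfg$dsas_min <- w[1]; cfg$dsas_max <- w[2]; cfg$n_modes <- as.integer(m)
    ok <- vapply(seq_along(structures), function(i) {
      prof <- all_profiles[[i]][seq_len(min(m, length(all_profiles[[i]])))]
      flagged <- tryCatch(flag_exposed_residues(prof, cfg),
                          exposite_no_signal = function(e) NULL)
      if (is.null(flagged)) return(FALSE)
      site <- ca_centroid(structures[[i]], unique(flagged$residue))
      sqrt(sum((site - observed[[i]])^2)) < cfg$centroid_cutoff
    }, logical(1))
    rows[[length(rows) + 1]] <- data.frame(
      dsas_min = w[1], dsas_max = w[2], n_modes = m,
      success_rate = mean(ok), n = length(ok))
  }
  do.call(rbind, rows)
}

#' Serialise a prediction as a JSON report
#'
#' @param prediction an `exposite_prediction`.
#' @param file optional output path.
#' @return JSON string (invisibly when `file` is given).
#' @export
prediction_report <- function(prediction, file = NULL) {
  pk <- lapply(prediction$ranked_pockets, function(p)
    list(center = round(as.numeric(p$center), 3), volume = p$volume,
         n_cells = p$n_cells, rank_by_size = p$rank_by_size,
         dist_to_site = round(p$dist_to_site, 3)))
  cfg <- prediction$config
  rep <- list(
    id = prediction$id,
    site = round(as.numeric(prediction$site), 3),
    flagged = prediction$flagged,
    ranked_pockets = pk,
    baseline_site = if (is.null(prediction$baseline_site)) NULL
                    else round(as.numeric(prediction$baseline_site), 3),
    config = cfg[!vapply(cfg, is.null, logical(1))])
  txt <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}
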