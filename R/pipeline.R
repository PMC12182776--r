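# End-to-end orchestration of the post-docking workflow: per-pose interface
# reports, ensemble contact frequencies, top-k lists, Venn overlaps,
# annotated structures, spatial groups and correlation summaries.

#' Full interface report for one docking pose
#'
#' Assembles, for a single receptor-ligand pose: interface residues at the
#' residue cutoff, typed intermolecular contacts at the contact cutoff,
#' hydrogen bonds, salt bridges, non-interacting-surface composition and
#' the contact-based binding-affinity estimate. Receptor residues forming
#' hydrogen bonds or salt bridges are flagged within the interface-residue
#' list.
#'
#' @param pose list with `rank`, `score`, `structure`.
#' @param receptor_chain,ligand_chains chain designations.
#' @param contacts a [contact_config()].
#' @param affinity an [affinity_config()].
#' @param sasa_points sphere points per atom for the surface terms
#'   (default 960); set to `NULL` to skip the surface terms.
#' @return list of class `interface_report` with scalar summary fields
#'   (`pose_rank`, `ld_score`, `dG`, `Kd`, `imc_total`, `n_hbonds`,
#'   `n_salt_bridges`), per-class contact counts, and the underlying
#'   tables.
#' @export
report_pose <- function(pose, receptor_chain, ligand_chains,
                        contacts = contact_config(),
                        affinity = affinity_config(),
                        sasa_points = 960) {
  parts <- .pose_partners(pose, receptor_chain, ligand_chains)
  cr <- contact_residues(parts$receptor, parts$ligand,
                         cutoff = contacts$residue_cutoff,
                         heavy_only = contacts$heavy_only)
  imc <- intermolecular_contacts(parts$receptor, parts$ligand,
                                 cutoff = contacts$imc_cutoff,
                                 heavy_only = contacts$heavy_only)
  hb <- hydrogen_bonds(parts$receptor, parts$ligand)
  sb <- salt_bridges(parts$receptor, parts$ligand)
  nis <- if (is.null(sasa_points)) NULL else
    tryCatch(nis_fractions(parts$receptor, parts$ligand,
                           n_points = sasa_points),
             error = function(e) NULL)
  est <- predict_dG(imc, nis, affinity)
  hb_rec <- unique(ifelse(hb$donor_side == "receptor", hb$donor_key,
                          hb$acceptor_key))
  sb_rec <- unique(ifelse(sb$basic_side == "receptor", sb$basic_key,
                          sb$acidic_key))
  cr$forms_hbond <- cr$key %in% hb_rec
  cr$forms_salt_bridge <- cr$key %in% sb_rec
  summary_ <- contact_class_summary(imc)
  structure(list(
    pose_rank = pose$rank, ld_score = pose$score,
    dG = est$dG, Kd = est$Kd,
    imc_total = summary_$total, imc_by_pair = summary_$by_pair,
    imc_participation = summary_$participation,
    n_contact_residues = nrow(cr),
    contact_residues = cr,
    n_hbonds = nrow(hb), hbonds = hb, hbond_residues = hb_rec,
    n_salt_bridges = nrow(sb), salt_bridge_list = sb,
    salt_bridge_residues = sb_rec,
    nis = nis, affinity = est), class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(
    "<interface_report> rank %s  score %.3f  dG %.2f kcal/mol  Kd %.2e M\n",
    x$pose_rank, x$ld_score, x$dG, x$Kd))
  cat(sprintf("  IMC %d | contact residues %d | H-bonds %d | salt bridges %d\n",
              x$imc_total, x$n_contact_residues, x$n_hbonds,
              x$n_salt_bridges))
  invisible(x)
}

# one-row data frame summary of a report
.report_row <- function(rep_) {
  bp <- rep_$imc_by_pair
  data.frame(rank = rep_$pose_rank, ld_score = rep_$ld_score,
             dG = rep_$dG, Kd = rep_$Kd, imc_total = rep_$imc_total,
             imc_cc = bp[["charged-charged"]],
             imc_cp = bp[["charged-polar"]],
             imc_ca = bp[["apolar-charged"]],
             imc_pp = bp[["polar-polar"]],
             imc_pa = bp[["apolar-polar"]],
             imc_aa = bp[["apolar-apolar"]],
             n_contact_residues = rep_$n_contact_residues,
             n_hbonds = rep_$n_hbonds,
             n_salt_bridges = rep_$n_salt_bridges,
             contact_residues = paste(rep_$contact_residues$key,
                                      collapse = ","),
             stringsAsFactors = FALSE)
}

#' Run the full consensus analysis for one docking combination
#'
#' Reproduces the post-docking workflow end to end: optional pose
#' standardization into the top model's receptor frame, deep interface
#' reports for the best `n_reports` poses, contact frequencies over the
#' configured number of models, the top-k list, Venn regions of the
#' top-pose contact sets, spatial groups of the threshold consensus, a
#' frequency-annotated receptor copy, and correlations of predicted dG
#' with contact counts and docking score. A manifest logs every parameter.
#'
#' @param ensemble a `docking_ensemble`.
#' @param out_dir optional output directory; when given, writes
#'   `interface_reports.tsv`, `frequencies.tsv`, `top<k>.tsv`,
#'   `venn.json`, `groups.tsv`, `frequency_map.pdb` and `manifest.json`.
#' @param consensus a [consensus_config()].
#' @param contacts a [contact_config()].
#' @param affinity an [affinity_config()].
#' @param n_reports poses given the deep per-pose report (default 5).
#' @param standardize superpose every pose's receptor onto the top pose
#'   (default `TRUE`).
#' @param linkage_cutoff spatial grouping cutoff in Angstrom (default 15).
#' @param sasa_points forwarded to [report_pose()].
#' @return list of class `combination_bundle` with `label`, `reports`,
#'   `report_table`, `frequency_table`, `top`, `venn`, `consensus`,
#'   `groups`, `annotated`, `correlations`, `manifest`.
#' @export
run_combination <- function(ensemble, out_dir = NULL,
                            consensus = consensus_config(),
                            contacts = contact_config(),
                            affinity = affinity_config(),
                            n_reports = 5, standardize = TRUE,
                            linkage_cutoff = 15, sasa_points = 960) {
  stopifnot(inherits(ensemble, "docking_ensemble"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", what, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (standardize)
    ensemble <- stage("standardize", standardize_ensemble(ensemble))
  n_reports <- min(n_reports, length(ensemble$poses))
  reports <- stage("interface-reports",
    lapply(ensemble$poses[seq_len(n_reports)], report_pose,
           receptor_chain = ensemble$receptor_chain,
           ligand_chains = ensemble$ligand_chains,
           contacts = contacts, affinity = affinity,
           sasa_points = sasa_points))
  report_table <- do.call(rbind, lapply(reports, .report_row))
  freq <- stage("frequencies", contact_frequencies(ensemble, consensus))
  top <- stage("top-residues", top_residues(freq, consensus$top_k))
  venn <- stage("venn", {
    # Venn overlap is drawn for at most the top five models
    n_venn <- min(5, length(reports))
    sets <- lapply(reports[seq_len(n_venn)], function(r)
      r$contact_residues$key)
    names(sets) <- paste0("model", vapply(reports[seq_len(n_venn)],
                                          function(r) r$pose_rank,
                                          numeric(1)))
    if (length(sets) >= 2) venn_regions(sets) else NULL
  })
  consensus_set <- stage("threshold-consensus",
    threshold_consensus(list(freq), consensus$min_frequency))
  receptor_ref <- keep_chains(ensemble$poses[[1]]$structure,
                              ensemble$receptor_chain)
  groups <- stage("spatial-groups",
    if (nrow(consensus_set)) {
      spatial_groups(consensus_set, receptor_ref, linkage_cutoff)
    } else list())
  annotated <- stage("annotate", annotate_frequencies(receptor_ref, freq))
  correlations <- stage("correlations", {
    if (nrow(report_table) >= 3) {
      pairs <- list(
        c("dG", "imc_total"),
        c("dG", "n_contact_residues"),
        c("dG", "ld_score"))
      do.call(rbind, lapply(pairs, function(p) {
        ct <- suppressWarnings(correlate(report_table[[p[1]]],
                                         report_table[[p[2]]]))
        data.frame(x = p[1], y = p[2], r = ct$r, r2 = ct$r2,
                   n = nrow(report_table), stringsAsFactors = FALSE)
      }))
    } else NULL
  })
  manifest <- list(
    label = ensemble$label,
    n_poses = length(ensemble$poses),
    receptor_chain = ensemble$receptor_chain,
    ligand_chains = ensemble$ligand_chains,
    residue_cutoff = contacts$residue_cutoff,
    imc_cutoff = contacts$imc_cutoff,
    heavy_only = contacts$heavy_only,
    n_models = consensus$n_models,
    n_models_used = freq$n_models,
    top_k = consensus$top_k,
    min_frequency = consensus$min_frequency,
    n_reports = n_reports,
    standardize = standardize,
    linkage_cutoff = linkage_cutoff,
    sasa_points = sasa_points,
    affinity_intercept = affinity$intercept,
    affinity_temperature = affinity$temperature,
    affinity_coefficients = as.list(affinity$coefficients))
  bundle <- structure(list(label = ensemble$label, reports = reports,
                           report_table = report_table,
                           frequency_table = freq, top = top, venn = venn,
                           consensus = consensus_set, groups = groups,
                           annotated = annotated,
                           correlations = correlations,
                           manifest = manifest),
                      class = "combination_bundle")
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
  bundle
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tsv(bundle$report_table, "interface_reports.tsv")
  tsv(bundle$frequency_table$counts, "frequencies.tsv")
  tsv(bundle$top, sprintf("top%d.tsv", nrow(bundle$top)))
  if (!is.null(bundle$venn))
    jsonlite::write_json(
      list(set_names = bundle$venn$set_names,
           regions = bundle$venn$regions,
           k_of_n = as.list(bundle$venn$k_of_n)),
      file.path(out_dir, "venn.json"), auto_unbox = TRUE, pretty = TRUE)
  if (length(bundle$groups)) {
    gdf <- do.call(rbind, lapply(bundle$groups, function(g)
      cbind(group = g$label, g$members[, c("key", "chain", "resno",
                                           "resid")])))
    tsv(gdf, "groups.tsv")
  }
  if (!is.null(bundle$correlations))
    tsv(bundle$correlations, "correlations.tsv")
  write_pdb(bundle$annotated, file.path(out_dir, "frequency_map.pdb"))
  jsonlite::write_json(bundle$manifest, file.path(out_dir,
                                                  "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Compare analysis bundles across docking combinations
#'
#' Cross-combination synthesis: the shared top-k residue matrix, pooled
#' correlations over all per-pose reports, and per-group threshold
#' consensus unions (e.g. one union per antibody) with their spatial
#' groups on a reference structure.
#'
#' @param bundles named list of `combination_bundle` objects (names are
#'   combination labels).
#' @param k top-list size for the overlap matrix (default 20).
#' @param min_frequency threshold for the consensus unions (default 20).
#' @param union_groups optional named list mapping a group name (e.g. an
#'   antibody clone) to the bundle names pooled into its consensus union.
#' @param reference optional `epi_structure` for spatial grouping of each
#'   union.
#' @param linkage_cutoff grouping cutoff (default 15).
#' @return list with `overlap_matrix`, `pooled_correlations`,
#'   `consensus_unions` and `union_spatial_groups`.
#' @export
compare_combinations <- function(bundles, k = 20, min_frequency = 20,
                                 union_groups = NULL, reference = NULL,
                                 linkage_cutoff = 15) {
  if (length(bundles) < 2) stop("need at least 2 bundles")
  if (is.null(names(bundles)) || any(!nzchar(names(bundles))))
    names(bundles) <- vapply(bundles, function(b) b$label, character(1))
  tables <- lapply(bundles, function(b) b$frequency_table)
  overlap <- shared_top_matrix(tables, k)
  pooled <- do.call(rbind, lapply(names(bundles), function(nm)
    cbind(combination = nm, bundles[[nm]]$report_table,
          stringsAsFactors = FALSE)))
  pooled_correlations <- if (nrow(pooled) >= 3) {
    pairs <- list(c("dG", "imc_total"), c("dG", "n_contact_residues"),
                  c("dG", "ld_score"))
    do.call(rbind, lapply(pairs, function(p) {
      ct <- suppressWarnings(correlate(pooled[[p[1]]], pooled[[p[2]]]))
      data.frame(x = p[1], y = p[2], r = ct$r, r2 = ct$r2,
                 n = nrow(pooled), stringsAsFactors = FALSE)
    }))
  } else NULL
  if (is.null(union_groups))
    union_groups <- setNames(as.list(names(bundles)), names(bundles))
  consensus_unions <- lapply(union_groups, function(members) {
    threshold_consensus(lapply(bundles[members], function(b)
      b$frequency_table), min_frequency)
  })
  union_spatial_groups <- if (!is.null(reference)) {
    lapply(consensus_unions, function(u)
      if (nrow(u)) spatial_groups(u, reference, linkage_cutoff) else
        list())
  } else NULL
  list(overlap_matrix = overlap,
       pooled_correlations = pooled_correlations,
       consensus_unions = consensus_unions,
       union_spatial_groups = union_spatial_groups,
       pooled_reports = pooled)
}
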