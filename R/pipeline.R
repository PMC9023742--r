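#' Assemble a run configuration for the comparative pipeline
#'
#' A run configuration names two (or more) systems — canonically `binary`
#' and `ternary` — each backed either by a synthetic spec or by a
#' multi-model PDB plus parameter sidecar, together with the analysis
#' toggles and parameters.  `run_config()` validates and fills defaults;
#' [read_run_config()] loads the same structure from a YAML file.
#'
#' @param systems Named list; each element has either `synthetic` (a list of
#'   [synthetic_spec()] arguments) or `pdb` (+ optional `sidecar`) paths.
#' @param seed Global integer seed, fanned out deterministically to stages.
#' @param analyses Named logical toggles: `rmsd`, `rmsf`, `pca`,
#'   `distances`, `interface`, `energetics`, `network` (all default `TRUE`).
#' @param distance_pairs List of residue-index pairs for distance
#'   distributions (default: none).
#' @param cluster_k Number of PC-plane clusters, default 2.
#' @param energy List: `receptor`, `ligand` segment ids, `n_frames` (evenly
#'   spaced frames used for the energy averages, default 10), and any
#'   [energy_params()] argument (`eps_in`, `eps_out`, `gamma`, `b`,
#'   `probe_radius`, `n_sphere_points`).
#' @param network List: `contact_cutoff` (4.5), `occupancy_min` (0.75),
#'   `tolerance` (20), optional `pairs` of source/sink node pairs.
#' @param interface List: `segA`, `segB` segment ids.
#' @param regions Optional named list of region definitions, each a list with
#'   `segid` and/or `resid` (residue index vector or `c(lo, hi)` range is the
#'   caller's concern); per-region RMSD series are reported over each.
#' @return A list of class `run_config`.
#' @export
run_config <- function(systems, seed = 1,
                       analyses = list(), distance_pairs = NULL,
                       cluster_k = 2, energy = list(), network = list(),
                       interface = list(), regions = NULL) {
  if (is.null(names(systems)) || any(!nzchar(names(systems))))
    abort("systems must be a named list")
  an <- utils::modifyList(list(rmsd = TRUE, rmsf = TRUE, pca = TRUE,
                               distances = TRUE, interface = TRUE,
                               energetics = TRUE, network = TRUE), analyses)
  en <- utils::modifyList(list(receptor = "SOS", ligand = "RASC",
                               n_frames = 10), energy)
  nw <- utils::modifyList(list(contact_cutoff = 4.5, occupancy_min = 0.75,
                               tolerance = 20, pairs = NULL), network)
  ifc <- utils::modifyList(list(segA = "RASC", segB = "SOS"), interface)
  if (!is.null(regions) && (is.null(names(regions)) || any(!nzchar(names(regions)))))
    abort("regions must be a named list")
  structure(list(systems = systems, seed = as.integer(seed), analyses = an,
                 distance_pairs = distance_pairs, cluster_k = cluster_k,
                 energy = en, network = nw, interface = ifc, regions = regions),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(systems = y$systems, seed = y$seed %||% 1,
             analyses = y$analyses %||% list(),
             distance_pairs = y$distance_pairs,
             cluster_k = y$cluster_k %||% 2,
             energy = y$energy %||% list(), network = y$network %||% list(),
             interface = y$interface %||% list(), regions = y$regions)
}

# deterministic per-stage seed derivation from the global seed
stage_seed <- function(seed, system_index, stage_index) {
  (seed * 1009L + system_index * 101L + stage_index) %% 2147483647L
}

load_system <- function(sys_cfg, seed) {
  if (!is.null(sys_cfg$synthetic)) {
    args <- sys_cfg$synthetic
    if (is.null(args$seed)) args$seed <- seed
    if (!is.null(args$plant_path) && !is.null(names(args$plant_path)))
      args$plant_path <- list(source = args$plant_path$source,
                              sink = args$plant_path$sink)
    spec <- do.call(synthetic_spec, args)
    synthetic_system(spec)
  } else if (!is.null(sys_cfg$pdb)) {
    ens <- read_multimodel_pdb(sys_cfg$pdb, sys_cfg$sidecar)
    list(ensemble = ens, truth = NULL, spec = NULL)
  } else abort("system needs either a 'synthetic' spec or a 'pdb' path")
}

#' Run the full comparative analysis pipeline
#'
#' Executes superposition, RMSD/RMSF, PCA and clustering, residue-pair
#' distances, interface occupancy, binding energetics, and the
#' DCCM/community/pathway network analysis for every configured system, and
#' writes per-system CSVs plus a comparative summary into `output_dir`.
#' Every output carries a header comment with the configuration hash and
#' seed; reruns with the same configuration are byte-identical.  A stage
#' failure aborts with the stage name and cause, leaving earlier outputs in
#' place beside a `FAILED` marker file.
#'
#' @param config A [run_config()] (or path of a YAML file).
#' @param output_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with per-system results and the comparative
#'   summary data.frame.
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(config))
  header <- sprintf("# allosnet pipeline config=%s seed=%d", hash, config$seed)
  say <- function(fmt, ...) if (!quiet) message(sprintf(paste0("[%s] ", fmt),
                                                        format(Sys.time(), "%H:%M:%S"), ...))
  emit <- function(df, name) {
    path <- file.path(output_dir, name)
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(header, sprintf("stage=%s", name), conditionMessage(e)),
                 file.path(output_dir, "FAILED"))
      abort("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  results <- list()
  comp_rows <- NULL
  an <- config$analyses
  for (si in seq_along(config$systems)) {
    sname <- names(config$systems)[si]
    say("system %s: loading", sname)
    sys <- stage(paste0(sname, "/load"),
                 load_system(config$systems[[si]],
                             stage_seed(config$seed, si, 0L)))
    ens <- sys$ensemble
    res <- list(system = sys)
    row <- list(system = sname)

    # synthetic systems: save the planted ground truth for downstream checks
    if (!is.null(sys$truth)) stage(paste0(sname, "/truth"), {
      a <- ens$topology$atoms
      emit(data.frame(resid = a$resid, segid = a$segid,
                      community = sys$truth$partition),
           sprintf("%s_truth_partition.csv", sname))
      if (!is.null(sys$truth$path))
        emit(data.frame(step = seq_along(sys$truth$path),
                        resid = sys$truth$path),
             sprintf("%s_truth_path.csv", sname))
    })

    if (isTRUE(an$rmsd)) stage(paste0(sname, "/rmsd"), {
      say("system %s: RMSD", sname)
      rs <- rmsd_series(ens)
      emit(rs, sprintf("%s_rmsd.csv", sname))
      res$rmsd <- rs
      row$rmsd_mean <- attr(rs, "mean")
      if (!is.null(config$regions)) {
        reg <- do.call(rbind, lapply(names(config$regions), function(rn) {
          rdef <- config$regions[[rn]]
          mask <- select_atoms(ens$topology, segid = rdef$segid,
                               resid = rdef$resid)
          rr <- rmsd_series(ens, report_mask = mask)
          data.frame(region = rn, frame = rr$frame, rmsd = rr$rmsd)
        }))
        emit(reg, sprintf("%s_rmsd_regions.csv", sname))
        res$rmsd_regions <- reg
      }
    })
    if (isTRUE(an$rmsf)) stage(paste0(sname, "/rmsf"), {
      say("system %s: RMSF", sname)
      rf <- rmsf_per_residue(ens)
      emit(rf, sprintf("%s_rmsf.csv", sname))
      res$rmsf <- rf
      row$rmsf_mean <- mean(rf$rmsf)
    })
    if (isTRUE(an$pca)) stage(paste0(sname, "/pca"), {
      say("system %s: PCA + clustering", sname)
      pca <- compute_pca(ens)
      emit(data.frame(pc = seq_along(pca$values), eigenvalue = pca$values,
                      var_fraction = pca$var_fraction),
           sprintf("%s_pca_eigenvalues.csv", sname))
      emit(data.frame(frame = seq_len(nrow(pca$projections)),
                      PC1 = pca$projections[, 1], PC2 = pca$projections[, 2]),
           sprintf("%s_pca_projections.csv", sname))
      cl <- cluster_landscape(pca, K = config$cluster_k,
                              seed = stage_seed(config$seed, si, 3L))
      emit(data.frame(frame = seq_along(cl$labels), cluster = cl$labels),
           sprintf("%s_clusters.csv", sname))
      for (k in seq_len(cl$K))
        write_multimodel_pdb(subset_frames(ens, cl$representative[k]),
                             file.path(output_dir,
                                       sprintf("%s_cluster%d_representative.pdb", sname, k)))
      res$pca <- pca; res$clusters <- cl
      row$pc1_fraction <- pca$var_fraction[1]
    })
    if (isTRUE(an$distances) && length(config$distance_pairs)) {
      stage(paste0(sname, "/distances"), {
        say("system %s: residue-pair distances", sname)
        dd <- lapply(config$distance_pairs, function(p)
          pair_distance_distribution(ens, unlist(p)))
        tab <- do.call(rbind, lapply(dd, function(d)
          data.frame(res_i = d$pair[1], res_j = d$pair[2],
                     mean = d$mean, mode = d$mode)))
        emit(tab, sprintf("%s_distances.csv", sname))
        hist_tab <- do.call(rbind, lapply(dd, function(d) {
          mids <- (d$breaks[-1] + d$breaks[-length(d$breaks)]) / 2
          data.frame(res_i = d$pair[1], res_j = d$pair[2], bin_mid = mids,
                     prob = d$prob)
        }))
        emit(hist_tab, sprintf("%s_distance_histograms.csv", sname))
        res$distances <- dd
      })
    }
    if (isTRUE(an$interface)) stage(paste0(sname, "/interface"), {
      say("system %s: interface contacts", sname)
      rep_frame <- if (!is.null(res$clusters)) res$clusters$representative[1] else 1L
      ifc <- interface_summary(ens, config$interface$segA, config$interface$segB,
                               representative_frame = rep_frame)
      emit(ifc$records, sprintf("%s_interface.csv", sname))
      # cluster-table style: interaction count at each cluster representative
      if (!is.null(res$clusters)) {
        per_cluster <- do.call(rbind, lapply(seq_len(res$clusters$K), function(k) {
          rf <- res$clusters$representative[k]
          ik <- interface_summary(ens, config$interface$segA,
                                  config$interface$segB,
                                  representative_frame = rf)
          data.frame(cluster = k, representative_frame = rf,
                     interaction_count = ik$count_representative)
        }))
        emit(per_cluster, sprintf("%s_interface_counts.csv", sname))
      }
      res$interface <- ifc
      row$interface_pairs <- nrow(ifc$records)
      row$interface_mean_occupancy <- ifc$mean_occupancy
      row$interface_count_representative <- ifc$count_representative
    })
    if (isTRUE(an$energetics)) stage(paste0(sname, "/energetics"), {
      say("system %s: binding energetics", sname)
      nf <- nrow(ens$xyz)
      fr <- unique(round(seq(1, nf, length.out = min(config$energy$n_frames, nf))))
      pnames <- intersect(names(config$energy), names(formals(energy_params)))
      pars <- do.call(energy_params, config$energy[pnames])
      be <- binding_energy(ens, config$energy$receptor, config$energy$ligand,
                           params = pars, frames = fr)
      emit(be$summary, sprintf("%s_energy.csv", sname))
      dec <- per_residue_decomposition(ens, config$energy$receptor,
                                       config$energy$ligand, params = pars,
                                       frames = fr)
      emit(dec, sprintf("%s_energy_per_residue.csv", sname))
      res$energy <- be; res$energy_decomposition <- dec
      row$dG_binding <- be$summary$mean[be$summary$component == "dG_binding"]
    })
    if (isTRUE(an$network)) stage(paste0(sname, "/network"), {
      say("system %s: DCCM / communities / pathways", sname)
      dc <- compute_dccm(ens)
      emit(as.data.frame(unclass(dc)), sprintf("%s_dccm.csv", sname))
      g <- build_graph(ens, dc, config$network$contact_cutoff,
                       config$network$occupancy_min)
      emit(g$edges, sprintf("%s_network_edges.csv", sname))
      write_graph_file(g, file.path(output_dir, sprintf("%s_network.graphml", sname)),
                       "graphml")
      write_graph_file(g, file.path(output_dir, sprintf("%s_network.dot", sname)), "dot")
      cm <- detect_communities(g)
      emit(data.frame(node = seq_along(cm$membership), resid = g$resids,
                      segid = g$segids, community = cm$membership),
           sprintf("%s_communities.csv", sname))
      ics <- intercommunity_strength(g, cm)
      emit(as.data.frame(ics), sprintf("%s_intercommunity.csv", sname))
      res$graph <- g; res$communities <- cm
      row$n_communities <- length(cm$sizes)
      # default pathway pair: the planted source/sink of any synthetic system,
      # so systems without planted couplings are probed between the same sites
      pairs <- config$network$pairs
      if (is.null(pairs)) {
        for (other in config$systems) {
          pp <- other$synthetic$plant_path
          if (!is.null(pp)) { pairs <- list(c(pp$source, pp$sink)); break }
        }
      }
      if (!is.null(pairs)) {
        pt <- pathway_table(g, pairs, tolerance = config$network$tolerance)
        emit(pt, sprintf("%s_pathways.csv", sname))
        res$pathways <- pt
        row$optimal_length_mean <- mean(pt$length)
        row$subopt_mean <- mean(pt$subopt)
      }
    })
    results[[sname]] <- res
    comp_rows <- c(comp_rows, list(row))
  }
  if (length(comp_rows)) {
    cols <- unique(unlist(lapply(comp_rows, names)))
    summary_df <- do.call(rbind, lapply(comp_rows, function(r) {
      r[setdiff(cols, names(r))] <- NA
      as.data.frame(r[cols])
    }))
    emit(summary_df, "comparative_summary.csv")
  } else summary_df <- NULL
  say("done: outputs in %s", output_dir)
  invisible(list(systems = results, summary = summary_df,
                 config_hash = hash))
}
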