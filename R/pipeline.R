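#' Run the complete analysis pipeline and write all artifacts
#'
#' End-to-end driver: simulate (or accept) a milking-order study, wrangle it
#' to a filtered quantile matrix, run the stochasticity, embedding,
#' co-clustering, subperiod-consistency and (optionally) sensor MCE
#' analyses, and write every table as CSV, every figure as PNG, and a run
#' manifest as JSON into `outdir`. Re-running with the manifest's
#' configuration and seed reproduces the CSV outputs byte for byte.
#'
#' @param config a [sim_config()] (its `seed` drives all randomness).
#' @param outdir output directory (created if needed).
#' @param study optional pre-simulated study from [simulate_study()]; by
#'   default one is simulated from `config`.
#' @param B permutations for the stochasticity tests.
#' @param B_mce permutations for the MCE tests.
#' @param grid_r,grid_c Data Mechanics grid bounds.
#' @param sensor logical; run the sensor branch (simulation + MCE + tube
#'   table)?
#' @return (invisibly) a list with every fitted object and the manifest.
#' @export
run_pipeline <- function(config = sim_config(), outdir, study = NULL,
                         B = 1000L, B_mce = 500L, grid_r = 10L, grid_c = 10L,
                         sensor = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fig <- function(name) file.path(outdir, paste0(name, ".png"))
  csv <- function(df, name) utils::write.csv(df, file.path(outdir, paste0(name, ".csv")),
                                             row.names = FALSE)

  if (is.null(study)) study <- simulate_study(config, sensor = sensor)
  log <- study$log
  profiles <- study$profiles
  csv(log$records, "milk_log")
  csv(profiles, "cow_attributes")

  qm <- to_quantiles(log)
  qm <- filter_days(qm, warmup = 0L, drop_windows = NULL, min_coverage = 0.75)
  qm <- filter_cows(qm, min_attendance = 0.5)
  qmh <- subset_healthy(qm, profiles)
  csv(data.frame(cow_id = rownames(qm), unclass(qm), check.names = FALSE),
      "quantile_matrix")

  st <- queue_stochasticity(qmh, B = B, seed = config$seed + 10L)
  csv(st$per_segment, "stochasticity_per_segment")
  csv(st$per_cow, "stochasticity_per_cow")
  grDevices::png(fig("entropy_by_segment"), 900, 600); plot(st, "segment"); grDevices::dev.off()
  grDevices::png(fig("entropy_by_cow"), 900, 600); plot(st, "cow"); grDevices::dev.off()

  med <- apply(unclass(qmh), 1L, stats::median, na.rm = TRUE)
  pca <- pca_correlation(qmh)
  dmap <- diffusion_map(qmh)
  csv(data.frame(cow_id = rownames(qmh), pca$coordinates[, 1:3]), "pca_scores")
  csv(data.frame(cow_id = rownames(qmh), dmap$coordinates), "diffusion_coordinates")
  csv(data.frame(eigenvalue = dmap$eigenvalues), "diffusion_eigenvalues")
  grDevices::png(fig("embedding_diffusion"), 900, 600)
  plot(dmap, color_by = med); grDevices::dev.off()
  grDevices::png(fig("embedding_pca"), 900, 600)
  plot(pca, color_by = med); grDevices::dev.off()

  sp <- subperiod_consistency(qm)
  csv(sp$per_cow, "subperiod_medians")
  grDevices::png(fig("subperiod_consistency"), 700, 700); plot(sp); grDevices::dev.off()

  grid <- dm_grid(qm, r_max = grid_r, c_max = grid_c)
  csv(grid$summary, "dm_grid_summary")
  outliers <- flag_outlier_days(grid)
  writeLines(outliers, file.path(outdir, "outlier_days.txt"))
  best <- grid$fits[[min(4L, grid_r)]][[min(8L, grid_c)]]
  csv(data.frame(cow_id = names(best$row_labels), cluster = best$row_labels),
      "cocluster_rows")
  csv(data.frame(day = names(best$col_labels), cluster = best$col_labels),
      "cocluster_cols")
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    ann <- data.frame(health = ifelse(profiles$n_health_events > 0, "sick", "healthy"),
                      row.names = profiles$cow_id)
    try(plot_cocluster_heatmap(best, qm, row_annotations = ann,
                               filename = fig("cocluster_heatmap")),
        silent = TRUE)
  }

  out <- list(config = config, study = study, qm = qm, qm_healthy = qmh,
              stochasticity = st, pca = pca, diffusion = dmap,
              subperiod = sp, dm_grid = grid, outlier_days = outliers)

  if (sensor && !is.null(study$sensor)) {
    slog <- study$sensor[study$sensor$cow_id %in% rownames(qmh), ]
    subsets <- sensor_subsets(slog)
    queue_groups <- tree_discretize(unclass(qmh), k = 2L)
    mce_res <- mce_grid_select(unclass(qmh), subsets$aggregate$active,
                               ka_range = 2:4, kb_range = 2:4,
                               B = B_mce, seed = config$seed + 20L)
    csv(mce_res$grid, "mce_sensor_grid")
    tt <- tube_table(slog, queue_groups)
    csv(tt, "tube_table")
    out$sensor_mce <- mce_res
    out$tube_table <- tt
  }

  manifest <- list(package_version = as.character(utils::packageVersion("milkorder")),
                   r_version = R.version.string,
                   seed = config$seed,
                   config = unclass(config),
                   dropped_days = attr(qm, "dropped_days"),
                   outlier_days = outliers,
                   files = list.files(outdir))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}

#' Read a simulator configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys raise an
#' error.
#'
#' @param path YAML file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}
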