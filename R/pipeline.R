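#' Config-driven pipeline orchestration
#'
#' One nested configuration document drives deterministic end-to-end runs
#' over synthetic (or user-supplied) inputs, writing stage tables and one
#' machine-readable JSON report that echoes the config, the seed, and the
#' row counts at every filter step, so every reported number is
#' reproducible from the report alone.
#'
#' @name cli-pipeline
#' @keywords internal
NULL

#' Default pipeline configuration
#'
#' @param seed Global integer seed.
#' @return Nested configuration list: `sim` ([sim_config()]) plus blocks
#'   `pools`, `pairs`, `minflux`, `conformation`.
#' @export
pipeline_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    sim = sim_config(seed),
    pools = list(margin_nm = 10),
    pairs = list(k = 10L, restarts = 20L, cluster_seed = as.integer(seed),
                 axis_tolerance_deg = 30, shift_scale_nm = 60,
                 d_min = 60, d_max = 120, sector = 9:12),
    minflux = list(valid_iteration = 9L, efo_max_khz = 100,
                   min_locs = 4L, z_scale = 0.7),
    conformation = list(subset = 2:8,
                        reference_csv = system.file(
                          "extdata", "synthetic_closed_ring.csv",
                          package = "turcorg"),
                        query_csv = system.file(
                          "extdata", "synthetic_displaced_ring.csv",
                          package = "turcorg"))
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values present in the file override the defaults of
#' [pipeline_config()]; unknown keys are rejected with their field path.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param seed Seed for the defaults layer (overridden by a `seed` key in
#'   the file).
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path, seed = 1) {
  user <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(user$seed)) seed <- as.integer(user$seed)
  cfg <- .merge_config(pipeline_config(seed), user, "config")
  validate_pipeline_config(cfg)
}

.merge_config <- function(base, user, path) {
  for (nm in names(user)) {
    if (!nm %in% names(base)) {
      stop("config error: unknown key '", path, "$", nm, "'")
    }
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]],
                                  paste0(path, "$", nm))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate a pipeline configuration
#' @param config Configuration list.
#' @return The config, invisibly, or an error naming the offending block.
#' @export
validate_pipeline_config <- function(config) {
  ref <- pipeline_config(config$seed)
  .check_keys <- function(base, user, path) {
    extra <- setdiff(names(user), names(base))
    if (length(extra)) stop("config error: unknown key '", path, "$",
                            extra[1], "'")
    for (nm in names(user)) {
      if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
        .check_keys(base[[nm]], user[[nm]], paste0(path, "$", nm))
      }
    }
  }
  .check_keys(ref, config, "config")
  if (config$pairs$d_min > config$pairs$d_max) {
    stop("config error in distance-cutoff block: d_min > d_max")
  }
  if (config$sim$lumenal$background_fraction < 0 ||
      config$sim$lumenal$background_fraction > 1) {
    stop("config error: background_fraction must lie in [0, 1]")
  }
  invisible(config)
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (centriole, particle pools, MINFLUX table),
#' `spatial` (pool classification, signed B-tubule distances,
#' nearest-neighbor statistics), `pairs` (pair features, distance filter,
#' 7D k-means, wall-facing angles), `minflux` (filter, aggregate,
#' precision, per-structure axes, pooled radial summary), `conformation`
#' (deviation profile of the bundled synthetic rings), or `all`. Output is
#' deterministic given the config: re-running writes byte-identical files.
#'
#' @param config Configuration from [pipeline_config()] /
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stage Stage name or `"all"`.
#' @return The report list, invisibly; on disk: `report.json`, stage CSV
#'   and TSV tables, and a CMM marker file for MINFLUX trace centers.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, stage = "all") {
  stage <- match.arg(stage, c("all", "simulate", "spatial", "pairs",
                              "minflux", "conformation"))
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config, stages = list())
  sum_list <- function(s) list(n = s$n, median = s$median,
                               interval_90 = s$interval_90,
                               interval_95 = s$interval_95)

  needs_particles <- stage %in% c("all", "simulate", "spatial", "pairs")
  if (needs_particles) {
    model <- simulate_centriole(config$sim)
    lum <- simulate_lumenal_turcs(model, config$sim)
    pcm <- simulate_pericentriolar_turcs(model, config$sim)
    particles <- validate_particle_table(rbind(as.data.frame(lum),
                                               as.data.frame(pcm)))
    segments <- centriole_mtt_segments(model)
  }
  if (stage %in% c("all", "simulate")) {
    write_particle_table(particles, file.path(out_dir, "particles.tsv"))
    report$stages$simulate <- list(
      n_lumenal = nrow(lum), n_pericentriolar = nrow(pcm),
      n_mtt_segments = nrow(segments))
  }
  if (stage %in% c("all", "simulate", "minflux")) {
    locs <- simulate_minflux(config$sim)
    if (stage %in% c("all", "simulate")) {
      write_localization_table(locs, file.path(out_dir, "localizations.tsv"))
      report$stages$simulate$n_localizations <- nrow(locs)
    }
  }

  if (stage %in% c("all", "spatial")) {
    labeled <- classify_pools(particles, model, config$pools$margin_nm)
    sd_res <- signed_mtt_distances(labeled, model)
    utils::write.csv(sd_res, file.path(out_dir, "signed_distances.csv"),
                     row.names = FALSE, quote = FALSE)
    nn <- nearest_neighbor_distances(labeled, within_pool = TRUE)
    utils::write.csv(nn, file.path(out_dir, "nearest_neighbors.csv"),
                     row.names = FALSE, quote = FALSE)
    smry <- attr(sd_res, "summary")
    nn_lum <- nn$nn_nm[nn$pool == "lumenal"]
    nn_pcm <- nn$nn_nm[nn$pool == "pericentriolar"]
    report$stages$spatial <- list(
      n_lumenal = sum(labeled$pool == "lumenal"),
      n_pericentriolar = sum(labeled$pool == "pericentriolar"),
      signed_distance = lapply(smry, sum_list),
      nearest_neighbor = list(
        lumenal = sum_list(summarize_distribution(nn_lum)),
        pericentriolar = sum_list(summarize_distribution(nn_pcm))))
    particles <- labeled
  }

  if (stage %in% c("all", "pairs")) {
    if (all(particles$pool == "unassigned")) {
      particles <- classify_pools(particles, model, config$pools$margin_nm)
    }
    lum_only <- particles[particles$pool == "lumenal", , drop = FALSE]
    pairs0 <- pair_particles_to_mtts(
      particles, segments,
      axis_tolerance_deg = config$pairs$axis_tolerance_deg,
      shift_scale_nm = config$pairs$shift_scale_nm)
    pairs1 <- filter_pairs_by_distance(pairs0, config$pairs$d_min,
                                       config$pairs$d_max)
    cl <- cluster_pair_configurations(pairs1, k = config$pairs$k,
                                      seed = config$pairs$cluster_seed,
                                      restarts = config$pairs$restarts)
    main_members <- pairs1[cl$assignments == cl$main_cluster, , drop = FALSE]
    wf <- wall_facing_angle(main_members, sector = config$pairs$sector)
    utils::write.csv(cbind(pairs1, cluster = cl$assignments),
                     file.path(out_dir, "pair_clusters.csv"),
                     row.names = FALSE, quote = FALSE)
    report$stages$pairs <- list(
      counts = attr(pairs0, "counts"),
      n_after_distance_filter = nrow(pairs1),
      k = cl$k, sizes = cl$sizes, main_cluster = cl$main_cluster,
      main_fraction_all = cl$main_fraction_all,
      main_fraction_lumenal = cl$main_fraction_lumenal,
      mean_shift_nm = unname(cl$mean_shift_nm),
      mean_q_rel = cl$mean_q_rel,
      angular_spread_deg = cl$angular_spread_deg,
      wall_facing_median_deg = percentile_median_unbiased(wf, 0.5))
  }

  if (stage %in% c("all", "minflux")) {
    mf <- minflux_pipeline(locs,
                           valid_iteration = config$minflux$valid_iteration,
                           efo_max_khz = config$minflux$efo_max_khz,
                           min_locs = config$minflux$min_locs,
                           z_scale = config$minflux$z_scale)
    utils::write.csv(mf$centers, file.path(out_dir, "trace_centers.csv"),
                     row.names = FALSE, quote = FALSE)
    write_marker_cmm(as.matrix(mf$centers[, c("x_nm", "y_nm", "z_nm")]),
                     radius = 6, file.path(out_dir, "trace_centers.cmm"))
    report$stages$minflux <- list(
      counts = attr(mf$filtered, "counts"),
      sigma_x_nm = mf$precision$sigma_x_nm,
      sigma_y_nm = mf$precision$sigma_y_nm,
      sigma_z_nm = mf$precision$sigma_z_nm,
      sigma_xy_nm = mf$precision$sigma_xy_nm,
      radial_pooled = sum_list(mf$radial_pooled))
  }

  if (stage %in% c("all", "conformation")) {
    ref <- read_ring_centers(config$conformation$reference_csv,
                             model_id = "synthetic_closed_reference")
    qry <- read_ring_centers(config$conformation$query_csv,
                             model_id = "synthetic_displaced_query")
    prof <- ring_deviation_profile(qry, ref,
                                   subset = config$conformation$subset)
    utils::write.csv(prof, file.path(out_dir, "deviation_profile.csv"),
                     row.names = FALSE, quote = FALSE)
    report$stages$conformation <- list(
      subset = config$conformation$subset,
      rmsd_A = attr(prof, "rmsd_A"),
      deviations = stats::setNames(as.list(prof$deviation_A),
                                   paste0("spoke_", prof$spoke)))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
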