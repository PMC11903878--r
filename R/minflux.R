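#' MINFLUX localization post-processing
#'
#' Filtering (valid iteration, axial rescaling, EFO cut, minimum trace
#' length), trace aggregation to emitter centers, per-structure precision
#' summaries, cylinder-axis fitting and radial profiling.
#'
#' @name minflux-axis
#' @keywords internal
NULL

#' Filter a MINFLUX localization table
#'
#' Applied in fixed order: (1) keep rows whose `iteration` equals
#' `valid_iteration`; (2) multiply z by `z_scale` (the 0.7 axial
#' correction); (3) drop rows with `efo_khz >= efo_max_khz` (strict `<`
#' keeps); (4) drop entire traces whose surviving localization count is
#' below `min_locs`. Row order is preserved and the filter is idempotent.
#'
#' @param table A `localization_table`.
#' @param valid_iteration Acquisition iteration treated as valid (9).
#' @param efo_max_khz Upper EFO bound in kHz (100, exclusive).
#' @param min_locs Minimum surviving localizations per trace (4).
#' @param z_scale Axial rescaling factor (0.7). Tables already corrected by
#'   a previous [filter_localizations()] call carry a `z_corrected`
#'   attribute and are not rescaled again, making the filter idempotent.
#' @return Filtered `localization_table`; attribute `counts` records rows
#'   and traces in/out at each step; attribute `z_corrected` is set.
#' @export
filter_localizations <- function(table, valid_iteration = 9,
                                 efo_max_khz = 100, min_locs = 4,
                                 z_scale = 0.7) {
  corrected <- isTRUE(attr(table, "z_corrected"))
  table <- validate_localization_table(as.data.frame(table))
  n0 <- nrow(table)
  t1 <- table[table$iteration == valid_iteration, , drop = FALSE]
  if (!corrected) t1$z_nm <- t1$z_nm * z_scale
  n_iter <- nrow(t1)
  t2 <- t1[t1$efo_khz < efo_max_khz, , drop = FALSE]
  n_efo <- nrow(t2)
  key <- paste(t2$structure_id, t2$trace_id)
  cnt <- table(key)
  keep_tr <- names(cnt)[cnt >= min_locs]
  t3 <- t2[key %in% keep_tr, , drop = FALSE]
  rownames(t3) <- NULL
  attr(t3, "counts") <- list(
    rows_in = n0, rows_after_iteration = n_iter, rows_after_efo = n_efo,
    rows_out = nrow(t3),
    traces_in = length(unique(paste(table$structure_id, table$trace_id))),
    traces_out = length(unique(paste(t3$structure_id, t3$trace_id))))
  attr(t3, "z_corrected") <- TRUE
  validate_localization_table(t3)
}

#' Aggregate traces to emitter centers
#'
#' One center per trace: the arithmetic mean of its localization
#' coordinates, with per-axis sample standard deviations (n - 1
#' denominator) as the per-trace localization-precision estimate.
#'
#' @param table A filtered `localization_table`.
#' @return Data frame of class `trace_centers` with `structure_id`,
#'   `trace_id`, `x_nm`, `y_nm`, `z_nm`, `n_locs`, `sd_x_nm`, `sd_y_nm`,
#'   `sd_z_nm` (NA for single-localization traces).
#' @export
aggregate_traces <- function(table) {
  table <- validate_localization_table(as.data.frame(table))
  key <- paste(table$structure_id, table$trace_id, sep = "\r")
  idx <- split(seq_len(nrow(table)), factor(key, levels = unique(key)))
  rows <- lapply(idx, function(ii) {
    sub <- table[ii, , drop = FALSE]
    data.frame(structure_id = sub$structure_id[1],
               trace_id = sub$trace_id[1],
               x_nm = mean(sub$x_nm), y_nm = mean(sub$y_nm),
               z_nm = mean(sub$z_nm),
               n_locs = nrow(sub),
               sd_x_nm = stats::sd(sub$x_nm),
               sd_y_nm = stats::sd(sub$y_nm),
               sd_z_nm = stats::sd(sub$z_nm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- unique(c("trace_centers", class(out)))
  out
}

#' Localization-precision summary
#'
#' Per structure, the median (type-8) of the per-trace standard deviations
#' on each axis; across structures, the unweighted mean of those medians.
#' The single lateral value `sigma_xy` is the mean of the x and y entries.
#'
#' @param centers A `trace_centers` data frame.
#' @return List with `per_structure` (data frame of medians) and
#'   `sigma_x_nm`, `sigma_y_nm`, `sigma_z_nm`, `sigma_xy_nm`
#'   (cross-structure averages).
#' @export
precision_summary <- function(centers) {
  sids <- unique(centers$structure_id)
  per <- do.call(rbind, lapply(sids, function(s) {
    sub <- centers[centers$structure_id == s & centers$n_locs >= 2, ]
    data.frame(structure_id = s,
               med_sd_x = percentile_median_unbiased(sub$sd_x_nm, 0.5),
               med_sd_y = percentile_median_unbiased(sub$sd_y_nm, 0.5),
               med_sd_z = percentile_median_unbiased(sub$sd_z_nm, 0.5),
               stringsAsFactors = FALSE)
  }))
  sx <- mean(per$med_sd_x); sy <- mean(per$med_sd_y); sz <- mean(per$med_sd_z)
  list(per_structure = per,
       sigma_x_nm = sx, sigma_y_nm = sy, sigma_z_nm = sz,
       sigma_xy_nm = (sx + sy) / 2)
}

#' Fit the central axis of one structure
#'
#' Starts from the total-least-squares axis through the collective
#' centroid of the trace centers ([fit_axis_tls()]) and, when
#' `refine = TRUE` (default), polishes it with a cylinder fit: the axis
#' orientation and transverse offset minimizing the variance of the radial
#' distances. For centers on a cylindrical shell the refined axis is exact
#' at any finite angular sampling, whereas the scatter-based axis tilts
#' with the sampling covariance between azimuth and height.
#'
#' @param centers A `trace_centers` data frame (one structure).
#' @param breaks Radial histogram bin edges passed to
#'   [radial_axial_profile()].
#' @param refine Apply the cylinder-variance refinement.
#' @return List with `axis` (`axis3d`), `profile`
#'   (`radial_axial_profile`), and `radial_summary` (`distance_summary`
#'   of the radial distances).
#' @export
fit_structure_axis <- function(centers, breaks = seq(0, 200, by = 5),
                               refine = TRUE) {
  P <- as.matrix(centers[, c("x_nm", "y_nm", "z_nm")])
  ax <- fit_axis_tls(P)
  if (refine) ax <- .refine_cylinder_axis(P, ax)
  prof <- radial_axial_profile(P, ax, breaks = breaks)
  list(axis = ax, profile = prof,
       radial_summary = summarize_distribution(prof$coords$r))
}

# minimize var(radial distance) over axis tilt (2 dof) and transverse
# anchor offset (2 dof), Nelder-Mead from the TLS solution
.refine_cylinder_axis <- function(P, ax) {
  d0 <- ax$direction
  u <- .frame_from_z(d0)[, 1]
  v <- .frame_from_z(d0)[, 2]
  c0 <- ax$point
  obj <- function(par) {
    d <- d0 + par[1] * u + par[2] * v
    d <- d / sqrt(sum(d^2))
    a <- c0 + par[3] * u + par[4] * v
    rel <- sweep(P, 2, a)
    s <- as.numeric(rel %*% d)
    r <- sqrt(rowSums((rel - outer(s, d))^2))
    stats::var(r)
  }
  if (obj(c(0, 0, 0, 0)) < 1e-12) return(ax)  # already on-axis (e.g. a line)
  opt <- stats::optim(c(0, 0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  d <- d0 + opt$par[1] * u + opt$par[2] * v
  d <- .orient_direction(d / sqrt(sum(d^2)))
  a <- c0 + opt$par[3] * u + opt$par[4] * v
  # anchor at the projection of the collective centroid onto the axis
  a <- a + sum((c0 - a) * d) * d
  structure(list(point = a, direction = d), class = "axis3d")
}

#' Full MINFLUX pipeline over a multi-structure table
#'
#' Filters, aggregates, summarizes precision, and fits one axis per
#' structure; pools the radial distances across structures.
#'
#' @param table A `localization_table`.
#' @param ... Passed to [filter_localizations()].
#' @return List with `filtered`, `centers`, `precision`, `per_structure`
#'   (list of [fit_structure_axis()] results), and `radial_pooled`
#'   (`distance_summary` over all structures' radial distances).
#' @export
minflux_pipeline <- function(table, ...) {
  filt <- filter_localizations(table, ...)
  centers <- aggregate_traces(filt)
  prec <- precision_summary(centers)
  sids <- unique(centers$structure_id)
  fits <- lapply(sids, function(s) {
    fit_structure_axis(centers[centers$structure_id == s, , drop = FALSE])
  })
  names(fits) <- sids
  rall <- unlist(lapply(fits, function(f) f$profile$coords$r))
  list(filtered = filt, centers = centers, precision = prec,
       per_structure = fits, radial_pooled = summarize_distribution(rall))
}
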