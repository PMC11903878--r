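#' File formats
#'
#' Readers and writers for the tabular and structural formats the pipeline
#' touches: canonical TSV particle tables, STAR particle loops (ZYZ Euler
#' dialect), tabular MINFLUX exports, Chimera CMM marker XML, ring-center
#' CSV, and PDB ATOM records (via bio3d). All delimited files are UTF-8
#' with "." as decimal separator; writers use fixed 6-decimal formatting so
#' output is byte-deterministic.
#'
#' @name io-formats
#' @keywords internal
NULL

.fmt6 <- function(x) formatC(x, format = "f", digits = 6)

#' Read a particle table
#'
#' `canonical_tsv` expects columns `particle_id`, `tomo_id`, `x_nm`,
#' `y_nm`, `z_nm`, `qw`, `qx`, `qy`, `qz` and optionally `pool`. `star`
#' reads a particles data loop with `_rlnCoordinateX/Y/Z` (pixel units,
#' scaled by `pixel_size_nm`) and ZYZ intrinsic Euler angles
#' `_rlnAngleRot/Tilt/Psi` (degrees), converted to quaternions so that
#' Euler `(0, 0, 0)` maps to the identity.
#'
#' Quaternions deviating from unit norm by less than `1e-3` are normalized
#' with a warning; larger deviations are an error.
#'
#' @param path File path.
#' @param dialect `"canonical_tsv"` or `"star"`.
#' @param pixel_size_nm Scale applied to STAR coordinates (nm per pixel).
#' @return A `particle_table`.
#' @export
read_particle_table <- function(path, dialect = c("canonical_tsv", "star"),
                                pixel_size_nm = 1) {
  dialect <- match.arg(dialect)
  if (dialect == "canonical_tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(particle_id = "character",
                                           tomo_id = "character"))
    need <- c("particle_id", "tomo_id", "x_nm", "y_nm", "z_nm",
              "qw", "qx", "qy", "qz")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("format error: missing column(s) ",
                           paste(miss, collapse = ", "), " in ", path)
    if (is.null(df$pool)) df$pool <- "unassigned"
    Q <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
  } else {
    df <- read_star_particles(path)
    Q <- t(mapply(euler_zyz_to_quat, df$rot, df$tilt, df$psi))
    df <- data.frame(particle_id = df$particle_id, tomo_id = df$tomo_id,
                     x_nm = df$x * pixel_size_nm, y_nm = df$y * pixel_size_nm,
                     z_nm = df$z * pixel_size_nm,
                     qw = Q[, 1], qx = Q[, 2], qy = Q[, 3], qz = Q[, 4],
                     pool = "unassigned", stringsAsFactors = FALSE)
  }
  if (nrow(df)) {
    qn <- sqrt(rowSums(Q^2))
    dev <- abs(qn - 1)
    if (any(dev >= 1e-3)) stop("format error: non-unit quaternion (deviation ",
                               format(max(dev)), ") in ", path)
    if (any(dev > 1e-9)) {
      if (any(dev > 1e-6)) warning("normalizing near-unit quaternions in ", path)
      Qn <- Q / qn
      df[, c("qw", "qx", "qy", "qz")] <- Qn
    }
  }
  validate_particle_table(df)
}

# minimal STAR particles-loop parser: one data block, one loop_, columns
# named _rlnXxx (trailing #N ignored); no installed R package reads STAR
read_star_particles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  loop_at <- which(lines == "loop_")
  if (!length(loop_at)) stop("format error: no loop_ block in ", path)
  i <- loop_at[1] + 1L
  cols <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    cols <- c(cols, sub("^_", "", sub("\\s*#\\d+$", "", lines[i])))
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  body <- body[nzchar(body) & !startsWith(body, "#") & !startsWith(body, "data_")]
  if (!length(body)) {
    tab <- as.data.frame(matrix(character(0), 0, length(cols)))
  } else {
    tab <- utils::read.table(text = paste(body, collapse = "\n"),
                             col.names = cols, stringsAsFactors = FALSE)
  }
  names(tab) <- cols
  col_of <- function(nm) {
    hit <- which(tolower(cols) == tolower(nm))
    if (!length(hit)) stop("format error: missing column _", nm, " in ", path)
    tab[[hit[1]]]
  }
  n <- nrow(tab)
  tomo <- if (any(tolower(cols) == "rlnmicrographname")) {
    as.character(col_of("rlnMicrographName"))
  } else rep("tomo_1", n)
  pid <- if (any(tolower(cols) == "rlnimagename")) {
    as.character(col_of("rlnImageName"))
  } else as.character(seq_len(n))
  data.frame(particle_id = pid, tomo_id = tomo,
             x = as.numeric(col_of("rlnCoordinateX")),
             y = as.numeric(col_of("rlnCoordinateY")),
             z = as.numeric(col_of("rlnCoordinateZ")),
             rot = as.numeric(col_of("rlnAngleRot")),
             tilt = as.numeric(col_of("rlnAngleTilt")),
             psi = as.numeric(col_of("rlnAnglePsi")),
             stringsAsFactors = FALSE)
}

#' Write a particle table
#'
#' Deterministic column order and fixed 6-decimal formatting; round-trips
#' through [read_particle_table()]. The `star` dialect writes coordinates
#' divided by `pixel_size_nm` and ZYZ Euler angles.
#'
#' @param table A `particle_table`.
#' @param path Output path.
#' @inheritParams read_particle_table
#' @return `path`, invisibly.
#' @export
write_particle_table <- function(table, path,
                                 dialect = c("canonical_tsv", "star"),
                                 pixel_size_nm = 1) {
  dialect <- match.arg(dialect)
  table <- validate_particle_table(as.data.frame(table))
  if (dialect == "canonical_tsv") {
    out <- data.frame(particle_id = table$particle_id, tomo_id = table$tomo_id,
                      x_nm = .fmt6(table$x_nm), y_nm = .fmt6(table$y_nm),
                      z_nm = .fmt6(table$z_nm),
                      qw = .fmt6(table$qw), qx = .fmt6(table$qx),
                      qy = .fmt6(table$qy), qz = .fmt6(table$qz),
                      pool = table$pool, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
  } else {
    Q <- particle_quaternions(table)
    E <- t(apply(Q, 1, quat_to_euler_zyz))
    hdr <- c("data_particles", "", "loop_",
             "_rlnImageName #1", "_rlnMicrographName #2",
             "_rlnCoordinateX #3", "_rlnCoordinateY #4", "_rlnCoordinateZ #5",
             "_rlnAngleRot #6", "_rlnAngleTilt #7", "_rlnAnglePsi #8")
    rows <- paste(table$particle_id, table$tomo_id,
                  .fmt6(table$x_nm / pixel_size_nm),
                  .fmt6(table$y_nm / pixel_size_nm),
                  .fmt6(table$z_nm / pixel_size_nm),
                  .fmt6(E[, 1]), .fmt6(E[, 2]), .fmt6(E[, 3]))
    if (!nrow(table)) rows <- character(0)
    writeLines(c(hdr, rows), path)
  }
  invisible(path)
}

#' Read a tabular MINFLUX localization export
#'
#' Expects columns `trace_id` (alias `tid`), `iteration` (alias `itr`),
#' `x`, `y`, `z`, `efo`, and optionally `structure_id`. Coordinates are
#' multiplied by `unit_scale` (default `1e9`: meters to nm, the vendor
#' export unit). EFO is taken as kHz unless `efo_unit = "hz"`, in which
#' case it is divided by 1000.
#'
#' @param path File path (TSV or CSV; delimiter sniffed from the header).
#' @param unit_scale Multiplier taking file coordinates to nm.
#' @param efo_unit `"khz"` or `"hz"`.
#' @return A `localization_table`.
#' @export
read_localization_table <- function(path, unit_scale = 1e9,
                                    efo_unit = c("khz", "hz")) {
  efo_unit <- match.arg(efo_unit)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl(",", hdr, fixed = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  alias <- c(tid = "trace_id", itr = "iteration")
  for (a in names(alias)) {
    if (a %in% names(df) && !(alias[[a]] %in% names(df))) {
      names(df)[names(df) == a] <- alias[[a]]
    }
  }
  need <- c("trace_id", "iteration", "x", "y", "z", "efo")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("format error: missing column(s) ",
                         paste(miss, collapse = ", "), " in ", path)
  for (cc in c("x", "y", "z", "efo")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad)) stop("parse error: non-numeric ", cc, " at row ", bad[1],
                          " of ", path)
    df[[cc]] <- v
  }
  if (is.null(df$structure_id)) df$structure_id <- "structure_1"
  localization_table(
    trace_id = df$trace_id, structure_id = df$structure_id,
    iteration = df$iteration,
    position = cbind(df$x, df$y, df$z) * unit_scale,
    efo_khz = if (efo_unit == "hz") df$efo / 1000 else df$efo)
}

#' Write a localization table (canonical TSV, nm / kHz)
#' @param table A `localization_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localization_table <- function(table, path) {
  table <- validate_localization_table(as.data.frame(table))
  out <- data.frame(trace_id = table$trace_id,
                    structure_id = table$structure_id,
                    iteration = table$iteration,
                    x = .fmt6(table$x_nm), y = .fmt6(table$y_nm),
                    z = .fmt6(table$z_nm), efo = .fmt6(table$efo_khz),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write a UCSF Chimera marker (CMM) file
#'
#' One `<marker>` element per point with `id`, `x`, `y`, `z` and `radius`
#' attributes inside a `<marker_set>` document.
#'
#' @param points n x 3 matrix (n >= 1).
#' @param radius Marker display radius (same unit as points).
#' @param path Output path.
#' @param name Marker-set name attribute.
#' @return `path`, invisibly.
#' @export
write_marker_cmm <- function(points, radius, path, name = "marker set") {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("write_marker_cmm: empty point list")
  doc <- xml2::xml_new_root("marker_set", name = name)
  for (i in seq_len(nrow(points))) {
    xml2::xml_add_child(doc, "marker", id = as.character(i),
                        x = .fmt6(points[i, 1]), y = .fmt6(points[i, 2]),
                        z = .fmt6(points[i, 3]), radius = .fmt6(radius))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read gamma-tubulin ring centers
#'
#' CSV with columns `spoke`, `x`, `y`, `z` (Angstrom). Duplicate spokes or
#' spokes outside 1..14 are format errors; models with fewer than 14 spokes
#' are flagged partial.
#'
#' @param path File path.
#' @param model_id Identifier for the resulting model.
#' @return A `ring_model`.
#' @export
read_ring_centers <- function(path, model_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spoke", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("format error: missing column(s) ",
                         paste(miss, collapse = ", "), " in ", path)
  ring_model(df$spoke, cbind(df$x, df$y, df$z), model_id = model_id)
}

#' Write ring centers to CSV
#' @param ring A `ring_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ring_centers <- function(ring, path) {
  out <- data.frame(spoke = ring$spoke, x = .fmt6(ring$x),
                    y = .fmt6(ring$y), z = .fmt6(ring$z))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Centroid of a PDB atom selection
#'
#' Unweighted arithmetic mean of the coordinates of the selected ATOM
#' records (Angstrom), the reproducible reading of a "measure center"
#' operation without an element-mass table.
#'
#' @param path PDB-format file.
#' @param chain Character vector of chain identifiers (NULL = all).
#' @param resno Optional integer residue-number range (e.g. `1:120`).
#' @return Length-3 numeric centroid (Angstrom).
#' @export
pdb_group_centroid <- function(path, chain = NULL, resno = NULL) {
  pdb <- bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, type = "ATOM", chain = chain,
                            resno = resno, verbose = FALSE)
  if (length(sel$atom) == 0L) stop("selection error: no atoms matched")
  xyz <- matrix(pdb$xyz[sel$xyz], ncol = 3, byrow = TRUE)
  colMeans(xyz)
}
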