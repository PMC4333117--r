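# Configuration files, snapshots, result serialization and the fixture
# registry.

config_defaults <- function() {
  list(
    lattice = list(nrows = 100L, ncols = 100L),
    composition = list(CH = 0.378, PC = 0.465, SM = 0.157),
    energy = list(w_ho = NULL, w_lo = NULL, j = NULL, beta = 1),
    control = list(n_J = 100L, n_W = 10L),
    lifetime_ms = c(0.1, 1, 10),
    radii = c(0L, 3L, 7L, 14L),
    seeds = 1:10,
    time_mapping = list(a_nm = 0.8, D_ref_um2_s = 2.5),
    output_dir = "nanobile-out",
    scan = NULL
  )
}

# "CH.SM: -1.7" style overrides onto a symmetric matrix
apply_w_overrides <- function(m, overrides) {
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% lipid_species()))
      stop("bad interaction entry name: ", nm)
    m[parts[1], parts[2]] <- overrides[[nm]]
    m[parts[2], parts[1]] <- overrides[[nm]]
  }
  m
}

#' Load a run configuration
#'
#' Reads a YAML configuration file, validates it against the schema and
#' fills in the defaults (the calibrated energy model, physiological
#' composition, `n_J = 100`, `n_W = 10`, life-times 0.1/1/10 ms). An empty
#' file yields the all-defaults configuration. Unknown keys are rejected.
#'
#' Energy-matrix overrides use entry names, e.g.
#' `energy: {w_ho: {CH.SM: -2.0}}`; ordering overrides use
#' `j: {PC.lo.PC: 0.8}`.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return List of class `nanobile_config` with fully materialized entries:
#'   `lattice`, `composition` (a [lipid_composition()]), `model`
#'   (an [energy_model()]), `control` template, `lifetime_ms`, `radii`,
#'   `seeds`, `time_mapping`, `output_dir`, `scan`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list()
         else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, raw)

  if (cfg$lattice$nrows < 3 || cfg$lattice$ncols < 3)
    stop("lattice dimensions must be >= 3")
  comp <- lipid_composition(cfg$composition$CH, cfg$composition$PC,
                            cfg$composition$SM)
  w <- default_interaction_matrices()
  w_ho <- apply_w_overrides(w$w_ho, cfg$energy$w_ho)
  w_lo <- apply_w_overrides(w$w_lo, cfg$energy$w_lo)
  j <- default_ordering_matrix()
  for (nm in names(cfg$energy$j)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 3) stop("bad ordering entry name: ", nm)
    j[parts[1], parts[2], parts[3]] <- cfg$energy$j[[nm]]
  }
  model <- energy_model(w_ho, w_lo, j, beta = cfg$energy$beta)
  if (any(cfg$lifetime_ms <= 0)) stop("lifetime_ms must be positive")
  if (any(cfg$radii < 0)) stop("radii must be non-negative")
  control <- sim_control(n_W = cfg$control$n_W, n_J = cfg$control$n_J,
                         a_nm = cfg$time_mapping$a_nm,
                         D_ref_um2_s = cfg$time_mapping$D_ref_um2_s)
  structure(list(lattice = cfg$lattice, composition = comp, model = model,
                 control = control, lifetime_ms = cfg$lifetime_ms,
                 radii = as.integer(cfg$radii),
                 seeds = as.integer(cfg$seeds),
                 time_mapping = cfg$time_mapping,
                 output_dir = cfg$output_dir, scan = cfg$scan),
            class = "nanobile_config")
}

config_metadata <- function(config) {
  list(
    package = "nanobile",
    version = as.character(utils::packageVersion("nanobile")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    lattice = config$lattice,
    composition = as.list(unclass(config$composition)),
    control = unclass(config$control),
    lifetime_ms = config$lifetime_ms,
    radii = config$radii,
    seeds = config$seeds,
    time_mapping = config$time_mapping,
    energy = list(w_ho = config$model$w_ho, w_lo = config$model$w_lo,
                  j = as.vector(config$model$j), beta = config$model$beta)
  )
}

#' Write a lattice snapshot
#'
#' Plain-text grid: a header line with dimensions, composition and time
#' stamp, then one line per lattice row with tokens `C`/`P`/`S`
#' (species) followed by `+` (lo) or `-` (ho).
#'
#' @param lattice A `lipid_lattice`.
#' @param path Output file.
#' @param t_real_ms Optional time stamp (ms) recorded in the header.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(lattice, path, t_real_ms = NA) {
  n <- n_sites(lattice)
  cnt <- tabulate(lattice$species, 3)
  header <- sprintf(
    "# nanobile nrows=%d ncols=%d CH=%.6f PC=%.6f SM=%.6f t_ms=%s",
    lattice$nrows, lattice$ncols, cnt[1] / n, cnt[2] / n, cnt[3] / n,
    format(t_real_ms))
  tok <- paste0(c("C", "P", "S")[lattice$species],
                ifelse(lattice$state > 0, "+", "-"))
  rows <- vapply(seq_len(lattice$nrows), function(u) {
    paste(tok[((u - 1) * lattice$ncols + 1):(u * lattice$ncols)],
          collapse = " ")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a lattice snapshot
#'
#' @param path File written by [write_snapshot()].
#' @return A `lipid_lattice`.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# nanobile"))
    stop("not a nanobile snapshot: ", path)
  rows <- lines[-1]
  tok <- strsplit(paste(rows, collapse = " "), " +")[[1]]
  tok <- tok[nzchar(tok)]
  species <- match(substr(tok, 1, 1), c("C", "P", "S"))
  state <- ifelse(substr(tok, 2, 2) == "+", 1L, -1L)
  ncols <- length(strsplit(trimws(rows[1]), " +")[[1]])
  new_lattice(length(rows), ncols, species, state)
}

#' Write run results
#'
#' Serializes a [bile_table()] result (or a [composition_scan()]) together
#' with self-describing metadata into a directory: `bile_table.csv` /
#' `scan.csv`, per-run tables, and `metadata.json` (seed list, configuration
#' echo, package version). File naming is deterministic, so identical
#' configuration and seeds reproduce identical files.
#'
#' @param result A `bile_table()` list or `composition_scan` data frame.
#' @param dir Output directory (created if needed).
#' @param config Optional `nanobile_config` echoed into the metadata.
#' @return The directory, invisibly.
#' @export
write_results <- function(result, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(result, "composition_scan")) {
    write.csv(result, file.path(dir, "scan.csv"), row.names = FALSE)
  } else if (is.list(result) && !is.null(result$table)) {
    write.csv(result$table, file.path(dir, "bile_table.csv"),
              row.names = FALSE)
    runs <- do.call(rbind, result$runs)
    write.csv(runs, file.path(dir, "bile_runs.csv"), row.names = FALSE)
  } else stop("unsupported result object")
  meta <- if (is.null(config)) list(
    package = "nanobile",
    version = as.character(utils::packageVersion("nanobile")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  else config_metadata(config)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Deterministic test fixtures
#'
#' Small hand-constructed lattices used across the test-suite and examples:
#' \describe{
#'   \item{`all_lo_10x10_PC`}{100 PC sites, all lo.}
#'   \item{`all_ho_10x10_CH`}{100 CH sites, all ho.}
#'   \item{`hex_r2_island`}{11 x 12 lattice of PC with exactly the 19 sites
#'     of a radius-2 hexagon in the lo state, in an ho sea.}
#'   \item{`checkerboard_6x6`}{6 x 6 PC lattice with states alternating by
#'     column parity, so no two like-state sites are adjacent in a row.}
#'   \item{`enum_3x3`}{3 x 3 lattice with a fixed mixed species pattern
#'     (CH/PC/SM), all lo; used for exhaustive spin enumeration.}
#' }
#'
#' @param name Fixture name.
#' @return A `lipid_lattice`.
#' @export
make_fixture <- function(name) {
  switch(name,
    all_lo_10x10_PC = new_lattice(10, 10, rep(2L, 100), rep(1L, 100)),
    all_ho_10x10_CH = new_lattice(10, 10, rep(1L, 100), rep(-1L, 100)),
    hex_r2_island = {
      lat <- new_lattice(11, 12, rep(2L, 132), rep(-1L, 132))
      center <- axial_site(lat, 6L, 6L)
      lat$state[hex_patch(lat, center, 2)] <- 1L
      lat
    },
    checkerboard_6x6 = {
      lat <- new_lattice(6, 6, rep(2L, 36), rep(1L, 36))
      uv <- site_axial(lat, seq_len(36))
      lat$state <- ifelse(uv[, "v"] %% 2 == 0, 1L, -1L)
      lat
    },
    enum_3x3 = new_lattice(3, 3, c(1L, 2L, 3L, 2L, 1L, 3L, 3L, 2L, 1L),
                           rep(1L, 9)),
    stop("unknown fixture: ", name)
  )
}
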