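# configuration schema: known keys per block; unknown keys are rejected

CONFIG_SCHEMA <- list(
  top = c("seed", "model", "cell_types", "pathways", "expression", "output"),
  model = c("initial_num", "hours", "density", "boundary",
            "boundary_radius", "epsilon_rep", "epsilon_adh",
            "adhesion_range", "mc_steps_per_hour", "max_migration",
            "mitosis_duration", "phase_thresholds", "record_every",
            "radius_factor", "density_grid"),
  cell_type = c("name", "size", "cycle_mean", "cycle_sd", "proportion"),
  pathway = c("name", "genes", "n_genes", "gene_set_file", "gene_set_name",
              "rule", "rule_params", "calibration"),
  calibration = c("method", "lambda", "stddev", "reference_file"),
  expression = c("sample_freq", "n_cells", "rnaseq", "single_cell",
                 "microarray_sd", "library_size", "nb_dispersion",
                 "dropout_midpoint", "dropout_shape", "sc_library_mean",
                 "sc_library_sd", "combine"),
  output = c("dir", "formats")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0) {
    stop("unknown config key(s) at ", where, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Load and validate a run configuration
#'
#' Reads a JSON run configuration, validates it against the package schema
#' (unknown keys are rejected, value errors name the offending key path)
#' and fills in all defaults, returning the effective configuration.
#'
#' @param path Path to a JSON configuration file.
#' @return A validated `run_config` list with blocks `model`,
#'   `cell_types`, `pathways`, `expression`, `output` and `seed`.
#' @seealso [write_config()] for the round-trip writer; the package README
#'   documents the schema.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  validate_config(raw)
}

#' @rdname load_config
#' @param config A raw configuration list (as parsed from JSON).
#' @export
validate_config <- function(config) {
  check_keys(config, CONFIG_SCHEMA$top, "top level")
  if (is.null(config$model)) stop("config is missing the 'model' block")
  check_keys(config$model, CONFIG_SCHEMA$model, "model")

  types_raw <- config$cell_types %||%
    list(list(name = "default", cycle_mean = 24, cycle_sd = 4,
              proportion = 1))
  types <- lapply(seq_along(types_raw), function(i) {
    tr <- types_raw[[i]]
    check_keys(tr, CONFIG_SCHEMA$cell_type, paste0("cell_types[", i, "]"))
    cell_type(tr$name %||% paste0("type", i), tr$size %||% 1,
              tr$cycle_mean %||% 24, tr$cycle_sd %||% 4,
              tr$proportion %||% 1)
  })
  types <- check_cell_types(types)

  m <- config$model
  params <- tryCatch(
    model_params(
      initial_num = m$initial_num %||% stop("model.initial_num is required"),
      hours = m$hours %||% stop("model.hours is required"),
      density = m$density %||% stop("model.density is required"),
      boundary = m$boundary %||% "unbounded",
      boundary_radius = m$boundary_radius,
      epsilon_rep = m$epsilon_rep %||% 10,
      epsilon_adh = m$epsilon_adh %||% 0.1,
      adhesion_range = m$adhesion_range %||% 0.3,
      mc_steps_per_hour = m$mc_steps_per_hour %||% 10,
      max_migration = m$max_migration %||% 0.25,
      mitosis_duration = m$mitosis_duration %||% 1,
      phase_thresholds = unlist(m$phase_thresholds) %||% c(1.3, 1.7, 2),
      record_every = m$record_every %||% 1,
      radius_factor = m$radius_factor %||% 3,
      density_grid = unlist(m$density_grid) %||% c(16L, 64L),
      seed = config$seed),
    error = function(e) stop("invalid 'model' block: ", conditionMessage(e),
                             call. = FALSE))

  pathways_cfg <- lapply(seq_along(config$pathways %||% list()),
                         function(i) {
    p <- config$pathways[[i]]
    check_keys(p, CONFIG_SCHEMA$pathway, paste0("pathways[", i, "]"))
    if (!is.null(p$calibration)) {
      check_keys(p$calibration, CONFIG_SCHEMA$calibration,
                 paste0("pathways[", i, "].calibration"))
    }
    rule_name <- if (is.list(p$rule)) p$rule$name else p$rule
    if (is.null(rule_name)) {
      stop("pathways[", i, "] needs a rule", call. = FALSE)
    }
    p
  })

  e <- config$expression %||% list()
  check_keys(e, CONFIG_SCHEMA$expression, "expression")
  expr_params <- gene_expression_params(
    sample_freq = e$sample_freq %||% 4,
    n_cells = e$n_cells %||% 50,
    rnaseq = e$rnaseq %||% FALSE,
    single_cell = e$single_cell %||% FALSE,
    microarray_sd = e$microarray_sd %||% 0.25,
    library_size = e$library_size %||% 1e6,
    nb_dispersion = e$nb_dispersion %||% 0.1,
    dropout_midpoint = e$dropout_midpoint,
    dropout_shape = e$dropout_shape %||% 1,
    sc_library_mean = e$sc_library_mean %||% 1e4,
    sc_library_sd = e$sc_library_sd %||% 0.2,
    combine = e$combine %||% "mean",
    seed = config$seed)

  out <- config$output %||% list()
  check_keys(out, CONFIG_SCHEMA$output, "output")

  structure(list(seed = config$seed, model = params, cell_types = types,
                 pathways = pathways_cfg, expression = expr_params,
                 output = list(dir = out$dir %||% ".")),
            class = "run_config")
}

# build pathway objects from their config description
build_pathways <- function(config) {
  lapply(seq_along(config$pathways), function(i) {
    p <- config$pathways[[i]]
    rule <- p$rule
    rule_name <- if (is.list(rule)) rule$name else rule
    rp <- if (is.list(rule)) rule[setdiff(names(rule), "name")] else list()
    name <- p$name %||% paste0("pathway", i)
    genes <- if (!is.null(p$genes)) {
      as.character(unlist(p$genes))
    } else if (!is.null(p$gene_set_file)) {
      sets <- read_gmt(p$gene_set_file)
      sets[[p$gene_set_name %||% name]] %||%
        stop("gene set '", p$gene_set_name %||% name, "' not found in ",
             p$gene_set_file)
    } else {
      placeholder_genes(name, p$n_genes %||% 50)
    }
    pw <- switch(rule_name,
      phase_transition = pathway_phase_transition(
        name, genes, rp$phase %||% "S", rp$window %||% 1),
      contact_inhibition = pathway_contact_inhibition(name, genes),
      growth_rate = pathway_growth_rate(name, genes),
      cell_type = pathway_cell_type(
        name, genes,
        rp$type_name %||% stop("cell_type rule needs type_name")),
      stop("unknown pathway rule: ", rule_name))
    cal <- p$calibration %||% list(method = "distribution")
    if ((cal$method %||% "distribution") == "reference") {
      ref <- as.matrix(read.table(cal$reference_file, header = TRUE,
                                  row.names = 1, sep = "\t",
                                  check.names = FALSE))
      calibrate_from_reference(pw, ref)
    } else {
      calibrate_from_distribution(pw, cal$lambda %||% 20,
                                  cal$stddev %||% 2,
                                  seed = derive_seed(config$seed,
                                                     "calibration") %||%
                                    NULL)
    }
  })
}

# serializable form of the effective configuration
config_to_list <- function(config) {
  p <- config$model
  list(
    seed = config$seed,
    model = list(initial_num = p$initial_num, hours = p$hours,
                 density = p$density, boundary = p$boundary,
                 boundary_radius = p$boundary_radius,
                 epsilon_rep = p$epsilon_rep, epsilon_adh = p$epsilon_adh,
                 adhesion_range = p$adhesion_range,
                 mc_steps_per_hour = p$mc_steps_per_hour,
                 max_migration = p$max_migration,
                 mitosis_duration = p$mitosis_duration,
                 phase_thresholds = p$phase_thresholds,
                 record_every = p$record_every,
                 radius_factor = p$radius_factor,
                 density_grid = p$density_grid),
    cell_types = lapply(config$cell_types, function(ty)
      list(name = ty$name, size = ty$size, cycle_mean = ty$cycle_mean,
           cycle_sd = ty$cycle_sd, proportion = ty$proportion)),
    pathways = config$pathways,
    expression = {
      e <- config$expression
      list(sample_freq = e$sample_freq, n_cells = e$n_cells,
           rnaseq = e$rnaseq, single_cell = e$single_cell,
           microarray_sd = e$microarray_sd, library_size = e$library_size,
           nb_dispersion = e$nb_dispersion,
           dropout_midpoint = e$dropout_midpoint,
           dropout_shape = e$dropout_shape,
           sc_library_mean = e$sc_library_mean,
           sc_library_sd = e$sc_library_sd,
           combine = if (is.character(e$combine)) e$combine else "custom")
    },
    output = config$output)
}

#' @rdname load_config
#' @param config A `run_config`.
#' @param path Output file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   then gene names).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1),
    USE.NAMES = FALSE)
  sets
}

# ---------------------------------------------------------------------------
# trajectory serialization: JSON Lines, one record per snapshot plus a
# header record (schema_version, params, seed); events in a parallel file

TRAJECTORY_SCHEMA_VERSION <- 1L

#' Write / read a trajectory as JSON Lines
#'
#' One JSON record per line: a header (schema version, model parameters,
#' cell types, seed) followed by one record per snapshot; the event log
#' goes to `<path>.events` in the same format.
#'
#' @param trajectory A `cell_trajectory`.
#' @param path Output path (conventionally `trajectory.jsonl`).
#' @return `write_trajectory()` returns `path`; `read_trajectory()`
#'   returns the reconstructed `cell_trajectory`.
#' @export
write_trajectory <- function(trajectory, path) {
  p <- trajectory$params
  header <- list(schema_version = TRAJECTORY_SCHEMA_VERSION,
                 seed = trajectory$seed,
                 domain_radius = trajectory$domain_radius,
                 params = config_to_list(
                   list(seed = trajectory$seed, model = p,
                        cell_types = trajectory$types,
                        pathways = list(),
                        expression = gene_expression_params(),
                        output = list(dir = ".")))[c("model", "cell_types")])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                              null = "null"), con)
  for (i in seq_along(trajectory$times)) {
    rec <- list(time = trajectory$times[i],
                cells = trajectory$snapshots[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns", na = "null"), con)
  }
  ev_path <- paste0(path, ".events")
  con2 <- file(ev_path, open = "wb")
  writeLines(jsonlite::toJSON(trajectory$events, auto_unbox = FALSE,
                              digits = NA, dataframe = "columns",
                              na = "null"), con2)
  close(con2)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
  if (header$schema_version != TRAJECTORY_SCHEMA_VERSION) {
    stop("unsupported trajectory schema version: ", header$schema_version)
  }
  types <- lapply(header$params$cell_types, function(ty)
    cell_type(ty$name, ty$size, ty$cycle_mean, ty$cycle_sd, ty$proportion))
  m <- header$params$model
  params <- model_params(m$initial_num, m$hours, m$density, m$boundary,
                         m$boundary_radius, m$epsilon_rep, m$epsilon_adh,
                         m$adhesion_range, m$mc_steps_per_hour,
                         m$max_migration, m$mitosis_duration,
                         unlist(m$phase_thresholds), m$record_every,
                         m$radius_factor, unlist(m$density_grid),
                         seed = header$seed)
  char_cols <- c("type", "phase")
  fix_types <- function(df) {
    for (cn in names(df)) {
      df[[cn]] <- if (cn %in% char_cols) as.character(df[[cn]])
                  else as.numeric(df[[cn]])  # all-null columns parse logical
    }
    df
  }
  snaps <- list(); times <- numeric(0)
  for (l in lines[-1]) {
    rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    times <- c(times, rec$time)
    snaps[[length(snaps) + 1]] <- fix_types(as.data.frame(rec$cells))
  }
  ev_path <- paste0(path, ".events")
  events <- if (file.exists(ev_path)) {
    as.data.frame(jsonlite::fromJSON(readLines(ev_path, warn = FALSE)))
  } else {
    data.frame(cell_id = integer(0), event = character(0),
               time = numeric(0), birth_time = numeric(0),
               type = character(0))
  }
  structure(list(times = times, snapshots = snaps, events = events,
                 energy = NULL, params = params, types = types,
                 seed = header$seed,
                 domain_radius = header$domain_radius),
            class = "cell_trajectory")
}

# ---------------------------------------------------------------------------
# result writers

write_tsv_matrix <- function(m, path, rowname_header = "gene") {
  df <- data.frame(rownames(m), as.matrix(m), check.names = FALSE)
  colnames(df) <- c(rowname_header, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulation outputs to a directory
#'
#' Bulk platforms get dense TSV matrices (`expression.tsv` noisy data,
#' `mean_expression.tsv`, `activity.tsv` ground truth,
#' `sample_metadata.tsv`); the single-cell platform gets a Matrix Market
#' triplet (`counts.mtx`, `features.tsv`, `barcodes.tsv`) plus
#' `cell_metadata.tsv`.  The trajectory is written as JSON Lines and the
#' effective configuration as `config.json`.  Byte output is deterministic
#' given identical inputs.
#'
#' @param result An `expression_result`.
#' @param trajectory The `cell_trajectory` it was computed from (optional).
#' @param config The effective `run_config` (optional).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(result, trajectory = NULL, config = NULL,
                          dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  path <- function(f) file.path(dir, f)

  write_tsv_matrix(result$mean_matrix, path("mean_expression.tsv"))
  write_tsv_matrix(result$activity_matrix, path("activity.tsv"),
                   rowname_header = "pathway")
  if (result$platform == "singlecell") {
    counts <- methods::as(result$noisy_matrix, "CsparseMatrix")
    Matrix::writeMM(counts, path("counts.mtx"))
    writeLines(rownames(counts), path("features.tsv"))
    writeLines(colnames(counts), path("barcodes.tsv"))
    write.table(result$sample_metadata, path("cell_metadata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write_tsv_matrix(result$noisy_matrix, path("expression.tsv"))
    write.table(result$sample_metadata, path("sample_metadata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(trajectory)) {
    write_trajectory(trajectory, path("trajectory.jsonl"))
  }
  if (!is.null(config)) write_config(config, path("config.json"))
  invisible(dir)
}

#' Read a Matrix Market count triplet back
#'
#' @param dir Directory holding `counts.mtx`, `features.tsv`,
#'   `barcodes.tsv` as written by [write_outputs()].
#' @return Sparse `dgCMatrix` with dimnames restored.
#' @export
read_counts_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")),
                        "CsparseMatrix")
  dimnames(counts) <- list(readLines(file.path(dir, "features.tsv")),
                           readLines(file.path(dir, "barcodes.tsv")))
  counts
}
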