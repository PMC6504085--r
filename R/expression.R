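#' Gene expression simulation parameters
#'
#' Controls sampling of cells from the trajectory and the platform-specific
#' measurement-error model.  Exactly one platform is active: microarray
#' (default), bulk RNA-seq (`rnaseq = TRUE`) or single-cell RNA-seq
#' (`single_cell = TRUE`).  Mean expression lives on the calibrated
#' platform scale: microarray output adds Gaussian noise to it directly,
#' while the count platforms normalize the means per sample into linear
#' relative abundances.
#'
#' @param sample_freq Hours between samples (> 0).
#' @param n_cells Cells drawn per sample time (>= 1).
#' @param rnaseq Simulate counts (bulk RNA-seq) instead of microarray.
#' @param single_cell Emit one column per sampled cell with the single-cell
#'   error model (negative binomial + logistic dropout).
#' @param microarray_sd SD of the Gaussian log-intensity noise.
#' @param library_size Expected total counts per bulk RNA-seq sample.
#' @param nb_dispersion Negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2).
#' @param dropout_midpoint Mean expression at which dropout
#'   probability is 0.5; default (`NULL`) is the median of the mean matrix.
#' @param dropout_shape Steepness of the logistic dropout curve (> 0).
#' @param sc_library_mean Mean single-cell library size (counts).
#' @param sc_library_sd SD of log10 library size across cells.
#' @param combine How genes annotated to several pathways combine their
#'   per-pathway expression values: `"mean"` (default) or a function.
#' @param seed RNG seed governing cell sampling and noise sub-streams.
#' @return An object of class `gene_expression_params`.
#' @export
gene_expression_params <- function(sample_freq = 4, n_cells = 50,
                                   rnaseq = FALSE, single_cell = FALSE,
                                   microarray_sd = 0.25,
                                   library_size = 1e6, nb_dispersion = 0.1,
                                   dropout_midpoint = NULL,
                                   dropout_shape = 1,
                                   sc_library_mean = 1e4,
                                   sc_library_sd = 0.2,
                                   combine = "mean", seed = NULL) {
  stopifnot_scalar(sample_freq, "sample_freq", lower = 0,
                   strict_lower = TRUE)
  stopifnot_scalar(n_cells, "n_cells", lower = 1)
  stopifnot_scalar(microarray_sd, "microarray_sd", lower = 0)
  stopifnot_scalar(library_size, "library_size", lower = 1)
  stopifnot_scalar(nb_dispersion, "nb_dispersion", lower = 0)
  stopifnot_scalar(dropout_shape, "dropout_shape", lower = 0,
                   strict_lower = TRUE)
  if (!is.null(dropout_midpoint)) {
    stopifnot_scalar(dropout_midpoint, "dropout_midpoint")
  }
  platform <- if (isTRUE(single_cell)) "singlecell"
              else if (isTRUE(rnaseq)) "rnaseq" else "microarray"
  structure(list(sample_freq = sample_freq, n_cells = as.integer(n_cells),
                 rnaseq = isTRUE(rnaseq), single_cell = isTRUE(single_cell),
                 platform = platform, microarray_sd = microarray_sd,
                 library_size = library_size, nb_dispersion = nb_dispersion,
                 dropout_midpoint = dropout_midpoint,
                 dropout_shape = dropout_shape,
                 sc_library_mean = sc_library_mean,
                 sc_library_sd = sc_library_sd,
                 combine = combine, seed = seed),
            class = "gene_expression_params")
}

#' Sample cells from a trajectory snapshot
#'
#' Uniform sample without replacement from the population at the snapshot
#' recorded at time `t`.  When the population is smaller than `n_cells`
#' the whole population is returned with a warning.
#'
#' @param trajectory A `cell_trajectory`.
#' @param t Snapshot time (must be recorded).
#' @param n_cells Number of cells to draw.
#' @return Integer vector of cell ids.
#' @export
sample_cells <- function(trajectory, t, n_cells) {
  snap <- snapshot_at(trajectory, t, exact = TRUE)
  ids <- snap$id
  if (length(ids) <= n_cells) {
    if (length(ids) < n_cells) {
      warning(sprintf(
        "population at t = %g has %d cells, fewer than n_cells = %d",
        t, length(ids), n_cells))
    }
    return(ids)
  }
  sample(ids, n_cells)
}

#' Evaluate pathway activities for a set of cells
#'
#' @param trajectory A `cell_trajectory`.
#' @param pathways List of [pathway()] objects.
#' @param cell_ids Cells to evaluate.
#' @param t Time in hours.
#' @return Matrix (pathways x cells) of activities in \[0, 1\].
#' @export
pathway_activity <- function(trajectory, pathways, cell_ids, t) {
  if (inherits(pathways, "pathway")) pathways <- list(pathways)
  rows <- lapply(pathways, function(pw) {
    p <- pw$rule(trajectory, cell_ids, t)
    if (length(p) != length(cell_ids)) {
      stop("pathway '", pw$name, "' returned ", length(p),
           " values for ", length(cell_ids), " cells")
    }
    if (any(p < -1e-9 | p > 1 + 1e-9)) {
      stop("pathway '", pw$name, "' returned activity outside [0, 1]")
    }
    pmin(1, pmax(0, p))
  })
  P <- do.call(rbind, rows)
  dimnames(P) <- list(vapply(pathways, `[[`, character(1), "name"),
                      cell_ids)
  P
}

# per-gene-within-pathway interpolation table
pathway_gene_table <- function(pathways) {
  for (pw in pathways) {
    if (!is_calibrated(pw)) {
      stop("pathway '", pw$name, "' is not calibrated")
    }
  }
  genes <- unique(unlist(lapply(pathways, `[[`, "genes")))
  list(genes = genes)
}

#' Mean expression from pathway activities
#'
#' For pathway k with activity `P_k`, every gene i annotated to k gets the
#' interpolated value `P_k * gmax_ik + (1 - P_k) * gmin_ik`.  A gene in
#' several pathways combines its per-pathway values with `combine`
#' (arithmetic mean by default).  In bulk mode `P_k` is first averaged over
#' the sampled cells, giving one column; in single-cell mode each sampled
#' cell keeps its own activities, giving one column per cell.
#'
#' @param P Activity matrix (pathways x cells) from [pathway_activity()].
#' @param pathways Calibrated pathways, in the row order of `P`.
#' @param mode `"bulk"` or `"single_cell"`.
#' @param combine `"mean"` or a function reducing a vector of per-pathway
#'   values to one value.
#' @return Matrix (genes x 1) in bulk mode, (genes x cells) otherwise;
#'   genes ordered by first appearance across pathways.
#' @export
mean_expression <- function(P, pathways, mode = c("bulk", "single_cell"),
                            combine = "mean") {
  mode <- match.arg(mode)
  if (inherits(pathways, "pathway")) pathways <- list(pathways)
  stopifnot(nrow(P) == length(pathways))
  genes <- pathway_gene_table(pathways)$genes

  if (mode == "bulk") {
    P <- matrix(rowMeans(P), ncol = 1,
                dimnames = list(rownames(P), NULL))
  }
  ncol_out <- ncol(P)

  use_mean <- identical(combine, "mean")
  if (use_mean) {
    acc <- matrix(0, length(genes), ncol_out,
                  dimnames = list(genes, colnames(P)))
    cnt <- numeric(length(genes))
    for (k in seq_along(pathways)) {
      pw <- pathways[[k]]
      idx <- match(pw$genes, genes)
      vals <- outer(pw$gmax, P[k, ]) + outer(pw$gmin, 1 - P[k, ])
      acc[idx, ] <- acc[idx, ] + vals
      cnt[idx] <- cnt[idx] + 1
    }
    return(acc / cnt)
  }

  if (!is.function(combine)) stop("combine must be \"mean\" or a function")
  out <- matrix(NA_real_, length(genes), ncol_out,
                dimnames = list(genes, colnames(P)))
  per_gene <- lapply(genes, function(g) list())
  names(per_gene) <- genes
  for (k in seq_along(pathways)) {
    pw <- pathways[[k]]
    vals <- outer(pw$gmax, P[k, ]) + outer(pw$gmin, 1 - P[k, ])
    for (gi in seq_along(pw$genes)) {
      g <- pw$genes[gi]
      per_gene[[g]] <- c(per_gene[[g]], list(vals[gi, ]))
    }
  }
  for (g in genes) {
    m <- do.call(rbind, per_gene[[g]])
    out[g, ] <- apply(m, 2, combine)
  }
  out
}

#' Gaussian microarray noise
#'
#' Adds i.i.d. `Normal(0, microarray_sd^2)` noise to every entry of the
#' mean matrix (interpreted as log-style intensities).
#'
#' @param mean_matrix Genes x samples means.
#' @param microarray_sd Noise standard deviation.
#' @return Noisy matrix of the same shape.
#' @export
noise_microarray <- function(mean_matrix, microarray_sd) {
  mean_matrix + matrix(rnorm(length(mean_matrix), 0, microarray_sd),
                       nrow(mean_matrix), ncol(mean_matrix))
}

# linear-scale means -> per-column relative abundances.  Calibrated
# expression levels are treated as proportional to transcript abundance;
# an exponential spread of gene means (the calibration default) then gives
# a realistic ~100:1 dynamic range of counts rather than the astronomical
# ratios a log2 reading of the same numbers would imply.
relative_abundance <- function(mean_matrix) {
  a <- pmax(mean_matrix, 0)
  sweep(a, 2, colSums(a), "/")
}

# NB draw with mean mu and dispersion phi (variance mu + phi mu^2);
# phi -> 0 falls back to Poisson
rnb <- function(mu, dispersion) {
  if (dispersion < 1e-12) return(rpois(length(mu), mu))
  rnbinom(length(mu), size = 1 / dispersion, mu = mu)
}

#' Negative-binomial bulk RNA-seq noise
#'
#' Means (linear platform scale) are normalized per sample to relative
#' abundances `a`; counts are drawn from
#' `NB(mean = library_size * a, dispersion)` with variance
#' `mu + dispersion * mu^2`.
#'
#' @param mean_matrix Genes x samples means (linear scale).
#' @param library_size Expected total counts per sample.
#' @param nb_dispersion Dispersion phi.
#' @return Integer count matrix of the same shape.
#' @export
noise_bulk_rnaseq <- function(mean_matrix, library_size, nb_dispersion) {
  mu <- library_size * relative_abundance(mean_matrix)
  counts <- matrix(rnb(mu, nb_dispersion), nrow(mu), ncol(mu),
                   dimnames = dimnames(mean_matrix))
  counts
}

# dropout probability: logistic, decreasing in the mean
dropout_probability <- function(mean_matrix, midpoint, shape) {
  1 / (1 + exp(shape * (mean_matrix - midpoint)))
}

#' Single-cell RNA-seq noise (negative binomial + dropout)
#'
#' Per-cell library sizes are log-normal (`sc_library_sd` on the log10
#' scale); counts are negative binomial as in [noise_bulk_rnaseq()]; each
#' entry is then zeroed independently with the logistic dropout
#' probability `1 / (1 + exp(shape * (g - midpoint)))`, which decreases
#' with the mean expression `g`.
#'
#' @param mean_matrix Genes x cells means (linear platform scale).
#' @param nb_dispersion Dispersion phi.
#' @param dropout_midpoint Mean value at which dropout probability is 0.5.
#' @param dropout_shape Logistic steepness (> 0).
#' @param sc_library_mean Mean library size in counts.
#' @param sc_library_sd SD of log10 library size across cells.
#' @return Sparse `dgCMatrix` of counts.
#' @export
noise_single_cell <- function(mean_matrix, nb_dispersion, dropout_midpoint,
                              dropout_shape, sc_library_mean = 1e4,
                              sc_library_sd = 0.2) {
  libs <- 10^rnorm(ncol(mean_matrix), log10(sc_library_mean), sc_library_sd)
  mu <- sweep(relative_abundance(mean_matrix), 2, libs, "*")
  counts <- matrix(rnb(mu, nb_dispersion), nrow(mu), ncol(mu))
  pi_drop <- dropout_probability(mean_matrix, dropout_midpoint,
                                 dropout_shape)
  keep <- matrix(rbinom(length(pi_drop), 1, 1 - pi_drop),
                 nrow(pi_drop), ncol(pi_drop))
  out <- counts * keep
  dimnames(out) <- dimnames(mean_matrix)
  Matrix::Matrix(out, sparse = TRUE)
}

#' Simulate gene expression along a cell trajectory
#'
#' Samples cells at t = 0, `sample_freq`, 2 `sample_freq`, ... up to and
#' including the final simulated hour when divisible; evaluates pathway
#' activities for the sampled cells; converts them to mean expression with
#' [mean_expression()]; and applies the platform's error model.  Cell
#' sampling and noise use named RNG sub-streams of `params$seed`, so runs
#' are reproducible and the two stages can be re-run independently.
#'
#' @param trajectory A `cell_trajectory` from [run_cell_model()].
#' @param pathways List of calibrated pathways.
#' @param params A [gene_expression_params()].
#' @return An `expression_result`: list with `gene_names`, `platform`,
#'   `mean_matrix`, `noisy_matrix`, `activity_matrix` (ground-truth
#'   pathway activities per sample column) and `sample_metadata`.
#' @export
simulate_gene_expression <- function(trajectory, pathways, params) {
  stopifnot(inherits(trajectory, "cell_trajectory"),
            inherits(params, "gene_expression_params"))
  if (inherits(pathways, "pathway")) pathways <- list(pathways)
  genes <- pathway_gene_table(pathways)$genes
  pw_names <- vapply(pathways, `[[`, character(1), "name")

  t_end <- max(trajectory$times)
  times <- seq(0, t_end, by = params$sample_freq)
  single <- params$platform == "singlecell"
  mode <- if (single) "single_cell" else "bulk"

  set_stream_seed(params$seed, "sampling")
  sampled <- lapply(times, function(t)
    sample_cells(trajectory, t, params$n_cells))

  cols_mean <- list(); cols_act <- list(); meta <- list()
  for (s in seq_along(times)) {
    t <- times[s]
    ids <- sampled[[s]]
    P <- pathway_activity(trajectory, pathways, ids, t)
    m <- mean_expression(P, pathways, mode, params$combine)
    snap_rows <- snapshot_rows(trajectory, ids, t)
    if (single) {
      colnames(m) <- sprintf("cell%d_t%g", ids, t)
      cols_act[[s]] <- P
      meta[[s]] <- data.frame(sample_id = colnames(m), time = t,
                              cell_id = ids, cell_type = snap_rows$type,
                              phase = snap_rows$phase)
    } else {
      colnames(m) <- sprintf("t%g", t)
      cols_act[[s]] <- matrix(rowMeans(P), ncol = 1,
                              dimnames = list(pw_names, colnames(m)))
      meta[[s]] <- data.frame(sample_id = colnames(m), time = t,
                              n_cells = length(ids),
                              cell_ids = paste(ids, collapse = ";"))
    }
    cols_mean[[s]] <- m
  }
  mean_matrix <- do.call(cbind, cols_mean)
  activity_matrix <- do.call(cbind, cols_act)
  rownames(activity_matrix) <- pw_names
  metadata <- do.call(rbind, meta)

  set_stream_seed(params$seed, "noise")
  noisy <- switch(params$platform,
    microarray = noise_microarray(mean_matrix, params$microarray_sd),
    rnaseq = noise_bulk_rnaseq(mean_matrix, params$library_size,
                               params$nb_dispersion),
    singlecell = {
      midpoint <- params$dropout_midpoint %||% median(mean_matrix)
      noise_single_cell(mean_matrix, params$nb_dispersion, midpoint,
                        params$dropout_shape, params$sc_library_mean,
                        params$sc_library_sd)
    })

  structure(list(gene_names = genes, platform = params$platform,
                 mean_matrix = mean_matrix, noisy_matrix = noisy,
                 activity_matrix = activity_matrix,
                 sample_metadata = metadata, sample_times = times,
                 params = params),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("<expression_result> %s, %d genes x %d samples\n",
              x$platform, nrow(x$mean_matrix), ncol(x$mean_matrix)))
  invisible(x)
}
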