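#' Define a pathway
#'
#' A pathway links a set of genes to a cellular process through an activity
#' rule: a function `rule(trajectory, cell_ids, t)` returning one value in
#' \[0, 1\] per cell.  Per-gene expression ranges (`gmin`, `gmax`) are set
#' by [calibrate_from_distribution()] or [calibrate_from_reference()];
#' expression then interpolates between them by activity.
#'
#' @param name Pathway name.
#' @param genes Character vector of gene names, non-empty and unique
#'   within the pathway (genes may be shared across pathways).
#' @param rule Activity function `function(trajectory, cell_ids, t)`.
#' @param rule_name Optional label describing the rule (used when writing
#'   configs back out).
#' @param rule_params Named list of rule parameters, for serialization.
#' @return An object of class `pathway` (uncalibrated).
#' @seealso [pathway_phase_transition()], [pathway_contact_inhibition()],
#'   [pathway_growth_rate()], [pathway_cell_type()]
#' @export
pathway <- function(name, genes, rule, rule_name = "custom",
                    rule_params = list()) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  stopifnot(is.character(genes), length(genes) >= 1)
  if (anyDuplicated(genes)) stop("pathway genes must be unique")
  stopifnot(is.function(rule))
  structure(list(name = name, genes = genes, rule = rule,
                 rule_name = rule_name, rule_params = rule_params,
                 gmin = NULL, gmax = NULL),
            class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf("<pathway '%s'> %d genes, rule '%s', %s\n", x$name,
              length(x$genes), x$rule_name,
              if (is.null(x$gmin)) "uncalibrated" else "calibrated"))
  invisible(x)
}

is_calibrated <- function(pw) !is.null(pw$gmin) && !is.null(pw$gmax)

# snapshot rows for given cell ids at the snapshot nearest t
snapshot_rows <- function(trajectory, cell_ids, t) {
  snap <- snapshot_at(trajectory, t)
  idx <- match(cell_ids, snap$id)
  if (anyNA(idx)) {
    stop("unknown cell id(s) at t = ", t, ": ",
         paste(cell_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  snap[idx, , drop = FALSE]
}

#' Phase-transition pathway activity
#'
#' Binary activity: 1 when the cell's most recent entry into the given
#' phase lies in the window `(t - window, t]`, else 0.
#'
#' @param trajectory A `cell_trajectory`.
#' @param cell_ids Cell id(s), as recorded in snapshots.
#' @param t Time in hours.
#' @param phase `"S"` or `"M"`.
#' @param window Event window in hours (default 1).
#' @return 0/1 value per cell.
#' @export
activity_phase_transition <- function(trajectory, cell_ids, t,
                                      phase = c("S", "M"), window = 1) {
  phase <- match.arg(phase)
  rows <- snapshot_rows(trajectory, cell_ids, t)
  entry <- if (phase == "S") rows$enter_S else rows$enter_M
  as.numeric(!is.na(entry) & entry > t - window & entry <= t)
}

#' Contact-inhibition pathway activity
#'
#' The cell's local density (fraction of its neighborhood annulus occupied
#' by other cells) at the snapshot nearest `t`; delegates to the value
#' computed by [run_cell_model()] via [local_density()].
#'
#' @inheritParams activity_phase_transition
#' @return Value in \[0, 1\] per cell.
#' @export
activity_contact_inhibition <- function(trajectory, cell_ids, t) {
  snapshot_rows(trajectory, cell_ids, t)$local_density
}

#' Growth-rate pathway activity
#'
#' Accepted growth (area per hour over the last recording interval)
#' relative to the unimpeded schedule of the cell's type, clamped to
#' \[0, 1\].  A mitotic cell, which schedules no growth, reports 0 by
#' convention.
#'
#' @inheritParams activity_phase_transition
#' @return Value in \[0, 1\] per cell.
#' @export
activity_growth_rate <- function(trajectory, cell_ids, t) {
  snapshot_rows(trajectory, cell_ids, t)$growth_rate
}

#' Cell-type identity pathway activity
#'
#' Binary: 1 when the cell's type matches `type_name`.
#'
#' @inheritParams activity_phase_transition
#' @param type_name Cell-type name.
#' @return 0/1 value per cell.
#' @export
activity_cell_type <- function(trajectory, cell_ids, t, type_name) {
  known <- vapply(trajectory$types, `[[`, character(1), "name")
  if (!type_name %in% known) stop("unknown cell type: ", type_name)
  as.numeric(snapshot_rows(trajectory, cell_ids, t)$type == type_name)
}

#' @rdname pathway
#' @param phase,window Passed to [activity_phase_transition()].
#' @export
pathway_phase_transition <- function(name, genes, phase = c("S", "M"),
                                     window = 1) {
  phase <- match.arg(phase)
  force(window)
  pathway(name, genes,
          function(trajectory, cell_ids, t)
            activity_phase_transition(trajectory, cell_ids, t, phase,
                                      window),
          rule_name = "phase_transition",
          rule_params = list(phase = phase, window = window))
}

#' @rdname pathway
#' @export
pathway_contact_inhibition <- function(name, genes) {
  pathway(name, genes, activity_contact_inhibition,
          rule_name = "contact_inhibition")
}

#' @rdname pathway
#' @export
pathway_growth_rate <- function(name, genes) {
  pathway(name, genes, activity_growth_rate, rule_name = "growth_rate")
}

#' @rdname pathway
#' @param type_name Cell-type name for [activity_cell_type()].
#' @export
pathway_cell_type <- function(name, genes, type_name) {
  force(type_name)
  pathway(name, genes,
          function(trajectory, cell_ids, t)
            activity_cell_type(trajectory, cell_ids, t, type_name),
          rule_name = "cell_type",
          rule_params = list(type_name = type_name))
}

#' Calibrate a pathway from a statistical distribution
#'
#' Per-gene mean expression is exponential with mean `lambda`; the range
#' width is `|Normal(0, stddev)|`.  Each gene gets
#' `gmin = max(0, mean - width / 2)` and `gmax = mean + width / 2`.  Units
#' are log2-scale expression for the count platforms and log intensities
#' for microarrays.
#'
#' @param pathway A [pathway()].
#' @param lambda Mean of the exponential distribution of gene means (> 0).
#' @param stddev Scale of the half-normal range-width distribution (>= 0).
#' @param seed Optional RNG seed (calibration sub-stream); `NULL` uses the
#'   current RNG state.
#' @return The pathway with `gmin` and `gmax` filled in.
#' @examples
#' pw <- pathway_growth_rate("growth", paste0("g", 1:5))
#' pw <- calibrate_from_distribution(pw, lambda = 20, stddev = 2, seed = 1)
#' @export
calibrate_from_distribution <- function(pathway, lambda = 20, stddev = 2,
                                        seed = NULL) {
  stopifnot(inherits(pathway, "pathway"))
  stopifnot_scalar(lambda, "lambda", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(stddev, "stddev", lower = 0)
  set_stream_seed(seed, "calibration")
  n <- length(pathway$genes)
  m <- rexp(n, rate = 1 / lambda)
  w <- abs(rnorm(n, 0, stddev))
  pathway$gmin <- stats::setNames(pmax(0, m - w / 2), pathway$genes)
  pathway$gmax <- stats::setNames(m + w / 2, pathway$genes)
  pathway$calibration <- list(method = "distribution", lambda = lambda,
                              stddev = stddev, seed = seed)
  pathway
}

#' Calibrate a pathway from a reference expression matrix
#'
#' Sets each gene's expression range to the 5th and 95th percentiles
#' (linear-interpolation quantiles) of its row in a reference matrix,
#' trading the extremes for outlier robustness.
#'
#' @param pathway A [pathway()].
#' @param reference Numeric genes x samples matrix with gene row names.
#' @return The calibrated pathway.
#' @export
calibrate_from_reference <- function(pathway, reference) {
  stopifnot(inherits(pathway, "pathway"))
  stopifnot(is.matrix(reference), !is.null(rownames(reference)))
  missing <- setdiff(pathway$genes, rownames(reference))
  if (length(missing) > 0) {
    stop("genes missing from the reference matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  q <- t(apply(reference[pathway$genes, , drop = FALSE], 1, quantile,
               probs = c(0.05, 0.95), names = FALSE, type = 7))
  pathway$gmin <- stats::setNames(q[, 1], pathway$genes)
  pathway$gmax <- stats::setNames(q[, 2], pathway$genes)
  pathway$calibration <- list(method = "reference")
  pathway
}

# default placeholder gene names for packaged pathway sets
placeholder_genes <- function(prefix, n) {
  sprintf("%s_g%03d", prefix, seq_len(n))
}
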