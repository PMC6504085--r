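# internal helpers

# Named sub-streams derived from one user seed so that model run, pathway
# calibration, cell sampling and measurement noise can be re-run
# independently yet reproducibly.  Offsets are arbitrary fixed constants;
# results stay below 2^31 - 1.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  offsets <- c(model = 101L, calibration = 211L, sampling = 307L,
               noise = 401L, scenario = 503L)
  if (!stream %in% names(offsets)) {
    stop("unknown seed stream: ", stream)
  }
  m <- 2147483647
  ((as.numeric(seed) %% m) * 48271 + offsets[[stream]]) %% m
}

set_stream_seed <- function(seed, stream) {
  s <- derive_seed(seed, stream)
  if (!is.null(s)) set.seed(s)
  invisible(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("'%s' = %g is outside its valid range", name, x),
         call. = FALSE)
  }
  invisible(x)
}
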