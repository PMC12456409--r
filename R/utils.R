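#' @keywords internal
"_PACKAGE"

# Error helpers: every user-facing failure is classed so callers (and the
# CLI) can distinguish bad parameters from bad data from bad file formats.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "dcmotion_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_param  <- function(msg) abort(msg, "dcmotion_parameter_error")
abort_data   <- function(msg) abort(msg, "dcmotion_data_error")
abort_format <- function(msg) abort(msg, "dcmotion_format_error")
abort_config <- function(msg) abort(msg, "dcmotion_config_error")

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    abort_param(sprintf("`%s` must be a single non-missing number", name))
  if (!allow_inf && !is.finite(x))
    abort_param(sprintf("`%s` must be finite", name))
  if (x < lower || x > upper)
    abort_param(sprintf("`%s` must be in [%s, %s], got %s",
                        name, lower, upper, format(x)))
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_scalar(x, name, lower = lower)
  if (x != round(x))
    abort_param(sprintf("`%s` must be a whole number", name))
  as.integer(x)
}

# Run `expr` under a given seed, restoring the caller's RNG state afterwards
# so library calls never perturb a user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Derive `n` independent substream seeds from one master seed. All package
# randomness flows through this, so per-cell / per-replicate streams are
# reproducible yet decoupled from how many draws each consumes.
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

unit_vector <- function(v, name = "vector") {
  if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)))
    abort_param(sprintf("`%s` must be a finite numeric 2-vector", name))
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12)
    abort_param(sprintf("`%s` must be nonzero", name))
  v / nrm
}
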