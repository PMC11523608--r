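# Internal helpers: classed error conditions, small vector algebra.

fg_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fossagii_error", "error", "condition")))
}

fg_validation_error <- function(msg) fg_stop(msg, "fossagii_validation_error")
fg_format_error     <- function(msg) fg_stop(msg, "fossagii_format_error")
fg_domain_error     <- function(msg) fg_stop(msg, "fossagii_domain_error")
fg_resolution_error <- function(msg) fg_stop(msg, "fossagii_resolution_error")
fg_config_error     <- function(msg) fg_stop(msg, "fossagii_config_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_point3 <- function(p, name = "point") {
  if (!is.numeric(p) || length(p) != 3L || !all(is.finite(p)))
    fg_validation_error(sprintf("'%s' must be a finite numeric 3-vector", name))
  as.numeric(p)
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v, name = "vector") {
  n <- vnorm(v)
  if (!is.finite(n) || n == 0)
    fg_validation_error(sprintf("cannot normalize zero-length '%s'", name))
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Deterministic unit vector orthogonal to `axis`: project out the coordinate
# axis least aligned with it.
orthonormal_ref <- function(axis) {
  e <- diag(3)[, which.min(abs(axis)), drop = TRUE]
  unitize(e - sum(e * axis) * axis)
}

# Derive independent sub-streams from one master seed; keeps each output
# table on its own stream so adding a table never perturbs the others.
fg_stream_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) + 1000003 * k) %% 2147483647)
}
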