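# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Display rounding for reported percentages. `base::round()` rounds half to
#' even; clinical tables conventionally round 0.05 up, so exact .x5 values
#' must not fall back to the IEC 60559 rule.
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic child-seed derivation: one master seed fans out to per-stage
# (or per-iteration) seeds without collisions in practice. Kept < 2^31 - 1.
derive_seed <- function(seed, stage) {
  seed <- as.double(seed)
  stage <- as.double(stage)
  as.integer((seed * 48271 + stage * 30269 + 1) %% 2147483647)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state so
# that taking a seed as an argument never perturbs the global stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Cheap content fingerprint used to assert that two bootstrap distributions
# were produced from the same cohort (pairing precondition).
cohort_fingerprint <- function(y, r) {
  sprintf(
    "n=%d;pos=%d;sum=%.6e;min=%.6e;max=%.6e",
    length(y), sum(y), sum(r), min(r), max(r)
  )
}

# MD5 of a canonical JSON rendering; provenance stamp for report bundles.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
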