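# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring caller state
#'
#' All stochastic operations in the package take an explicit `seed` argument
#' and route it through this helper so that the caller's `.Random.seed` is
#' never disturbed and identical seeds give identical results.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a sub-seed from a base seed and a stage label, kept below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483647)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# Round half away from zero (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

#' Canonical ecotone labels
#' @return character vector of the three blue carbon ecotone labels.
#' @export
ecotone_levels <- function() c("mangrove", "salt_marsh", "seagrass")

match_ecotone <- function(ecotone) {
  match.arg(ecotone, ecotone_levels())
}

# FNV-1a 32-bit hash of a string; used to stamp outputs with a config hash.
# Arithmetic kept in doubles < 2^53; the 32-bit product is computed in
# 16-bit halves to avoid precision loss.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

fitness_columns <- function() c("area", "fragment_area", "age", "height", "agb", "soc")

climate_columns <- function() c("par", "tidal_amplitude", "sst", "air_temperature", "precipitation")

pressure_sublayers <- function() {
  list(
    p_climate = c("oa", "sst_pressure", "slr"),
    p_land    = c("ocp", "dp", "np"),
    p_marine  = c("af", "cfplb", "cfphb", "cfdnlb", "cfdnhb", "dd", "ligt", "ship"),
    p_species = "species_threat_fraction"
  )
}
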