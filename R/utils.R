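# Internal helpers shared across modules.

# Stop with a classed condition naming the offending configuration field.
abort_config <- function(field, msg) {
  abort(paste0("invalid configuration field `", field, "`: ", msg),
        class = "radsurvey_config_error")
}

# Coerce a per-modality (or per-region) mapping given either as a named
# numeric vector or as a two-column data frame into a named numeric vector.
as_named_rates <- function(x, key, value, what) {
  if (is.numeric(x) && !is.null(names(x))) {
    return(x)
  }
  if (is.data.frame(x)) {
    if (!all(c(key, value) %in% names(x))) {
      abort(paste0("`", what, "` must have columns `", key, "` and `", value, "`"))
    }
    return(setNames(x[[value]], x[[key]]))
  }
  abort(paste0("`", what, "` must be a named numeric vector or a data frame"))
}

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a deterministic sub-stream seed (kept below 2^31) for one table.
substream_seed <- function(seed, index) {
  (as.double(seed) %% 1e6) * 1009 + 7919 * index
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort_config(field, "must be a single probability in [0, 1]")
  }
  invisible(x)
}
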