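# Internal helpers shared across modules.

# Classed conditions so callers can distinguish validation failures
# (bad input data), schema failures (bad config) and evaluation failures
# (unresolvable score source) programmatically.
ts_stop <- function(message, class) {
  stop(structure(
    class = c(class, "tiescope_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

ts_validation_error <- function(message) ts_stop(message, "tiescope_validation_error")
ts_schema_error     <- function(message) ts_stop(message, "tiescope_schema_error")
ts_eval_error       <- function(message) ts_stop(message, "tiescope_eval_error")

# Normalise free text for matching questionnaire response options:
# case-folded, unicode dashes to ASCII hyphen, whitespace collapsed,
# no spaces around hyphens.
normalize_option_text <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("–|—|‐|−", "-", x)
  x <- gsub("\\s+", " ", x)
  x <- gsub("\\s*-\\s*", "-", x)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# Canonical undirected edge keys "min|max" for set arithmetic on edges.
edge_keys <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Evaluate a comparator name against observed/threshold vectors.
apply_comparator <- function(comparator, observed, threshold) {
  switch(comparator,
    ge = observed >= threshold,
    gt = observed > threshold,
    le = observed <= threshold,
    lt = observed < threshold,
    ts_schema_error(sprintf(
      "unknown comparator '%s' (must be one of ge, gt, le, lt)", comparator
    ))
  )
}

comparator_symbol <- function(comparator) {
  c(ge = ">=", gt = ">", le = "<=", lt = "<")[[comparator]]
}

# Run code with the RNG seeded, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit integer hash of a string (polynomial rolling hash,
# exact in double precision), used to derive RNG streams from a study
# secret without external hash packages.
string_seed <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 0
  for (b in bytes) {
    h <- (h * 69069 + b + 1) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}
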