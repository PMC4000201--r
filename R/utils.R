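# Internal helpers: argument validation and reproducible seed substreams.

stop_if_not_scalar_number <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  if (integerish && x != round(x))
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  invisible(x)
}

# Counter-based substream derivation: a deterministic map from
# (root seed, trial counter, purpose) to a 31-bit seed. Adding trials or
# purposes never perturbs streams already drawn, because each stream is a
# pure function of its own counters.
.purpose_codes <- c(
  initial_conditions = 1L, labels = 2L, folds = 3L, shuffle = 4L,
  drift = 5L, replicate = 6L, multiclass = 7L, noise = 8L
)

derive_seed <- function(seed, trial = 0L, purpose = "initial_conditions") {
  stop_if_not_scalar_number(seed, "seed", integerish = TRUE)
  code <- .purpose_codes[[purpose]]
  if (is.null(code)) stop("unknown seed purpose: ", purpose, call. = FALSE)
  base <- abs(seed) %% 1048573
  # all intermediate products stay far below 2^53, result below 2^31
  (base * 2017 + trial * 99991 + code * 7919 + 12345) %% 2147483629
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
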