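# Condition helpers: every user-facing failure carries a subclass so the CLI
# can map validation errors to exit code 2 and computation errors to 3.

stop_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "metaprop_validation_error")
}

stop_format <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...),
               class = c("metaprop_format_error", "metaprop_validation_error"))
}

stop_not_computable <- function(metric, msg, ...) {
  rlang::abort(sprintf("metaproperty '%s' not computable: %s", metric, sprintf(msg, ...)),
               class = c("metaprop_not_computable", "metaprop_computation_error"),
               metric = metric)
}

stop_computation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "metaprop_computation_error")
}

check_number <- function(x, name, min = -Inf, max = Inf, allow_na = FALSE) {
  if (allow_na && length(x) == 1 && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    stop_validation("`%s` must be a single number", name)
  }
  if (x < min || x > max) {
    stop_validation("`%s` must be in [%s, %s], got %s", name,
                    format(min), format(max), format(x))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    stop_validation("`%s` must be TRUE or FALSE", name)
  }
  invisible(x)
}

# Deterministic child seeds: draw from a private RNG stream so callers'
# streams are untouched. Kept below 2^31 (R integers).
derive_seeds <- function(base_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(base_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

`%f|%` <- function(x, default) if (is.null(x) || length(x) == 0) default else x
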