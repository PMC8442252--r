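# Shared internal helpers: classed conditions, RNG scoping, name hygiene.

pm_stop <- function(msg, class = "piecemeal_argument_error", call. = NULL) {
  stop(errorCondition(msg, class = c(class, "piecemeal_error")))
}

pm_check_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    pm_stop(sprintf("`%s` must be a single non-empty string", what))
  invisible(x)
}

# Characters reserved by the text serializations (constraint grammar and the
# "TAIL -> HEAD" edge-list format).
.RESERVED_NAME_RX <- "[][|;,#:>[:space:]]"

pm_check_names <- function(variables, what = "variables") {
  if (!is.character(variables) || length(variables) < 1L)
    pm_stop(sprintf("`%s` must be a non-empty character vector", what))
  if (anyNA(variables) || any(!nzchar(variables)))
    pm_stop(sprintf("`%s` must not contain missing or empty names", what))
  if (anyDuplicated(variables))
    pm_stop(sprintf("`%s` must not contain duplicated names", what))
  bad <- grepl(.RESERVED_NAME_RX, variables)
  if (any(bad))
    pm_stop(sprintf(
      "variable name(s) %s contain characters reserved by the text formats",
      paste0("'", variables[bad], "'", collapse = ", ")
    ))
  invisible(variables)
}

pm_check_count <- function(x, what, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    pm_stop(sprintf("`%s` must be a single integer >= %s", what, min))
  invisible(as.numeric(x))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL means "use the ambient RNG".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  pm_check_count(seed, "seed")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# sample() treats a length-1 numeric as 1:n; this picks one element literally.
pick1 <- function(x) {
  if (length(x) == 0L) pm_stop("internal: empty choice set")
  if (length(x) == 1L) x else x[sample.int(length(x), 1L)]
}

# Deterministic per-run seed derivation, kept below 2^31 - 1 (R integers are
# 32-bit).  All factors are < 2^21 so products stay exact in doubles.
derive_seed <- function(base_seed, graph_index, policy_id, rep) {
  s <- (as.numeric(base_seed) %% 2147483629) * 1000003 +
    graph_index * 7919 + policy_id * 104729 + rep * 31337
  as.integer(s %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Memoization environment for enumeration contexts and DAG-count tables.
.pm_cache <- new.env(parent = emptyenv())
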