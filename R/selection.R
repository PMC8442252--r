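# Experiment-selection policies.
#
# All three policies draw from the full study-design pool (ordered pair x
# methodological symbol) and never repeat a performed design while an
# unperformed one exists.  The informative policies consult a suggestion
# table mapping each pair's remaining degree-of-freedom pattern to the
# constraint-level designs able to discriminate between the remaining
# relations; sign variants of a constraint-level design are informationally
# identical, so a concrete variant is drawn uniformly at the end.
#
# The table (patterns keyed relative to the sorted pair (a, b); "right" is
# a -> b):
#   {right}             -> intervene on a   (only an intervention on the
#   {left}              -> intervene on b    putative cause tests the
#                                            directed path)
#   {none}              -> both interventions (observational dependence can
#                                            arise from confounding paths
#                                            elsewhere in the system, so
#                                            interventional verdicts are the
#                                            cleaner test of edge absence)
#   {right, none}       -> intervene on a, or observe -- never intervene on
#                          b: that surgery removes a -> b and makes the two
#                          remaining relations indistinguishable
#   {left, none}        -> intervene on b, or observe (mirror)
#   {right, left}       -> both interventions
#   {right, left, none} -> both interventions

.SUGGESTION_TABLE <- list(
  "right"           = "int_first",
  "left"            = "int_second",
  "none"            = c("int_first", "int_second"),
  "left+right"      = c("int_first", "int_second"),
  "none+right"      = c("int_first", "obs"),
  "left+none"       = c("int_second", "obs"),
  "left+none+right" = c("int_first", "int_second")
)

pattern_key <- function(relations) paste(sort(relations), collapse = "+")

#' Most informative experiments for a degree-of-freedom pattern
#'
#' @param pair Two distinct variable names (canonicalized by sorting).
#' @param pattern Character vector of the edge relations still viable for
#'   the pair (subset of `c("right", "left", "none")`, relative to the
#'   sorted pair), or a single relation.
#' @return A data frame of constraint-level designs (columns `a`, `b`,
#'   `code`, `intervened`), one row per suggested experiment.
#' @examples
#' suggested_experiments(c("X", "Y"), c("right", "none"))
#' @export
suggested_experiments <- function(pair, pattern) {
  if (!is.character(pair) || length(pair) != 2L || pair[1L] == pair[2L])
    pm_stop("`pair` must be two distinct variable names")
  pattern <- unique(as.character(pattern))
  if (length(pattern) == 0L)
    pm_stop("`pattern` must contain at least one relation")
  if (!all(pattern %in% .RELATIONS))
    pm_stop("`pattern` must be drawn from 'right', 'left', 'none'")
  pair <- sort(pair)
  codes <- .SUGGESTION_TABLE[[pattern_key(pattern)]]
  data.frame(a = pair[1L], b = pair[2L], code = codes,
             intervened = ifelse(codes == "obs", NA_character_,
                                 ifelse(codes == "int_first",
                                        pair[1L], pair[2L])),
             stringsAsFactors = FALSE)
}

#' Selection bookkeeping state
#'
#' Tracks which study designs have been performed (the set P) and which
#' variables have been involved in selected experiments, plus an optional
#' RNG seed making each selection a pure function of (class, state, seed).
#'
#' @param variables Character vector of variable names (defines the pool).
#' @param performed Already-performed designs: `NULL`, a vector of design
#'   ids into [enumerate_study_designs()] order, or a data frame with
#'   `source`, `target`, `method` columns.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @param variables_used Optional character vector; defaults to the
#'   variables touched by `performed`.
#' @return An object of class `pm_selection_state`.
#' @export
selection_state <- function(variables, performed = NULL, seed = NULL,
                            variables_used = NULL) {
  pm_check_names(variables)
  pool <- design_pool(variables)
  ids <- performed_ids(performed, pool)
  used <- variables_used %||% unique(c(
    pool$designs$source[ids], pool$designs$target[ids]))
  structure(list(variables = variables, performed = ids,
                 variables_used = used, rng_seed = seed),
            class = "pm_selection_state")
}

performed_ids <- function(performed, pool) {
  if (is.null(performed)) return(integer(0))
  if (is.numeric(performed)) {
    ids <- as.integer(performed)
    if (any(is.na(ids)) || any(ids < 1L) || any(ids > nrow(pool$designs)))
      pm_stop("`performed` contains invalid design ids")
    return(ids)
  }
  if (is.data.frame(performed)) {
    key <- paste(performed$source, performed$target, performed$method)
    full <- paste(pool$designs$source, pool$designs$target,
                  pool$designs$method)
    ids <- match(key, full)
    if (anyNA(ids)) pm_stop("`performed` contains designs outside the pool")
    return(ids)
  }
  pm_stop("`performed` must be NULL, design ids, or a design data frame")
}

#' Record a performed design in a selection state
#'
#' @param state A `pm_selection_state`.
#' @param design A study design (as returned by the `select_*` functions).
#' @return The updated state.
#' @export
state_after <- function(state, design) {
  if (!inherits(state, "pm_selection_state"))
    pm_stop("`state` must be a `pm_selection_state`")
  pool <- design_pool(state$variables)
  id <- performed_ids(as_design_frame(design), pool)
  state$performed <- c(state$performed, id)
  state$variables_used <- unique(c(state$variables_used,
                                   pool$designs$source[id],
                                   pool$designs$target[id]))
  state
}

as_design_frame <- function(design) {
  d <- as_study_design(design)
  data.frame(source = d$source, target = d$target, method = d$method,
             stringsAsFactors = FALSE)
}

design_from_id <- function(id, pool) {
  row <- pool$designs[id, ]
  out <- study_design(row$source, row$target, row$method)
  out$design_id <- id
  out
}

# ---- policy cores ----------------------------------------------------------
# Operate on the pool tables plus a 3 x npairs relation-presence matrix P
# (degrees-of-freedom policy) or a 3 x npairs count matrix m with class size
# E (expectation policy).  RNG is the ambient stream; callers scope it.

unperformed_by_cld <- function(pool, perf) {
  lapply(pool$cld_designs, function(ids) ids[!perf[ids]])
}

sel_fallback <- function(pool, perf) {
  open <- which(!perf)
  if (length(open) == 0L)
    pm_stop("every design in the pool has been performed",
            class = "piecemeal_exhausted")
  pick1(open)
}

suggested_cld_ids <- function(pool, pair_id, codes) {
  pool$clds$cld_id[pool$clds$pair_id == pair_id & pool$clds$code %in% codes]
}

sel_dof_core <- function(P, pool, perf, vars_used) {
  if (all(perf))
    pm_stop("every design in the pool has been performed",
            class = "piecemeal_exhausted")
  n <- colSums(P) - 1L
  open_by_cld <- unperformed_by_cld(pool, perf)
  max_pairs <- which(n == max(n))
  cand_clds <- integer(0)
  for (p in max_pairs) {
    codes <- .SUGGESTION_TABLE[[pattern_key(.RELATIONS[P[, p]])]]
    ids <- suggested_cld_ids(pool, p, codes)
    ids <- ids[vapply(open_by_cld[ids], length, integer(1)) > 0L]
    cand_clds <- c(cand_clds, ids)
  }
  cand_clds <- unique(cand_clds)
  if (length(cand_clds) == 0L) return(sel_fallback(pool, perf))
  # prefer constraint-level designs least represented in P...
  reps <- vapply(pool$cld_designs[cand_clds],
                 function(ids) sum(perf[ids]), integer(1))
  cand_clds <- cand_clds[reps == min(reps)]
  # ...then designs touching variables not previously selected
  fresh <- vapply(cand_clds, function(ci) {
    sum(!(c(pool$clds$a[ci], pool$clds$b[ci]) %in% vars_used))
  }, integer(1))
  cand_clds <- cand_clds[fresh == max(fresh)]
  cld <- pick1(cand_clds)
  pick1(open_by_cld[[cld]])
}

single_relation_codes <- function(relation) {
  switch(relation,
         right = "int_first",
         left = "int_second",
         none = c("int_first", "int_second"))
}

sel_expectation_core <- function(m, E, pool, perf) {
  if (all(perf))
    pm_stop("every design in the pool has been performed",
            class = "piecemeal_exhausted")
  open_by_cld <- unperformed_by_cld(pool, perf)
  reps <- vapply(pool$cld_designs, function(ids) sum(perf[ids]), integer(1))
  e <- (m / E) * (E - m)
  e[m < 1L] <- -Inf
  cand <- which(m >= 1L, arr.ind = TRUE)             # rows: relation, pair
  # descending e; ties shuffled so equal-score tuples are chosen uniformly
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  cand <- cand[order(-e[cand]), , drop = FALSE]
  # first pass: only constraint-level designs with no performed variant yet
  # (a sign variant of an answered design repeats its constraint verbatim
  # and cannot prune the class); second pass: any unperformed variant
  for (pass in 1:2) {
    for (i in seq_len(nrow(cand))) {
      ids <- suggested_cld_ids(pool, cand[i, 2L],
                               single_relation_codes(.RELATIONS[cand[i, 1L]]))
      ids <- ids[vapply(open_by_cld[ids], length, integer(1)) > 0L]
      if (pass == 1L) ids <- ids[reps[ids] == 0L]
      if (length(ids)) {
        cld <- pick1(ids)
        return(pick1(open_by_cld[[cld]]))
      }
    }
  }
  sel_fallback(pool, perf)
}

sel_random_core <- function(pool, perf) sel_fallback(pool, perf)

perf_vector <- function(state, pool) {
  perf <- logical(nrow(pool$designs))
  perf[state$performed] <- TRUE
  perf
}

class_relation_counts <- function(ec, ctx = NULL) {
  vars <- ec$variables
  pool <- design_pool(vars)
  np <- nrow(pool$pairs)
  m <- matrix(0L, 3L, np)
  ctx <- ctx %||% .pm_cache[[paste0("ctx:", paste(vars, collapse = "\r"), ":t")]]
  if (!is.null(ctx) && !is.null(ctx$R) && !is.null(ec$graph_indices)) {
    for (p in seq_len(np)) {
      m[, p] <- tabulate(ctx$R[ec$graph_indices, p], 3L)
    }
  } else {
    for (g in ec$graphs) {
      for (p in seq_len(np)) {
        r <- match(edge_relation(g, c(pool$pairs$a[p], pool$pairs$b[p])),
                   .RELATIONS)
        m[r, p] <- m[r, p] + 1L
      }
    }
  }
  m
}

# ---- public policies -------------------------------------------------------

#' Select the next experiment by degrees of freedom
#'
#' Ranks variable pairs by their remaining degrees of freedom, restricts the
#' max-ranked pairs to those with an unperformed suggested experiment,
#' prefers constraint-level designs least represented among the performed
#' set and then designs touching previously unselected variables, and breaks
#' remaining ties uniformly at random.  If every suggested design of every
#' max-ranked pair has been performed, a uniformly random unperformed design
#' from the full pool is returned instead.
#'
#' @param ec A `pm_equivalence_class`.
#' @param state A `pm_selection_state` over the same variables.
#' @return A `pm_study_design` (with its pool `design_id` attached).
#' @export
select_dof <- function(ec, state) {
  check_class(ec)
  check_state_vars(state, ec$variables)
  pool <- design_pool(state$variables)
  perf <- perf_vector(state, pool)
  P <- class_relation_presence(ec)
  id <- with_seed(state$rng_seed,
                  sel_dof_core(P, pool, perf, state$variables_used))
  design_from_id(id, pool)
}

#' Select the next experiment by expectation
#'
#' For every pair and candidate relation `d` present in the class, computes
#' the expectation score `e = (m / |E|) (|E| - m)` where `m` graphs assign
#' `d` to the pair: the empirical probability of `d` times the number of
#' graphs its confirmation would eliminate.  The highest-scoring
#' (pair, relation) tuple (ties broken at random) is probed with one of the
#' single-relation suggested experiments; bookkeeping and fallback are as in
#' [select_dof()].
#'
#' @inheritParams select_dof
#' @return A `pm_study_design`.
#' @export
select_expectation <- function(ec, state) {
  check_class(ec)
  check_state_vars(state, ec$variables)
  pool <- design_pool(state$variables)
  perf <- perf_vector(state, pool)
  m <- class_relation_counts(ec)
  id <- with_seed(state$rng_seed,
                  sel_expectation_core(m, length(ec$graphs), pool, perf))
  design_from_id(id, pool)
}

#' Select the next experiment uniformly at random
#'
#' @param state A `pm_selection_state`.
#' @return A `pm_study_design` drawn uniformly from the unperformed designs.
#' @export
select_random <- function(state) {
  if (!inherits(state, "pm_selection_state"))
    pm_stop("`state` must be a `pm_selection_state`")
  pool <- design_pool(state$variables)
  perf <- perf_vector(state, pool)
  id <- with_seed(state$rng_seed, sel_random_core(pool, perf))
  design_from_id(id, pool)
}

check_state_vars <- function(state, variables) {
  if (!inherits(state, "pm_selection_state"))
    pm_stop("`state` must be a `pm_selection_state`")
  if (!setequal(state$variables, variables))
    pm_stop("`state` and `ec` must be over the same variables")
  invisible(state)
}
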