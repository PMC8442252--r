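# Equivalence classes under the weighted-constraint optimum and their
# degrees of freedom.
#
# The optimization criterion: over all candidate DAGs G, minimize
#   sum of w(k) over constraints k that G does not imply,
# where a dependence constraint is violated iff the pair is d-separated
# (given C, under the intervention J) and an independence constraint is
# violated iff it is d-connected.  Every DAG attaining the minimum is kept;
# with conflict-free constraints the minimum is zero.

# Enumeration context: cached per variable set.  For four or fewer variables
# it also carries memoized verdict tables over the whole DAG universe:
#   V[g, cld]  dependent verdict of constraint-level design cld in graph g
#   R[g, p]    edge relation (1 right, 2 left, 3 none) of pair p in graph g
# These make class updates and the simulations pure vector operations.
sim_context <- function(variables, tables = length(variables) <= 4L) {
  key <- paste0("ctx:", paste(variables, collapse = "\r"),
                if (tables) ":t" else "")
  cached <- .pm_cache[[key]]
  if (!is.null(cached)) return(cached)
  graphs <- enumerate_dags(variables)
  pool <- design_pool(variables)
  ctx <- list(variables = variables, graphs = graphs, pool = pool,
              encodings = vapply(graphs, dag_encoding, character(1)))
  if (tables) {
    ng <- length(graphs)
    vs <- sort(variables)
    np <- nrow(pool$pairs)
    V <- matrix(FALSE, ng, nrow(pool$clds))
    R <- matrix(0L, ng, np)
    ai <- match(pool$pairs$a, variables)
    bi <- match(pool$pairs$b, variables)
    for (g in seq_len(ng)) {
      adj <- graphs[[g]]$adj
      for (p in seq_len(np)) {
        R[g, p] <- if (adj[ai[p], bi[p]]) 1L else if (adj[bi[p], ai[p]]) 2L else 3L
      }
      for (ci in seq_len(nrow(pool$clds))) {
        cl <- pool$clds[ci, ]
        ji <- if (is.na(cl$intervened)) integer(0) else
          match(cl$intervened, variables)
        V[g, ci] <- !dsep_adj(adj, match(cl$a, variables),
                              match(cl$b, variables), integer(0), ji)
      }
    }
    ctx$V <- V
    ctx$R <- R
  }
  .pm_cache[[key]] <- ctx
  ctx
}

# TRUE iff constraint k can be answered from the memoized verdict tables
is_simple_constraint <- function(k) {
  length(k$cond) == 0L && length(k$intervened) <= 1L &&
    all(k$intervened %in% c(k$x, k$y))
}

simple_cld_id <- function(k, pool) {
  p <- match(paste(k$x, k$y), paste(pool$pairs$a, pool$pairs$b))
  code <- if (length(k$intervened) == 0L) "obs"
    else if (k$intervened == k$x) "int_first" else "int_second"
  pool$clds$cld_id[pool$clds$pair_id == p & pool$clds$code == code]
}

# per-graph violation indicator for one constraint
violation_vector <- function(k, ctx) {
  dep_wanted <- k$polarity == "dep"
  if (!is.null(ctx$V) && is_simple_constraint(k)) {
    dep_actual <- ctx$V[, simple_cld_id(k, ctx$pool)]
  } else {
    vars <- ctx$variables
    xi <- match(k$x, vars); yi <- match(k$y, vars)
    ci <- match(k$cond, vars); ji <- match(k$intervened, vars)
    dep_actual <- !vapply(ctx$graphs,
                          function(g) dsep_adj(g$adj, xi, yi, ci, ji),
                          logical(1))
  }
  dep_actual != dep_wanted
}

#' Compute the equivalence class of a constraint set
#'
#' Enumerates every DAG over `variables`, scores each by the summed weight
#' of the constraints it violates, and returns all DAGs attaining the
#' minimum (ties kept; weights compared with absolute tolerance `tol`).
#' With mutually satisfiable constraints the achieved minimum is zero and
#' the class is exactly the set of consistent DAGs.
#'
#' @param variables Character vector of variable names.
#' @param constraints List of `pm_constraint` (may be empty).  Constraints
#'   may only mention variables in `variables`.
#' @param tol Absolute tolerance for comparing summed weights (default 1e-9).
#' @param max_variables Enumeration capacity guard, as in [enumerate_dags()].
#' @return An object of class `pm_equivalence_class` with fields
#'   `variables`, `graphs` (list of `pm_dag`), `graph_indices` (positions in
#'   the canonical enumeration), `constraints`, and `unsat_weight`.
#' @examples
#' k <- list(parse_constraint("X dep Y"), parse_constraint("Y dep Z"),
#'           parse_constraint("X dep Z"), parse_constraint("X indep Z | Y"))
#' compute_class(c("X", "Y", "Z"), k)   # the 3-graph chain/fork class
#' @export
compute_class <- function(variables, constraints = list(), tol = 1e-9,
                          max_variables = 6L) {
  pm_check_names(variables)
  constraints <- as_constraint_list(constraints)
  extra <- setdiff(unique(unlist(lapply(constraints, constraint_vars))),
                   variables)
  if (length(extra))
    pm_stop(sprintf("constraints mention unknown variable(s): %s",
                    paste(extra, collapse = ", ")))
  ctx <- sim_context_guarded(variables, max_variables)
  ng <- length(ctx$graphs)
  scores <- numeric(ng)
  for (k in constraints) {
    if (k$weight == 0) next
    scores <- scores + k$weight * violation_vector(k, ctx)
  }
  best <- min(scores)
  members <- which(scores <= best + tol)
  structure(list(variables = variables,
                 graphs = ctx$graphs[members],
                 graph_indices = members,
                 constraints = constraints,
                 unsat_weight = best),
            class = "pm_equivalence_class")
}

sim_context_guarded <- function(variables, max_variables = 6L) {
  if (length(variables) > max_variables)
    pm_stop(sprintf(
      "%d variables exceed the enumeration capacity limit of %d",
      length(variables), max_variables), class = "piecemeal_capacity_error")
  sim_context(variables)
}

is_equivalence_class <- function(x) inherits(x, "pm_equivalence_class")

check_class <- function(ec) {
  if (!is_equivalence_class(ec))
    pm_stop("`ec` must be a `pm_equivalence_class` (see `compute_class()`)")
  if (length(ec$graphs) == 0L) pm_stop("the equivalence class is empty")
  invisible(ec)
}

#' @export
print.pm_equivalence_class <- function(x, ...) {
  cat(sprintf(
    "equivalence class: %d graph(s) over %d variable(s) [%s], unsat weight %g\n",
    length(x$graphs), length(x$variables),
    paste(x$variables, collapse = ", "), x$unsat_weight))
  if (length(x$graphs) <= 8L) {
    for (g in x$graphs) cat(" ", format(g), "\n")
  }
  invisible(x)
}

# edge-relation presence per pair across the class: logical matrix 3 x npairs
class_relation_presence <- function(ec, ctx = NULL) {
  vars <- ec$variables
  pool <- design_pool(vars)
  np <- nrow(pool$pairs)
  P <- matrix(FALSE, 3L, np)
  ctx <- ctx %||% .pm_cache[[paste0("ctx:", paste(vars, collapse = "\r"), ":t")]]
  if (!is.null(ctx) && !is.null(ctx$R) && !is.null(ec$graph_indices)) {
    for (p in seq_len(np)) {
      rels <- unique(ctx$R[ec$graph_indices, p])
      P[rels, p] <- TRUE
    }
  } else {
    for (g in ec$graphs) {
      for (p in seq_len(np)) {
        r <- match(edge_relation(g, c(pool$pairs$a[p], pool$pairs$b[p])),
                   .RELATIONS)
        P[r, p] <- TRUE
      }
    }
  }
  P
}

dof_report_from_presence <- function(P, pool) {
  np <- ncol(P)
  keys <- paste(pool$pairs$a, pool$pairs$b, sep = " ~ ")
  per_pair <- lapply(seq_len(np), function(p) .RELATIONS[P[, p]])
  names(per_pair) <- keys
  n <- vapply(per_pair, length, integer(1)) - 1L
  total <- sum(n)
  structure(list(per_pair = per_pair, n = n, total = total,
                 percent_remaining = 100 * total / (2 * np)),
            class = "pm_dof_report")
}

#' Degrees of freedom of an equivalence class
#'
#' For each unordered variable pair, collects the edge relations (`right`,
#' `left`, `none`) realized across the class's graphs; the pair's degrees of
#' freedom is that count minus one (0 when the relation is fixed, at most 2).
#' The total over pairs, as a share of the trivial class's `2 * choose(N, 2)`,
#' quantifies how underdetermined the causal structure still is.
#'
#' @param ec A `pm_equivalence_class`.
#' @return An object of class `pm_dof_report` with fields `per_pair` (named
#'   list of realized relations), `n` (named integer vector), `total`, and
#'   `percent_remaining`.
#' @export
degrees_of_freedom <- function(ec) {
  check_class(ec)
  pool <- design_pool(ec$variables)
  dof_report_from_presence(class_relation_presence(ec), pool)
}

#' @export
print.pm_dof_report <- function(x, ...) {
  cat("degrees of freedom\n")
  for (key in names(x$per_pair)) {
    cat(sprintf("  %-12s n = %d  {%s}\n", key, x$n[[key]],
                paste(x$per_pair[[key]], collapse = ", ")))
  }
  cat(sprintf("  total = %d (%.1f%% of the trivial class remaining)\n",
              x$total, x$percent_remaining))
  if (!is.null(x$n_queries))
    cat(sprintf("  (%d satisfiability queries issued)\n", x$n_queries))
  invisible(x)
}

#' Satisfiability backend over the class of optimal graphs
#'
#' Returns a query function `function(h)` answering whether hypothesis `h`
#' (a `pm_hypothesis`; see [relation_hypothesis()] and
#' [constraint_hypothesis()]) is consistent with at least one graph in the
#' equivalence class of `constraints`.  This exact-enumeration backend is the
#' default behind [dof_via_queries()] and [categorize_hypothesis()]; any
#' drop-in replacement with the same signature (e.g. wrapping an external
#' solver) can be supplied instead.  The class is computed lazily on the
#' first query.
#'
#' @param variables Character vector of variable names.
#' @param constraints List of `pm_constraint` (the knowledge base K).
#' @return A function `function(h) -> logical`.
#' @export
enumeration_backend <- function(variables, constraints = list()) {
  force(variables)
  force(constraints)
  env <- new.env(parent = emptyenv())
  function(h) {
    h <- as_hypothesis(h)
    if (is.null(env$ec)) env$ec <- compute_class(variables, constraints)
    any(vapply(env$ec$graphs, graph_satisfies, logical(1), h = h))
  }
}

#' Degrees of freedom via the satisfiability-query protocol
#'
#' Instead of enumerating the class and scanning it, this issues exactly
#' `3 * choose(N, 2)` satisfiability queries -- one per pair per candidate
#' edge relation, each asking whether K plus the asserted relation is
#' satisfiable -- and assembles the same report as
#' [degrees_of_freedom()] applied to [compute_class()].  The query count is
#' attached as `n_queries`.
#'
#' @param variables Character vector of variable names.
#' @param constraints List of `pm_constraint`; should be conflict-free (with
#'   the default backend, conflicts are resolved by the weighted optimum
#'   first, since queries run against the optimal class).
#' @param backend A query function as produced by [enumeration_backend()]
#'   (the default); any `function(h) -> logical` works, which is how a
#'   plug-in SAT/ASP solver, or a pure query-counting stub for large N,
#'   would be supplied.
#' @return A `pm_dof_report` with an extra `n_queries` field.
#' @export
dof_via_queries <- function(variables, constraints = list(), backend = NULL) {
  pm_check_names(variables)
  constraints <- as_constraint_list(constraints)
  backend <- backend %||% enumeration_backend(variables, constraints)
  pool <- design_pool(variables)
  np <- nrow(pool$pairs)
  P <- matrix(FALSE, 3L, np)
  queries <- 0L
  for (p in seq_len(np)) {
    pair <- c(pool$pairs$a[p], pool$pairs$b[p])
    for (r in seq_along(.RELATIONS)) {
      h <- relation_hypothesis(pair, .RELATIONS[r])
      ans <- backend(h)
      queries <- queries + 1L
      if (!is.logical(ans) || length(ans) != 1L || is.na(ans))
        pm_stop("backend must return a single TRUE/FALSE",
                class = "piecemeal_backend_error")
      P[r, p] <- ans
    }
    if (!any(P[, p]))
      pm_stop(sprintf("backend reports no viable edge relation for pair {%s, %s}",
                      pair[1L], pair[2L]), class = "piecemeal_backend_error")
  }
  rep <- dof_report_from_presence(P, pool)
  rep$n_queries <- queries
  rep
}
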