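# Independent oracles used to validate the package's algorithms.  These are
# deliberately written with different algorithms from the implementation:
# d-separation by brute-force enumeration of all simple undirected paths with
# the collider/non-collider activation rules applied directly, DAG-ness by
# powers of the adjacency matrix, and equivalence classes by re-scoring every
# graph from scratch.

# Brute-force d-separation: TRUE iff no active simple path connects x and y
# given cond, in the graph after deleting edges into intervened variables.
oracle_dsep <- function(g, x, y, cond = character(), intervened = character()) {
  vars <- g$variables
  adj <- g$adj
  if (length(intervened)) adj[, match(intervened, vars)] <- FALSE
  n <- length(vars)
  xi <- match(x, vars)
  yi <- match(y, vars)
  ci <- match(cond, vars)
  # reflexive-transitive descendant closure via matrix powers
  reach <- diag(n) > 0
  repeat {
    new <- reach | ((reach %*% adj) > 0)
    if (identical(new, reach)) break
    reach <- new
  }
  und <- adj | t(adj)
  path_active <- function(path) {
    if (length(path) < 3L) return(TRUE)
    for (k in 2:(length(path) - 1L)) {
      a <- path[k - 1L]; b <- path[k]; cc <- path[k + 1L]
      collider <- adj[a, b] && adj[cc, b]
      if (collider) {
        opened <- length(ci) > 0L && any(reach[b, ci])
        if (!opened) return(FALSE)
      } else {
        if (b %in% ci) return(FALSE)
      }
    }
    TRUE
  }
  found <- FALSE
  dfs <- function(path) {
    if (found) return(invisible())
    v <- path[length(path)]
    if (v == yi) {
      if (path_active(path)) found <<- TRUE
      return(invisible())
    }
    for (w in which(und[v, ])) {
      if (!(w %in% path)) dfs(c(path, w))
    }
    invisible()
  }
  dfs(xi)
  !found
}

# Independent enumeration of all labeled DAGs on <= 3 nodes: every subset of
# ordered pairs, acyclicity checked via traces of adjacency-matrix powers.
oracle_enumerate_dags <- function(variables) {
  n <- length(variables)
  stopifnot(n <= 3L)
  cells <- which(diag(n) == 0, arr.ind = TRUE)
  out <- list()
  for (code in 0:(2^nrow(cells) - 1L)) {
    adj <- matrix(FALSE, n, n)
    bits <- as.integer(intToBits(code))[seq_len(nrow(cells))]
    adj[cells[bits == 1L, , drop = FALSE]] <- TRUE
    a <- adj * 1
    p <- a
    cyclic <- FALSE
    for (k in seq_len(n)) {
      if (sum(diag(p)) > 0) { cyclic <- TRUE; break }
      p <- p %*% a
    }
    if (!cyclic) {
      dimnames(adj) <- list(variables, variables)
      out <- c(out, list(adj))
    }
  }
  out
}

# Independent weighted re-scoring of every candidate graph: the argmin set
# and achieved minimum, using the path oracle for every verdict.
oracle_class <- function(variables, constraints) {
  graphs <- enumerate_dags(variables)
  scores <- vapply(graphs, function(g) {
    s <- 0
    for (k in constraints) {
      dep <- !oracle_dsep(g, k$x, k$y, cond = k$cond, intervened = k$intervened)
      if (dep != (k$polarity == "dep")) s <- s + k$weight
    }
    s
  }, numeric(1))
  list(indices = which(scores <= min(scores) + 1e-9), unsat = min(scores))
}

# Category of a hypothesis by scanning every class graph (independent of the
# two-query protocol).
oracle_categorize <- function(ec, h) {
  sat <- vapply(ec$graphs, piecemeal:::graph_satisfies, logical(1), h = h)
  if (!any(sat)) "none" else if (all(sat)) "all" else "some"
}

# A random conflict-free constraint set: verdicts supplied by an oracle over
# a random true DAG, so the set is always mutually satisfiable.
random_consistent_kb <- function(variables, n_constraints) {
  pool <- piecemeal:::design_pool(variables)
  graphs <- enumerate_dags(variables)
  g <- graphs[[sample.int(length(graphs), 1L)]]
  ids <- sample.int(nrow(pool$designs), n_constraints)
  kb <- lapply(ids, function(id) {
    d <- pool$designs[id, c("source", "target", "method")]
    study_result_to_constraint(d, oracle_verdict(g, d))
  })
  list(true_graph = g, kb = kb)
}

worked_example_kb <- function() {
  list(parse_constraint("X dep Y"), parse_constraint("Y dep Z"),
       parse_constraint("X dep Z"), parse_constraint("X indep Z | Y"))
}
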