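# d-separation under interventions.  Interventions use graph surgery: every
# edge whose head is an intervened variable is deleted before testing, so an
# intervened variable keeps its outgoing edges but loses all incoming ones
# (standard do-operator semantics).  The test itself is the classical
# moralized-ancestral-graph criterion: restrict to the ancestors of
# {x, y} union cond, moralize (marry parents of a common child, drop
# directions), delete the conditioning set, and check whether x and y are
# disconnected in the resulting undirected graph.

#' Test d-separation in a DAG, optionally under interventions
#'
#' @param g A `pm_dag`.
#' @param x,y Two distinct variable names; neither may appear in `cond`.
#' @param cond Character vector of conditioning variables (may be empty).
#' @param intervened Character vector of intervened variables (may be empty,
#'   and may include `x` or `y`).  A variable cannot be both conditioned on
#'   and intervened on in one statement.
#' @return `TRUE` if `x` and `y` are d-separated given `cond` in the
#'   manipulated graph, else `FALSE`.
#' @examples
#' chain <- dag(c("X", "Y", "Z"), list(c("X", "Y"), c("Y", "Z")))
#' d_separated(chain, "X", "Z", cond = "Y")          # TRUE
#' d_separated(chain, "X", "Z", intervened = "X")    # FALSE
#' @export
d_separated <- function(g, x, y, cond = character(), intervened = character()) {
  check_dag(g)
  pm_check_string(x, "x")
  pm_check_string(y, "y")
  cond <- as.character(cond)
  intervened <- as.character(intervened)
  unknown <- setdiff(c(x, y, cond, intervened), g$variables)
  if (length(unknown))
    pm_stop(sprintf("unknown variable(s): %s", paste(unknown, collapse = ", ")))
  if (x == y) pm_stop("`x` and `y` must be distinct")
  if (x %in% cond || y %in% cond)
    pm_stop("`x` and `y` may not appear in the conditioning set")
  if (length(intersect(cond, intervened)))
    pm_stop("a variable cannot be both conditioned on and intervened on")
  dsep_adj(g$adj,
           match(x, g$variables), match(y, g$variables),
           match(cond, g$variables), match(intervened, g$variables))
}

# index-based workhorse, shared with the memoized verdict tables
dsep_adj <- function(adj, xi, yi, ci = integer(0), ji = integer(0)) {
  if (length(ji)) adj[, ji] <- FALSE
  # ancestral closure of {x, y} union cond
  anc <- unique(c(xi, yi, ci))
  repeat {
    parents <- which(rowSums(adj[, anc, drop = FALSE]) > 0)
    new <- setdiff(parents, anc)
    if (length(new) == 0L) break
    anc <- c(anc, new)
  }
  anc <- sort(anc)
  sub <- adj[anc, anc, drop = FALSE]
  und <- sub | t(sub)
  for (v in seq_along(anc)) {
    pa <- which(sub[, v])
    if (length(pa) > 1L) und[pa, pa] <- TRUE
  }
  diag(und) <- FALSE
  keep <- !(anc %in% ci)
  und <- und[keep, keep, drop = FALSE]
  ids <- anc[keep]
  xs <- match(xi, ids)
  ys <- match(yi, ids)
  seen <- logical(length(ids))
  seen[xs] <- TRUE
  frontier <- xs
  while (length(frontier)) {
    nb <- which(colSums(und[frontier, , drop = FALSE]) > 0)
    nb <- nb[!seen[nb]]
    if (length(nb) == 0L) break
    seen[nb] <- TRUE
    frontier <- nb
  }
  !seen[ys]
}
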