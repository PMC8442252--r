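# Hypotheses and their categorization by utility for causal discovery.
#
# A hypothesis is either an (in)dependence constraint or a structural
# assertion about one variable pair.  Structural assertions are represented
# as a non-empty proper subset of the three edge relations the pair may
# take; "edge X -> Y present" is the singleton {right} (or {left}, per the
# canonical pair order) and "no edge between X and Y" is {none}.  Negation
# is set complement for structural bodies and polarity flip for constraint
# bodies, so it is involutive by construction.

#' Construct a structural hypothesis from a relation set
#'
#' @param pair Two distinct variable names (canonicalized by sorting).
#' @param relations Non-empty proper subset of `c("right", "left", "none")`,
#'   read relative to the sorted pair: the hypothesis asserts that the true
#'   graph assigns the pair one of these relations.  The full set is refused
#'   (its negation would be unsatisfiable).
#' @return A `pm_hypothesis`.
#' @seealso [edge_hypothesis()], [no_edge_hypothesis()],
#'   [constraint_hypothesis()]
#' @export
relation_hypothesis <- function(pair, relations) {
  if (!is.character(pair) || length(pair) != 2L || pair[1L] == pair[2L])
    pm_stop("`pair` must be two distinct variable names")
  pm_check_names(pair, "pair")
  relations <- unique(as.character(relations))
  if (!all(relations %in% .RELATIONS))
    pm_stop("`relations` must be drawn from 'right', 'left', 'none'")
  if (length(relations) == 0L || length(relations) == 3L)
    pm_stop("`relations` must be a non-empty proper subset of the three relations")
  structure(list(type = "relation", pair = sort(pair),
                 relations = .RELATIONS[.RELATIONS %in% relations]),
            class = "pm_hypothesis")
}

#' Hypothesis that a directed edge is present
#'
#' @param from,to Tail and head variable names.
#' @return A `pm_hypothesis` asserting the edge `from -> to`.
#' @export
edge_hypothesis <- function(from, to) {
  pair <- sort(c(from, to))
  relation_hypothesis(pair, if (identical(from, pair[1L])) "right" else "left")
}

#' Hypothesis that a pair has no edge in either orientation
#'
#' @param x,y The two variable names.
#' @return A `pm_hypothesis` asserting the relation `none`.
#' @export
no_edge_hypothesis <- function(x, y) relation_hypothesis(c(x, y), "none")

#' Wrap an (in)dependence constraint as a hypothesis
#'
#' @param k A `pm_constraint`.
#' @return A `pm_hypothesis` with a constraint body; its weight is ignored
#'   by categorization.
#' @export
constraint_hypothesis <- function(k) {
  if (!is_constraint(k)) pm_stop("`k` must be a `pm_constraint`")
  structure(list(type = "constraint", constraint = k), class = "pm_hypothesis")
}

as_hypothesis <- function(h) {
  if (inherits(h, "pm_hypothesis")) return(h)
  if (is_constraint(h)) return(constraint_hypothesis(h))
  pm_stop("`h` must be a `pm_hypothesis` or a `pm_constraint`")
}

#' @export
print.pm_hypothesis <- function(x, ...) {
  if (x$type == "constraint") {
    cat("hypothesis:", serialize_constraint(x$constraint), "\n")
  } else {
    cat(sprintf("hypothesis: relation of {%s, %s} in {%s}\n",
                x$pair[1L], x$pair[2L], paste(x$relations, collapse = ", ")))
  }
  invisible(x)
}

#' Negate a hypothesis
#'
#' Constraint bodies flip polarity (same conditioning and intervention
#' sets); structural bodies take the complementary relation set.  Negation
#' is involutive: `negate_hypothesis(negate_hypothesis(h))` equals `h`.
#'
#' @param h A `pm_hypothesis` (or a `pm_constraint`, wrapped implicitly).
#' @return The negated `pm_hypothesis`.
#' @export
negate_hypothesis <- function(h) {
  h <- as_hypothesis(h)
  if (h$type == "constraint") {
    k <- h$constraint
    k$polarity <- if (k$polarity == "dep") "indep" else "dep"
    return(constraint_hypothesis(k))
  }
  relation_hypothesis(h$pair, setdiff(.RELATIONS, h$relations))
}

# does one graph satisfy the hypothesis?
graph_satisfies <- function(g, h) {
  h <- as_hypothesis(h)
  if (h$type == "relation")
    return(edge_relation(g, h$pair) %in% h$relations)
  k <- h$constraint
  dep <- !d_separated(g, k$x, k$y, cond = k$cond, intervened = k$intervened)
  dep == (k$polarity == "dep")
}

#' Categorize a hypothesis by its utility for causal discovery
#'
#' Uses at most two satisfiability queries against the knowledge base K:
#' if K plus the hypothesis is unsatisfiable the category is `"none"` (the
#' hypothesis contradicts every graph in the equivalence class; one query).
#' Otherwise K plus the negation is queried: unsatisfiable means `"all"`
#' (the hypothesis is in the backbone -- it already follows from K, so
#' testing it cannot prune the class), satisfiable means `"some"` (the only
#' category whose test is guaranteed to prune the equivalence class).
#'
#' With the default backend, a knowledge base containing conflicts is first
#' reduced to its weighted-optimal class, against which the queries run.
#'
#' @param variables Character vector of variable names.
#' @param kb List of `pm_constraint` (the knowledge base).
#' @param h A `pm_hypothesis` or `pm_constraint`.
#' @param backend Optional query function; see [enumeration_backend()].
#' @return `"none"`, `"all"`, or `"some"`, with the number of queries used
#'   attached as attribute `"queries"`.
#' @examples
#' k <- list(parse_constraint("X dep Y"), parse_constraint("Y dep Z"),
#'           parse_constraint("X dep Z"), parse_constraint("X indep Z | Y"))
#' categorize_hypothesis(c("X", "Y", "Z"), k, no_edge_hypothesis("X", "Z"))
#' @export
categorize_hypothesis <- function(variables, kb = list(), h, backend = NULL) {
  pm_check_names(variables)
  kb <- as_constraint_list(kb)
  h <- as_hypothesis(h)
  backend <- backend %||% enumeration_backend(variables, kb)
  sat_h <- backend(h)
  if (!sat_h) return(structure("none", queries = 1L))
  sat_neg <- backend(negate_hypothesis(h))
  structure(if (sat_neg) "some" else "all", queries = 2L)
}
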