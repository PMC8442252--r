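# Seed-deterministic synthetic fixtures: a random true DAG, a set of study
# designs answered by the oracle, and the equivalent research-map and
# constraint files.  Because every verdict comes from the oracle, the
# generated constraints are always mutually satisfiable and their
# equivalence class always contains the generating graph.

#' Generate a synthetic piecemeal-discovery fixture
#'
#' Samples a DAG (edges drawn independently, oriented along a random
#' topological order so acyclicity holds by construction), samples
#' `n_studies` designs without replacement from the schema pool, answers
#' each via the oracle, and packages the results as a research map and a
#' constraint list.
#'
#' @param n_vars Number of variables (2..6); variables are named
#'   `LETTERS[1:n_vars]`.
#' @param edge_probability Probability of each (topologically ordered) pair
#'   receiving an edge (default 0.5, making every edge count equally
#'   likely in expectation).
#' @param n_studies Number of study designs to simulate (default: the whole
#'   pool, `4 n (n - 1)`).
#' @param seed Integer seed; the same seed reproduces the fixture exactly,
#'   byte-for-byte after [write_fixture()].
#' @return A list of class `pm_fixture`: `true_graph` (`pm_dag`), `designs`
#'   (data frame with a `verdict` column), `constraints` (list of
#'   `pm_constraint`), and `research_map` (`pm_research_map`).
#' @examples
#' fx <- generate_fixture(n_vars = 3, seed = 7)
#' length(fx$constraints)
#' @export
generate_fixture <- function(n_vars = 4, edge_probability = 0.5,
                             n_studies = NULL, seed = 1L) {
  pm_check_count(n_vars, "n_vars", min = 2)
  if (n_vars > 6) pm_stop("`n_vars` must be between 2 and 6",
                          class = "piecemeal_capacity_error")
  if (!is.numeric(edge_probability) || length(edge_probability) != 1L ||
      is.na(edge_probability) || edge_probability < 0 || edge_probability > 1)
    pm_stop("`edge_probability` must be a probability")
  pm_check_count(seed, "seed")
  variables <- LETTERS[seq_len(n_vars)]
  pool <- design_pool(variables)
  n_studies <- n_studies %||% nrow(pool$designs)
  pm_check_count(n_studies, "n_studies", min = 1)
  if (n_studies > nrow(pool$designs))
    pm_stop(sprintf("`n_studies` exceeds the %d-design pool",
                    nrow(pool$designs)))
  with_seed(seed, {
    ord <- sample(variables)
    edges <- list()
    for (i in seq_len(n_vars - 1L)) {
      for (j in seq.int(i + 1L, n_vars)) {
        if (stats::runif(1) < edge_probability)
          edges <- c(edges, list(c(ord[i], ord[j])))
      }
    }
    g <- dag(variables, edges)
    ids <- sort(sample.int(nrow(pool$designs), n_studies))
    designs <- pool$designs[ids, c("source", "target", "method")]
    rownames(designs) <- NULL
    designs$verdict <- vapply(seq_len(nrow(designs)), function(i) {
      oracle_verdict(g, designs[i, ])
    }, character(1))
    constraints <- lapply(seq_len(nrow(designs)), function(i) {
      study_result_to_constraint(designs[i, c("source", "target", "method")],
                                 designs$verdict[i])
    })
    # group studies into research-map edges by (source, target, verdict);
    # a dependent edge gets a random correlation sign (metadata only)
    key <- paste(designs$source, designs$target, designs$verdict)
    map_edges <- lapply(split(seq_len(nrow(designs)), key), function(rows) {
      verdict <- designs$verdict[rows[1L]]
      relation <- if (verdict == "indep") "independence" else
        sample(c("excitation", "inhibition"), 1L)
      list(source = designs$source[rows[1L]],
           target = designs$target[rows[1L]],
           relation = relation,
           studies = lapply(designs$method[rows],
                            function(mm) list(method = mm)))
    })
    names(map_edges) <- NULL
    map <- structure(list(nodes = variables, edges = map_edges),
                     class = "pm_research_map")
    structure(list(true_graph = g, designs = designs,
                   constraints = constraints, research_map = map,
                   seed = seed),
              class = "pm_fixture")
  })
}

#' Write a fixture's files to a directory
#'
#' Writes `true_graph.txt` (edge-list format), `constraints.json`, and
#' `research_map.json`.  Output is deterministic: the same fixture always
#' produces byte-identical files.
#'
#' @param fixture A `pm_fixture` from [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!inherits(fixture, "pm_fixture"))
    pm_stop("`fixture` must come from `generate_fixture()`")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dag(fixture$true_graph, file.path(dir, "true_graph.txt"))
  write_constraints(fixture$constraints, file.path(dir, "constraints.json"),
                    variables = fixture$true_graph$variables)
  map <- fixture$research_map
  jsonlite::write_json(
    list(nodes = lapply(map$nodes, function(nm) list(name = nm)),
         edges = map$edges),
    file.path(dir, "research_map.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
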