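# Oracle-driven simulation of piecemeal causal discovery.
#
# A run fixes a true DAG, starts from the trivial equivalence class (every
# DAG; no constraints), and repeatedly (1) lets a policy pick the next
# study design from the pool, (2) asks the oracle -- d-separation on the
# true graph, i.e. causal sufficiency plus faithfulness -- for the verdict,
# (3) appends the resulting constraint and recomputes the class, until the
# pool is exhausted (48 steps for four variables).  All class updates use
# the memoized per-(graph, constraint-level design) verdict tables, so a
# step is a handful of vector operations over the DAG universe.

#' Oracle verdict for a study design
#'
#' @param true_graph The true `pm_dag`.
#' @param design A study design.
#' @return `"dep"` if the design's pair is d-connected (given no
#'   conditioning, under the design's intervention) in the true graph,
#'   `"indep"` otherwise.  Deterministic: the same design always yields the
#'   same verdict.
#' @export
oracle_verdict <- function(true_graph, design) {
  check_dag(true_graph)
  cl <- to_constraint_level(design)
  dep <- !d_separated(true_graph, cl$pair[1L], cl$pair[2L],
                      intervened = cl$intervened)
  if (dep) "dep" else "indep"
}

POLICIES <- c("random", "dof", "expectation")

true_graph_index <- function(true_graph, ctx) {
  idx <- match(dag_encoding(true_graph), ctx$encodings)
  if (is.na(idx)) pm_stop("internal: true graph not found in enumeration")
  idx
}

# single simulation run on context tables; the workhorse behind both the
# user-facing trajectory functions and the full study
sim_run <- function(ctx, true_idx, policy, seed, record_hypotheses = FALSE) {
  pool <- ctx$pool
  nd <- nrow(pool$designs)
  np <- nrow(pool$pairs)
  ng <- length(ctx$graphs)
  truth <- ctx$V[true_idx, ]                             # per cld
  viable <- rep(TRUE, ng)
  perf <- logical(nd)
  vars_used <- character(0)
  chosen <- integer(nd)
  class_size <- integer(nd)
  dof_total <- integer(nd)
  if (record_hypotheses) {
    n_none <- integer(nd); n_all <- integer(nd); n_some <- integer(nd)
  }
  set.seed(seed)
  for (step in seq_len(nd)) {
    if (policy == "random") {
      id <- sel_random_core(pool, perf)
    } else {
      m <- matrix(0L, 3L, np)
      for (p in seq_len(np)) m[, p] <- tabulate(ctx$R[viable, p], 3L)
      if (policy == "dof") {
        id <- sel_dof_core(m > 0L, pool, perf, vars_used)
      } else {
        id <- sel_expectation_core(m, sum(viable), pool, perf)
      }
    }
    perf[id] <- TRUE
    vars_used <- unique(c(vars_used, pool$designs$source[id],
                          pool$designs$target[id]))
    cld <- pool$designs$cld_id[id]
    viable <- viable & (ctx$V[, cld] == truth[cld])
    chosen[step] <- id
    class_size[step] <- sum(viable)
    dt <- 0L
    for (p in seq_len(np)) {
      dt <- dt + length(unique(ctx$R[viable, p])) - 1L
    }
    dof_total[step] <- dt
    if (record_hypotheses) {
      open <- which(!perf)
      sat <- vapply(seq_len(ncol(ctx$V)),
                    function(ci) any(viable & ctx$V[, ci]), logical(1))
      sat_neg <- vapply(seq_len(ncol(ctx$V)),
                        function(ci) any(viable & !ctx$V[, ci]), logical(1))
      cat_of <- function(ci) if (!sat[ci]) 1L else if (!sat_neg[ci]) 2L else 3L
      cats <- vapply(pool$designs$cld_id[open], cat_of, integer(1))
      n_none[step] <- sum(cats == 1L)
      n_all[step] <- sum(cats == 2L)
      n_some[step] <- sum(cats == 3L)
    }
  }
  out <- list(chosen = chosen, class_size = class_size, dof_total = dof_total,
              final_viable = which(viable))
  if (record_hypotheses) {
    out$n_none <- n_none; out$n_all <- n_all; out$n_some <- n_some
  }
  out
}

#' Run one oracle-driven simulation
#'
#' @param true_graph The true `pm_dag` (at most 4 variables by default; the
#'   guard can be raised via `max_variables` at a steep cost in time).
#' @param policy `"random"`, `"dof"`, or `"expectation"`.
#' @param seed Integer seed controlling every random choice in the run.
#' @param record_hypotheses If `TRUE`, after each step every hypothesis
#'   implied by a still-unperformed design (its dependence-polarity
#'   constraint) is categorized against the current class and the category
#'   counts are recorded (columns `n_none`, `n_all`, `n_some`).
#' @param max_variables Capacity guard for the verdict tables (default 4).
#' @return A `pm_trajectory`: list with `policy`, `seed`, `true_graph`, and
#'   `records`, a data frame with one row per step (design, class size,
#'   total degrees of freedom, optional category counts).
#' @export
run_simulation <- function(true_graph, policy = c("random", "dof", "expectation"),
                           seed = 1L, record_hypotheses = FALSE,
                           max_variables = 4L) {
  check_dag(true_graph)
  policy <- match.arg(policy)
  pm_check_count(seed, "seed")
  if (length(true_graph$variables) > max_variables)
    pm_stop(sprintf(
      "simulation over %d variables exceeds the capacity limit of %d",
      length(true_graph$variables), max_variables),
      class = "piecemeal_capacity_error")
  ctx <- sim_context(true_graph$variables, tables = TRUE)
  true_idx <- true_graph_index(true_graph, ctx)
  run <- sim_run(ctx, true_idx, policy, seed, record_hypotheses)
  d <- ctx$pool$designs[run$chosen, ]
  records <- data.frame(step = seq_along(run$chosen),
                        source = d$source, target = d$target,
                        method = d$method, design_id = run$chosen,
                        class_size = run$class_size,
                        dof_total = run$dof_total,
                        stringsAsFactors = FALSE)
  if (record_hypotheses) {
    records$n_none <- run$n_none
    records$n_all <- run$n_all
    records$n_some <- run$n_some
  }
  structure(list(policy = policy, seed = seed, true_graph = true_graph,
                 final_class_indices = run$final_viable, records = records),
            class = "pm_trajectory")
}

#' @export
print.pm_trajectory <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "simulation trajectory: policy '%s', %d steps, class %d -> %d graph(s)\n",
    x$policy, nrow(r), r$class_size[1L], r$class_size[nrow(r)]))
  invisible(x)
}

#' Hypothesis-category trajectory of one run
#'
#' Convenience wrapper around [run_simulation()] with
#' `record_hypotheses = TRUE`: after each of the `4 N (N - 1)` steps, the
#' hypotheses implied by the remaining unperformed designs are categorized
#' and counted (the counts always partition the unperformed designs).
#'
#' @inheritParams run_simulation
#' @return A `pm_trajectory` whose records carry `n_none`, `n_all`,
#'   `n_some` columns.
#' @export
run_hypothesis_trajectory <- function(true_graph,
                                      policy = c("dof", "random", "expectation"),
                                      seed = 1L, max_variables = 4L) {
  policy <- match.arg(policy)
  run_simulation(true_graph, policy, seed, record_hypotheses = TRUE,
                 max_variables = max_variables)
}

#' Exhaustive simulation study over every true DAG
#'
#' Repeats [run_simulation()] for every DAG over `variables` as the true
#' graph, with `repetitions` seeded runs each, and aggregates per-run
#' first-passage statistics: the first step at which the class size drops
#' below each threshold, the first step at which it reaches its final
#' (last-step) value, and the final size.  A run that never crosses a
#' threshold contributes the pool size (it has, at that point, performed
#' every design).
#'
#' @param policy `"random"`, `"dof"`, or `"expectation"`.
#' @param repetitions Seeded repetitions per true graph (default 5).
#' @param base_seed Base seed; each run's seed is derived deterministically
#'   from (base seed, graph index, policy, repetition) and recorded.
#' @param variables Variable set (default `c("A", "B", "C", "D")`).
#' @param thresholds Class-size thresholds for first-passage steps
#'   (default `c(50, 10)`).
#' @param graphs Optional integer vector restricting which true-graph
#'   indices (into the canonical enumeration) are simulated; default all.
#' @param record_hypotheses If `TRUE`, hypothesis-category counts are
#'   recorded each step and their per-step means returned as
#'   `mean_categories`.
#' @param max_variables Capacity guard (default 4).
#' @return A `pm_study_summary`: per-run statistics (`runs` data frame), the
#'   per-step mean class size (`mean_size_by_step`), and two flavours of
#'   first-passage summary.  The `curve_first_below_*` / `curve_first_minimum`
#'   fields threshold the averaged class-size curve -- the number of studies
#'   after which the *average* equivalence class has shrunk below a size, or
#'   reached its final (minimum average) value; the `mean_first_*` fields
#'   instead average per-run first-passage steps.  The averaged-curve flavour
#'   is the headline summary (see the methods vignette for why).
#' @export
run_full_study <- function(policy = c("random", "dof", "expectation"),
                           repetitions = 5L, base_seed = 1L,
                           variables = c("A", "B", "C", "D"),
                           thresholds = c(50, 10), graphs = NULL,
                           record_hypotheses = FALSE, max_variables = 4L) {
  policy <- match.arg(policy)
  pm_check_count(repetitions, "repetitions", min = 1)
  pm_check_count(base_seed, "base_seed")
  if (length(variables) > max_variables)
    pm_stop(sprintf(
      "study over %d variables exceeds the capacity limit of %d",
      length(variables), max_variables), class = "piecemeal_capacity_error")
  ctx <- sim_context(variables, tables = TRUE)
  ng <- length(ctx$graphs)
  graphs <- graphs %||% seq_len(ng)
  if (any(graphs < 1L | graphs > ng))
    pm_stop("`graphs` contains indices outside the enumeration")
  repetitions <- as.integer(repetitions)
  policy_id <- match(policy, POLICIES)
  nd <- nrow(ctx$pool$designs)
  nruns <- length(graphs) * repetitions
  runs <- data.frame(graph_index = rep(graphs, each = repetitions),
                     rep = rep(seq_len(repetitions), length(graphs)),
                     seed = NA_integer_, final_size = NA_integer_,
                     first_minimum = NA_integer_,
                     final_class = NA_character_)
  for (thr in thresholds) runs[[paste0("first_below_", thr)]] <- NA_integer_
  size_acc <- numeric(nd)
  cat_acc <- if (record_hypotheses) matrix(0, nd, 3L)
  row <- 0L
  for (gi in graphs) {
    for (rep_i in seq_len(repetitions)) {
      row <- row + 1L
      seed <- derive_seed(base_seed, gi, policy_id, rep_i)
      run <- sim_run(ctx, gi, policy, seed, record_hypotheses)
      sizes <- run$class_size
      runs$seed[row] <- seed
      runs$final_size[row] <- sizes[nd]
      runs$first_minimum[row] <- which(sizes == sizes[nd])[1L]
      runs$final_class[row] <- paste(run$final_viable, collapse = ",")
      for (thr in thresholds) {
        hit <- which(sizes < thr)
        runs[[paste0("first_below_", thr)]][row] <-
          if (length(hit)) hit[1L] else nd
      }
      size_acc <- size_acc + sizes
      if (record_hypotheses)
        cat_acc <- cat_acc + cbind(run$n_none, run$n_all, run$n_some)
    }
  }
  mean_curve <- size_acc / nruns
  out <- list(policy = policy, repetitions = repetitions,
              base_seed = base_seed, variables = variables,
              n_runs = nruns, runs = runs,
              mean_size_by_step = mean_curve,
              mean_final_size = mean(runs$final_size),
              mean_first_minimum = mean(runs$first_minimum),
              curve_first_minimum =
                which(abs(mean_curve - mean_curve[nd]) < 1e-9)[1L])
  for (thr in thresholds) {
    out[[paste0("mean_first_below_", thr)]] <-
      mean(runs[[paste0("first_below_", thr)]])
    hit <- which(mean_curve < thr)
    out[[paste0("curve_first_below_", thr)]] <-
      if (length(hit)) hit[1L] else nd
  }
  if (record_hypotheses) {
    colnames(cat_acc) <- c("n_none", "n_all", "n_some")
    out$mean_categories <- cat_acc / nruns
  }
  structure(out, class = "pm_study_summary")
}

#' @export
print.pm_study_summary <- function(x, ...) {
  cat(sprintf("simulation study: policy '%s', %d true graph(s) x %d rep(s)\n",
              x$policy, length(unique(x$runs$graph_index)), x$repetitions))
  thr_cols <- grep("^curve_first_below_", names(x), value = TRUE)
  for (cn in thr_cols) {
    cat(sprintf("  studies until the average class is < %s graphs: %d\n",
                sub("curve_first_below_", "", cn), x[[cn]]))
  }
  cat(sprintf("  studies until the average class reaches its minimum: %d\n",
              x$curve_first_minimum))
  cat(sprintf("  mean final class size: %.2f\n", x$mean_final_size))
  invisible(x)
}
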