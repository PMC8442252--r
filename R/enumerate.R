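# Counting and exhaustive enumeration of labeled DAGs.

#' Count labeled DAGs on n nodes
#'
#' Evaluates the classical alternating-sign recurrence for the number of
#' labeled directed acyclic graphs,
#' \deqn{D(N) = \sum_{k=1}^{N} (-1)^{k-1} \binom{N}{k} 2^{k(N-k)} D(N-k),}
#' with \eqn{D(0) = 1}, using exact integer arithmetic throughout (the count
#' exceeds what a double can hold exactly from ten nodes on).
#'
#' @param n Number of labeled nodes (a single non-negative integer).
#' @return The exact count: a numeric when exactly representable as a double
#'   (n <= 9), otherwise a decimal character string.
#' @examples
#' count_dags(3)  # 25
#' count_dags(4)  # 543
#' @export
count_dags <- function(n) {
  pm_check_count(n, "n", min = 0)
  n <- as.integer(n)
  tab <- .pm_cache$count_dags %||% list(bi(1))  # tab[[m + 1]] = D(m)
  if (length(tab) < n + 1L) {
    for (m in seq.int(length(tab), n)) {
      acc <- bi_zero()
      for (k in seq_len(m)) {
        term <- bi_mul(bi_mul(bi_binom(m, k), bi_pow2(k * (m - k))),
                       tab[[m - k + 1L]])
        acc <- if (k %% 2L == 1L) bi_add(acc, term) else bi_sub(acc, term)
      }
      tab[[m + 1L]] <- acc
    }
    .pm_cache$count_dags <- tab
  }
  val <- bi_to_double(tab[[n + 1L]])
  if (is.na(val)) bi_to_character(tab[[n + 1L]]) else val
}

#' Enumerate every labeled DAG over a variable set
#'
#' Generates each DAG exactly once by assigning one of the three edge
#' relations (none, right, left) to every variable pair in turn, pruning
#' assignments that would close a directed cycle via an incrementally
#' maintained reachability matrix.  The result is returned sorted by the
#' row-major binary encoding of the adjacency matrix, so the order is
#' deterministic and reproducible.
#'
#' @param variables Character vector of distinct variable names.
#' @param max_variables Capacity guard; enumeration refuses beyond this many
#'   variables (default 6) with a capacity error.  Raise it explicitly at
#'   your own risk: the number of DAGs grows super-exponentially.
#' @return A list of `pm_dag` objects of length `count_dags(length(variables))`.
#' @examples
#' length(enumerate_dags(c("X", "Y", "Z")))  # 25
#' @export
enumerate_dags <- function(variables, max_variables = 6L) {
  pm_check_names(variables)
  n <- length(variables)
  if (n > max_variables)
    pm_stop(sprintf(
      "enumeration over %d variables exceeds the capacity limit of %d",
      n, max_variables), class = "piecemeal_capacity_error")
  key <- paste0("enum:", paste(variables, collapse = "\r"))
  cached <- .pm_cache[[key]]
  if (!is.null(cached)) return(cached)

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  acc <- new.env(parent = emptyenv())
  acc$out <- vector("list", 1024L)
  acc$k <- 0L

  emit <- function(adj) {
    acc$k <- acc$k + 1L
    if (acc$k > length(acc$out)) acc$out <- c(acc$out, vector("list", length(acc$out)))
    acc$out[[acc$k]] <- adj
  }
  recurse <- function(p, adj, reach) {
    if (p > nrow(pairs)) {
      emit(adj)
      return(invisible())
    }
    i <- pairs[p, 1L]
    j <- pairs[p, 2L]
    recurse(p + 1L, adj, reach)                      # no edge
    # i -> j is safe unless j already reaches i
    if (!reach[j, i]) {
      adj2 <- adj
      adj2[i, j] <- TRUE
      recurse(p + 1L, adj2, reach | outer(reach[, i], reach[j, ]))
    }
    if (!reach[i, j]) {
      adj2 <- adj
      adj2[j, i] <- TRUE
      recurse(p + 1L, adj2, reach | outer(reach[, j], reach[i, ]))
    }
    invisible()
  }
  reach0 <- diag(n) > 0
  recurse(1L, matrix(FALSE, n, n), reach0)

  adjs <- acc$out[seq_len(acc$k)]
  enc <- vapply(adjs, function(a) paste(as.integer(t(a)), collapse = ""),
                character(1))
  adjs <- adjs[order(enc, method = "radix")]
  out <- lapply(adjs, function(a) new_dag(variables, a))
  .pm_cache[[key]] <- out
  out
}
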