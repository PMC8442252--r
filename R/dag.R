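# Directed acyclic graphs over named variables.  A `pm_dag` stores the
# variable sequence and a logical adjacency matrix; adj[i, j] = TRUE means
# variables[i] -> variables[j], i.e. i is a Markovian parent of j.

new_dag <- function(variables, adj) {
  dimnames(adj) <- list(variables, variables)
  structure(list(variables = variables, adj = adj), class = "pm_dag")
}

#' Construct a directed acyclic graph
#'
#' @param variables Character vector of distinct variable names.  Names may
#'   not contain whitespace or the characters reserved by the text formats
#'   (`| ; , # : > [ ]`).
#' @param edges Edge set: `NULL` (no edges), a two-column character matrix or
#'   data frame (tail, head), or a list of length-2 character vectors.  An
#'   edge `c("X", "Y")` means X is a direct cause of Y.
#'
#' @return An object of class `pm_dag`.
#' @examples
#' g <- dag(c("X", "Y", "Z"), list(c("X", "Y"), c("Y", "Z")))
#' g
#' @export
dag <- function(variables, edges = NULL) {
  pm_check_names(variables)
  n <- length(variables)
  adj <- matrix(FALSE, n, n)
  if (!is.null(edges)) {
    em <- as_edge_matrix(edges)
    if (nrow(em) > 0L) {
      bad <- !(c(em) %in% variables)
      if (any(bad))
        pm_stop(sprintf("unknown variable(s) in edges: %s",
                        paste(unique(c(em)[bad]), collapse = ", ")))
      if (any(em[, 1L] == em[, 2L]))
        pm_stop("self-loops are not allowed")
      idx <- cbind(match(em[, 1L], variables), match(em[, 2L], variables))
      if (anyDuplicated(idx))
        pm_stop("duplicate edges are not allowed")
      adj[idx] <- TRUE
    }
  }
  if (!is_acyclic_adj(adj))
    pm_stop("edges contain a directed cycle; the graph must be acyclic")
  new_dag(variables, adj)
}

as_edge_matrix <- function(edges) {
  if (is.list(edges) && !is.data.frame(edges)) {
    if (length(edges) == 0L) return(matrix(character(0), 0L, 2L))
    if (!all(vapply(edges, function(e) is.character(e) && length(e) == 2L,
                    logical(1))))
      pm_stop("`edges` list elements must be length-2 character vectors")
    return(do.call(rbind, edges))
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.matrix(edges) && ncol(edges) == 2L) {
    storage.mode(edges) <- "character"
    return(edges)
  }
  pm_stop("`edges` must be NULL, a 2-column matrix/data frame, or a list of pairs")
}

is_acyclic_adj <- function(adj) {
  remaining <- rep(TRUE, ncol(adj))
  indeg <- colSums(adj)
  while (any(remaining)) {
    src <- which(remaining & indeg == 0)
    if (length(src) == 0L) return(FALSE)
    remaining[src] <- FALSE
    indeg <- indeg - colSums(adj[src, , drop = FALSE])
    indeg[!remaining] <- Inf
  }
  TRUE
}

is_dag_obj <- function(x) inherits(x, "pm_dag")

check_dag <- function(g) {
  if (!is_dag_obj(g)) pm_stop("`g` must be a `pm_dag` object (see `dag()`)")
  invisible(g)
}

#' Extract the edge list of a DAG
#'
#' @param g A `pm_dag`.
#' @return A two-column character matrix (tail, head), one row per edge.
#' @export
dag_edges <- function(g) {
  check_dag(g)
  idx <- which(g$adj, arr.ind = TRUE)
  m <- cbind(tail = g$variables[idx[, 1L]], head = g$variables[idx[, 2L]])
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' @export
print.pm_dag <- function(x, ...) {
  em <- dag_edges(x)
  cat(sprintf("DAG over %d variable(s): %s\n", length(x$variables),
              paste(x$variables, collapse = ", ")))
  if (nrow(em) == 0L) {
    cat("  (no edges)\n")
  } else {
    cat(paste0("  ", em[, 1L], " -> ", em[, 2L], collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
format.pm_dag <- function(x, ...) {
  em <- dag_edges(x)
  if (nrow(em) == 0L) "(no edges)" else
    paste(paste0(em[, 1L], " -> ", em[, 2L]), collapse = ", ")
}

# canonical binary encoding of the adjacency matrix, row-major
dag_encoding <- function(g) paste(as.integer(t(g$adj)), collapse = "")

#' Edge relation of a variable pair
#'
#' Reports which of the three DAG edge relations a graph assigns to an
#' unordered pair, relative to the pair's canonical (alphabetically sorted)
#' orientation: `"right"` is first -> second, `"left"` is second -> first,
#' `"none"` is no edge either way.
#'
#' @param g A `pm_dag`.
#' @param pair Character vector of two distinct variable names.
#' @return One of `"right"`, `"left"`, `"none"`.
#' @examples
#' edge_relation(dag(c("X", "Y"), list(c("X", "Y"))), c("Y", "X"))  # "right"
#' @export
edge_relation <- function(g, pair) {
  check_dag(g)
  if (!is.character(pair) || length(pair) != 2L || pair[1L] == pair[2L])
    pm_stop("`pair` must be two distinct variable names")
  if (!all(pair %in% g$variables))
    pm_stop(sprintf("unknown variable(s): %s",
                    paste(setdiff(pair, g$variables), collapse = ", ")))
  pair <- sort(pair)
  a <- match(pair[1L], g$variables)
  b <- match(pair[2L], g$variables)
  if (g$adj[a, b]) "right" else if (g$adj[b, a]) "left" else "none"
}

.RELATIONS <- c("right", "left", "none")

#' Write a DAG to disk
#'
#' Two plain-text formats are supported.  `"edgelist"` writes one line per
#' edge as `TAIL -> HEAD` plus a `NODE name` line for each isolated variable;
#' `"json"` writes `{"variables": [...], "edges": [[tail, head], ...]}`.  The
#' format is inferred from a `.json` extension unless given explicitly.
#'
#' @param g A `pm_dag`.
#' @param path Output file path.
#' @param format `"edgelist"`, `"json"`, or `NULL` to infer from `path`.
#' @return `path`, invisibly.
#' @export
write_dag <- function(g, path, format = NULL) {
  check_dag(g)
  format <- format %||% (if (grepl("\\.json$", path)) "json" else "edgelist")
  if (format == "json") {
    em <- dag_edges(g)
    edges <- lapply(seq_len(nrow(em)), function(i) unname(em[i, ]))
    jsonlite::write_json(list(variables = g$variables, edges = edges),
                         path, auto_unbox = FALSE, pretty = TRUE)
  } else if (format == "edgelist") {
    em <- dag_edges(g)
    isolated <- setdiff(g$variables, unique(c(em)))
    lines <- c(paste("NODE", isolated),
               if (nrow(em)) paste(em[, 1L], "->", em[, 2L]))
    writeLines(lines, path)
  } else {
    pm_stop("`format` must be 'edgelist' or 'json'")
  }
  invisible(path)
}

#' Read a DAG from disk
#'
#' @param path File written by [write_dag()] (either format).
#' @param format `"edgelist"`, `"json"`, or `NULL` to infer from `path`.
#' @return A `pm_dag`.
#' @export
read_dag <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.json$", path)) "json" else "edgelist")
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    vars <- vapply(obj$variables, identity, character(1))
    edges <- lapply(obj$edges, function(e) c(e[[1L]], e[[2L]]))
    return(dag(vars, edges))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  nodes <- character(0)
  edges <- list()
  for (ln in lines) {
    if (startsWith(ln, "NODE ")) {
      nodes <- c(nodes, trimws(sub("^NODE ", "", ln)))
    } else if (grepl("->", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "->", fixed = TRUE)[[1L]])
      if (length(parts) != 2L)
        pm_stop(sprintf("cannot parse edge line: '%s'", ln),
                class = "piecemeal_parse_error")
      edges <- c(edges, list(parts))
    } else {
      pm_stop(sprintf("cannot parse line: '%s'", ln),
              class = "piecemeal_parse_error")
    }
  }
  vars <- unique(c(nodes, unlist(edges)))
  dag(vars, edges)
}
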