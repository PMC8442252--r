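# Interventional (in)dependence constraints, the two-variable study-design
# schema, and conversions between them.
#
# A constraint states "X indep Y | C || J" or its dependence counterpart:
# X and Y were found (in)dependent after conditioning on the set C, in an
# experiment that intervened on the set J.  Study designs are the schema's
# annotation-level unit: an ordered variable pair plus one of four
# methodological symbols -- int_up / int_down (interventions on the source,
# increasing or decreasing it) and obs_up / obs_down (passive observations of
# an increase or decrease).  The direction of change and the sign of a
# correlation are metadata only: both excitatory and inhibitory findings are
# statistical dependence, so the four symbols collapse to three
# constraint-level designs per unordered pair (observe, intervene on one
# side, intervene on the other).

.METHODS <- c("int_up", "int_down", "obs_up", "obs_down")
.POLARITIES <- c("dep", "indep")

#' Construct an (in)dependence constraint
#'
#' @param x,y Two distinct variable names; stored sorted, so the constraint
#'   is canonical in the unordered pair.
#' @param polarity `"dep"` (statistical dependence) or `"indep"`.
#' @param cond Conditioning set C (character, possibly empty); may not
#'   contain `x` or `y`.
#' @param intervened Intervention set J (character, possibly empty); disjoint
#'   from `cond`.
#' @param weight Non-negative confidence weight (default 1).
#' @return An object of class `pm_constraint`.
#' @examples
#' independence_constraint("Z", "X", "indep", cond = "Y")
#' @export
independence_constraint <- function(x, y, polarity = c("dep", "indep"),
                                    cond = character(),
                                    intervened = character(),
                                    weight = 1) {
  pm_check_string(x, "x")
  pm_check_string(y, "y")
  polarity <- match.arg(polarity)
  cond <- sort(unique(as.character(cond)))
  intervened <- sort(unique(as.character(intervened)))
  pm_check_names(unique(c(x, y, cond, intervened)), "constraint variables")
  if (x == y) pm_stop("`x` and `y` must be distinct")
  if (x %in% cond || y %in% cond)
    pm_stop("`x` and `y` may not appear in the conditioning set")
  if (length(intersect(cond, intervened)))
    pm_stop("conditioning and intervention sets must be disjoint")
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) || weight < 0)
    pm_stop("`weight` must be a single non-negative number")
  pr <- sort(c(x, y))
  structure(list(x = pr[1L], y = pr[2L], polarity = polarity, cond = cond,
                 intervened = intervened, weight = as.numeric(weight)),
            class = "pm_constraint")
}

is_constraint <- function(x) inherits(x, "pm_constraint")

#' @export
print.pm_constraint <- function(x, ...) {
  cat(serialize_constraint(x), "\n")
  invisible(x)
}

constraint_vars <- function(k) unique(c(k$x, k$y, k$cond, k$intervened))

# value-equality key; weight included so duplicate detection is literal
constraint_key <- function(k) serialize_constraint(k)

#' Serialize a constraint to the one-line text notation
#'
#' The grammar (one constraint per line, `#` starts a comment) is
#' `<var> ("dep"|"indep") <var> [ "|" C ] [ "||" J ] [ ";" "w=" float ]`,
#' with `C` and `J` comma-separated variable lists.  A weight of 1 is
#' omitted.  [parse_constraint()] inverts this exactly.
#'
#' @param k A `pm_constraint`.
#' @return A single string.
#' @examples
#' serialize_constraint(independence_constraint("X", "Y", "dep", intervened = "X"))
#' @export
serialize_constraint <- function(k) {
  if (!is_constraint(k)) pm_stop("`k` must be a `pm_constraint`")
  out <- paste(k$x, k$polarity, k$y)
  if (length(k$cond)) out <- paste(out, "|", paste(k$cond, collapse = ", "))
  if (length(k$intervened))
    out <- paste(out, "||", paste(k$intervened, collapse = ", "))
  if (k$weight != 1) out <- paste0(out, " ; w=", format(k$weight, digits = 15))
  out
}

#' Parse the one-line constraint notation
#'
#' @param text A single line in the grammar documented at
#'   [serialize_constraint()].
#' @return A `pm_constraint`.
#' @examples
#' parse_constraint("X indep Z | Y")
#' parse_constraint("X dep Y || X ; w=2.5")
#' @export
parse_constraint <- function(text) {
  pm_check_string(text, "text")
  parse_fail <- function(what) {
    pm_stop(sprintf("cannot parse constraint '%s': %s", text, what),
            class = "piecemeal_parse_error")
  }
  body <- sub("#.*$", "", text)
  weight <- 1
  semi <- strsplit(body, ";", fixed = TRUE)[[1L]]
  if (length(semi) > 2L) parse_fail("more than one ';'")
  if (length(semi) == 2L) {
    wtxt <- trimws(semi[2L])
    if (!grepl("^w=", wtxt)) parse_fail("expected 'w=<number>' after ';'")
    weight <- suppressWarnings(as.numeric(sub("^w=", "", wtxt)))
    if (is.na(weight)) parse_fail("weight is not a number")
    body <- semi[1L]
  }
  # split off J (after '||') first, then C (after a single '|')
  jpart <- strsplit(body, "||", fixed = TRUE)[[1L]]
  if (length(jpart) > 2L) parse_fail("more than one '||'")
  intervened <- if (length(jpart) == 2L) split_vars(jpart[2L]) else character()
  body <- jpart[1L]
  cpart <- strsplit(body, "|", fixed = TRUE)[[1L]]
  if (length(cpart) > 2L) parse_fail("more than one '|'")
  cond <- if (length(cpart) == 2L) split_vars(cpart[2L]) else character()
  head <- strsplit(trimws(cpart[1L]), "[[:space:]]+")[[1L]]
  if (length(head) != 3L || !(head[2L] %in% .POLARITIES))
    parse_fail("expected '<var> dep|indep <var>' at the start")
  out <- tryCatch(
    independence_constraint(head[1L], head[3L], head[2L], cond = cond,
                            intervened = intervened, weight = weight),
    piecemeal_error = function(e) parse_fail(conditionMessage(e))
  )
  out
}

split_vars <- function(txt) {
  parts <- trimws(strsplit(txt, ",", fixed = TRUE)[[1L]])
  parts[nzchar(parts)]
}

#' Construct a single two-variable study design
#'
#' @param source,target Distinct variable names; for interventional methods
#'   the intervention acts on `source`.
#' @param method One of `"int_up"`, `"int_down"`, `"obs_up"`, `"obs_down"`.
#' @return An object of class `pm_study_design`.
#' @export
study_design <- function(source, target,
                         method = c("int_up", "int_down", "obs_up", "obs_down")) {
  pm_check_string(source, "source")
  pm_check_string(target, "target")
  method <- match.arg(method)
  if (source == target) pm_stop("`source` and `target` must be distinct")
  pm_check_names(c(source, target), "design variables")
  structure(list(source = source, target = target, method = method),
            class = "pm_study_design")
}

#' @export
print.pm_study_design <- function(x, ...) {
  what <- if (startsWith(x$method, "int")) "intervene on" else "observe"
  cat(sprintf("study design: %s %s, record %s  [%s]\n",
              what, x$source, x$target, x$method))
  invisible(x)
}

#' Enumerate the full study-design pool over a variable set
#'
#' Every ordered pair of distinct variables combined with each of the four
#' methodological symbols, in a fixed deterministic order: `4 N (N - 1)`
#' designs for `N` variables (48 for four).
#'
#' @param variables Character vector of at least two variable names.
#' @return A data frame with columns `source`, `target`, `method`, one row
#'   per design, plus the canonical pair columns `pair_a`, `pair_b` and the
#'   `intervened` column (`NA` for observational designs).
#' @examples
#' nrow(enumerate_study_designs(LETTERS[1:4]))  # 48
#' @export
enumerate_study_designs <- function(variables) {
  pm_check_names(variables)
  if (length(variables) < 2L)
    pm_stop("at least two variables are required")
  pool <- design_pool(variables)
  pool$designs[, c("source", "target", "method", "pair_a", "pair_b",
                   "intervened")]
}

# Internal pool structure shared by selection, simulation and fixtures:
#  $pairs        data frame pair_id, a, b (a < b, lexicographic pair order)
#  $clds         data frame cld_id, pair_id, a, b, code (obs/int_first/
#                int_second), intervened (NA or variable)
#  $designs      data frame design_id, source, target, method, pair_id,
#                cld_id, pair_a, pair_b, intervened
#  $cld_designs  list: design ids per cld_id
design_pool <- function(variables) {
  key <- paste0("pool:", paste(variables, collapse = "\r"))
  cached <- .pm_cache[[key]]
  if (!is.null(cached)) return(cached)
  n <- length(variables)
  vs <- sort(variables)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  pairs <- data.frame(pair_id = seq_len(nrow(idx)),
                      a = vs[idx[, 1L]], b = vs[idx[, 2L]],
                      stringsAsFactors = FALSE)
  clds <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(p) {
    data.frame(pair_id = p, a = pairs$a[p], b = pairs$b[p],
               code = c("obs", "int_first", "int_second"),
               intervened = c(NA_character_, pairs$a[p], pairs$b[p]),
               stringsAsFactors = FALSE)
  }))
  clds$cld_id <- seq_len(nrow(clds))
  ordered <- expand.grid(target = variables, source = variables,
                         stringsAsFactors = FALSE)[, 2:1]
  ordered <- ordered[ordered$source != ordered$target, ]
  ordered <- ordered[order(match(ordered$source, variables),
                           match(ordered$target, variables)), ]
  designs <- do.call(rbind, lapply(seq_len(nrow(ordered)), function(i) {
    data.frame(source = ordered$source[i], target = ordered$target[i],
               method = .METHODS, stringsAsFactors = FALSE)
  }))
  designs$design_id <- seq_len(nrow(designs))
  designs$pair_a <- pmin(designs$source, designs$target)
  designs$pair_b <- pmax(designs$source, designs$target)
  designs$pair_id <- match(paste(designs$pair_a, designs$pair_b),
                           paste(pairs$a, pairs$b))
  designs$intervened <- ifelse(startsWith(designs$method, "int"),
                               designs$source, NA_character_)
  code <- ifelse(is.na(designs$intervened), "obs",
                 ifelse(designs$intervened == designs$pair_a,
                        "int_first", "int_second"))
  designs$cld_id <- clds$cld_id[match(paste(designs$pair_id, code),
                                      paste(clds$pair_id, clds$code))]
  rownames(designs) <- NULL
  cld_designs <- split(designs$design_id, designs$cld_id)
  out <- list(variables = variables, pairs = pairs, clds = clds,
              designs = designs, cld_designs = cld_designs)
  .pm_cache[[key]] <- out
  out
}

#' Collapse a study design to its constraint-level design
#'
#' The four methodological symbols distinguish direction of change only;
#' at the constraint level a design is just its unordered pair plus which
#' side (if any) was intervened on, so each pair has exactly three
#' constraint-level designs and each is hit by 4 observational + 2 + 2
#' interventional study designs.
#'
#' @param d A `pm_study_design` (or a one-row slice of
#'   [enumerate_study_designs()]).
#' @return A list with elements `pair` (sorted character pair) and
#'   `intervened` (character of length 0 or 1), class
#'   `pm_constraint_level_design`.
#' @export
to_constraint_level <- function(d) {
  d <- as_study_design(d)
  pair <- sort(c(d$source, d$target))
  intervened <- if (startsWith(d$method, "int")) d$source else character()
  structure(list(pair = pair, intervened = intervened),
            class = "pm_constraint_level_design")
}

as_study_design <- function(d) {
  if (inherits(d, "pm_study_design")) return(d)
  if (is.data.frame(d) && nrow(d) == 1L &&
      all(c("source", "target", "method") %in% names(d)))
    return(study_design(d$source, d$target, d$method))
  if (is.list(d) && all(c("source", "target", "method") %in% names(d)))
    return(study_design(d$source, d$target, d$method))
  pm_stop("`d` must be a study design")
}

#' @export
print.pm_constraint_level_design <- function(x, ...) {
  j <- if (length(x$intervened)) x$intervened else "{}"
  cat(sprintf("constraint-level design: {%s, %s} || J = %s\n",
              x$pair[1L], x$pair[2L], j))
  invisible(x)
}

#' Turn a study result into a constraint
#'
#' @param d A study design.
#' @param verdict `"dep"` or `"indep"` -- the study's statistical finding
#'   (excitatory and inhibitory correlations are both `"dep"`).
#' @param weight Non-negative constraint weight (default 1); research-map
#'   evidence scores can be supplied here.
#' @return A `pm_constraint` with empty conditioning set and the design's
#'   intervention set.
#' @examples
#' study_result_to_constraint(study_design("X", "Y", "int_up"), "dep")
#' @export
study_result_to_constraint <- function(d, verdict = c("dep", "indep"),
                                       weight = 1) {
  verdict <- match.arg(verdict)
  cl <- to_constraint_level(d)
  independence_constraint(cl$pair[1L], cl$pair[2L], polarity = verdict,
                          cond = character(), intervened = cl$intervened,
                          weight = weight)
}

# ---- constraint files ------------------------------------------------------

as_constraint_list <- function(constraints) {
  if (is_constraint(constraints)) return(list(constraints))
  if (!is.list(constraints) || !all(vapply(constraints, is_constraint, logical(1))))
    pm_stop("`constraints` must be a list of `pm_constraint` objects")
  constraints
}

#' Read constraints from disk
#'
#' Two formats: the one-line text notation (one constraint per line, blank
#' lines and `#` comments ignored) and JSON
#' (`{"variables": [...], "constraints": [{"x", "y", "polarity", "cond",
#' "intervene", "weight"}, ...]}`).  JSON is detected by a `.json` extension
#' or a leading `{`.
#'
#' @param path Input file path.
#' @return A list with elements `variables` (character) and `constraints`
#'   (list of `pm_constraint`).  For text files the variable set is the
#'   union of the names mentioned.
#' @export
read_constraints <- function(path) {
  first <- substr(trimws(paste(readLines(path, n = 1L, warn = FALSE),
                               collapse = "")), 1L, 1L)
  if (grepl("\\.json$", path) || identical(first, "{")) {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    cons <- lapply(obj$constraints, function(k) {
      independence_constraint(
        k$x, k$y, polarity = k$polarity,
        cond = vapply(k$cond %||% list(), identity, character(1)),
        intervened = vapply(k$intervene %||% list(), identity, character(1)),
        weight = k$weight %||% 1)
    })
    vars <- vapply(obj$variables %||% list(), identity, character(1))
    if (length(vars) == 0L)
      vars <- sort(unique(unlist(lapply(cons, constraint_vars))))
    return(list(variables = vars, constraints = cons))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cons <- lapply(lines, parse_constraint)
  list(variables = sort(unique(unlist(lapply(cons, constraint_vars)))),
       constraints = cons)
}

#' Write constraints to disk
#'
#' @param constraints List of `pm_constraint`.
#' @param path Output file path; a `.json` extension selects the JSON form,
#'   anything else the text notation.
#' @param variables Variable set to record in the JSON form; defaults to the
#'   union of the constraints' variables.
#' @return `path`, invisibly.
#' @export
write_constraints <- function(constraints, path, variables = NULL) {
  constraints <- as_constraint_list(constraints)
  if (grepl("\\.json$", path)) {
    variables <- variables %||%
      sort(unique(unlist(lapply(constraints, constraint_vars))))
    obj <- list(
      variables = as.list(variables),
      constraints = lapply(constraints, function(k) {
        list(x = k$x, y = k$y, polarity = k$polarity,
             cond = as.list(k$cond), intervene = as.list(k$intervened),
             weight = k$weight)
      }))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    writeLines(vapply(constraints, serialize_constraint, character(1)), path)
  }
  invisible(path)
}

# ---- research maps ---------------------------------------------------------

#' Read a research-map annotation file
#'
#' Expected JSON schema: `{"nodes": [{"name": ...}], "edges": [{"source",
#' "target", "relation", "studies": [{"method": ...}], "score"}]}` with
#' `relation` one of `"excitation"`, `"inhibition"`, `"independence"` and
#' `method` one of the four schema symbols.
#'
#' @param path Input JSON path.
#' @return The validated research map as a list, class `pm_research_map`.
#' @export
read_research_map <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  validate_research_map(obj)
}

validate_research_map <- function(obj) {
  nodes <- vapply(obj$nodes, function(nd) nd$name %||% nd[[1L]], character(1))
  pm_check_names(nodes, "research map nodes")
  for (e in obj$edges) {
    if (!all(c("source", "target", "relation") %in% names(e)))
      pm_stop("research-map edges need source, target and relation",
              class = "piecemeal_parse_error")
    if (!(e$relation %in% c("excitation", "inhibition", "independence")))
      pm_stop(sprintf("unknown edge relation '%s'", e$relation),
              class = "piecemeal_parse_error")
    if (!all(c(e$source, e$target) %in% nodes))
      pm_stop("research-map edge mentions an undeclared node",
              class = "piecemeal_parse_error")
    for (s in e$studies %||% list()) {
      if (!(s$method %in% .METHODS))
        pm_stop(sprintf("unknown study method '%s'", s$method),
                class = "piecemeal_parse_error")
    }
  }
  structure(list(nodes = nodes, edges = obj$edges), class = "pm_research_map")
}

#' Convert a research map to constraints
#'
#' Emits one constraint per annotated study: the edge's relation gives the
#' verdict (excitation and inhibition both mean dependence), the study's
#' method gives the intervention set, and the edge's evidence score (when
#' present) becomes the constraint weight.
#'
#' @param map A `pm_research_map` (see [read_research_map()]).
#' @return A list of `pm_constraint`.
#' @export
research_map_to_constraints <- function(map) {
  if (!inherits(map, "pm_research_map"))
    pm_stop("`map` must be a `pm_research_map`")
  out <- list()
  for (e in map$edges) {
    verdict <- if (e$relation == "independence") "indep" else "dep"
    w <- e$score %||% 1
    for (s in e$studies %||% list()) {
      d <- study_design(e$source, e$target, s$method)
      out <- c(out, list(study_result_to_constraint(d, verdict, weight = w)))
    }
  }
  out
}
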