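# DAG representation, counting, enumeration, d-separation.

test_that("the DAG-count recurrence reproduces the known sequence exactly", {
  expect_identical(count_dags(0), 1)
  expect_identical(count_dags(1), 1)
  expect_identical(count_dags(2), 3)
  expect_identical(count_dags(3), 25)
  expect_identical(count_dags(4), 543)
  expect_identical(count_dags(7), 1138779265)
  # beyond double precision the exact decimal expansion is returned;
  # expected strings computed independently with arbitrary-precision
  # integer arithmetic
  expect_identical(count_dags(10), "4175098976430598143")
  expect_identical(count_dags(14), "1439428141044398334941790719839535103")
  expect_error(count_dags(-1), class = "piecemeal_argument_error")
  expect_error(count_dags(2.5), class = "piecemeal_argument_error")
})

test_that("enumeration is exhaustive, duplicate-free and deterministic", {
  for (n in 1:4) {
    vars <- LETTERS[seq_len(n)]
    graphs <- enumerate_dags(vars)
    expect_length(graphs, count_dags(n))
    encs <- vapply(graphs, piecemeal:::dag_encoding, character(1))
    expect_false(anyDuplicated(encs) > 0)
    expect_identical(encs, sort(encs))  # canonical lexicographic order
  }
  # first graph in canonical order is always the empty graph
  expect_identical(nrow(dag_edges(enumerate_dags(LETTERS[1:3])[[1]])), 0L)
  expect_error(enumerate_dags(LETTERS[1:7]),
               class = "piecemeal_capacity_error")
})

test_that("enumeration agrees with an independent subset-based enumerator", {
  vars <- c("X", "Y", "Z")
  mine <- enumerate_dags(vars)
  ref <- oracle_enumerate_dags(vars)
  expect_length(mine, length(ref))
  enc <- function(a) paste(as.integer(t(a)), collapse = "")
  expect_setequal(vapply(mine, function(g) enc(g$adj), character(1)),
                  vapply(ref, enc, character(1)))
})

test_that("dag() validates its inputs", {
  expect_error(dag(c("A", "A")), class = "piecemeal_argument_error")
  expect_error(dag(c("A", "B"), list(c("A", "A"))),
               class = "piecemeal_argument_error")
  expect_error(dag(c("A", "B"), list(c("A", "B"), c("A", "B"))),
               class = "piecemeal_argument_error")
  expect_error(dag(c("A", "B"), list(c("A", "C"))),
               class = "piecemeal_argument_error")
  expect_error(dag(c("A", "B", "C"),
                   list(c("A", "B"), c("B", "C"), c("C", "A"))),
               class = "piecemeal_argument_error")
  expect_error(dag(c("A|B", "C")), class = "piecemeal_argument_error")
})

test_that("edge_relation reports relative to the sorted pair", {
  g <- dag(c("X", "Y"), list(c("X", "Y")))
  expect_identical(edge_relation(g, c("X", "Y")), "right")
  expect_identical(edge_relation(g, c("Y", "X")), "right")
  expect_identical(edge_relation(dag(c("X", "Y"), list(c("Y", "X"))),
                                 c("X", "Y")), "left")
  expect_identical(edge_relation(dag(c("X", "Y")), c("X", "Y")), "none")
  expect_error(edge_relation(g, c("X", "Q")),
               class = "piecemeal_argument_error")
})

test_that("d-separation matches its textbook examples", {
  chain <- dag(c("X", "Y", "Z"), list(c("X", "Y"), c("Y", "Z")))
  collider <- dag(c("X", "Y", "Z"), list(c("X", "Y"), c("Z", "Y")))
  expect_true(d_separated(chain, "X", "Z", cond = "Y"))
  expect_false(d_separated(chain, "X", "Z"))
  expect_false(d_separated(collider, "X", "Z", cond = "Y"))
  expect_true(d_separated(collider, "X", "Z"))
  # surgery: intervening on X removes the only edge (whose head is X)
  g <- dag(c("X", "Y"), list(c("Y", "X")))
  expect_true(d_separated(g, "X", "Y", intervened = "X"))
  expect_false(d_separated(g, "X", "Y"))
  # argument validation
  expect_error(d_separated(chain, "X", "X"), class = "piecemeal_argument_error")
  expect_error(d_separated(chain, "X", "Y", cond = "X"),
               class = "piecemeal_argument_error")
  expect_error(d_separated(chain, "X", "Z", cond = "Y", intervened = "Y"),
               class = "piecemeal_argument_error")
  expect_error(d_separated(chain, "X", "Q"), class = "piecemeal_argument_error")
})

test_that("d-separation agrees with the path-enumeration oracle on every
           3-variable DAG and query", {
  vars <- c("X", "Y", "Z")
  graphs <- enumerate_dags(vars)
  pairs <- list(c("X", "Y"), c("X", "Z"), c("Y", "Z"))
  for (g in graphs) {
    for (pr in pairs) {
      third <- setdiff(vars, pr)
      for (cond in list(character(), third)) {
        free <- setdiff(vars, cond)
        for (ji in 0:(2^length(free) - 1L)) {
          intervened <- free[as.logical(intToBits(ji))[seq_along(free)]]
          expect_identical(
            d_separated(g, pr[1], pr[2], cond, intervened),
            oracle_dsep(g, pr[1], pr[2], cond, intervened),
            info = sprintf("g={%s} pair=%s,%s cond=%s J=%s", format(g),
                           pr[1], pr[2], paste(cond, collapse = ""),
                           paste(intervened, collapse = ",")))
        }
      }
    }
  }
})

test_that("d-separation is symmetric and interventions on x never create
           dependence", {
  set.seed(11)
  graphs <- enumerate_dags(LETTERS[1:4])
  for (i in sample.int(length(graphs), 60)) {
    g <- graphs[[i]]
    pr <- sample(g$variables, 2)
    cond <- setdiff(g$variables, pr)[sample.int(3, 1) - 1]
    expect_identical(d_separated(g, pr[1], pr[2], cond),
                     d_separated(g, pr[2], pr[1], cond))
    if (d_separated(g, pr[1], pr[2])) {
      expect_true(d_separated(g, pr[1], pr[2], intervened = pr[1]))
    }
  }
})

test_that("DAG serialization round-trips in both formats", {
  g <- dag(c("A", "B", "C", "D"),
           list(c("A", "B"), c("C", "B")))
  for (fmt in c("edgelist", "json")) {
    path <- tempfile(fileext = if (fmt == "json") ".json" else ".txt")
    write_dag(g, path, format = fmt)
    g2 <- read_dag(path, format = fmt)
    expect_setequal(g2$variables, g$variables)
    expect_identical(
      piecemeal:::dag_encoding(dag(g$variables, dag_edges(g2))),
      piecemeal:::dag_encoding(g))
    unlink(path)
  }
})
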