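# Suggestion table and the three selection policies.

test_that("the suggestion table discriminates remaining relations and never
           intervenes on the effect-side variable", {
  s <- suggested_experiments(c("X", "Y"), c("right", "none"))
  expect_setequal(s$code, c("int_first", "obs"))
  expect_false("Y" %in% s$intervened)  # never intervene on the putative effect
  s <- suggested_experiments(c("X", "Y"), c("left", "none"))
  expect_setequal(s$code, c("int_second", "obs"))
  expect_false("X" %in% s$intervened)
  expect_setequal(suggested_experiments(c("X", "Y"), c("right", "left"))$code,
                  c("int_first", "int_second"))
  expect_setequal(
    suggested_experiments(c("X", "Y"), c("right", "left", "none"))$code,
    c("int_first", "int_second"))
  expect_identical(suggested_experiments(c("X", "Y"), "right")$code,
                   "int_first")
  expect_identical(suggested_experiments(c("X", "Y"), "left")$code,
                   "int_second")
  expect_setequal(suggested_experiments(c("X", "Y"), "none")$code,
                  c("int_first", "int_second"))
  expect_error(suggested_experiments(c("X", "Y"), character()),
               class = "piecemeal_argument_error")
})

test_that("on the trivial class the DoF policy proposes interventions and,
           over many seeds, reaches every pair", {
  vars <- LETTERS[1:4]
  ec <- compute_class(vars, list())
  pairs_seen <- character(0)
  for (s in 1:200) {
    d <- select_dof(ec, selection_state(vars, seed = s))
    expect_true(startsWith(d$method, "int"))  # all-three patterns: interventions
    pairs_seen <- c(pairs_seen, paste(sort(c(d$source, d$target)),
                                      collapse = "~"))
  }
  expect_length(unique(pairs_seen), 6)
})

test_that("the DoF policy never proposes the excluded intervention for an
           {edge, none} pattern", {
  vars <- c("X", "Y", "Z")
  # pin down everything except the {X, Y} pair, whose pattern is {right, none}
  kb <- list(parse_constraint("X indep Z"), parse_constraint("X indep Z || X"),
             parse_constraint("X indep Z || Z"),
             parse_constraint("Y indep Z"), parse_constraint("Y indep Z || Y"),
             parse_constraint("Y indep Z || Z"),
             parse_constraint("X indep Y || Y"))
  ec <- compute_class(vars, kb)
  rels <- sort(unique(vapply(ec$graphs, edge_relation, character(1),
                             pair = c("X", "Y"))))
  expect_identical(rels, c("none", "right"))
  for (s in 1:100) {
    d <- select_dof(ec, selection_state(vars, seed = s))
    expect_identical(paste(sort(c(d$source, d$target)), collapse = ""), "XY")
    if (startsWith(d$method, "int")) expect_identical(d$source, "X")
  }
})

test_that("expectation scores are the m/(|E|) (|E| - m) parabola and
           partition the class", {
  ec <- compute_class(c("X", "Y", "Z"), worked_example_kb())
  m <- piecemeal:::class_relation_counts(ec)
  expect_true(all(colSums(m) == length(ec$graphs)))
  pool <- piecemeal:::design_pool(c("X", "Y", "Z"))
  p_xy <- which(pool$pairs$a == "X" & pool$pairs$b == "Y")
  E <- length(ec$graphs)
  e <- (m[, p_xy] / E) * (E - m[, p_xy])
  # in the worked class, pair {X,Y} splits 1 right / 2 left
  expect_equal(e[1], 2 / 3, tolerance = 1e-12)
  expect_equal(e[2], 2 / 3, tolerance = 1e-12)
  expect_identical(e[3], 0)
  expect_true(all(e <= E / 4 + 1e-12))
})

test_that("the expectation policy ignores zero-reward relations and probes a
           max-e pair", {
  vars <- c("X", "Y", "Z")
  ec <- compute_class(vars, worked_example_kb())
  # {X,Z} is fixed at none (m = |E|, e = 0); only the two oriented pairs
  # carry positive expectation
  for (s in 1:60) {
    d <- select_expectation(ec, selection_state(vars, seed = s))
    pair <- paste(sort(c(d$source, d$target)), collapse = "")
    expect_true(pair %in% c("XY", "YZ"))
    expect_true(startsWith(d$method, "int"))
  }
})

test_that("policies are pure functions of (class, state, seed) and never
           repeat a performed design", {
  vars <- LETTERS[1:4]
  ec <- compute_class(vars, list())
  st <- selection_state(vars, seed = 123)
  expect_identical(select_dof(ec, st), select_dof(ec, st))
  expect_identical(select_expectation(ec, st), select_expectation(ec, st))
  expect_identical(select_random(st), select_random(st))
  # exhaust the pool with the random policy: no repeats, then exhaustion
  st <- selection_state(vars, seed = 5)
  seen <- character(0)
  for (i in 1:48) {
    d <- select_random(st)
    key <- paste(d$source, d$target, d$method)
    expect_false(key %in% seen)
    seen <- c(seen, key)
    st <- state_after(st, d)
    st$rng_seed <- st$rng_seed + 1L
  }
  expect_error(select_random(st), class = "piecemeal_exhausted")
  expect_error(select_dof(ec, st), class = "piecemeal_exhausted")
})

test_that("the random policy is uniform over unperformed designs", {
  vars <- c("X", "Y")
  pool_n <- 8L
  counts <- integer(pool_n)
  for (s in 1:2000) {
    d <- select_random(selection_state(vars, seed = s))
    counts[d$design_id] <- counts[d$design_id] + 1L
  }
  expect_true(all(counts > 0))
  # loose binomial band around 2000/8 = 250
  expect_true(all(abs(counts - 250) < 5 * sqrt(2000 * (1 / 8) * (7 / 8))))
  # forced single remaining design
  st <- selection_state(vars, performed = 1:7, seed = 1)
  expect_identical(select_random(st)$design_id, 8L)
})

test_that("when every suggested design is exhausted the policies fall back to
           the unperformed pool", {
  vars <- c("X", "Y")
  kb <- list(parse_constraint("X indep Y || Y"), parse_constraint("X dep Y"))
  ec <- compute_class(vars, kb)          # single relation: right
  pool <- piecemeal:::design_pool(vars)
  # perform both sign variants of the only suggested cld (intervene on X)
  sugg <- pool$designs$design_id[!is.na(pool$designs$intervened) &
                                   pool$designs$intervened == "X"]
  st <- selection_state(vars, performed = sugg, seed = 9)
  d <- select_dof(ec, st)
  expect_false(d$design_id %in% sugg)
})
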