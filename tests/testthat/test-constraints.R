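# Constraint model, study-design schema, text/JSON formats, research maps.

test_that("the study-design pool has 4 N (N-1) designs", {
  expect_identical(nrow(enumerate_study_designs(c("X", "Y"))), 8L)
  expect_identical(nrow(enumerate_study_designs(c("X", "Y", "Z"))), 24L)
  expect_identical(nrow(enumerate_study_designs(LETTERS[1:4])), 48L)
  d <- enumerate_study_designs(LETTERS[1:4])
  expect_false(anyDuplicated(paste(d$source, d$target, d$method)) > 0)
  expect_error(enumerate_study_designs("X"), class = "piecemeal_argument_error")
})

test_that("study designs collapse onto 3 C(N,2) constraint-level designs with
           multiplicity 4 + 2 + 2 per pair", {
  for (vars in list(c("X", "Y"), c("X", "Y", "Z"), LETTERS[1:4])) {
    d <- enumerate_study_designs(vars)
    cl <- lapply(seq_len(nrow(d)), function(i) to_constraint_level(d[i, ]))
    key <- vapply(cl, function(x) {
      paste(x$pair[1], x$pair[2], paste(x$intervened, collapse = ""))
    }, character(1))
    np <- as.integer(choose(length(vars), 2))
    expect_identical(length(unique(key)), 3L * np)
    counts <- table(key)
    # per pair: 4 observational variants, 2 per intervened side
    obs_keys <- !grepl("[A-Z]$", sub("^\\S+ \\S+ ?", "", key))
    expect_true(all(counts[unique(key[obs_keys])] == 4L))
    expect_true(all(counts[unique(key[!obs_keys])] == 2L))
  }
})

test_that("to_constraint_level maps interventions onto the source variable", {
  cl <- to_constraint_level(study_design("X", "Y", "int_up"))
  expect_identical(cl$pair, c("X", "Y"))
  expect_identical(cl$intervened, "X")
  cl <- to_constraint_level(study_design("Y", "X", "obs_down"))
  expect_identical(cl$pair, c("X", "Y"))
  expect_length(cl$intervened, 0)
  cl <- to_constraint_level(study_design("Y", "X", "int_down"))
  expect_identical(cl$intervened, "Y")
})

test_that("study results become constraints with the design's J and the
           verdict's polarity", {
  k <- study_result_to_constraint(study_design("X", "Y", "int_up"), "dep")
  expect_identical(serialize_constraint(k), "X dep Y || X")
  k <- study_result_to_constraint(study_design("X", "Y", "obs_up"), "indep")
  expect_identical(serialize_constraint(k), "X indep Y")
  expect_error(
    study_result_to_constraint(study_design("X", "Y", "obs_up"), "dep", -1),
    class = "piecemeal_argument_error")
})

test_that("constraint text notation parses and round-trips", {
  k <- parse_constraint("X indep Z | Y")
  expect_identical(k$polarity, "indep")
  expect_identical(k$cond, "Y")
  expect_length(k$intervened, 0)
  k <- parse_constraint("X dep Y || X ; w=2.5")
  expect_identical(k$polarity, "dep")
  expect_identical(k$intervened, "X")
  expect_identical(k$weight, 2.5)
  # canonicalization sorts the pair
  expect_identical(serialize_constraint(parse_constraint("Z dep A")),
                   "A dep Z")
  expect_error(parse_constraint("X dep X"), class = "piecemeal_parse_error")
  expect_error(parse_constraint("X foo Y"), class = "piecemeal_parse_error")
  expect_error(parse_constraint("X dep Y ; weight=2"),
               class = "piecemeal_parse_error")
})

test_that("parsing is total on serializer output (fuzzed round-trip)", {
  set.seed(42)
  vars <- c("Alpha", "B2", "Gamma", "D")
  for (i in 1:200) {
    pr <- sample(vars, 2)
    rest <- setdiff(vars, pr)
    cond <- rest[stats::runif(length(rest)) < 0.4]
    j <- setdiff(c(pr, rest), cond)[stats::runif(4 - length(cond)) < 0.3]
    j <- intersect(j, c(pr, rest))
    k <- independence_constraint(pr[1], pr[2],
                                 sample(c("dep", "indep"), 1),
                                 cond = cond, intervened = j,
                                 weight = sample(c(1, 0.5, 2, 3.25), 1))
    k2 <- parse_constraint(serialize_constraint(k))
    expect_identical(k2, k)
  }
})

test_that("constraint JSON files round-trip", {
  kb <- worked_example_kb()
  path <- tempfile(fileext = ".json")
  write_constraints(kb, path, variables = c("X", "Y", "Z"))
  got <- read_constraints(path)
  expect_identical(got$variables, c("X", "Y", "Z"))
  expect_identical(got$constraints, kb)
  # text format too
  path2 <- tempfile(fileext = ".txt")
  write_constraints(kb, path2)
  got2 <- read_constraints(path2)
  expect_identical(got2$constraints, kb)
  unlink(c(path, path2))
})

test_that("research maps convert to one constraint per study, collapsing
           correlation sign to dependence", {
  map <- piecemeal:::validate_research_map(list(
    nodes = list(list(name = "LTP"), list(name = "learning")),
    edges = list(
      list(source = "LTP", target = "learning", relation = "excitation",
           studies = list(list(method = "int_up"),
                          list(method = "obs_down")),
           score = 0.8),
      list(source = "learning", target = "LTP", relation = "inhibition",
           studies = list(list(method = "int_down"))),
      list(source = "LTP", target = "learning", relation = "independence",
           studies = list(list(method = "obs_up"))))))
  kb <- research_map_to_constraints(map)
  expect_length(kb, 4)
  expect_identical(vapply(kb, function(k) k$polarity, character(1)),
                   c("dep", "dep", "dep", "indep"))
  expect_identical(kb[[1]]$intervened, "LTP")
  expect_identical(kb[[1]]$weight, 0.8)
  expect_length(kb[[2]]$intervened, 0)
  expect_identical(kb[[3]]$intervened, "learning")
})
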