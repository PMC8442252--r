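---
title: "Piecemeal causal discovery: model, policies, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecemeal causal discovery: model, policies, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In much of molecular and cellular biology, no single experiment observes a
whole system.  A study intervenes on one phenomenon and records another, or
passively observes two of them, and the literature accumulates as a pile of
two-variable results.  *Piecemeal causal discovery* asks what such a pile
implies about the causal structure of the whole system, and — just as
importantly — which experiment to run next.

`piecemeal` models the system as a causal directed acyclic graph (DAG)
$G = (\mathbf{V}, \mathbf{D})$: an edge $X \to Y$ means $X$ is a direct
cause (Markovian parent) of $Y$.  Each reported result is encoded as a
constraint

$$X \perp\!\!\!\perp Y \mid \mathbf{C} \;\|\; \mathbf{J}
\qquad\text{or}\qquad
X \not\perp\!\!\!\perp Y \mid \mathbf{C} \;\|\; \mathbf{J},$$

read as: $X$ and $Y$ were found (in)dependent after conditioning on
$\mathbf{C}$, in an experiment intervening on $\mathbf{J}$.  The bridge from
statistics to structure is d-separation under the causal Markov and
faithfulness conditions; an intervention is graph surgery — every edge
pointing *into* an intervened variable is deleted before the d-separation
test, which is why intervening on the putative effect of an edge destroys
exactly the dependence that would have revealed it.

## Equivalence classes and the weighted optimum

Evidence can conflict.  Given constraints $\mathbf{K}$ with non-negative
weights $w(k)$, the package searches for

$$G^* \in \arg\min_{G} \sum_{k \in \mathbf{K} :\, G \not\models k} w(k),$$

i.e. the DAGs minimizing the summed weight of unsatisfied constraints.  All
optima are kept (ties matter: they *are* the residual ambiguity), and the
achieved minimum is reported as `unsat_weight`.  With mutually satisfiable
constraints the minimum is zero and the class is the familiar set of
consistent graphs.  `compute_class()` implements this by exhaustive
enumeration — exact and, for the four-to-five-variable systems this tool
targets, fast, since per-graph verdicts for the two-variable constraint
schema are memoized as bit tables over the whole DAG universe (543 graphs
at $N = 4$).  The satisfiability interface behind `dof_via_queries()` and
`categorize_hypothesis()` is deliberately a plain function
`function(hypothesis) -> logical`, so an external SAT/ASP solver could be
plugged in without touching any calling code; the enumeration backend then
doubles as its test oracle.

Weights are compared with an absolute tolerance of `1e-9` when collecting
the argmin set, so floating-point weight sums cannot split exact ties.

## Degrees of freedom

Between any two variables a DAG realizes exactly one of three edge
relations: $X \to Y$, $X \leftarrow Y$, or no edge.  For each pair, the
class realizes between one and three of them; the pair's *degrees of
freedom* $n_{X,Y}$ is that count minus one, and the class total
$\sum n_{X,Y}$ (out of $2\binom{N}{2}$ for the trivial class) quantifies
how underdetermined the structure still is.  The count-minus-one reading is
forced by two facts: $n_{X,Y} \le 2$, and the canonical three-variable
example (three dependence statements plus one conditional independence,
yielding the chain/reversed-chain/fork class) totals exactly two degrees of
freedom, about 33% of the trivial six.

`degrees_of_freedom()` scans the computed class; `dof_via_queries()`
instead issues exactly $3\binom{N}{2}$ satisfiability queries (one per pair
per asserted relation) and never enumerates — 18 queries at $N = 4$, 273 at
$N = 14$.  Both paths must agree; the test suite checks them against each
other on randomized conflict-free constraint sets.

## Selecting the next experiment

The study-design pool mirrors the research-map annotation schema: every
ordered pair combined with one of four methodological symbols (intervene
up/down on the source, observe an increase/decrease), $4N(N-1)$ designs in
all — 48 for four variables.  Direction of change and correlation sign are
metadata; at the constraint level each unordered pair has three designs
(observe, intervene on either side), so the 48 collapse onto
$3\binom{4}{2} = 18$ distinct constraints.

A suggestion table maps each pair's remaining-relation pattern to the
designs able to discriminate it.  Its one non-obvious row is the exclusion
rule: for the pattern $\{X \to Y,\ X \dots Y\}$ an intervention on $Y$ is
never suggested, because deleting the edges into $Y$ makes the two
candidates generate identical verdicts.  Two rows were genuinely open
design choices, documented here rather than decided silently:

* a pair fixed at *no edge* maps to both interventions rather than an
  observation — inside a larger system observational dependence can arise
  from confounding paths elsewhere, so interventional verdicts are the
  cleaner probe of edge absence;
* for single-relation patterns the mirror rule applies (single
  $X \to Y$ probes by intervening on $X$, etc.).

**Degrees-of-freedom policy** (`select_dof()`): rank pairs by $n_{X,Y}$;
among the top-ranked pairs keep those with an unperformed suggested design;
prefer constraint-level designs least represented among performed designs,
then designs touching variables not yet selected; break remaining ties
uniformly at random.  If every suggested design of every top-ranked pair is
exhausted, fall back to a uniformly random unperformed design.

**Expectation policy** (`select_expectation()`): for each pair and relation
$d$ realized by $m$ of the $|E|$ class graphs, score

$$e = \frac{m}{|E|}\,(|E| - m),$$

the empirical probability of $d$ times the number of graphs its
confirmation would eliminate ($e$ peaks at $m = |E|/2$ and vanishes for
relations that are impossible or already certain).  The policy walks down
the $e$-ranking (ties shuffled) and probes the first tuple offering a
suggested design whose constraint-level verdict is not yet known; only if
every candidate's constraint is already answered does it accept a sign
variant of an answered one, and only with nothing suggested at all does it
fall back to the random pool.  The strict preference for unanswered
constraint-level designs is the package's reading of the policy's
bookkeeping requirement that experiments not be repeated unnecessarily: a
sign variant of an answered design contributes a verbatim-duplicate
constraint and cannot prune the class, and without this preference the
policy measurably stalls (its averaged class-size curve keeps shrinking
until nearly the end of the pool instead of flattening after roughly a
dozen studies).

**Random policy** (`select_random()`): uniform over unperformed designs —
the baseline, not a model of real scientists.

All three are pure functions of (class, state, seed).

## Categorizing hypotheses

A hypothesis — an (in)dependence constraint or a structural assertion about
one pair — falls into one of three categories relative to a knowledge base:
consistent with **none** of the class's graphs (testing it is pointless
unless you distrust the knowledge base), with **all** of them (it is in the
backbone: it already follows, so its test is equally unable to prune the
class), or with **some** (the only kind whose test is guaranteed to shrink
the class).  `categorize_hypothesis()` needs at most two satisfiability
queries: unsatisfiable with the knowledge base means *none* (one query);
otherwise the negation decides between *all* and *some*.  Structural
assertions are represented as non-empty proper subsets of the three edge
relations, which makes negation set complement and hence involutive, and
makes the none/all duality between a hypothesis and its negation exact.

## The simulation study

`run_full_study()` replays the whole protocol against ground truth: for
every one of the 543 four-variable DAGs as the true graph, a run starts
from the trivial class and lets a policy pick designs until the 48-design
pool is exhausted, an oracle answering each design by d-separation on the
true graph (causal sufficiency and faithfulness by construction).  Each
step appends the constraint, updates the class via the memoized verdict
tables, and records the class size.  Because the final constraint set is
the same 18 distinct constraints regardless of order, the step-48 class is
identical across policies for a fixed true graph — a structural invariant
the tests check exhaustively.

Summary statistics follow the *averaged-curve* convention: the per-step
class sizes are averaged over all runs, and the reported "number of studies
to reach fewer than $s$ graphs" (or "to reach the minimum") is the first
step at which that average curve crosses $s$ (or flattens at its final
value).  This choice was validated empirically: with it, the random
policy's three statistics land on 7 / 19 / 47 studies, whereas averaging
per-run first-passage steps gives a "minimum" near 23 — irreconcilable with
the published behaviour of the averaged curve this figure summarizes.  The
per-run flavour remains available in the summary (`mean_first_*` fields and
the per-run `runs` table).  A run that never crosses a threshold
contributes the pool size to the per-run statistics.

Default study conditions: all 543 true graphs, 5 seeded repetitions per
graph per policy, 48 steps each.  Per-run seeds are derived
deterministically from (base seed, graph index, policy, repetition) and
recorded in the output for exact replay; all derived seeds stay below
$2^{31}$.  At these sizes a full three-policy study takes on the order of a
minute; the problem sizes were chosen because they exhaust the model space
(every possible four-variable truth) rather than sample it.

Measured at these conditions, the averaged-curve statistics are 7 / 19 / 47
for the random policy and the mean final class size is about 4.3 — the
piecemeal limit: even after all 48 two-variable studies, between four and
five graphs typically remain, because a direct edge $X \to Y$ cannot be
separated from mediation $X \to Z \to Y$ by any two-variable design.  The
expectation policy reaches a sub-10-graph class in about 8 studies against
the random policy's 19.  Since the suggestion table and tie-breaking rules
are this package's own reconstruction, the informative policies are not
expected to match their originals step for step — the degrees-of-freedom
variant here is in fact somewhat stronger than its published counterpart —
and only order-of-magnitude agreement on the expectation policy is claimed.

The hypothesis-categorization trajectory (`run_hypothesis_trajectory()`)
repeats a run while categorizing, after each step $t$, the
dependence-polarity hypothesis of each of the $48 - t$ unperformed designs
(38 of them after ten studies).  Polarity is a convention: by the duality
above, flipping it swaps the none/all counts and leaves the *some* count —
the scientifically interesting one — unchanged.  The mean *some* count
shrinks as results accumulate: the more is known, the harder informative
experiments are to find.

## What the synthetic generator does and does not emulate

`generate_fixture()` samples a true DAG (edges with probability 0.5 along a
random topological order, so every edge count is equally likely in
expectation and acyclicity holds by construction), samples study designs
without replacement, and answers them with the oracle.  It emulates a
*clean* literature: noiseless verdicts, no conflicting studies, no
selection bias in which pairs get studied, causal sufficiency.  Passing
tests on such fixtures therefore validate the algebra — constraint
encoding, class computation, policy behaviour — not robustness to
finite-sample error, publication bias, or latent confounding; real
annotated literatures violate all three.  Conflict handling is exercised
separately through explicitly conflicting weighted constraint sets.

## Numerical and degenerate-input choices

* DAG counts use exact arbitrary-precision integer arithmetic (the count
  for ten variables already exceeds exact double range); values are
  returned as numerics when exactly representable and as decimal strings
  beyond that.
* Enumeration output is sorted by the row-major binary encoding of the
  adjacency matrix, so class membership, tie-breaking and trajectories are
  reproducible across platforms.  Enumeration refuses more than six
  variables (capacity error), simulation more than four by default.
* An empty constraint set is legal everywhere and yields the trivial
  class; an empty equivalence class is impossible by construction (some
  graph always attains the minimum) and is rejected as an argument error
  where a class is required.
* The full three-relation set is refused as a structural hypothesis (its
  negation would be unsatisfiable); conflicting knowledge bases are
  reduced to their weighted-optimal class before categorization.

## Known limitations

Cyclic graphs (the $X \rightleftarrows Y$ relation), latent-confounder
model spaces, conditioning sets in schema-generated constraints (retained
in the constraint type for user-supplied knowledge), multi-intervention
designs, statistical calibration of weights from p-values, and any
noisy-oracle simulation are all out of scope.  Beyond six variables the
exact backend must be replaced by an external solver through the backend
interface; only the query-counting contract is exercised at that scale.
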