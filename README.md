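# piecemeal

Piecemeal causal discovery and experiment selection from two-variable
studies.

Most experiments in molecular and cellular biology observe two phenomena at
a time: intervene on one and record the other, or passively observe both.
`piecemeal` synthesizes a pile of such results — annotated from the
literature, no primary data needed — into the set of causal structures that
remain viable, quantifies what is still undetermined, and tells you which
experiment to run next.

## The model in brief

A candidate causal structure is a DAG *G* over the system's variables.  A
study result is a constraint *X* ⫫ *Y* | **C** ‖ **J** (or its dependence
counterpart): *X* and *Y* were found (in)dependent given conditioning set
**C** in an experiment intervening on **J**.  Whether a DAG implies a
constraint is decided by d-separation after graph surgery (delete every
edge into an intervened variable).  Given weighted constraints **K**, the
*equivalence class* is

> argmin over DAGs *G* of Σ w(k) over constraints k ∈ **K** not implied by *G*,

computed exactly by enumeration (543 DAGs at four variables; the count
follows the recurrence D(N) = Σₖ (−1)^(k−1) C(N,k) 2^(k(N−k)) D(N−k)).  The
class's *degrees of freedom* count, per variable pair, the edge relations
(→, ←, none) still realized beyond one; they drive two selection policies —
one ranking pairs by remaining freedom, one scoring each candidate relation
by e = (m/|E|)(|E|−m), its probability times the number of graphs its
confirmation would eliminate.  A hypothesis can be categorized with at most
two satisfiability queries as consistent with **none**, **all**, or
**some** of the class — only the last kind is guaranteed to prune it.

## Worked example

Three phenomena, four annotated results: all three pairs dependent, but
*X* and *Z* independent given *Y*.

```r
library(piecemeal)

k <- list(parse_constraint("X dep Y"), parse_constraint("Y dep Z"),
          parse_constraint("X dep Z"), parse_constraint("X indep Z | Y"))
ec <- compute_class(c("X", "Y", "Z"), k)
ec
#> equivalence class: 3 graph(s) over 3 variable(s) [X, Y, Z], unsat weight 0
#>   Y -> X, Z -> Y
#>   Y -> X, Y -> Z
#>   X -> Y, Y -> Z

degrees_of_freedom(ec)
#> degrees of freedom
#>   X ~ Y        n = 1  {right, left}
#>   X ~ Z        n = 0  {none}
#>   Y ~ Z        n = 1  {right, left}
#>   total = 2 (33.3% of the trivial class remaining)
```

The evidence pins down the skeleton (edges X–Y and Y–Z, no edge X–Z) but
not the two orientations: two degrees of freedom remain of the trivial
class's six.  Asking for the most informative next study:

```r
select_expectation(ec, selection_state(c("X", "Y", "Z"), seed = 1))
#> study design: intervene on X, record Y  [int_up]
```

— an intervention on a putative cause, which splits the class whichever way
it comes out.  And a proposed study of the X–Z pair would be a waste:

```r
categorize_hypothesis(c("X", "Y", "Z"), k, no_edge_hypothesis("X", "Z"))
#> [1] "all"
#> attr(,"queries")
#> [1] 2
```

The absence of that edge is already in the backbone — every viable graph
agrees, so the experiment could not eliminate anything.

Oracle-driven simulations replay this loop over every four-variable truth
(`run_simulation()`, `run_full_study()`, `run_hypothesis_trajectory()`),
and a command-line wrapper exposes the same operations
(`system.file("scripts", "piecemeal-cli.R", package = "piecemeal")`, with
subcommands `count-dags`, `solve`, `dof`, `suggest`, `categorize`,
`simulate`, `fixture`).

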