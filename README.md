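# liabgame

Evolutionary game dynamics of school sports injury liability.

When a student is injured in school sports, who should bear the loss — and
how does the answer change what schools and families *do* beforehand?
`liabgame` treats the question as an asymmetric two-population evolutionary
game: schools and students/guardians each either exercise **appropriate
caution** (paying a prevention cost, `cc` or `cs`) or **no caution**; an
accident with total loss `p` occurs whenever at least one side is careless,
and the liability rule in force apportions the loss (share `a` to the
school) and possibly reimburses the cautious student's prevention cost
(share `b`). The package is for policy modellers and law-and-economics
researchers who want the full analysis pipeline reproducible: payoff
construction under strict and proportional liability, closed-form
replicator dynamics, equilibrium enumeration, evolutionarily-stable-strategy
(ESS) classification, numerical trajectories, and parameter sweeps.

## The model in brief

The state is `(alpha, beta)`, the shares of schools and students playing
appropriate caution. The two-population replicator equations are

    dalpha/dt = alpha (1 - alpha) [ beta ((1-a) p + b cs) - (cc - a p) ]
    dbeta/dt  = beta (1 - beta) [ ((1-a) p - (1-b) cs) - (b cs - a p) alpha ]

Rest points are the four corners of the unit square plus, when it lies
inside, the interior point `(alpha*, beta*)`. Local stability follows from
the Jacobian: an equilibrium is an ESS iff `Det(J) > 0` and `Tr(J) < 0`.
Writing the corner net gains `pi1 = a p - cc`, `pi2 = p + b cs - cc`,
`pi3 = p - cs`, `pi4 = (1-a) p - (1-b) cs`, the corner ESS conditions
reduce to sign patterns — e.g. `(0,0)` (mutual no-caution) is an ESS iff
`pi1 < 0` and `pi4 < 0`. See the methods vignette
(`vignettes/liability-game-methods.Rmd`) for derivations, numerical
choices, and the documented discrepancies in the canonical case studies.

## Worked example

High prevention costs under a proportional rule that pins the whole loss on
the school (`a = 1`):

```r
library(liabgame)
pars <- game_params(cc = 10, cs = 6, p = 5, a = 1, b = 0.5)
build_payoff_matrix(pars)
#> Payoff bimatrix (student, school), rule: parametric
#>                      school
#> student               appropriate_caution no_caution
#>   appropriate_caution (-6, -10)           (-3, -8)
#>   no_caution          (-5, -10)           (0, -5)

classify_equilibria(pars)
#> Stability report (scenario 1 )
#>   net gains: pi1 = -5, pi2 = -2, pi3 = -1, pi4 = -3
#>  point det tr    class
#>  (0,0)  15 -8      ESS
#>  (0,1)  -6  1   saddle
#>  (1,0)  -5  4   saddle
#>  (1,1)   2  3 unstable

integrate_game(pars, c(0.5, 0.5))
#> Replicator trajectory (rule: parametric )
#>   start (0.5, 0.5) -> final (5.12211e-75, 1.33046e-20) at t = 500
#>   verdict: corner (0, 0)
#>   flow norm at final state: 3.99e-20; max boundary overshoot: 3.08e-14
```

Read: all four net gains are negative (scenario 1), so caution does not pay
for either side; the only ESS is mutual no-caution, and the simulated
population starting from an even split converges there. Sweeping the
liability shares instead:

```r
res <- run_case(liability_cases()$case2, grid_resolution = 11)
res$modal_verdict
#> [1] "corner (1,1)"
```

— when the accident loss is high and the school reimburses most of the
student's prevention cost, both populations evolve to appropriate caution.

A thin command-line front end wrapping these functions lives at
`inst/cli/liabgame.R` (`simulate`, `sweep`, `classify`, `portrait`
subcommands; YAML/JSON configs as in `inst/extdata/example-config.yaml`).

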