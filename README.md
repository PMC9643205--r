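# mixcv

Bayesian cross-validation comparison of amino acid replacement models on
a fixed tree: single matrices (F81, GTR), empirical profile mixtures with
free weights (C10–C60, UDM, or any profile table you supply), free finite
profile mixtures (CATf=k), and the Dirichlet-process profile mixture (the
CAT family), each with or without discrete-gamma rate variation.  It is
aimed at molecular evolutionists who want to quantify how much each
modeling ingredient — pattern heterogeneity, free exchangeabilities, rate
heterogeneity — contributes to a model's predictive power on a given
protein alignment, and at methods developers who need a compact,
fully-testable reference implementation of the CAT/CV machinery.

## The statistic at the core

Every model is a reversible Markov process on the 20 amino acids with
off-diagonal rates q_ab ∝ ρ_ab π_b, normalized to one expected
replacement per unit branch length.  "Poisson" fixes all ρ_ab equal, GTR
frees the 190 of them; the profile π is single, an empirical mixture, a
free finite mixture, or a Dirichlet-process mixture over sites; `+G`
multiplies branch lengths by mean-one discrete-gamma site rates.

Model fit is compared by fivefold Bayesian cross-validation.  A random
fifth of the alignment columns is set aside; an MCMC sample
θ_1, …, θ_K is drawn from the posterior under the remaining four fifths;
the testing columns D_i are then scored by

    cv-score = Σ_i ln( (1/K) Σ_k p(D_i | θ_k) )

and scores are reported per model as mean ± SD of the difference from a
reference model across five independent random splits, together with the
number of replicates each model won.

## Worked example

Simulate an alignment whose sites draw their amino acid preferences from
three well-separated profiles, then ask whether cross-validation detects
that a free three-component mixture beats a single-matrix model with
gamma rates:

```r
library(mixcv)

sim <- make_benchmark_suite(seed = 1, which = "mix3")$mix3
aln <- sim$alignment[1:800]              # 10 taxa x 800 columns

models <- list(model_spec("poisson", "single", gamma = TRUE),     # F81+G
               model_spec("poisson", "free", n_components = 3,
                          gamma = FALSE))                         # CATf=3
cfg <- experiment_config(models, alignment = aln, tree = sim$tree,
                         chain = chain_config(n_cycles = 200,
                                              burn_in = 50, thin = 2),
                         n_replicates = 3, reference = "F81+G",
                         out_dir = tempfile("mixcv_demo"), seed = 42)
run_experiment(cfg)
```

```
Cross-validation scores relative to F81+G (3 replicates)
  F81+G                         0.0 +/- 0.0
  CATf=3-Poisson               79.3 +/- 23.9 *
  (* best in at least one replicate)
Replicates won:
  CATf=3-Poisson         3
```

The mixture model scores about 79 natural-log units higher than `F81+G`
per ~160-column test set (mean ± sample SD over the three replicates) and
wins every replicate: even without gamma rates, modeling pattern
heterogeneity dominates here.  The output directory holds every
artifact — fold file, per-task traces, fits, scores table, report,
manifest — and rerunning the same configuration reuses finished fits.

Lower-level entry points: `read_alignment()` / `read_tree()` /
`read_profile_set()` for FASTA/PHYLIP/Newick/profile tables,
`run_chain()` for a single posterior sample (a classed fit with `print`,
`summary`, `coef`, `logLik`, `plot`, `predict`, and `simulate` methods),
`split_folds()` / `cv_score()` / `relative_score_table()` /
`best_model_tally()` for the cross-validation pieces, and
`simulate_alignment()` for the generator.  A thin command-line front end
with `simulate`/`split`/`learn`/`score`/`report`/`run` subcommands is in
`inst/cli/mixcv.R`.

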