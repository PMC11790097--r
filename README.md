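# rlwbs — reinforcement-learning wavelet base selection for ECG features

Wavelet scalograms are a standard feature representation for deep-learning
ECG diagnosis, but the mother wavelet ψ that defines the continuous wavelet
transform (CWT)

  W(c, b) = c^(−1/2) ∫ x(t) ψ((t − b)/c) dt

is usually fixed once for the whole dataset, by habit or by trial and
error.  Different cardiac abnormalities concentrate their evidence in
different time–frequency shapes, so a single base is a compromise.

`rlwbs` implements an adaptive alternative: a stochastic policy network
π_θ maps **each individual signal** to a probability vector over an indexed
catalog of 35 candidate mother wavelets (haar; db2–db20; sym3–sym8, sym10,
sym20; coif3–coif5; bior1.1–bior4.4) and is trained by REINFORCE policy
gradient.  Every training iteration:

1. a mini-batch of B signals is sampled and one base per signal is drawn
   from π_θ (Algorithm: sample → transform → train → score → reinforce →
   reset);
2. scalogram features built with the sampled bases train a freshly
   re-initialised evaluation ("backbone") classifier;
3. the backbone is scored on a held-out split whose bases are chosen
   greedily (argmax of π_θ); the score η_t is the reward;
4. the policy ascends α (η_t − b) Σ_i ∇_θ log p(a_i | x_i), and the
   backbone is reset to its initial weights.

The package is self-contained R: cascade-algorithm sampling of the
wavelet functions from their filter banks, the sampled CWT, compact dense
policy/backbone networks, a full multi-label metric suite (precision,
recall, sensitivity, specificity, F1, MCC, rank-based AUROC; macro and
micro averaging), an energy-to-Shannon-entropy (EE-WBS) static comparator,
and a synthetic ECG generator whose class-discriminative morphology is
wavelet-matched, so base-selection recovery is testable without clinical
data.  For whom: researchers in biomedical signal processing who want a
desk-scale, fully reproducible reference implementation of RL-driven
wavelet selection.

## Worked example

```r
library(rlwbs)

catalog <- build_catalog()            # the 35-entry action space
catalog_table(catalog)[c(1, 4, 34), ]
#> # A tibble: 3 × 4
#>   index family       name    center_frequency
#>   <int> <chr>        <chr>              <dbl>
#> 1     1 haar         haar               1.00
#> 2     4 daubechies   db4                0.717
#> 3    34 biorthogonal bior3.3            1.00

spec    <- synthetic_spec()           # two classes: db4 vs bior3.3 atoms
dataset <- generate_dataset(spec, n_per_class = 120, seed = 421)
config  <- training_config(B = 16, E = 5, M = 32, f_min = 1, f_max = 30,
                           alpha = 0.4, alpha_decay = 0.995,
                           policy_hidden = integer(0), baseline = TRUE,
                           backbone_batch = 4, max_iterations = 200,
                           term_eps = 1e-6)
store <- build_feature_store(dataset, catalog, config)   # cache transforms
fit   <- run_training(dataset, catalog, config, store = store)
glance(fit)
#> # A tibble: 1 × 5
#>   iterations final_reward mean_reward_last10 best_reward terminated_early
#>        <int>        <dbl>              <dbl>       <dbl> <lgl>
#> 1        200        0.730              0.763       0.937 FALSE

ev <- evaluate_policy(fit, catalog = catalog, store = store,
                      idx = which(dataset$split == "test"), config = config)
ev$family_distribution
#> # A tibble: 5 × 2
#>   family       share
#>   <chr>        <dbl>
#> 1 haar         10.4
#> 2 daubechies   33.3
#> 3 symlets       0
#> 4 coiflets      8.33
#> 5 biorthogonal 47.9
```

The reward trace climbs from the ~0.45 macro-F1 of undifferentiated
selection toward 0.8–1.0 as the policy learns to give the two classes
different wavelet families (here one class's held-out records are
assigned a biorthogonal base while the other's concentrate on
Daubechies/haar), while the best *fixed* base at the same training budget
stays below 0.5.
`autoplot(fit)` draws the reward trace; `tidy(fit)` returns the per-
iteration history.

A thin command-line front end over the same functions ships under
`inst/cli/rlwbs.R` (`simulate`, `train`, `select`, `evaluate`, `report`).

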