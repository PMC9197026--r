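# shmindel

Statistics of somatic-hypermutation (SHM) insertions and deletions in
antibody V segments, inferred probabilistically from repertoire
sequencing reads.

Affinity maturation mutates immunoglobulin genes mostly by point
substitutions, but the same machinery also produces rare indels. Indel
statistics estimated from best-scoring alignments are biased: nearby
deletion events get merged into spurious long ones, unmutated reads are
always called naive, and rare long indels are over-called. `shmindel` is
for immunology and repertoire-sequencing researchers who want unbiased
estimates of those statistics. It implements:

* a **generative SHM-indel model**: each sequence carries a hidden
  maturation age `mu` (its point-mutation rate per base pair) drawn from a
  repertoire prior `P(mu) = f δ(mu) + (1-f) P̃(mu)`; deletion and
  insertion events occur at rates `β_del·mu` and `β_ins·mu` per base pair
  with event lengths from distributions `P_del`, `P_ins`;
* a **forward algorithm** computing the likelihood of a read as the sum
  over *all* alignment scenarios to its germline template (not just the
  best one), with forward/backward pruning of implausible cells;
* **maximum-likelihood inference** of `(f, P̃, β_del, β_ins, P_del,
  P_ins)` by expectation-maximization for the rate prior combined with
  projected momentum gradient ascent for the indel parameters;
* a **deterministic baseline**: affine-gap Needleman-Wunsch annotation
  with log-odds penalties derived from rates (mismatch `ln 0.05 ≈ -3`,
  deletion open `≈ -7.7`, insertion open `≈ -9.1`, ...);
* a **synthetic-repertoire generator** with ground-truth mutation
  scenarios, and the descriptive **summary statistics** of indel analyses
  (count distributions, length profiles, positional profiles, flank
  overlaps, inter-deletion distances, co-localization against a
  reshuffled null).

## Worked example

Generate a synthetic repertoire under known parameters, fit the model
back, and compare with the deterministic baseline:

```r
library(shmindel)

templates <- template_set(read_fasta(system.file(
  "extdata", "synthetic_v_templates.fasta", package = "shmindel")))

truth <- indel_model(mu_prior(0.1, rep(1, 2000)),     # 10% naive
                     beta_del = 0.025, beta_ins = 0.025,
                     len_del = geometric_length_distribution(15, 30),
                     len_ins = geometric_length_distribution(15, 30))

rep <- generate_repertoire(templates, truth, n = 400, seed = 11)
mean(rep$mu == 0)            # realized naive fraction: 0.0975

fit <- fit_indel_model(rep$reads, templates,
                       config = optimizer_config(T = 30, seed = 99))
det <- deterministic_estimates(annotate(rep$reads, templates))

c(det = det$f, fit = fit$model$prior$f)
#>        det        fit
#> 0.10500000 0.09211617
c(det = det$beta_ins, fit = fit$model$beta_ins)
#>        det        fit
#> 0.02368314 0.02336561
```

The deterministic baseline overestimates the naive fraction (0.105
against a realized truth of 0.0975) because experienced reads that happen
to carry no mutation are indistinguishable from naive ones in a single
best alignment; the probabilistic fit (0.092) weighs both possibilities
and lands closer to the truth. Both estimators agree on the rescaled
insertion rate at this low indel density, as expected. The likelihood
machinery itself is checked against brute-force enumeration of all
alignment scenarios on short sequences (agreement to 1e-12 relative).

A command-line interface over the same functions (modes `generate`,
`annotate`, `evaluate`, `infer`, `stats`) is installed at
`inst/cli/shmindel.R`.

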