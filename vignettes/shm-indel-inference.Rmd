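---
title: "Probabilistic inference of SHM indel statistics"
author: "shmindel package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic inference of SHM indel statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shmindel)
```

## The problem

During affinity maturation, somatic hypermutation (SHM) diversifies
antibody genes mostly through point substitutions, but also through rare
insertions and deletions (indels) of the V segment. Estimating indel
statistics from repertoire sequencing data is harder than it looks: the
standard approach annotates each read with its single best-scoring
alignment to a germline V template, and that best-scoring alignment is
systematically biased. Two nearby deletion events get merged into one long
one; a read without mutations is always called "naive" even though an
experienced cell may simply not have mutated; rare long indels are
over-called. `shmindel` implements a generative probabilistic model of the
SHM process whose likelihood sums over *all* alignment scenarios between a
read and its template, removing these biases, together with the
deterministic baseline it improves upon, a synthetic-data generator for
validation, and the descriptive indel statistics used to characterize
repertoires.

## The generative model

Each sequence `s` derives from a germline template `t` through a scenario
of point mutations, deletions and insertions. The model parameters are
`theta = (P(mu), beta_del, beta_ins, P_del, P_ins)`:

* **Maturation age `mu`** — a per-sequence, per-base-pair point-mutation
  rate, drawn from a repertoire-wide prior `P(mu) = f delta(mu) +
  (1-f) Ptilde(mu)`. The point mass at zero is the fraction `f` of naive
  sequences that never entered hypermutation; `Ptilde` is a smooth density
  stored on a uniform binning of [0, 1] with bin width 0.0005.
* **Rescaled indel rates `beta_del`, `beta_ins`** — dimensionless ratios of
  the per-base-pair deletion-event and insertion-event rates to the
  point-mutation rate, shared by all sequences (indel load scales linearly
  with SHM load in repertoire data). Per-base-pair rates are
  `mu_del = mu * beta_del` and `mu_ins = mu * beta_ins`.
* **Event-length distributions `P_del(l)`, `P_ins(l)`** — probabilities of
  single-event lengths `1..theta_max` base pairs. The generator uses a
  geometric (exponentially decaying) law, `P(l) ~ exp(-l / scale)`.

A scenario's probability multiplies, per aligned position, the
match/mismatch emission `M(a, b) = (1 - mu_del - mu_ins) * ((1-mu)` if
`a == b` else `mu)`, per deletion event `Gamma_del(l) = mu_del P_del(l)`,
and per insertion event `Gamma_ins(l) = mu_ins P_ins(l) (1/4)^l`, the last
factor being the probability of the specific inserted bases under the
uniform-insertion assumption. Note the mismatch emission assigns weight
`mu` to *any* of the three alternative bases — the model is implemented
with this literal form (no `mu/3` split), which is what makes the aligner's
mismatch penalty `ln(0.05) ≈ -3` at a 5% mutation rate. Consequently the
per-position emission mass does not sum exactly to one; the package asserts
the literal forms, not a normalization.

## The forward likelihood

`forward_sum()` computes `S(s, t | mu; phi)`, the sum over all global
alignment scenarios, by a pair-alignment forward recursion: a cell
`(i, j)` accumulates the diagonal term `S(i-1, j-1) M(s_i, t_j)`, deletion
terms `S(i, j-l) Gamma_del(l)` and insertion terms `S(i-l, j)
Gamma_ins(l)` for `l = 1..theta_max`. Two conventions matter:

* **Insertions consume read bases, deletions consume template bases.** The
  `(1/4)^l` factor belongs to observed non-templated read bases, which
  pins this reading of the recursion; the test suite enforces it with a
  brute-force scenario enumerator.
* **Abutting events are distinct scenarios** and are included in the sum.
  This is exactly what lets the probabilistic method disentangle one long
  observed gap into several shorter events where that is more likely.

Numerically the recursion runs in C++ on linearly-scaled probabilities
with one rescaling factor per read position (the standard pair-HMM
scaling), which is exact in floating point and immune to underflow over
~300 bp products; interfaces expose log-likelihoods. On sequences short
enough to enumerate, the forward sum agrees with explicit scenario
enumeration to 1e-12 relative.

Marginalizing, `L(s; theta) = f S(s,t*|0) + (1-f) sum_bins Ptilde(mu)
S(s,t*|mu) dmu` (midpoint quadrature on the prior bins), where `t*` is the
single best template by deterministic alignment score — with hundreds of
diverged templates only one contributes appreciably, so the template sum
is collapsed to its dominant term.

## Speed-ups

* **Pruning.** `passage_posterior()` combines a forward and a backward
  pass into `Shat_ij`, the probability that the alignment visits cell
  `(i, j)`. Cells with `Shat < 1e-5` (threshold `vartheta`, configurable)
  are excluded from all subsequent evaluations of that read
  (`build_pruning_mask()`). The mask is built once per read at an initial
  parameter guess — the deterministic annotation, with the rate floored at
  0.02 so that plausible indel cells survive for unmutated reads — and
  kept fixed thereafter, as refreshing it during the fit changes little
  but costs a full unpruned pass. The masked likelihood is within 0.1% of
  the unmasked one at the default threshold.
* **Admissible-length skipping.** A finite-difference gradient component
  for `P_del(l)` or `P_ins(l)` is exactly zero for reads whose mask admits
  no event of length `l`; those evaluations are skipped outright.
* **Posterior nodes.** The per-read posterior over `mu` is evaluated at 15
  nodes (25 for reads with 5+ substitutions) placed around the current
  posterior maximum with a spread set by the posterior standard deviation
  (inverse curvature), plus mandatory nodes at 0 and 1, and interpolated
  onto the prior grid with a natural cubic spline of the log-likelihood.
  On a first pass the center is the deterministic SHM-rate estimate.

## Maximum-likelihood fitting

`fit_indel_model()` alternates:

1. **E step** — per-read posteriors over `mu` (node-interpolated), giving
   the posterior naive weight `f_s` and density on the prior bins.
2. **EM update of the prior** — closed forms: `f` becomes the mean of
   `f_s`; `Ptilde` becomes the `(1-f_s)`-weighted average of the per-read
   posterior densities. With `phi` frozen this is exact EM and the data
   log-likelihood is non-decreasing (a property test asserts it).
3. **Monte-Carlo sampling** — one `mu` per read (`n_mc = 1`) drawn from
   its posterior by inverse-CDF sampling; slow parameter drift across
   iterations provides the effective averaging.
4. **Projected momentum gradient step for `phi`** — forward finite
   differences (`epsilon = 1e-4`) of the pruned log-likelihood at the
   sampled rates, then `phi <- P(phi + alpha_t * grad + omega_t *
   (phi_t - phi_{t-1}))` with schedules `alpha_t = alpha0 exp(-2t/T)` and
   `omega_t = t/(t+3)`, where `P` clips the rates at zero and projects
   each length distribution onto the probability simplex (sorting-based
   Euclidean projection).

Constants the schedules leave open are package choices: `alpha0 = 0.05`;
the learning rate for the two rates is scaled by the parameter magnitude
(floored at 0.005), while each length-distribution block shares one
uniform scale (`1/theta_max`) — a magnitude-proportional scale inside a
simplex block would bias the projected update away from its fixed point —
and per-component steps are clipped at 25% of their scale for stability.
The fit is initialized from the deterministic annotation: naive fraction
from event-free reads, rates from pooled event-count ratios, length
distributions from pseudocounted event-length histograms, and the prior
density from a kernel-smoothed histogram of per-read SHM rates. The fit
stops early when the relative log-likelihood change over a 10-iteration
window falls below `1e-6`.

Degenerate inputs are handled explicitly: a read whose likelihood
vanishes at every posterior node raises a degenerate-sequence error; if
every read is posterior-certainly naive the density update keeps the
previous density with a warning; rates are floored at 1e-8 after
projection so no read's likelihood can collapse to exactly zero
mid-fit.

## The synthetic-data generator

`generate_repertoire()` emulates the conditions used to validate the
method: a mixture of 10% naive sequences (`mu = 0`) and 90% experienced
sequences with `mu` drawn from a shifted Gamma — unshifted mode 0.07,
standard deviation 0.04, shift 0.02 subtracted with negative draws
rejected — giving a density with support down to infinitesimal rates and
mode 0.05. Rescaled indel rates default to `beta_del = beta_ins = 0.025`
in the validation experiments, with geometric event lengths of
characteristic scale 15 bp truncated at 30 bp. Per template position an
independent draw selects a deletion start (`mu beta_del`), an insertion
start (`mu beta_ins`), a point mutation (`(1 - mu beta_del - mu beta_ins)
mu`, uniform over the three alternative bases) or nothing; inserted bases
are uniform; a deletion overrunning the template end is truncated; events
are applied right-to-left, and an event starting inside an
already-deleted stretch is discarded (the generative process does not
specify collision handling — this rule keeps every scenario well defined
and reconstructible). Only template-derived positions mutate, at most
once each; inserted bases are never re-mutated.

What the generator does *not* emulate — by design, matching the model
class — are positional hotspots (profiles are uniform), homology of
inserted segments to their flanks (no duplication mechanism), lineage
structure, and sequencing error. Passing tests on synthetic data
therefore validate the inference machinery, not the model's adequacy for
any particular real repertoire.

Templates are arbitrary; the package ships five synthetic 300-bp
templates (`inst/extdata/synthetic_v_templates.fasta`, uniform random
composition) used by the tests and examples. Real germline sets can be
supplied as any FASTA.

## Deterministic baseline and its artifacts

`annotate()` is a standard three-state affine-gap Needleman-Wunsch global
aligner whose penalties derive from rates (`derive_penalties()`): match
`ln(1-p)`, mismatch `ln p`, gap open `ln(rate) - 1/scale` (the open
includes the first extension step), extension `-1/scale`, with `-ln 4`
per inserted base. At the conventional 5% substitution rate, 0.05% indel
rate and scale 10 this gives the familiar -0.05 / -3 / -7.7 / -0.1 /
-9.1 / -1.5. Ties in the traceback prefer diagonal over deletion over
insertion and place gaps leftmost, making annotations deterministic.

Two known biases of this baseline are reproduced and tested: deletion
pairs closer than ~3 bp are merged into single long events (depleting the
short-distance part of the inter-deletion distance distribution and
creating spurious long events), and the naive fraction is overestimated
because an unmutated read is always called naive even though experienced
cells stay unmutated with probability `exp(-L mu)`.

## Problem sizes and tolerances

The validation experiments in the test suite and acceptance script use a
single repertoire of 2,000 reads on the bundled 300-bp templates — large
enough that the naive fraction is recoverable to within ±2 percentage
points and the rescaled rates to within ±20% relative, which are the
recovery margins asserted — with 40 fit iterations and inference length
support up to 60 bp (double the generator cutoff, so that the fit itself
must discover where the true support ends). Oracle-equivalence checks run
on sequences up to length 6 with event support up to 3, where full
scenario enumeration is feasible; EM-monotonicity checks use a coarse
50-bin prior so the exact-grid E step stays cheap. The pruning threshold
(1e-5), prior bin width (0.0005) and node counts (15-25) are the
method's standard operating values, not tuned quantities.

## Limitations

* Positional homogeneity: the generative model places events uniformly
  along the template, contradicting real positional profiles; the
  summary statistics quantify that heterogeneity but the model does not
  represent it.
* Insertions are uniform random: flank-overlap statistics on real data
  (the signature of duplication) have no counterpart in the model.
* One template per read: the marginal over templates is collapsed to the
  best deterministic match, which is safe for diverged template sets but
  would misattribute reads between near-identical alleles.
* The `phi` gradient is stochastic (`n_mc = 1`); late-iteration noise in
  the fitted rates is a fraction of a percent under the default
  schedules but not zero.
* Finite-sample tail retention: when a repertoire contains two *abutting*
  indel events whose merged span exceeds the generative length cutoff, the
  single-long-event explanation is genuinely likelier than the pair (one
  fewer `beta*mu` event factor at the same emission cost), so the
  maximum-likelihood length distribution retains about `1/N_events`
  probability at the merged length. At a few thousand reads this leaves
  isolated bins of order 1e-3 beyond the cutoff whenever such a read occurs
  (roughly half of 2,000-read draws, more often for deletions than
  insertions since insertions pay `(1/4)^gap` for non-abutting merges);
  the retained mass shrinks as `1/N` and vanishes at repertoire scales of
  1e5 reads, where the simplex projection drives those bins to zero. Tail
  bins beyond the cutoff should therefore be read with this `1/N` floor in
  mind on small repertoires.
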