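---
title: "Multistable connectome dynamics: models, attractor sampling, and FCD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistable connectome dynamics: models, attractor sampling, and FCD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopscape)
```

## The model

`hopscape` simulates a graded-response Hopfield network coupled through a
structural connectome. Each node $i$ (a brain parcel) carries a potential
$x_i$ and a bounded output

$$\tau_x \dot x_i = -x_i + \sum_j W_{ij} A_j, \qquad
  A_i = \tfrac12\bigl(1 + \tanh(G(P x_i - \theta_i))\bigr),$$

where $W = C/\lVert C\rVert$ is the normalized coupling matrix, $G$ the gain
(node excitability; the inverse temperature of the spin-glass analogy) and
$P$ the scaling factor (excitation/inhibition ratio). Three threshold
variants are supported:

* **SL** (static, local): $\theta_i = \tfrac12\sum_j W_{ij}$. At $P = 1$
  the dynamics is symmetric around $A_i = 1/2$, which is what lets a large
  repertoire of mirrored attractor pairs coexist.
* **SG** (static, global): one scalar threshold, the mean of the SL vector.
* **DG** (dynamic, global): $\tau_\theta\dot\theta = -\theta + \bar A$,
  a global negative feedback that pins the mean activity; the attractor
  density is then set by $P$, not by where the dynamics started.

Stochastic generalizations add white noise to the potentials and thresholds.
We read the printed noise terms as diffusion strengths of the $\tau$-scaled
equations, so an Euler–Maruyama step uses increments
$(\sigma/\tau)\sqrt{dt}\,\xi$; the alternative convention
$\sigma\sqrt{dt}\,\xi$ is available via
`model_config(noise_scaling = "plain")` because the source equations do not
disambiguate.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `G` | 900 (high-gain searches) | sigmoid steepness; first pitchfork of SL at $G_c = 2/\lambda_\max(W)$ for $P=1$ |
| `P` | 1 | E/I ratio; density control in DG |
| `tau_x` | 10 ms | potential time constant |
| `tau_theta` | `tau_x` during attractor search, 80 ms in noisy runs | threshold adaptation time scale |
| `dt` | 0.1 ms | explicit Euler step |
| `sigma_x`, `sigma_theta` | 0 | noise strengths (0.2 is a "moderate" level for exploration runs) |

The norm in $W = C/\lVert C\rVert$ is configurable
(`normalize_connectome(w, "frobenius" | "spectral" | "max_row_sum")`). The
default is Frobenius: spectral normalization would force the SL critical
gain to exactly 2, which is inconsistent with critical gains around 13
reported for ~1000-node empirical connectomes, whereas Frobenius scaling of
a sparse graph of that size naturally yields $\lambda_\max(W)\approx 0.15$.
This is an inference, not a statement of the original authors.

## Attractor sampling

`sample_attractors()` reconstructs the landscape by relaxing random binary
initial patterns whose density runs over a grid (default 0.02 to 0.98 in
steps of 0.03 — 33 densities). A relaxation stops when the node-averaged
potential $\bar x$ satisfies

$$\frac{\lvert\langle\bar x\rangle_T - \bar x(t)\rvert}
       {\max(\lvert\bar x(t)\rvert, 10^{-6})} < 10^{-6},
  \qquad T = 100\ \mathrm{ms},$$

or after 1 s of simulated time. The printed form of this criterion in the
source material is typographically garbled; we implement the relative
criterion above with an absolute floor of $10^{-6}$ to guard the division
when the network dies out. Runs that hit the 1 s cap are counted
(`n_failed`) but excluded from the set — near a bifurcation, critical
slowing down makes this exclusion visible (whole sweep cells can fail to
equilibrate exactly at $G_c$), which is itself a useful diagnostic.

Deduplication uses the double-dissimilarity rule: a final pattern is novel
only if **both** its Pearson correlation **and** its Euclidean similarity
$1/(1+d)$ to every stored attractor are below 0.9. Pearson alone would
conflate sparse patterns; Euclidean alone would conflate scaled dense ones.
When a pattern is absorbed, the best-matching attractor — the one maximizing
$\max(\mathrm{sim}_{cor}, \mathrm{sim}_{eucl})$, ties to the lowest index —
gains cardinality. The max rule is our choice; the source does not define
"better matching". Per-density attractor counts are computed with the same
dedup rule (the original "soft clustering" is unspecified).

Energy/probability annotations: the potential function $V(x)$ is evaluated
verbatim, including the $\ln\cosh$ self-coupling term that vanishes for
zero-diagonal connectomes. As printed it is an exact Lyapunov function only
for $N = 1$ or diagonal coupling; for general symmetric $W$ its gradient
differs from the drift by a term proportional to $\mathrm{sech}^2$ that
vanishes at high gain. We evaluate it as given and treat it as an energy
proxy; $V$ is computed on potentials, not outputs. Binarized patterns get
the Ising energy $E^\alpha$, Boltzmann weights use a max-shift, and the
empirical entropy of cardinalities is reported in **bits**: the stated upper
bound of 11.69 for 3,300 equiprobable attractors equals $\log_2 3300$, which
fixes the base the source leaves implicit. The Boltzmann entropy defaults to
natural log (switchable) with $\beta = 2$ as the reference inverse
temperature for predicted attractor proportions.

## Clustering

Binary patterns (activity strictly above 0.5) are grouped by greedy
agglomeration on the symmetrized inclusion match
$\mathrm{sim}_{incl}(A,B) = \max(|A\cap B|/|A|, |A\cap B|/|B|)$, merging the
most similar pair of cluster references until the maximum drops to the
threshold $k$. The double pass first clusters raw patterns with
max-inclusion-score references (the member with the highest summed
similarity to its cluster mates — we sum `sim_incl`, as the source does not
say whether the one-sided or symmetrized form is summed), then re-clusters
the result using majority references (nodes active in more than half the
members). Reference thresholds from the original protocol: $k = 0.8$ for
attractor sets, $k = 0.5$ for empirical observation vectors.

The cached pairwise-similarity implementation updates one row per merge and
is tested for exact agreement with a naive $O(n^2)$-per-merge re-derivation.
Argmax ties break on the lexicographically lowest cluster-index pair;
frequency ties in `cluster_core()` break on the lower node index, so the
whole pipeline is deterministic given input order. Clusters whose members
are all empty are dropped with a warning.

Cores (top 10% or 25% most frequently active nodes) are compared with
reference patterns via the match fraction $m$ and
$t = (m - p)\sqrt{n_{core}/(p(1-p))}$, generalizing the printed case
$p = 0.25$, $n_{core} = 100$; bands significant/good/strong at
$t > 3, 6, 9$. The printed $m$-thresholds 0.37/0.51/0.65 are roundings of
that case and are not hard-coded.

## BOLD and functional connectivity dynamics

Simulated output is block-averaged to 100 Hz, convolved with the
Balloon/Windkessel kernel

$$H(t) = e^{-t/(2\tau_s)}\,\frac{\sin(\omega t)}{\omega},\qquad
  \omega^2 = \frac{1}{\tau_f} - \frac{1}{4\tau_s T},$$

($\tau_s = 0.8$ s, $\tau_f = 0.4$ s, $T = 10$; the alternative reading
$\omega^2 = 1/\tau_f - 1/(4\tau_s^2)$ is exposed as an option because the
printed formula is ambiguous), truncated at 15 s where the envelope is
below $10^{-4}$, then decimated to 0.5 Hz by strided sampling (the
convolution has already low-passed the signal) and mean-detrended.
Numerical choice: one kernel support (15 s) of warm-up is discarded after
convolution so that the zero-initial-condition transient never reaches the
output — this is what makes "constant input in, exactly zero detrended
output out" hold, at the cost of 15 s of usable signal.

`sliding_fc()` computes windowed Pearson FC (1-minute windows, 1-sample
step by default; the original step is unstated) and `fcd_matrix()`
correlates the vectorized upper triangles of every window pair. A 15-minute
series at 0.5 Hz with a 1-minute window yields exactly 421 window
positions. `attractor_fc()` correlates nodes **across** the attractor set,
weighting each attractor by its cardinality (unweighted is available), and
`compare_fc()` restricts comparisons to intra- or inter-hemispheric pairs.

## What the synthetic generator does and does not emulate

`synthetic_connectome()` produces a sparse, symmetric, non-negatively
weighted, modular graph with half/half hemisphere tags — the features the
dynamics actually feeds on (modularity sustains multistability; the
degree-preserving Maslov–Sneppen null `maslov_sneppen_randomize()`
demonstrably deflates it). It does **not** emulate spatial embedding,
distance-dependent weight decay, tract-length delays, hub topology beyond
what random modular blocks produce, or inter-subject averaging. A green
test on synthetic connectomes therefore establishes the *mechanisms*
(bifurcation structure, density control, randomization contrast, FCD
epochs), not the specific empirical numbers of any real connectome —
attractor counts in the tens of thousands, specific cluster anatomy, and
empirical FC correlations are out of reach at desk scale and out of scope.
Defaults (4 modules, intra-module edge probability 0.3, inter 0.02, uniform
weights) were chosen once to mimic the density regime of parcellated
connectomes and never tuned against test outcomes.

## Degenerate inputs and tie rules collected

* Asymmetric matrices are rejected at load, never symmetrized.
* All-zero connectomes cannot be normalized (error).
* Zero-variance patterns get Pearson similarity 0 with a warning.
* Swap proposals in the randomizer are rejected unless all four nodes are
  distinct and neither target edge exists; weights travel with their source
  node (the source material does not say how weights move — this is our
  documented convention). Graphs with no valid swap (complete graphs,
  stars) are returned unchanged with a warning.
* Exactly-0.5 activity binarizes to *inactive* (strict inequality).
* The DG threshold is initialized at `mean(A0)`; SL/SG at their static
  values; the initial binary pattern is assigned directly to the
  potentials.

## Known limitations

* The potential function is approximate for off-diagonal coupling (see
  above); no numerical continuation is provided, so bifurcations are
  resolved only to the sweep grid.
* Noisy-regime FCD structure is assessed against a monostable control run
  rather than a shuffled-window null: shuffling BOLD samples makes every
  window estimate the same global mixture FC, which *raises* the
  off-diagonal FCD median and so cannot serve as the low side of the
  comparison. The multistable-vs-monostable contrast is large (median
  off-diagonal FCD ≈ 0.85 vs ≈ 0.23 on 30-node probes) and stable across
  seeds.
* Pattern indices are 1-based throughout, per R convention.
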