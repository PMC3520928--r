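---
title: "Foldon macrobasin kinetic models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foldon macrobasin kinetic models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldkin)
```

## The model

`foldkin` assumes a funneled folding landscape: geometry is a good proxy
for kinetic proximity, so conformational space can be coarse-grained by
*structure* rather than by clustering trajectories. A protein is divided
into contiguous **foldons**; each frame is scored per foldon by the
Gaussian native-contact coordinate

$$Q = \frac{1}{N_\mathrm{pairs}} \sum_{(i,j)}
  \exp\!\left(-\frac{(r_{ij}-r^N_{ij})^2}{2\sigma_{ij}^2}\right),$$

and thresholding the per-foldon q values yields a binary **macrobasin**
label (leftmost bit = N-terminal foldon; `0101` = second and fourth
foldons folded). Macrobasin free energies over a temperature range come
from MBAR over umbrella windows biased along global Q. Kinetics then
follow from two assumptions:

* **Local connectivity.** Only macrobasins differing in one foldon bit
  interconvert directly; changing two foldons requires two elementary
  reconfiguration events.
* **Universal downhill rate.** Every free-energy-decreasing elementary
  transition proceeds at a common rate $k_0$ (motivated by the folding
  speed limit; default $10^6\,\mathrm{s^{-1}}$); uphill transitions are
  penalized by $e^{-\Delta F/k_BT}$. With columns of $K$ summing to zero
  this construction satisfies detailed balance with respect to
  $\pi \propto e^{-F}$ exactly.

The master equation $\dot P = K P$ is solved spectrally. Because detailed
balance holds, $S = \Pi^{-1/2} K \Pi^{1/2}$ is symmetric, so all
eigenvalues are real and non-positive, the zero mode is the Boltzmann
distribution, and the observed relaxation rate is the largest strictly
negative eigenvalue. Cumulative edge fluxes integrate analytically per
mode ($\int_0^\tau e^{\lambda t}dt$); at $\tau = \infty$ the zero mode
contributes nothing because its per-edge net flux vanishes under detailed
balance, which is also why the equilibrium-limit flux is finite.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| contact cutoff | 9.5 | Å (Cα–Cα) | standard Gō-model convention |
| min. sequence separation | 3 | residues | excludes trivially-close pairs that inflate Q |
| $\sigma_{ij}$ | $(1+|i-j|)^{0.15}$ | Å | wider tolerance for long-range pairs; widely used form |
| foldedness threshold | 0.6 | – | strict `>` at the boundary (deterministic tie-break: q = threshold is unfolded) |
| $k_0$ | $10^6$ | s⁻¹ | folding speed limit |
| MBAR tolerance | $10^{-8}$ | max $|\Delta f|$ | per self-consistent iteration |
| bias | $\kappa(Q-Q_0)^2$ | energy | harmonic in global Q; $\kappa$, $Q_0$ per window |

Temperatures are in model energy units with $k_B = 1$; free energies are
reported in units of $k_BT$ *at each table's own temperature*, which is
also the stability axis of the chevron scan.

Cross-boundary contact pairs contribute to **both** adjacent foldons' q,
each foldon normalizing by its own eligible pair count. The alternative
(counting such pairs once, for the lower-indexed foldon) changes q by only
a few percent for compact folds but would make foldon q values
discontinuous functions of the partition; the both-sides rule keeps every
foldon's q a faithful "how native is my environment" score.

## What the synthetic generator emulates

`synthetic_landscape()` is an Ising-like chain over $N \le 14$ foldons:
energy $E(\sigma) = -\sum_i \varepsilon_i \sigma_i - \sum_i J_i \sigma_i
\sigma_{i+1}$, and each unfolded foldon retains entropy $s_i$, so
$F(\sigma)/k_BT = E(\sigma)/T - \sum_i s_i (1-\sigma_i)$, enumerable
exactly. Frames store only $E$ and $Q$; the entropy enters through visit
frequencies, exactly as microstate multiplicity does in a real simulation,
which makes MBAR temperature transfer a genuine test rather than a
tautology. Defaults ($\varepsilon = 2$, $s = 1.5$, $J = 1$ per foldon)
give a funneled, weakly cooperative landscape with folding temperature
$T_f = 11/6$ and all 16 macrobasins populated above $10^{-3}$ at $T_f$ —
deliberately, so that free-energy recovery is tested over the *whole*
label set.

The umbrella sampler is single-spin-flip Metropolis over the $2^N$ states
under $E + \kappa(Q-Q_0)^2$, with $Q(\sigma)$ the folded-bit fraction.
One frame is recorded per MC sweep ($N$ flip attempts) — the discrete
analogue of saving MD frames every few hundred integration steps — after a
10% burn-in; no further thinning (MBAR tolerates correlation, at the cost
of variance). Per-foldon q values are emitted from Beta distributions
centred at 0.85 (folded) and 0.25 (unfolded) with concentration 30,
giving a whole-frame mislabel rate of roughly 0.2% at threshold 0.6: the
threshold machinery is genuinely exercised, while frame labels still
recover the generating states to better than 99%.

What a green test does **not** establish: the generator has no chain
geometry, no non-native interactions, no friction, and its biased
coordinate is discrete. Agreement with the enumeration oracle validates
the estimators and the kinetic algebra, not any claim about a specific
protein. Conversely, real trajectory data enters through the same
frame-table interface (`window_samples()`), so nothing downstream is
synthetic-specific.

## Numerical choices

* **MBAR.** The convex MBAR objective is minimized by BFGS with analytic
  gradients, then polished by self-consistent iteration until
  $\max_k |\Delta f_k| < 10^{-8}$ (gauge $f_1 = 0$); non-convergence is an
  error that reports the residual. Window overlap is audited through the
  MBAR overlap matrix; windows forming disconnected overlap groups
  produce a warning (large variance), not an error.
* **Standard errors** use a within-window moving-block bootstrap (block
  length $\approx \sqrt{n}$), warm-started from the converged solution.
  The default is 0 resamples — errors are opt-in (`n_boot`) — because a
  50-resample bootstrap multiplies the cost of the default pipeline by an
  order of magnitude while none of the default outputs consume the error
  bars.
* **Eigensolves** always go through the detailed-balance symmetrization;
  a matrix violating detailed balance beyond $10^{-8}$ (relative) falls
  back to the general solver with a warning, and $\tau = \infty$ fluxes
  are refused for non-relaxing spectra.
* **Degenerate inputs.** Disconnected sampled label sets are an error at
  the relaxation-rate stage (multiple zero modes are reported); unsampled
  macrobasins are simply absent from the network rather than imputed.
  Frames at exactly the threshold are unfolded (strict `>`).
* **Determinism.** All randomness flows through explicit integer seeds;
  graph and table outputs are emitted in sorted label order, so identical
  configs reproduce every artifact byte for byte.

## Design decisions taken where the design was open

* **Chevron shape.** A *single*-foldon model has no barrier: its exact
  relaxation rate $k_0(1+e^{-|\Delta F|})$ is maximal at $\Delta F = 0$
  and saturates at $k_0$ on both limbs — there is no V. A V-shaped
  chevron with its minimum at zero stability requires an interior barrier
  whose energy content is about half the native one (near-symmetric
  Leffler $\alpha$). The acceptance suite therefore checks the analytic
  no-barrier law for one foldon, and checks V-shape-with-minimum-near-zero
  on a purpose-built two-state-like landscape ($\varepsilon = 18$,
  $s = 20$, couplings $(4, 0, 4)$, $\alpha \approx 0.45$). For generic
  landscapes the thermal chevron minimum sits on the folding side of zero
  — the familiar difference between thermal and denaturant chevrons.
* **Pathway summary.** The "dominant pathway" is the widest-bottleneck
  source→sink path over positive net fluxes (ties broken
  lexicographically), computed as widest-path Dijkstra followed by a
  lexicographic DFS on the optimal-width subgraph. Bottleneck width, not
  total flow, is the quantity a flux diagram's thickest chain of arrows
  shows.
* **Flux at $\tau = \infty$** is evaluated analytically by dropping the
  zero mode rather than by integrating to a large horizon — exact under
  detailed balance and free of an arbitrary cutoff.
* **Gauge.** Free-energy tables are gauged to the fully unfolded label
  when sampled (else the minimum-F label, recorded in the table); the
  chevron stability is always F(all-ones) − F(all-zeros).

## Known limitations

* Single-chain proteins only; foldons must be contiguous in sequence.
* MBAR here reweights in temperature (and bias), not denaturant; chemical
  chevrons are out of scope.
* The MC sampler proposes single-foldon flips, mirroring the kinetic
  model's connectivity; landscapes whose real dynamics jump farther are
  outside the generator's world.
* Rate matrices beyond a few thousand sampled macrobasins (N ≳ 11 fully
  sampled) make dense eigensolves slow; the intended regime is N ≤ 8
  foldons, as in repeat-protein applications.
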