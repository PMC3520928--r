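# foldkin

Discrete kinetic models of protein folding from foldon macrobasins.

## The problem

Raw folding simulations on funneled energy landscapes are hard to compare
with stopped-flow experiments, which report relaxation rates, chevron plots
and pathway intermediates rather than trajectories. `foldkin` coarse-grains
a simulation into a small kinetic network in four steps:

1. **Foldons and Q.** The chain is partitioned into contiguous foldons
   (e.g. one ankyrin repeat, or half a repeat, per foldon). Foldedness of a
   foldon is measured by the native-similarity coordinate

   Q = (1/N_pairs) Σ_(i,j) exp( −(r_ij − r_ij^N)² / (2 σ_ij²) ),

   summed over native contact pairs with at least one residue in the
   foldon; r_ij^N is the native Cα–Cα distance and σ_ij = σ₀(1+|i−j|)^ε a
   sequence-separation dependent width.
2. **Macrobasins.** Thresholding each foldon's q (default 0.6, strict `>`)
   maps every frame to a binary label: `0101` means the second and fourth
   foldons are folded. N foldons give at most 2^N macrobasins; only sampled
   ones enter the model.
3. **Free energies.** Umbrella-sampled windows along global Q are combined
   with the multistate Bennett acceptance ratio (MBAR) to give macrobasin
   free energies F_a(T) in units of k_BT over a range of temperatures.
4. **Kinetics.** Macrobasins differing in a single foldon bit are
   connected. The rate a→b is k₀ (the universal downhill rate, default
   10⁶ s⁻¹) if ΔF = F_b − F_a ≤ 0, else k₀·e^(−ΔF); diagonal entries
   conserve probability. Diagonalizing the rate matrix yields relaxation
   rates (thermal chevron plots, scanning folded–unfolded stability via
   temperature) and cumulative net fluxes
   J_ab(τ) = ∫₀^τ [K_{a←b}P_b − K_{b←a}P_a] dt,
   from which dominant folding pathways are read off and drawn as
   GraphViz DOT diagrams (vertical position ≈ free energy, width ∝ flux).

A synthetic Ising-like landscape generator with exactly enumerable 2^N
free energies provides ground truth for every stage, so the whole pipeline
is testable without any MD engine.

## Worked example

```r
library(foldkin)

land <- synthetic_landscape(4, epsilon = 2, entropy = 1.5, coupling = 1,
                            seed = 1)
Tf  <- folding_temperature(land)     # 1.8333
tab <- exact_free_energies(land, Tf) # 16 macrobasins, F in kBT, gauge 0000
K   <- build_rate_matrix(tab, k0 = 1e6)
dec <- spectral_solve(K)
relaxation_rate(dec)
#> [1] 1364809          (s^-1; gap ratio 0.845 -> multi-exponential regime)

P0 <- setNames(as.numeric(rownames(K) == "0000"), rownames(K))
J  <- cumulative_flux(dec, K, P0, tau = Inf)
dominant_pathway(J, "0000", "1111")
#> [1] "0000" "0010" "0110" "1110" "1111"   (bottleneck flux 0.0247)
```

At the folding temperature the folded–unfolded stability is 0 k_BT by
construction, the observed relaxation rate is 1.36×10⁶ s⁻¹ (just above
k₀ because relaxation at T_f mixes several comparable modes), and folding
nucleates in the middle of the chain and propagates outward — the
inside-out mechanism typical of consensus repeat proteins.

The same analysis from sampled data instead of exact enumeration:

```r
wins <- sample_umbrella_windows(land, umbrella_protocol(5, 5000, 1, 10))
fit  <- mbar_solve(wins)
labs <- unlist(lapply(wins, function(w)
  label_trajectory(as.matrix(w$frames[, paste0("q_", 1:4)]), 0.6)$labels))
est  <- macrobasin_free_energies(fit, labs, temperature = 1)
stability(est)   # F(1111) - F(0000) in kBT
```

## Command line

```sh
exec/foldkin run --config config.txt --out-dir out/
# stages: synth | label | freeenergy | network | chevron | flux | run
```

`config.txt` is plain `key = value` (see `?read_run_config` for the keys
and defaults). Outputs are TSV tables, a DOT flux diagram and a JSON
manifest with MD5 hashes; identical configs and seeds reproduce every
file byte for byte.

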