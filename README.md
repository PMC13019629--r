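# siegertq

Bound-state and resonance identification for a benchmark model of molecular
predissociation, by simulated hybrid quantum-classical variational search in
the complex absorbing potential (CAP) formalism.

## The science

A metastable molecular state that decays by tunneling is a *Siegert
pseudostate*: an eigenstate with purely outgoing boundary conditions and
complex energy `E = E_r − iΓ/2`, where `Γ` is the decay width and
`τ = 1/Γ` the lifetime. Appending a negative imaginary absorber to the
potential,

    H_N = H_H + i·V_CAP,    V_CAP(x) = −(|x| − x0)²/2  for |x| > x0,

turns those states into discrete complex eigenvalues of a non-Hermitian
matrix. `siegertq` finds them two ways:

1. **Classical reference** — exact diagonalization of the projected `H_N`
   (`cap_reference()`).
2. **Variational search** (`resonance_search()`) — a chain of two
   variational stages per parity block, run as `B` independent batches on
   an arborescence task graph:
   * *Hermitian deflation*: eigenstates of `H_H` found successively by
     minimizing `⟨H_H⟩ + c·Σ_j |⟨ψ(θ)|ψ(θ_j)⟩|²` (penalty `c = 100`);
   * *Pseudovariance refinement*: each Hermitian state seeds a minimization
     of the nonnegative metric
     `σ² = ⟨H_N†H_N⟩ − |⟨H_N⟩|² = ⟨G⟩ − (⟨A⟩² + ⟨W⟩²)`,
     which vanishes exactly on right eigenvectors of `H_N` and is built
     entirely from Hermitian observables `A = H_H`, `W = V_CAP`,
     `G = H_H² + V_CAP² + i[H_H, V_CAP]` — no bilinear c-product needed.

   Records are deduplicated within a run, pooled across batches by minimum
   pseudovariance per physical state, and filtered for spurious CAP
   artifacts (nonresonant, diverging, indifferent).

Circuits are simulated exactly (statevector), with multinomial shot
sampling, or as density matrices under a thermal-relaxation + depolarizing
+ readout-confusion device model, with confusion-matrix inversion and
hybrid exponential/linear zero-noise extrapolation available as mitigation.
Everything runs on an ordinary CPU; the "quantum processor" is the
package's own simulator.

The benchmark potential is
`V0(x) = (x²/2 − J)·exp(−λx²) + J` with `λ = 0.1`, `J = 0.8`, CAP onset
`x0 = 8 au`, on `x ∈ [−10, 10]` with 2^12 grid points, projected onto `2^q`
parity-split sine basis functions. It supports one bound state
(`E_b ≈ 0.50`) and two resonances (`Re E ≈ 1.42` and `2.13`).

## Worked example

```r
library(siegertq)

# classical CAP reference, 16 even-parity basis states (q = 4)
cap_reference(4, "even")$table
#>   label        Re            Im
#> 1 bound 0.5020397 -9.983457e-11
#> 2    r2 2.1220777 -1.175141e-02

# batched variational search at q = 3 (both parities, 8 batches)
res <- resonance_search(3, batch = batch_config(B = 8, N = 4, seed = 4))
reference_comparison(res)[, c("parity", "label", "E", "sigma2", "rel_err_pct")]
#>   parity label                    E       sigma2  rel_err_pct
#> 1   even bound 0.5040872-0.0000202i 4.996004e-16 1.445673e-08
#> 2   even    r2 2.1462552-0.0202135i 2.224342e-06 3.910496e-02
#> 3    odd    r1 1.4274678-0.0001609i 1.755263e-10 2.032765e-05
```

The bound state reproduces the exact CAP eigenvalue of the same basis to
`1e-8 %`; the second resonance — whose Hermitian parent sits fourth in the
deflation chain — lands within `0.04 %`. Its width `Γ = 2|Im E| ≈ 0.040 au`
corresponds to a lifetime of about 25 au. The same search at `q = 4` is
budget-limited (32 ansatz angles, fixed evaluation budgets) and typically
lands within `~1 %` of the exact values.

Noise response of the converged states (gate-noise reduction × qubit
longevity grid, density-matrix simulation):

```r
sw <- noise_sweep(q = 3, seed = 5)
subset(sw$grid, label == "bound" & longevity == 1000)
#>    gate_factor longevity label    sigma2 fidelity_error
#> 7            1      1000 bound 0.2686500   1.807421e-02
#> 16          10      1000 bound 0.2147763   2.177351e-03
#> 25         100      1000 bound 0.1680558   5.728483e-04
```

Both the sampled pseudovariance and the fidelity error against the exact
eigenvector fall as the device improves.

A thin command-line front end ships at `inst/scripts/siegertq-cli.R`
(subcommands `reference`, `run`, `sweep`, `report`).

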