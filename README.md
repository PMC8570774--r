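# peddrs

Reconstruction of internal Cerenkov light sources from surface
measurements — Cerenkov luminescence tomography (CLT) — with the
P-EDDRS framework: probabilistic energy distribution density region
scaling.

## The problem

Radiotracers such as ¹⁸F-FDG emit Cerenkov light inside tissue. A CCD
camera sees only the photon flow rate on the animal's surface, and the
task is to recover the three-dimensional source distribution inside.
Photon transport at the Cerenkov band is well described by the
diffusion approximation with a Robin boundary condition,

    -∇·D(r)∇Φ(r) + μₐ(r)Φ(r) = S(r)        in Ω
    Φ(ξ) + 2 F D(ξ) ∂Φ/∂n(ξ) = 0          on ∂Ω
    D = 1 / (3 (μₐ + μs′)),  F = (1 + Rf)/(1 − Rf)

which, discretized with linear finite elements on a tetrahedral mesh,
yields a linear system **A** x = **B** mapping nodal source strengths
to boundary measurements. **A** is severely ill-conditioned, so one-step
regularized solvers (Tikhonov, damped SVD, soft-thresholded LSQR,
orthogonal matching pursuit) localize poorly on their own.

## The P-EDDRS framework

P-EDDRS wraps any of those solvers in an iterative feasible-region
loop. Each iteration i:

1. solves the subsystem restricted to the active candidate set,
   clamps the solution to be nonnegative;
2. scores it by residual `E_L2 = ‖A x − B‖₂` and cosine similarity
   `E_Cos = ⟨Ax, B⟩/(‖Ax‖‖B‖)`, and refreshes probability weights
   `P_Err ∝ (P_L2 + P_Cos)/2` over the whole history
   (`P_L2 ∝ 1/E_L2`, `P_Cos ∝ E_Cos`);
3. treats the normalized solution as a spatial probability
   distribution, takes its weighted centroid and 3×3 coordinate
   covariance, and forms an oriented cuboid ROI from the covariance
   eigenframe (half-lengths |eigenvalue|·Size);
4. rescales the ROI (Size ∈ {0.5, 1, 2}) by comparing its node supply
   to the look-ahead budget, and refreshes the active set: ROI nodes
   first, then intensity-ranked nodes, deduplicated and truncated to a
   budget that shrinks by the attenuation coefficient
   `β = (Cut_Num/Num_f)^(1/(L_max−1))`.

After at most `L_max = 50` iterations the history is Gaussian-filtered
(iterations within one standard deviation of the mean on both scores)
and the retained solutions are fused with recomputed weights into the
final distribution. Location error, Dice coefficient, volume ratio and
relative residual evaluate the result against ground truth.

Because no raw CLT data are deposited anywhere, the package also ships
a synthetic phantom module: structured tetrahedral box phantoms with
organ regions carrying published 630 nm optics, embedded sources of
four shapes, and an FEM-simulated noisy measurement generator — the
whole method is exercisable end to end without external data.

## Worked example

```r
library(peddrs)

mesh <- peddrs_phantom()                    # 3,150-node organ phantom
fem  <- assemble_fem(mesh)                  # FEM diffusion system
A    <- build_system_matrix(fem)            # boundary response operator

src   <- source_geometry("sphere", center = c(5.25, 5.25, 6), dims = 0.8)
truth <- true_source_nodes(mesh, src)
B <- simulate_surface_flux(A, truth$indicator[A$col_nodes],
                           noise_level = 0.05, seed = 1)

res <- run_peddrs(A, B, mesh, solver_spec("tikhonov"))
res
#> recon_result: tikhonov, 50 iterations (29 retained), beta = 1.1355
#>   final residual e_l2 = 0.08209, e_cos = 0.9986

evaluate_reconstruction(res, truth, mesh, A, B)
#>          x        y        z       e_l      dice       r_v       r_r
#> 1 5.220048 5.213294 6.012629 0.0490305 0.2258065 0.1272727 0.8546174
```

The loop localizes the 0.8 mm source to within 0.05 mm (`e_l`, the
Euclidean distance between the reconstructed and true centres), against
roughly 1 mm for the same solver run once on the full region. `dice`
measures node-set overlap with the truth at 10% of the peak intensity,
`r_v` the true-to-reconstructed volume ratio, and `r_r` the relative
data residual of the unit-mass-normalized fusion. The per-iteration
schedule (active nodes, budget, ROI size, scores, weights) is in
`res$audit`.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/clt-simulate.R   --out run1 --seed 1
Rscript inst/cli/clt-reconstruct.R --dir run1 --solver tikhonov
Rscript inst/cli/clt-evaluate.R    --dir run1
```

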