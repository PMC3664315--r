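# bbseg

Unsupervised segmentation of 3D end-effector trajectories into movement
primitives by **Bayesian binning**: exact Bayesian inference over all
partitions of a discretized time axis into contiguous segments, each
described by a multivariate Gaussian observation model whose mean is a
polynomial in time, with a conjugate extended Gauss–Wishart prior. The
package is aimed at motor-control and movement-kinematics researchers who
want to decompose recorded hand/wrist paths (e.g. signing or drawing
movements sampled at 240 Hz) into segments, choose the polynomial order of
the segment model by Bayesian model comparison, and relate the segments to
the generalized speed–curvature power law.

## The model

A trajectory on `[t_min, t_max]` is discretized into `T` bins of width
`Δt`. A segmentation with `M` boundaries splits the bins into `M + 1`
contiguous segments with inclusive upper boundaries `q_m`; the data
likelihood factorizes over segments,

```
P(D | {q_m}, M) = ∏_m P(D_m | q_(m-1), q_m)
```

with a flat prior `P({q_m} | M) = 1 / C(T-1, M)` over boundary
configurations and `P(M) = 1/T`. Within a segment, observations
`x_t ∈ R^3` are Gaussian with precision matrix `P` and polynomial mean
`μ(t) = Σ_i a_i φ_i(t)`; the conjugate prior is Wishart on `P` (density
`∝ |P|^((ν-L-1)/2) exp(-tr(V⁻¹P)/2)`) and matrix-normal on the
coefficients with Kronecker precision `B ⊗ P`, so the per-segment marginal
likelihood (evidence) is available in closed form. The marginal
`P(D | M)` is then computed *exactly* for every `M` by a sum–product
(forward/backward) recursion in `O(M T²)` rather than by enumerating the
`C(T-1, M)` configurations, and yields the posterior over the number of
boundaries, the per-edge boundary probability ("segmentation density"),
the posterior expected trajectory, and the predicted segmentation points
(PSP). Scanning polynomial orders 0–7 gives a posterior over orders — the
model-comparison question "are movement primitives minimum-acceleration
(cubic) or minimum-jerk (quintic) arcs?" becomes an evidence computation.

The package also implements the surrounding experimental protocol:

* **kinematics** — zero-phase 6 Hz FIR smoothing, speed `v = ||r'||` and
  Euclidean curvature `κ = ||r' × r''|| / ||r'||³`, and bound-constrained
  nonlinear regression of the generalized power law `v = α κ^β`
  (`β ∈ [-1, 0]`) with the compliance score `R²`.
* **ground truth** — synthesis of trajectories whose segments *exactly*
  obey segment-wise power laws: random partition (segments > 300 ms),
  uniform exponents with adjacent gaps > 0.1, continuity-constrained gain
  factors, and spline time warping `dτ/dt = v κ^(-β_i) / α_i` that
  reparameterizes the clock while preserving the spatial path.
* **evaluation** — greedy matching of predicted vs true boundaries within
  a 90 ms window, hit rate, false positives per second, HPFPPS
  (hit rate / fp/s), and a simulated homogeneous-Poisson "line of no
  discrimination".
* **synthetic** — seeded generators for smooth band-limited base
  movements and piecewise-polynomial stroke sequences with known
  boundaries, so every experiment runs without any recordings.

## Worked example

```r
library(bbseg)

## a piecewise-cubic 3-stroke movement with known boundaries, 0.08 cm noise
pp <- generate_piecewise_poly(piecewise_poly_spec(seed = 7))
pp$boundaries
#> [1] 0.48 1.58

## segment it at order 3 with T = 100 bins
res <- bb_segment(pp$trajectory, order = 3)
res
#> bb_result: order 3, T = 100 bins of 0.02 s; M_opt = 2 (posterior 1.000)
#>   predicted segmentation points (s): 0.480, 1.600

match_points(res$psp, pp$boundaries, window = 0.09, duration = 2)
#> match_result: 2 hits, 0 misses, 0 false positives | hit rate 1.000, 0.000 fp/s (window 90 ms)

## which polynomial order describes the strokes best?
scan <- bb_order_scan(pp$trajectory, orders = 0:7)
scan$order_opt
#> [1] 3

explained_variance(pp$trajectory, res$expected)
#> [1] 0.9998675
```

Both true boundaries are hit within the 90 ms window (the first exactly,
the second one bin off), the order posterior identifies the cubic segment
structure, and the posterior expected trajectory explains essentially all
variance.

A thin command-line wrapper is installed as `exec/bbseg` with subcommands
`generate`, `warp`, `segment`, `orderscan` and `evaluate`; see
`bbseg_cli()`.

## Acceptance script

`scripts/acceptance.R` regenerates the package's headline simulation
quantities from scratch against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It generates 20 seeded smooth synthetic movements, runs Bayesian binning
at orders 0 and 3, and reports the mean explained variance of the
posterior expected trajectories (t1, t2); it then synthesizes 20 power-law
ground-truth trajectories by time warping and reports the minimum
per-segment compliance `R²` of the refitted power laws (t3). All
randomness derives from `--seed`.

## Vignette

`vignettes/bayesian-binning.Rmd` documents the model and its assumptions,
the prior calibration (including why the Wishart scale carries the data
variances and why the coefficient prior lives in an orthonormal segment
basis), the synthetic worlds the generators emulate, numerical choices,
and known limitations of order selection on time-warped data.
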