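---
title: "Edge-enhancing reconstruction with flexible Golub-Kahan hybrid solvers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-enhancing reconstruction with flexible Golub-Kahan hybrid solvers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexgk)
```

## The problem

We consider large-scale linear inverse problems in imaging,
$$ A x_{\mathrm{true}} + e = b, \qquad A \in \mathbb{R}^{m\times n}, $$
where $b$ is measured data, $e$ is Gaussian white noise, and
$x_{\mathrm{true}}$ is the column-stacked vector of an $N\times N$ image
($n = N^2$). Deblurring, inpainting and computed tomography all fit this
template; in each case $A$ is severely ill-conditioned with singular values
clustering at zero, so plain least squares is useless and regularization is
required. Quadratic (Tikhonov) penalties are easy to minimize but
over-smooth edges. Edge-preserving penalties act on the discrete image
gradient: isotropic total variation (TV) penalizes the pointwise gradient
magnitude in the $\ell_1$ norm, anisotropic TV (aTV) the two gradient
components separately,
$$ \mathrm{TV}(x) = \bigl\| \sqrt{(D_v x)^2 + (D_h x)^2} \bigr\|_1, \qquad
   \mathrm{aTV}(x) = \| D_{2d}\, x \|_1 , $$
with $D_{2d} = [D_v; D_h] = [I\otimes D_{1d};\, D_{1d}\otimes I]$ the
stacked first-difference operator ([apply_gradient()]).

## Reweighted least squares and the three weighting schemes

Both penalties (smoothed by a parameter $\tau > 0$) can be written as
solution-dependent weighted 2-norms,
$\Omega(x) \approx \| W(D_{2d}x)\, D_{2d} x \|_2^2$, with diagonal weights
built from $f_{1,\tau}(v) = (\|v\|_2^2+\tau^2)^{-1/4}$:

* **tv** — both gradient blocks share the weight of the pointwise
  magnitude $\sqrt{(D_vx)_j^2 + (D_hx)_j^2}$;
* **atv** — componentwise weights per block;
* **diag** — a heuristic cumulative scheme: at each update, entries near
  the currently dominant edge (normalized weighted gradient magnitude close
  to one) keep almost no weight while flat regions are damped towards
  $1+\tau$ times their previous weight, so edge information accumulates
  across iterations. This scheme is not the gradient of any variational
  objective; it is a weighting rule only.

$\tau$ defaults to $10^{-10}$; it only guards divisions by zero and its
exact value is immaterial as long as it is small. The `diag` exponent
`a` controls how hard presumed-smooth regions are penalized; we default to
`a = 1` and expose it as a configuration knob, since no canonical value
exists — results with the `diag` scheme depend on it.

Classically these problems are solved by iteratively reweighted norms
(IRN): an outer loop freezes the weights, an inner Krylov solver minimizes
the quadratic, and the weights are then refreshed — implemented here in
[irn()], with cold restarts, identity first-cycle weights and a per-cycle
inner stopping rule. The flexible solvers below avoid the nested loop
entirely by refreshing the weights *every* iteration inside a single
growing subspace.

## Standard-form transformation

The penalty $\|W D_{2d} x\|^2$ has the constant image in its null space,
so the problem is first transformed to standard form. With
$K = n^{-1/2}\mathbf{1}$, the data determine a null-space component
$x_0 = K (AK)^+ b$ explicitly, and the remaining component is sought in
the range of the $A$-weighted pseudoinverse
$(W D_{2d})_A^+ = E\,(W D_{2d})^+$, where $E = I - K(AK)^+A$ is an oblique
projector. Both $x_0$ and $E$ cost one operator apply and are built once,
ahead of the iterations ([build_standard_form()]).

Applying $(W D_{2d})^+$ exactly is expensive because $W D_{2d}$ is
overdetermined and the diagonal weights break its Kronecker structure. We
therefore use the structured approximation
$$ \tilde{L}^+ = D_{2d}^+ W^{-1}, $$
which is the pseudoinverse of $W D_{2d}$ in the $W^{-2}$ norm and exact
whenever the weights are scalar. $D_{2d}^+$ itself is applied through the
Kronecker-structured SVD of the 1D difference operator: each right-basis
mode pairs one singular value from the vertical block with one from the
horizontal block via a Givens rotation, giving paired values
$\sqrt{\sigma_a^2+\sigma_b^2}$ with exactly one zero (the constant mode,
identified analytically rather than by thresholding, so the rank is never
tolerance-dependent). One application costs $O(n^{3/2})$ flops and no
$n \times n$ matrix is ever formed ([build_spectral_factors()],
[apply_gradient_pinv()]). For the cumulative `diag` weights the exact
reciprocal $w^{-1}$ behaves poorly (the weights are products over all
previous iterations and underflow towards $\tau$-sized values), so the
first-order expansion $W^{-1} \approx \mathrm{diag}(1+w)$ is used, which
is the form [apply_inverse_weights()] implements for that scheme.

An exact dense pseudoinverse of $W D_{2d}$ is available behind the
`exact_pinv` flag (guarded to $N \le 64$); it exists both as an oracle for
the test suite and as the exact-pseudoinverse solver variant, whose
behavior can be compared against the structured approximation.

## The flexible Golub-Kahan solver

The flexible factorization maintains orthonormal bases $U_{i+1}$ (data
space) and $V_{i+1}$ (image space) and preconditioned directions
$Z_i$ with
$$ A Z_i = U_{i+1} H_i, \qquad A^T U_{i+1} = V_{i+1} T_{i+1}, $$
$H_i$ upper Hessenberg, $T_{i+1}$ upper triangular. Each iteration costs
four operator applies: $v_i$ from $A^T u_i$ (orthogonalized), the new
direction
$z_i = E \tilde{L}^+ (\tilde{L}^+)^T E^T v_i$
with the *current* weights, and $u_{i+1}$ from $A z_i$ (orthogonalized).
Because the preconditioner changes with the weights, the span of $Z_i$ is
not a Krylov subspace — but if the weights are frozen it coincides with
the Krylov subspace generated by the preconditioned normal operator, and
the whole scheme collapses to the priorconditioned Golub-Kahan hybrid
([gkb_hybrid()]); the test suite verifies the iterates agree to $10^{-6}$
in the unregularized case. We include $E$ inside the preconditioner by
default, preserving the exact splitting $x = x_0 \oplus
\mathrm{range}(E D_{2d}^+)$; a flag drops it, since the factorization
itself never reuses $E$ after the setup step and both conventions are
defensible.

The projected problem at iteration $i$ is
$$ s_i = \arg\min_s \|H_i s - \beta e_1\|_2^2 + \lambda \|R_i s\|_2^2,
   \qquad x^{(i)} = x_0 + Z_i s_i , $$
where $R_i$ is the triangular factor of the economy QR of
$W_i D_{2d} Z_i$ — the *exact* projection of the current reweighted
penalty onto the subspace ($O(\tilde n i^2)$, negligible for
$i \ll n$). The data-fit term satisfies the residual identity
$\|b - A x^{(i)}\| = \|\beta e_1 - H_i s_i\|$, so everything needed for
parameter selection lives in dimension $O(i)$.

**Convergence.** For the tv/atv schemes with a *fixed* $\lambda$, each
iteration minimizes a quadratic tangent majorant of the smoothed
variational objective
$F(x) = \|Ax-b\|^2 + \hat\lambda\,\Omega(x)$, $\hat\lambda = 2\lambda$,
over a nested family of subspaces, so $F(x^{(i)})$ is non-increasing. In
our majorant the previous-iterate term enters as
$\lambda\,\Omega(x_l)$ — with that scaling tangency
$Q(x_l;x_l) = F(x_l)$ holds identically, which the test suite asserts
exactly, alongside the monotone decrease on a $16\times16$ deblurring
problem over 30 iterations. The smoothing $\tau$ perturbs the majorant
inequality by at most $\tau$ per gradient entry, far below the test
tolerances.

## Choosing lambda and stopping

With a noise-norm estimate $\|e\|_2$ (synthetic problems carry the exact
value), $\lambda_i$ solves the discrepancy equation
$\|\beta e_1 - H_i s_i(\lambda)\| = \eta \|e\|_2$ on the projected
problem, with safety factor $\eta = 1.01$. The projected residual is
monotone in $\lambda$, and the equation only becomes solvable once the
unregularized projected residual drops below the target — so the selected
parameter is zero for an initial run of iterations and then turns
positive. We solve it by bracketed bisection on $\log_{10}\lambda$ over
$[10^{-12}, 10^{12}]$ to a relative residual tolerance of $10^{-6}$;
the problem is tiny ($O(i)$) and monotone, so robustness beats
sophistication here. If even $\beta$ falls below the target, the guard
value $10^{12}$ is returned.

Iterations stop at the first $k > 2$ with
$$ \frac{|\lambda_k-\lambda_{k-1}|}{\lambda_k} < \xi
   \quad\text{and}\quad
   \frac{|\lambda_{k-1}-\lambda_{k-2}|}{\lambda_{k-1}} < \xi ,
   \qquad \xi = 0.9 , $$
with zero parameters excluded (the ratios divide by $\lambda$), i.e., two
consecutive stabilized positive values. Defaults throughout:
$\eta = 1.01$, $\xi = 0.9$, $\tau = 10^{-10}$, `maxit = 200`.

## Numerical choices

* Column-major vectorization everywhere; `matrix(x, N, N)` inverts it.
* Kronecker products are applied via `(A %x% B) x = vec(B X t(A))`, never
  materialized.
* Orthogonalization uses one modified Gram-Schmidt pass plus one
  refinement pass (full reorthogonalization): the subspaces hold at most a
  few hundred vectors, so robustness is cheap.
* Breakdown is declared when a new basis vector's norm falls below
  $10^{-12}$ times its pre-orthogonalization norm; the solver returns the
  best iterate instead of dividing by noise.
* The preconditioned directions $z_i$ are normalized before entering
  $Z_i$; this is a pure reparametrization of the subspace (the projected
  problem absorbs the scale) and equalizes the wildly different magnitudes
  the first $\tau$-dominated weight state would otherwise induce.
* The projected least-squares systems are solved through the SVD with a
  minimum-norm convention, so rank-deficient $R_i$ (constant-direction
  columns) cannot break the solver.
* Degenerate inputs: an operator that annihilates constant images is
  rejected at transformation time (tolerance $10^{-12}$ against a cheap
  norm estimate); data fully explained by the constant component return
  $x_0$ immediately.

## Synthetic test problems

The generators emulate the standard experimental setup for this class of
solvers with no external data:

* [pattern_phantom()] — a deterministic piecewise-constant scene
  (rectangle, disc, triangle, $\le 5$ intensity levels, mostly
  background): a low-TV target for deblurring.
* [blur_operator()] — Gaussian blur (separable, reflexive boundary
  conditions, matrix-free) or a seeded random-walk "shake" point-spread
  function (sparse matrix). Blur strengths "mild"/"medium" map to
  $\sigma = 1$ and $2$ pixels; these are our own calibration of
  qualitative labels, not a reproduction of any particular generator's
  kernels.
* [mask_operator()] — cluster undersampling: a union of seeded random
  discs, trimmed to hit the requested retained fraction exactly.
* [ct_operator()] — parallel-beam line-model system matrix: angle
  $\theta$ sends rays along $(-\sin\theta, \cos\theta)$ with unit
  detector spacing centered on the image and
  $\mathrm{round}(\sqrt{2}N)$ detector elements, so
  $m = |\text{angles}|\cdot\mathrm{round}(\sqrt 2 N)$ (for $N = 256$ and
  angles $0,2,\dots,178$: $32{,}580 \times 65{,}536$). Entries are exact
  ray-pixel intersection lengths; a fixed $10^{-6}$-pixel detector offset
  guards rays that would otherwise run exactly along pixel boundaries.
  The matrix is validated against an independent line-square clipping
  oracle.
* [grains_phantom()] — seeded Voronoi tessellation with per-cell random
  intensities, the standard crystalline-grain tomography target.
* [add_noise()] — white Gaussian noise rescaled so
  $\|e\|_2/\|b_{\mathrm{true}}\|_2$ matches the requested level exactly
  (default $0.01$), which also hands the solver the exact noise norm the
  discrepancy principle wants.

All randomness flows through explicit seeds; regenerating with the same
configuration is bit-identical. What these generators do *not* model:
real camera point-spread functions, correlated or signal-dependent noise,
detector physics (beam hardening, scatter), or natural-image statistics.
A passing suite therefore demonstrates the solvers' mathematical
contracts and their behavior on idealized piecewise-constant scenes, not
performance on any particular real dataset.

## Problem sizes used in the checks

The test suite and the acceptance script run the full solver stack at
$32\times 32$ (deblurring; a few hundred subspace dimensions at most),
dense-oracle comparisons at $N \le 8$, the exact-pseudoinverse
convergence check at $16\times 16$ over 30 iterations, and a single
full-size ($N = 256$) tomography matrix assembly. These sizes exercise
every code path while keeping the whole suite in the minutes range; the
solvers themselves are matrix-free and scale to the usual
$256\times 256$ experiments.

## Known limitations

* The `diag` scheme has no objective, hence no convergence theory and no
  `objective` column in its traces; its results depend on the exponent
  `a`.
* The adaptive-$\lambda$ solver is heuristic (as all hybrid
  parameter-choice schemes are): the monotonicity proof covers fixed
  $\lambda$ only.
* The discrepancy principle needs a noise-norm estimate;
  over/under-estimates over/under-regularize, and only a manual override
  (`noise_norm`) is provided for such studies.
* Only zero-boundary one-sided differences are implemented for the
  gradient; no periodic/Neumann variants or higher-order differences.
* The aTV scheme can perform poorly on problems whose solutions are not
  gradient-sparse; this is a property of the regularizer, not a defect of
  the solver.
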