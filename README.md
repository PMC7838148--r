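# gliostat

Estimating the invisible invasion extent of glioblastoma from a single
imaging snapshot, by *stationalizing* a reaction–diffusion growth model.

## The problem

Glioblastoma cells infiltrate far beyond the tumor margin visible on
MRI/DTI — imaging only detects tumor above a volume fraction of roughly
θ ≈ 0.16, while treatment must target the invisible tail.  Forward growth
models of the form

```
∂u/∂t = ∇·(D(x)∇u) + ∇·((∇·D(x)) u) + ρ u (1 − u)
```

(`D` a symmetric positive definite diffusion tensor field reconstructed
from DTI, `ρ` the logistic growth rate) could predict that tail, but need
the unknown seed location/time and patient-specific parameters.

`gliostat` implements the stationary alternative.  In the co-moving frame
of the 1D Fisher–KPP limit, the front converges to the closed-form profile
`U(x̃) = (1 + exp(x̃/√6))⁻²` at the special speed `ṽ = 5/√6`.  Composing
its exact gradient with its inverse turns the advection term into a
closed-form, amplitude-only penalty

```
p(u) = |v| √(2/3) (1 − √u) u ,
```

so the tumor density at scan time solves the *stationary* boundary-value
problem

```
0 = ∇·(D∇u_s) + ∇·((∇·D) u_s) + ρ u_s(1 − u_s) − p(u_s),   u_s = θ on ∂Ω_i,
```

pinned by an internal Dirichlet constraint on the segmented visible tumor
border ∂Ω_i — the only patient information a scan actually provides.  The
package contains the forward solvers (multilinear finite elements, implicit
Euler, Newton with line search), the stationary Newton solver with
outward-branch selection, synthetic diffusion-tensor field generators,
DTI-style scaling with fractional-anisotropy and Péclet diagnostics, and
the level-set error metrics (symmetric difference, characteristic level-set
distance `L_B = |A⊕B|/|∂A|`) used to validate the approximation against
full forward simulations.

## Worked example

The 1D nondimensional validation scenario: simulate growth to t̃ = 20,
threshold the forward solution at 16% (the simulated scan), solve the
pinned stationary problem, and compare:

```r
library(gliostat)

fisher_wave_speed()                        # 2.041241  (5/sqrt(6))
penalty(0.25)                              # 0.2083333 (= 5/24)
effective_reaction(c(0.16, 4/9, 0.7), 1)   # -0.0256  0.0000  0.0194

sc  <- make_fixture("1d-homogeneous")
rec <- run_estimation(sc, levels = c(1e-3, 1e-2, 0.16))
rec
#> run_record '1d-homogeneous'
#>   pinned nodes: 415; Peclet max 0 (100% below 0.3)
#>  level sym_diff L_B_spherical L_B_surface
#>  0.001      0.0           0.0         0.0
#>  0.010      0.4           0.2         0.2
#>  0.160      0.0           0.0         0.0

front_speed(rec$forward, level = 0.5, window = c(10, 20))$speed
#> 2.0931   # approaches the minimum wave speed 2*sqrt(rho*D) = 2
```

The effective reaction is zero at u = 4/9 — growth beats the penalty above
it, the penalty wins below — which is why a small initial guess selects
the outward-moving solution branch.  The level-set table says the
stationary estimate misplaces the 1%-density contour by 0.2 length units
on average (front width ≈ 10), i.e. the invisible margin is recovered to a
small fraction of the front width.  `plot(rec$stationary)` overlays the
estimate, and `write_vtk()` / `write_scalar_nifti()` export fields for
ParaView or neuroimaging viewers.

2D/3D scenarios (`"2d-butterfly"`, `"3d-synthetic"`) exercise banded and
anisotropic media the same way; `gradient_cloud()` and `peclet_field()`
are the diagnostics that tell you whether a given medium is inside the
method's diffusion-dominated validity envelope.

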