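# shared fixtures; expensive runs are computed once per test session
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# the reference 1D homogeneous validation run: [0, 200], 1000 elements,
# rho = D = 1, Gaussian start, t_end = 20
run_1d_homogeneous <- function() {
  cached("run1d", {
    grid <- build_grid(200, 1000)
    field <- homogeneous_field(grid, 1)
    params <- model_params(rho = 1, v_mag = fisher_wave_speed())
    sys <- assemble(grid, field)
    fwd <- solve_forward(grid, field, params,
                         gaussian_ic(grid, center = 100, sd = 1, amplitude = 1),
                         time_controls(20, dt = 0.1), system = sys)
    list(grid = grid, field = field, params = params, sys = sys, fwd = fwd)
  })
}

# paint a nodal disk indicator on a 2D grid
disk_indicator <- function(grid, center, radius) {
  xy <- node_coords(grid)
  as.numeric(sqrt(rowSums(sweep(xy, 2, center)^2)) <= radius)
}
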