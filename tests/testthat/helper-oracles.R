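# Hand-built fixture networks and independent numerical oracles used
# across the test files.  The oracles never call the code paths they
# check.

# minimal valid network object: n compartments, explicit flows
manual_network <- function(volumes, flows, H = 1, R = 0.5, z = NULL) {
  n <- length(volumes)
  comp <- data.frame(iz = seq_len(n), ir = 1L, iphi = 1L,
                     index = seq_len(n), volume = volumes,
                     z = if (is.null(z)) (seq_len(n) - 0.5) * H / n else z,
                     r = R / 2, phi = pi)
  structure(list(spec = NULL, grid = c(n, 1L, 1L), compartments = comp,
                 flows = flows, height = H, radius = R,
                 liquid_volume = sum(volumes)),
            class = "compartment_network")
}

# two equal compartments exchanging at rate q
two_comp_network <- function(q = 0.1, V = 1) {
  manual_network(c(V / 2, V / 2),
                 data.frame(from = c(1L, 2L), to = c(2L, 1L),
                            rate = q, kind = "exchange"))
}

# 1D chain of n cells, volume V total, neighbour exchange q
chain_network <- function(n, q, V = 1, H = 1) {
  i <- seq_len(n - 1L)
  manual_network(rep(V / n, n),
                 data.frame(from = c(i, i + 1L), to = c(i + 1L, i),
                            rate = q, kind = "exchange"),
                 H = H)
}

single_comp_network <- function(V = 1) {
  manual_network(V, data.frame(from = integer(0), to = integer(0),
                               rate = numeric(0), kind = character(0)))
}

toy_tank_spec <- function() {
  reactor_spec("toy", "stirred_tank", tank_diameter = 1,
               working_volume = pi / 4 * 2, aspect_ratio = 2,
               n_impellers = 1, impeller_ratio = 1 / 3, stirrer_speed = 1)
}

# explicit finite-volume integration of the 1D axial diffusion equation
# with insulated ends; point feed deposited in the cell containing z0
fv_axial_diffusion <- function(z0, t_end, H = 1, d = 1, n_cells = 400) {
  dz <- H / n_cells
  u <- numeric(n_cells)
  cell <- min(n_cells, max(1L, ceiling(z0 / dz)))
  u[cell] <- 1 / dz           # unit mass, mean 1
  dt <- 0.4 * dz^2 / (2 * d)
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps
  lam <- d * dt / dz^2
  for (s in seq_len(nsteps)) {
    flux <- lam * diff(u)                 # inward flux at interior faces
    u <- u + c(flux, 0) - c(0, flux)
  }
  list(z = (seq_len(n_cells) - 0.5) * dz, u = u)
}

# dense Newton root-finder for the substrate steady state (oracle for
# the sparse pseudo-time solver)
dense_substrate_oracle <- function(op, feed, params, F = params$F) {
  A <- as.matrix(op$A) * 3600
  V <- op$volumes
  f <- numeric(length(V))
  f[feed$index] <- feed$weight * F * sum(V) / V[feed$index]
  qX <- params$qS * params$X; KS <- params$KS
  S <- rep(ideal_reactor_state(params, F)$S, length(V))
  for (it in 1:200) {
    r <- A %*% S + f - qX * S / (S + KS)
    J <- A - diag(qX * KS / (S + KS)^2)
    step <- solve(J, -r)
    lam <- 1
    repeat {  # damped to keep S positive
      S_new <- S + lam * step
      if (all(S_new > 0)) break
      lam <- lam / 2
      if (lam < 1e-12) stop("oracle line search failed")
    }
    S <- as.numeric(S_new)
    if (max(abs(r)) < 1e-13 * F) break
  }
  S
}

vol_mean <- function(x, V) sum(x * V) / sum(V)
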