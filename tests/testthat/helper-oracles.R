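# Shared oracles and cached fixtures for the test suite.

# Explicit finite-difference solution of the 2D diffusion equation
# (independent oracle for the closed-form Gaussian generators).
fd_diffuse <- function(init, D, h, dt, n_steps) {
  u <- init
  lam <- D * dt / h^2
  stopifnot(lam <= 0.25)  # explicit-scheme stability
  ny <- nrow(u); nx <- ncol(u)
  for (s in seq_len(n_steps)) {
    up <- u[c(1, 1:(ny - 1)), ]; dn <- u[c(2:ny, ny), ]
    lf <- u[, c(1, 1:(nx - 1))]; rt <- u[, c(2:nx, nx)]
    u <- u + lam * (up + dn + lf + rt - 4 * u)
  }
  u
}

# lazily computed shared objects (built once per test run)
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

ref_geometry_1um <- function() device_geometry(1)
ref_geometry_6um <- function() device_geometry(6)
ref_config <- function(Q_inj = 0.16, Q_ratio = 0.3) {
  flow_config(Q_inj, Q_inj / Q_ratio)
}

ref_envelope_1um <- function() {
  cached("env1", compute_envelope(ref_geometry_1um(), ref_config(),
                                  n_streamlines = 200, seed = 1))
}

# synthetic deposition result with known transverse spread, for the
# stroke-width oracle tests
make_depo <- function(x, y, tip_path) {
  structure(data.frame(x = x, y = y, t = seq_along(x)),
            tip_path = cbind(t = seq_len(nrow(tip_path)), tip_path),
            n_released = length(x), n_adsorbed = length(x),
            n_aspirated = 0L,
            class = c("deposition_result", "data.frame"))
}
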