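# small gridded fields built in code for unit tests

static_forcing <- function(U0 = 1, period = 1) oscillatory_forcing(U0, period)

# time-constant gridded field from velocity functions u(x, y), v(x, y)
make_static_field <- function(ufun, vfun, L = 10, dx = 0.5, ny_extra = 0,
                              substrate = substrate_profile("flat")) {
  x <- seq(0, L, by = dx)
  y <- seq(0, L, by = dx)
  U <- outer(y, x, function(yy, xx) ufun(xx, yy))
  V <- outer(y, x, function(yy, xx) vfun(xx, yy))
  solid <- matrix(FALSE, length(y), length(x))
  gridded_field(x, y, times = 0,
                u = array(U, c(length(y), length(x), 1)),
                v = array(V, c(length(y), length(x), 1)),
                solid_mask = solid,
                forcing = static_forcing(U0 = max(abs(c(U, V)), 1)),
                substrate = substrate)
}

make_uniform_field <- function(u0, v0, L = 10, dx = 0.5) {
  make_static_field(function(x, y) u0 + 0 * x, function(x, y) v0 + 0 * x,
                    L = L, dx = dx)
}

# solid-body rotation about the domain centre
make_rotation_field <- function(omega = 1, L = 10, dx = 0.25) {
  xc <- L / 2
  make_static_field(function(x, y) -omega * (y - xc),
                    function(x, y) omega * (x - xc), L = L, dx = dx)
}

# simple shear u = gamma * y
make_shear_field <- function(gamma = 1, L = 10, dx = 0.5) {
  make_static_field(function(x, y) gamma * y, function(x, y) 0 * x,
                    L = L, dx = dx)
}

# random smooth divergence-free field from a streamfunction (central
# differences, so the discrete divergence vanishes like the generator's)
make_random_psi_field <- function(seed = 1, L = 10, dx = 0.25, nmodes = 4) {
  set.seed(seed)
  a <- rnorm(nmodes); b <- rnorm(nmodes)
  kx <- sample(1:3, nmodes, replace = TRUE)
  ky <- sample(1:3, nmodes, replace = TRUE)
  psi <- function(x, y) {
    out <- 0
    for (m in seq_len(nmodes)) {
      out <- out + a[m] * sin(2 * pi * kx[m] * x / L + b[m]) *
        sin(2 * pi * ky[m] * y / L)
    }
    out
  }
  x <- seq(0, L, by = dx)
  y <- seq(0, L, by = dx)
  xg <- c(x[1] - dx, x, x[length(x)] + dx)
  yg <- c(y[1] - dx, y, y[length(y)] + dx)
  P <- outer(yg, xg, function(yy, xx) psi(xx, yy))
  ny <- length(y); nx <- length(x)
  U <- (P[3:(ny + 2), 2:(nx + 1)] - P[1:ny, 2:(nx + 1)]) / (2 * dx)
  V <- -(P[2:(ny + 1), 3:(nx + 2)] - P[2:(ny + 1), 1:nx]) / (2 * dx)
  gridded_field(x, y, times = 0,
                u = array(U, c(ny, nx, 1)), v = array(V, c(ny, nx, 1)),
                solid_mask = matrix(FALSE, ny, nx),
                forcing = static_forcing(U0 = max(abs(c(U, V)))))
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
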