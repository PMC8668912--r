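# Independent numerical oracles, deliberately kept apart from the package's
# closed-form code paths.

# Countercurrent two-stream exchanger solved as a boundary-value problem.
# Blood enters at x = 0 with Cb = 1; dialysate enters at x = 1 with Cd = 0
# and flows toward x = 0. Local flux per unit fiber length is
# ka * (s * Cb - Cd):
#   qb Cb' = -ka (s Cb - Cd),   qd Cd' = -ka (s Cb - Cd).
# Discretised with the box (midpoint) scheme on a uniform grid and solved
# as one sparse banded linear system - a global solve is stable even when
# ka/qd is large, where marching/shooting blows up exponentially. Second
# order in h; Richardson extrapolation over n and 2n removes the leading
# error term.
.bvp_box <- function(qb, qd_ml_min, k0a, s, n) {
  ka <- k0a
  h <- 1 / n
  i <- 0:(n - 1)
  idxB <- function(j) 2 * j + 1        # Cb_j, j = 0..n
  idxD <- function(j) 2 * j + 2        # Cd_j
  rb <- 2 * i + 1                      # blood equation rows
  rd <- 2 * i + 2                      # dialysate equation rows
  rows <- c(rb, rb, rb, rb, rd, rd, rd, rd, 2 * n + 1, 2 * n + 2)
  cols <- c(idxB(i), idxB(i + 1), idxD(i), idxD(i + 1),
            idxD(i), idxD(i + 1), idxB(i), idxB(i + 1),
            idxB(0), idxD(n))
  one <- rep(1, n)
  vals <- c(one * (-1 / h + ka * s / (2 * qb)),
            one * ( 1 / h + ka * s / (2 * qb)),
            one * (-ka / (2 * qb)),
            one * (-ka / (2 * qb)),
            one * (-1 / h - ka / (2 * qd_ml_min)),
            one * ( 1 / h - ka / (2 * qd_ml_min)),
            one * ( ka * s / (2 * qd_ml_min)),
            one * ( ka * s / (2 * qd_ml_min)),
            1, 1)
  rhs <- numeric(2 * (n + 1))
  rhs[2 * n + 1] <- 1                  # Cb(0) = 1
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(2 * (n + 1), 2 * (n + 1)))
  y <- as.numeric(Matrix::solve(A, rhs))
  qb * (1 - y[idxB(n)])
}

bvp_clearance <- function(qb, qd_ml_min, k0a, s = 1, n = 1500) {
  k1 <- .bvp_box(qb, qd_ml_min, k0a, s, n)
  k2 <- .bvp_box(qb, qd_ml_min, k0a, s, 2 * n)
  (4 * k2 - k1) / 3
}

# Fine-step RK4 integrator for the well-mixed container ODE
# V dC/dt = -k/1000 * (C - cd), V in L, k in ml/min.
rk4_container <- function(c0, cd, k, v_l, duration, n_steps = 20000) {
  h <- duration / n_steps
  f <- function(c) -k / (1000 * v_l) * (c - cd)
  c <- c0
  for (i in seq_len(n_steps)) {
    k1 <- f(c); k2 <- f(c + h / 2 * k1)
    k3 <- f(c + h / 2 * k2); k4 <- f(c + h * k3)
    c <- c + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  c
}

default_assay <- function(cv = 0.02) assay_params(extinction_coefficient = 1,
                                                  noise_cv = cv)
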