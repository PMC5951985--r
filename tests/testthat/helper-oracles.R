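# Independent oracles used to freeze expected values. Each is a deliberately
# naive implementation, kept separate from the package's computational path.

# scalar-loop VAR recursion: y(t) = drive(t) + sum_p G(p) y(t-p)
naive_var <- function(kernels, drive) {
  n <- nrow(drive); T <- ncol(drive); P <- dim(kernels)[3]
  Y <- matrix(0, n, T)
  for (t in seq_len(T)) {
    for (i in seq_len(n)) {
      acc <- drive[i, t]
      for (p in seq_len(min(t - 1, P))) {
        for (j in seq_len(n)) acc <- acc + kernels[i, j, p] * Y[j, t - p]
      }
      Y[i, t] <- acc
    }
  }
  Y
}

# exhaustive 2x2 unitary minimizer of the off-diagonal L1 norm of U %*% B0.
# Any 2x2 unitary equals a left diagonal phase (which leaves entry moduli
# unchanged) times [[cos(th), sin(th) e^{i psi}], [-sin(th) e^{-i psi},
# cos(th)]], so a (th, psi) grid plus Nelder-Mead polish is exhaustive.
oracle_2x2_cost <- function(B0, n_grid = 180) {
  u_of <- function(th, psi)
    matrix(c(cos(th), -sin(th) * exp(-1i * psi),
             sin(th) * exp(1i * psi), cos(th)), 2, 2)
  cost <- function(par) {
    M <- u_of(par[1], par[2]) %*% B0
    Mod(M[1, 2]) + Mod(M[2, 1])
  }
  th <- seq(0, pi / 2, length.out = n_grid)
  psi <- seq(0, 2 * pi, length.out = n_grid)
  vals <- outer(th, psi, Vectorize(function(a, b) cost(c(a, b))))
  # polish from the best few distinct grid cells (narrow basins exist)
  ord <- order(vals)[1:8]
  starts <- cbind(th[(ord - 1) %% n_grid + 1], psi[(ord - 1) %/% n_grid + 1])
  best <- min(vals)
  for (i in seq_len(nrow(starts))) {
    pol <- stats::optim(starts[i, ], cost, method = "Nelder-Mead",
                        control = list(reltol = 1e-13, maxit = 3000))
    best <- min(best, pol$value)
  }
  best
}

# brute-force pair-counting AUC over off-diagonal entries
oracle_auc <- function(scores, truth) {
  s <- Mod(scores[row(scores) != col(scores)])
  y <- truth[row(truth) != col(truth)] != 0
  pos <- s[y]; neg <- s[!y]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# closed-form spectral density of a VAR(1): S(w) = H S_e H^H with
# H = (I - A e^{-iw})^{-1}, in the convention where unit-variance white
# noise has flat spectrum 1 (matching the package's CSD normalization)
var1_spectrum <- function(A, sigma2, freq, dt) {
  n <- nrow(A)
  H <- solve(diag(n) - A * exp(-2i * pi * freq * dt))
  H %*% (diag(sigma2, n)) %*% Conj(t(H))
}

# random Hermitian positive-definite complex matrix
rand_hpd <- function(n, jitter = 0.5) {
  Z <- matrix(complex(real = stats::rnorm(n * n),
                      imaginary = stats::rnorm(n * n)), n, n)
  Z %*% Conj(t(Z)) / n + diag(jitter, n)
}

# random complex sparse coupling matrix and its exact factor pair
make_sparse_truth <- function(n, density, wmin, wmax, seed) {
  withr::with_seed(seed, {
    G <- matrix(0 + 0i, n, n)
    off <- which(row(diag(n)) != col(diag(n)))
    pick <- sample(off, max(1, round(density * length(off))))
    w <- stats::runif(length(pick), wmin, wmax)
    G[pick] <- w * exp(1i * stats::runif(length(pick), -1, 1))
    X <- diag(stats::runif(n, 0.5, 2))
    B <- solve(sqrt(X)) %*% (diag(n) - G)
    list(G = G, B = B, C = solve(Conj(t(B)) %*% B))
  })
}
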