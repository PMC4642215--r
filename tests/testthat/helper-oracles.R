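# Independent oracles used across the suite.  These deliberately avoid the
# package's closed-form solvers: feasibility is decided by randomized
# numerical search, classicality by existence of a 4-atom probability mass
# function.

# Kolmogorov polytope oracle: a triplet is classical iff the 4-atom pmf
# (p11, p12, p21, p22) with the triplet's marginals has all atoms >= 0.
# The marginal constraints force p11 = mu_ab, so existence reduces to
# non-negativity of the implied atoms.
oracle_classical <- function(mu_a, mu_b, mu_ab, tol = 1e-9) {
  atoms <- c(mu_ab, mu_a - mu_ab, mu_b - mu_ab, 1 - mu_a - mu_b + mu_ab)
  all(atoms >= -tol)
}

# Randomized numerical search over C^3 states/projectors satisfying the
# norm and marginal conditions: returns the best residual reached for the
# orthogonality + interference objective; ~0 iff the triplet is
# representable in the first sector.
oracle_first_sector_search <- function(mu_a, mu_b, mu_ab, n_starts = 8) {
  intf <- mu_ab - (mu_a + mu_b) / 2
  obj_rank1 <- function(par) {
    lam <- sin(par[1])^2
    kap <- sin(par[2])^2
    g <- par[3:5]
    a <- c(
      sqrt(mu_a), sqrt(lam * (1 - mu_a)),
      sqrt((1 - lam) * (1 - mu_a))
    ) * exp(1i * g)
    b <- c(sqrt(mu_b), sqrt(kap * (1 - mu_b)), sqrt((1 - kap) * (1 - mu_b)))
    Mod(sum(Conj(a) * b))^2 + (Re(Conj(a[1]) * b[1]) - intf)^2
  }
  obj_rank2 <- function(par) {
    lam <- sin(par[1])^2
    kap <- sin(par[2])^2
    g <- par[3:5]
    a <- c(sqrt(lam * mu_a), sqrt((1 - lam) * mu_a), sqrt(1 - mu_a)) *
      exp(1i * g)
    b <- c(sqrt(kap * mu_b), sqrt((1 - kap) * mu_b), sqrt(1 - mu_b))
    Mod(sum(Conj(a) * b))^2 + (Re(sum(Conj(a[1:2]) * b[1:2])) - intf)^2
  }
  best <- Inf
  for (f in list(obj_rank1, obj_rank2)) {
    for (s in seq_len(n_starts)) {
      par0 <- c(runif(2, 0, pi / 2), runif(3, -pi, pi))
      o <- optim(par0, f, method = "BFGS", control = list(maxit = 300))
      best <- min(best, o$value)
      if (best < 1e-10) {
        return(best)
      }
    }
  }
  best
}

# Random complex unit vector (Haar-ish via normal components).
random_unit <- function(dim) {
  v <- complex(real = rnorm(dim), imaginary = rnorm(dim))
  v / sqrt(sum(Mod(v)^2))
}

# Random rank-1 projector on C^dim.
random_rank1_projector <- function(dim) {
  u <- random_unit(dim)
  outer(u, Conj(u))
}

# Random orthonormal pair in C^dim via Gram-Schmidt on random vectors.
random_orthonormal_pair <- function(dim) {
  a <- random_unit(dim)
  b <- random_unit(dim)
  b <- b - sum(Conj(a) * b) * a
  list(a, b / sqrt(sum(Mod(b)^2)))
}

fixture_csv <- function(name) {
  system.file("extdata", name, package = "fockconj", mustWork = TRUE)
}
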