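# Independent oracles used across the suite.  These deliberately avoid
# the package's closed-form code paths: kinetics are integrated with
# deSolve, integrals with stats::integrate, and rank statistics by
# exhaustive enumeration written from scratch.

# adaptive ODE integration of the two-compartment infusion system,
# optionally with a tissue store compartment
ode_oracle <- function(k_pc, k_cp, k_el, infusions, times,
                       k_on = 0, k_off = 0) {
  if (inherits(infusions, "infusion_record")) infusions <- list(infusions)
  rate_in <- function(t) {
    r <- 0
    for (inf in infusions) {
      if (t >= inf$t_start && t < inf$t_start + inf$duration)
        r <- r + inf$dose / inf$duration
    }
    r
  }
  rhs <- function(t, y, parms) {
    list(c(rate_in(t) - (k_el + k_cp) * y[1] + k_pc * y[2],
           k_cp * y[1] - k_pc * y[2],
           k_on * y[1] - k_off * y[3]))
  }
  ends <- sort(unique(unlist(lapply(infusions, function(i)
    c(i$t_start, i$t_start + i$duration)))))
  tout <- sort(unique(c(0, times, ends)))
  sol <- deSolve::ode(c(0, 0, 0), tout, rhs, NULL, rtol = 1e-11,
                      atol = 1e-13, method = "lsoda")
  idx <- match(times, tout)
  list(central = sol[idx, 2], peripheral = sol[idx, 3],
       store = sol[idx, 4])
}

# numerical quadrature of sum c_i exp(-(l_i + l_phys) t) on [0, Inf)
quad_cumulated <- function(coefs, rates, lambda_phys) {
  f <- function(t) {
    out <- 0
    for (i in seq_along(coefs))
      out <- out + coefs[i] * exp(-(rates[i] + lambda_phys) * t)
    out
  }
  stats::integrate(f, 0, 50 / (min(rates) + lambda_phys),
                   rel.tol = 1e-10, subdivisions = 1000L)$value
}

# brute-force Spearman: enumerate permutations by recursive insertion
# (independent of the package's generator)
brute_spearman <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  perms <- list(1L)
  for (k in 2:n) {
    nxt <- list()
    for (p in perms) for (pos in 0:(k - 1)) {
      nxt[[length(nxt) + 1]] <- append(p, k, after = pos)
    }
    perms <- nxt
  }
  rhos <- vapply(perms, function(p) cor(rx, ry[p]), 0)
  list(rho = rho_obs,
       p = mean(abs(rhos) >= abs(rho_obs) - 1e-12),
       n_perm = length(perms))
}

# brute-force paired Wilcoxon signed-rank: enumerate all sign vectors
brute_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  ev <- n * (n + 1) / 4
  list(V = v_obs, p = mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-12))
}

tf2_pop_params <- function() {
  two_compartment_params(k_pc = 0.034, k_cp = 0.0075, k_el = 0.182,
                         vol_per_m2 = 1.86)
}

random_params <- function() {
  two_compartment_params(k_pc = runif(1, 0.005, 0.1),
                         k_cp = runif(1, 0.005, 0.1),
                         k_el = runif(1, 0.05, 0.5),
                         vol_per_m2 = runif(1, 1, 8))
}
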