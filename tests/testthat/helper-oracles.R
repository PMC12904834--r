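# reference parameter set used across tests
p_ref <- dtr_params(k_alpha = 0.05, a_alpha = 10, k_delta = 0.01,
                    a_delta = 2, k_beta = 1, k_gamma = 0)

# independent plain-formula logistic growth curve (no clamping, no checks)
ref_growth <- function(t, k, a) a * 2^(k * t) / ((a - 1) + 2^(k * t))

# independent fine-grid quadrature oracle: trapezoid rule on a uniform grid,
# a different integration scheme from the package's corner-cuboid sums
trapz2d <- function(g, d_min, d_max, t_min, t_max, n = 2000) {
  dd <- seq(d_min, d_max, length.out = n + 1)
  tt <- seq(t_min, t_max, length.out = n + 1)
  G <- outer(dd, tt, g)
  wd <- rep(1, n + 1); wd[c(1, n + 1)] <- 0.5
  wt <- rep(1, n + 1); wt[c(1, n + 1)] <- 0.5
  as.numeric(wd %*% G %*% wt) * (dd[2] - dd[1]) * (tt[2] - tt[1])
}

# independent fine-grid normalised GRIVUS: trapezoid integral of the rescaled
# surface over the rescaled control volume
trapz_grivus <- function(params, d_min, d_max, t_max, n = 2000) {
  gp <- gr_params(params)
  raw <- trapz2d(function(d, t) dtr_surface(d, t, gp), d_min, d_max, 0, t_max, n)
  un <- trapz2d(function(d, t) growth_alpha(t, gp), d_min, d_max, 0, t_max, n)
  raw / un
}

# random valid parameter draws for property tests (consumes the RNG stream);
# plateaus kept >= 1 so any sign of the growth rates is pole-free
rand_params <- function() {
  dtr_params(k_alpha = runif(1, -0.03, 0.06),
             a_alpha = runif(1, 1, 20),
             k_delta = runif(1, -0.05, 0.05),
             a_delta = runif(1, 1, 10),
             k_beta = runif(1, 0, 3),
             k_gamma = runif(1, -2, 1.5))
}

# small noise-free simulation shortcut
sim_clean <- function(params, ...) {
  simulate_counts(params, synthetic_spec(noise_cv = 0, ...), seed = 1)
}
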