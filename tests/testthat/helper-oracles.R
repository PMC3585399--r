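# Independent oracles used by the tests.

kB_T <- function(T = 310) rlfep::rlf_constants()$kB * T

# Configuration-integral quadrature for an isotropic harmonic well:
# Z(kf) = integral 4 pi r^2 exp(-kf r^2 / (2 kB T)) dr.
harmonic_Z_quadrature <- function(kf, T = 310) {
  kT <- kB_T(T)
  stats::integrate(function(r) 4 * pi * r^2 * exp(-0.5 * kf * r^2 / kT),
                   0, Inf, rel.tol = 1e-10)$value
}

# Free energy of tightening a single-atom anchor, by quadrature.
harmonic_dG_quadrature <- function(kf0, kf1, T = 310) {
  -kB_T(T) * log(harmonic_Z_quadrature(kf1, T) / harmonic_Z_quadrature(kf0, T))
}

# 1-D scan of the isolated ion-ligand pair energy (closed-form oracle for
# minimisation checks); returns the distance of minimum energy.
pair_minimum_scan <- function(ion, template = "formaldehyde_like") {
  rlfep:::pair_scan_minimum(ion, rlfep::build_ligand_template(template))
}

# Build a minimal synthetic fep_leg for arithmetic-only tests.
fake_leg <- function(total, kind = "restraint_morph", ions = "Na", n = 4L,
                     kf = 100, direction = "forward", se = 0,
                     endpoint_u = c(0, 0)) {
  structure(list(leg_kind = kind, ions = ions, n = n, kf = kf,
                 per_window = data.frame(lambda_from = 0, lambda_to = 1,
                                         dG = total, se = se),
                 total_dG = total, total_se = se, estimator = "exp",
                 direction = direction, schedule = c(0, 1), seed = 1,
                 samples_per_window = NA_integer_, endpoint_u = endpoint_u,
                 samples = NULL), class = "fep_leg")
}

# Synthetic fep_samples with prescribed potential-energy columns.
fake_samples <- function(lambdas, du_next, nsamp = 50, direction = "forward",
                         temperature = 310) {
  K <- length(lambdas)
  wins <- lapply(seq_len(K), function(i) {
    list(lambda = lambdas[i], u_self = rep(0, nsamp),
         u_lo = if (i > 1) rep(-du_next[i - 1], nsamp),
         u_hi = if (i < K) rep(du_next[i], nsamp))
  })
  rlfep:::new_fep_samples(wins, direction, temperature)
}
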