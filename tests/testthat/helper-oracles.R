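# Shared fixtures and independent oracles.

# growth medium at 33 C with the viscosity value used throughout the study
m33 <- medium(306.15, 0.76e-3)
g_normal <- ellipsoid_geometry(1.7, 0.7)
g_long <- ellipsoid_geometry(10, 0.7)

# Independent oracle: numerical quadrature of the Oberbeck/Perrin integrals
# for a general ellipsoid, specialised to a prolate spheroid (b = c).
# Computed in um units and rescaled (f_t ~ eta L, f_r ~ eta L^3), entirely
# independent of the closed-form expressions in the package.
quad_frictions <- function(L_um, W_um, eta) {
  a <- L_um / 2; b <- W_um / 2
  Delta <- function(s) sqrt((a^2 + s) * (b^2 + s)^2)
  al <- function(ax2) stats::integrate(function(s) 1 / ((ax2 + s) * Delta(s)),
                                       0, Inf, rel.tol = 1e-12)$value
  chi <- stats::integrate(function(s) 1 / Delta(s), 0, Inf, rel.tol = 1e-12)$value
  aa <- al(a^2); ab <- al(b^2)
  list(f_t_major = 16 * pi * eta / (chi + a^2 * aa) * 1e-6,
       f_t_minor = 16 * pi * eta / (chi + b^2 * ab) * 1e-6,
       f_r_minor = 16 * pi * eta * (a^2 + b^2) / (3 * (a^2 * aa + b^2 * ab)) * 1e-18)
}

kB <- 1.380649e-23
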