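# Shared fixtures: models for the three arm conditions and an independent
# finite-difference Euler-Lagrange oracle built only from the energies.

default_body <- anthropometric_model()

models <- list(
  active = build_model(default_body, "active"),
  passive = build_model(default_body, "passive"),
  fixed = build_model(default_body, "fixed")
)

random_state <- function(model, angle_range = 1, vel_range = 2) {
  n <- model$dof
  list(q = runif(n, -angle_range, angle_range),
       qdot = runif(n, -vel_range, vel_range))
}

# d/dt (dL/dqdot) - dL/dq along (q, qdot, qddot), from energies alone.
# The inner dL/dqdot difference is exact for a kinetic energy quadratic in
# qdot, so a large step (1e-2) is used there to suppress roundoff; the
# outer time derivative and dL/dq use fourth-order stencils.
el_oracle <- function(model, q, qdot, qddot,
                      h_in = 1e-2, h_out = 1e-3) {
  n <- model$dof
  lag <- function(q, qd) {
    e <- energies(model, q, qd)
    e[["T"]] - e[["V"]]
  }
  dLdqd <- function(q, qd) {
    vapply(seq_len(n), function(i) {
      e <- numeric(n); e[i] <- h_in
      (lag(q, qd + e) - lag(q, qd - e)) / (2 * h_in)
    }, numeric(1))
  }
  stencil <- function(f, h) {
    (-f(2) + 8 * f(1) - 8 * f(-1) + f(-2)) / (12 * h)
  }
  dLdq <- vapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- 1
    stencil(function(s) lag(q + s * h_out * e, qdot), h_out)
  }, numeric(1))
  p_dot <- vapply(seq_len(n), function(i) {
    stencil(function(s) {
      dLdqd(q + s * h_out * qdot, qdot + s * h_out * qddot)[i]
    }, h_out)
  }, numeric(1))
  p_dot - dLdq
}
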