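# Shared fixtures: all models are built in code at test time.

one_n <- function(J0 = 0, D0 = 0, ...) one_nitrogen_model(J0 = J0, D0 = D0, ...)

bare_pair <- function() spin_system()

# axial relative anisotropy of a model under a trajectory spec
chi_axial_of <- function(system, laws, spec, magnitude = 50, ...) {
  pp <- propagate_yield_floquet(
    system, field_spec(magnitude, "parallel"), laws, spec, ...
  )$phi_s
  pq <- propagate_yield_floquet(
    system, field_spec(magnitude, "perpendicular"), laws, spec, ...
  )$phi_s
  relative_anisotropy_axial(pp, pq)
}

expect_hermitian <- function(H, tol = 1e-12) {
  expect_lt(max(abs(H - Conj(t(H)))), tol)
}
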