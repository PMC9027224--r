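# Small in-code fixtures shared across tests.

toy_phantom <- function() {
  phantom("toy", "male", total_mass_kg = 10,
          organ_masses_g = c(A = 1000, B = 500))
}

toy_patient <- function(weight = 70, injected = 200, id = "T01") {
  patient_meta(id, weight, injected)
}

# complete 2x2 S-matrix with hand-checkable values (mGy per MBq h)
toy_smatrix <- function() {
  smatrix("toy", data.frame(
    target = c("A", "A", "B", "B"),
    source = c("A", "B", "A", "B"),
    s_mGy_per_MBq_h = c(0.02, 0.004, 0.003, 0.05)
  ))
}

# analytic integral (hours) of f * ku/(ku-kw) (e^-kw t - e^-ku t) e^-lam t
uptake_washout_tiac <- function(f, ku, kw, lam) {
  f * ku / ((kw + lam) * (ku + lam)) / 60
}

small_config <- function(...) {
  cohort_config(n_bc = 1L, n_nen = 1L, n_pk = 2L, ...)
}
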