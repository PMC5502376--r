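# shared fixtures: small, fast objects built in code

quick_session <- function(kind = "random", n_trials = 200, seed = 1, ...) {
  generate_session(paradigm_spec(kind, n_trials = n_trials),
                   gen_params(...), seed = seed)
}

# brute-force partial correlation via two-stage regression residuals:
# independent oracle for the residualization-identity implementation
partial_cor_oracle <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}
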