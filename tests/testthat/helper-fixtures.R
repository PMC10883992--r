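# small synthetic design used across regression tests
make_design <- function(n = 30, p = 4, seed = 11) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  X
}

# tiny gradient experiment table with an internal control at 17:0
tiny_gradient_table <- function(noise_sd = 0, seed = 1) {
  generate_experiment(generator_config("gradient", noise_sd = noise_sd,
                                       seed = seed))
}

# roles for one bundled experiment: published references as Train
ref_exp <- function(cls, exp, ...) reference_experiment(cls, exp, ...)

expect_tbl_equal_numeric <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
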