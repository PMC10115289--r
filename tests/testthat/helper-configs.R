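# shared test fixtures, built in code

coventry <- coventry_fixture()

# small pool of random-but-valid configs reused across property tests
random_configs <- function(n, seed = 42) {
  sample_configs(generator_spec(seed = seed, n_configs = n))
}

# a distribution shifted toward regular cycling from a given source level
shifted_post <- function(config, source_level = 2, share = 0.01) {
  apply_shift(config$population$baseline,
              scenario_shift(source_level, share))
}
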