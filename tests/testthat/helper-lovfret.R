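# Shared fixtures: construct parameter sets at the plate-protocol scale
# (sensitivity in umol m^-2, relaxation in s, transfer limit as fraction).

mtq2_optones <- function() photocycle_params(162, 6.8, 0.189, "donor")
ypet_optones <- function() photocycle_params(559, 8.0, 0.535, "acceptor")
mtq2_optojnki <- function() photocycle_params(206, 13.7, 0.17, "donor")
ypet_optojnki <- function() photocycle_params(843, 23, 0.604, "acceptor")
mscarlet_optojnki <- function() photocycle_params(1594, 15.5, 0.688,
                                                  "acceptor")

# the LED-array protocol: 1 s of 2.3 umol m^-2 s^-1 every 7.5 s
led_train <- function(count = 54)
  flash_train(dose_per_flash = 2.3, flash_s = 1, period_s = 7.5,
              count = count)

# noise-free normalised cycle traces for a truth, at protocol defaults
clean_normalized_traces <- function(truth, ...) {
  spec <- generator_spec(truth, noise_sd = 0, n_replicates = 1, seed = 1,
                         ...)
  normalize_to_control(gen_cycle_traces(spec))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
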