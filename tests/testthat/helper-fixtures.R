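# Shared fixtures, built once per test session and cached.
# The expensive objects (the acceptance-scale CNN and its dataset) are
# created on first use and reused by every file that needs them.

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

fx_probe <- function() get_fixture("probe", default_probe)

# a clean noiseless homogeneous measurement (mua 0.05, musp 7)
fx_homog_measurement <- function() get_fixture("homog_m", function() {
  phi <- fluence_semi_infinite(optical_props(0.05, 7), separations(fx_probe()))
  dotprops:::measurement_from_fluence(phi, separations(fx_probe()), 140e6)
})

# acceptance-scale simulation dataset and CNN (desk-scale study size,
# same configuration as scripts/acceptance.R)
fx_sim_dataset <- function() get_fixture("sim_dataset", function() {
  make_simulation_dataset(n = 6000, seed = 101)
})

fx_cnn <- function() get_fixture("cnn", function() {
  cnn_train(fx_sim_dataset(),
            cnn_config(epochs = 80L, lr_decay_every = 40L, seed = 11))
})

# small dataset + quickly trained CNN for unit-level checks
fx_small_dataset <- function() get_fixture("small_dataset", function() {
  make_simulation_dataset(n = 700, seed = 55)
})

fx_small_cnn <- function() get_fixture("small_cnn", function() {
  cnn_train(fx_small_dataset(), cnn_config(epochs = 30L, seed = 9),
            min_examples = 500L)
})

# exact synthetic two-line measurement with known slopes
make_linear_measurement <- function(kr = 1.2, ki = 0.3, a0 = 2, p0 = 0.1,
                                    probe = fx_probe()) {
  rho <- separations(probe)
  fd_measurement(rho,
                 a0 - kr * rho - 2 * log(rho),
                 p0 + ki * rho,
                 modulation_freq = 140e6)
}
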