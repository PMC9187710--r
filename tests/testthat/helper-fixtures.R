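# Cached fixtures shared across test files.  Everything is generated in
# code under fixed seeds; heavy objects are built once per session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Generative agent parameters used as the study conditions throughout.
study_theta <- function() model_params()

# Small dataset for unit-level neural tests: 200 trials, 5 units
# (2 right-, 2 left-preferring, 1 untuned).
small_dataset <- function() fixture("small", function() {
  specs <- list(
    neuron_spec(baseline = 18, gain = 25, slope = 1, preferred = "right"),
    neuron_spec(baseline = 22, gain = 22, slope = 0.8, preferred = "left"),
    neuron_spec(baseline = 15, gain = 28, slope = 1.2, preferred = "right"),
    neuron_spec(baseline = 20, gain = 24, slope = 0.9, preferred = "left"),
    neuron_spec(baseline = 20, preferred = "none"))
  generate_dataset(200, 5, theta = study_theta(), specs = specs,
                   seed = 42)
})

small_rates <- function() fixture("small_rates", function() {
  ds <- small_dataset()
  compute_rates(ds$spikes, ds$trials)
})

small_classification <- function() fixture("small_cls", function() {
  ds <- small_dataset()
  classify_cells(ds$spikes, ds$trials)
})

# Large tuned population for the population-recovery and change-of-mind
# ordering analyses: 1000 trials, 20 tuned units (10 per side) + 4
# untuned.
big_dataset <- function() fixture("big", function() {
  specs <- c(
    lapply(1:10, function(i)
      neuron_spec(baseline = 12 + i, gain = 20 + i, slope = 0.9,
                  midpoint = (i - 5) * 0.1, preferred = "right")),
    lapply(1:10, function(i)
      neuron_spec(baseline = 12 + i, gain = 20 + i, slope = 0.9,
                  midpoint = (i - 5) * 0.1, preferred = "left")),
    lapply(1:4, function(i) neuron_spec(baseline = 15 + i,
                                        preferred = "none")))
  generate_dataset(1000, 24, theta = study_theta(), specs = specs,
                   seed = 7)
})

big_rates <- function() fixture("big_rates", function() {
  ds <- big_dataset()
  compute_rates(ds$spikes, ds$trials)
})

big_classification <- function() fixture("big_cls", function() {
  ds <- big_dataset()
  classify_cells(ds$spikes, ds$trials)
})

big_events <- function() fixture("big_events", function() {
  ds <- big_dataset()
  detect_changes(ds$trials, study_theta())
})

# Coarse posterior masses on the standard 25 ms tuning grid.
big_coarse_mass <- function() fixture("big_pcm", function() {
  ds <- big_dataset()
  posterior_coarse_mass(ds$trials, study_theta(), tuning_t_edges())
})

tuning_t_edges <- function() seq(0, 2, by = 0.025)
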