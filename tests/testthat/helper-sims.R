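# Shared simulation fixtures, built once per test session.

.fixture_store <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_store))
    assign(key, force(expr), envir = .fixture_store)
  get(key, envir = .fixture_store)
}

# Desk-scale scenario for unit tests: same paradigm structure, smaller field.
# Arguments in ... override the small-scene defaults.
small_scenario <- function(seed = 1L, ...) {
  args <- list(width = 96L, height = 96L, n_frames = 120L,
               baseline_frames = 20L, stim_start_frame = 41L,
               stim_len_frames = 30L, nh4_start_frame = 90L,
               n_vesicles = 25L, n_events = 8L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_scenario, args)
}

small_sim <- function(seed = 1L) {
  fixture(paste0("small", seed), simulate_movie(small_scenario(seed)))
}

small_paradigm <- function() {
  acquisition_paradigm(2, 20, 41, 30, 90)
}

clean_sim <- function(seed = 1L) {
  fixture(paste0("clean", seed), simulate_movie(simulation_scenario(seed = seed)))
}

clean_detection <- function(seed = 1L) {
  fixture(paste0("clean_det", seed), {
    s <- clean_sim(seed)
    detect_fusion_events(s$movie, s$paradigm)
  })
}

null_sim <- function(seed = 1L) {
  fixture(paste0("null", seed),
          simulate_movie(simulation_scenario(n_events = 0L, seed = seed)))
}

pool_scenario <- function(seed = 1L) {
  simulation_scenario(n_events = 30L, event_unit_matched = TRUE,
                      n_synapses = 40L, synaptic_event_fraction = 0.5,
                      seed = seed)
}

pool_sim <- function(seed = 1L) {
  fixture(paste0("pool", seed), simulate_movie(pool_scenario(seed)))
}

# Full per-cell analysis of a pool-scenario movie (detection + events + pool).
pool_cell <- function(seed = 1L) {
  fixture(paste0("pool_cell", seed), {
    s <- pool_sim(seed)
    analyze_cell(s$movie, s$paradigm, synapse_image = s$synapse_image,
                 cell_id = sprintf("pool%02d", seed))
  })
}

# Mid-size clean variant for the multi-seed recall/precision invariant.
recall_scenario <- function(seed = 1L) {
  simulation_scenario(width = 160L, height = 160L, n_vesicles = 80L,
                      n_events = 40L, seed = seed)
}
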