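# Small fixture builders used across the suite.

tiny_params <- function(...) sim_params(grid_size = 11, ...)

# A quiet world: no pulses, so only the agents placed by hand exist.
quiet_world <- function(..., grid_size = 11) {
  new_world(sim_params(grid_size = grid_size, pulse_prob = 0, ...))
}

final_row <- function(run) run$timeseries[nrow(run$timeseries), ]
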