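# small custom plates used across tests
tiny_plate <- function(rows, cols, capacity = 1000) {
  plate_spec(NULL, rows = rows, cols = cols, well_capacity_ul = capacity,
             well_depth_mm = 10)
}

# random valid command token tables for round-trip properties
random_tokens <- function(n) {
  toks <- lapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.15) {
      cmd_home()
    } else {
      cmd_move(well_id(sample(1:16, 1), sample(1:24, 1)),
               lower = stats::runif(1) < 0.5)
    }
  })
  out <- do.call(rbind, toks)
  class(out) <- c("command_tokens", "data.frame")
  out
}

# noiseless carryover preset with fixed residual fraction
exact_preset <- function(f = 0.0032) {
  carryover_preset(model = carryover_model(f = f, f_sd = 0),
                   noise_sd = 0, frames_per_well = 3)
}
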