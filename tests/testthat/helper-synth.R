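# Shared small-scale synthetic worlds.  Generated once per test run and
# cached so several test files can reuse the same simulation.

tiny_cfg <- function(...) {
  defaults <- list(duration_s = 120, activation_profile = c(0.2, 0.4),
                   ic_schedule = c(25, 85), seed = 42L)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, make) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- make()
  .sim_cache[[key]]
}

tiny_sim <- function() {
  cached_sim("tiny", function() simulate_recording(tiny_cfg()))
}

tiny_sim_1k <- function() {
  cached_sim("tiny1k", function() {
    sim <- tiny_sim()
    list(recording = resample_recording(sim$recording, 1000),
         ground_truth = sim$ground_truth)
  })
}

## synthetic breath table on an arbitrary sample grid (for unit tests that
## do not need a full simulation)
fake_breaths <- function(insp_start, insp_end, exp_end, fs = 1000) {
  df <- data.frame(breath_id = seq_along(insp_start),
                   insp_start = insp_start, insp_end = insp_end,
                   exp_end = exp_end,
                   insp_start_s = (insp_start - 1) / fs,
                   insp_end_s = (insp_end - 1) / fs,
                   exp_end_s = (exp_end - 1) / fs,
                   peak_insp_flow = 1, volume_l = 0.5,
                   is_ic = FALSE, minute_index = 1L, quality = "ok")
  attr(df, "fs") <- fs
  class(df) <- c("emgdi_breaths", "data.frame")
  df
}
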