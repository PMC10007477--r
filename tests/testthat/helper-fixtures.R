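# shared fixtures, built in code at test time

# RR series with a single sinusoidal modulation, no noise
sine_rr <- function(freq, amplitude = 50, mean_rr = 800, duration = 360,
                    noise_sd = 0, seed = 1) {
  generate_rr_series(rr_gen_spec(
    mean_rr,
    modulations = list(c(amplitude = amplitude, frequency = freq)),
    noise_sd = noise_sd, duration = duration, seed = seed
  ))
}

# rr_series with prescribed intervals (ms), beats from t = 0
rr_from_intervals <- function(intervals) {
  rr_series(c(0, cumsum(intervals) / 1000))
}

# a complete, fully correct 3 x 4 x 10 response design
full_correct_design <- function() {
  evs <- c("self_awareness", "others_awareness", "discrimination")
  doms <- c("HAHV", "HALV", "LALV", "LAHV")
  do.call(rbind, lapply(evs, function(ev) {
    do.call(rbind, lapply(doms, function(d) {
      generate_responses(10, 1, d, seed = 1, evaluation = ev)
    }))
  }))
}

# hrv_time_series with given per-window values for every index
flat_hts <- function(value, n_windows = 10, jitter = 0) {
  vals <- matrix(value, n_windows, length(hrv_index_names()),
                 dimnames = list(NULL, hrv_index_names()))
  if (jitter > 0) vals <- vals + matrix(rnorm(length(vals), 0, jitter),
                                        nrow = n_windows)
  structure(
    list(window_centers = seq_len(n_windows) * 10, values = vals,
         window = 180, step = 10),
    class = "hrv_time_series"
  )
}
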