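# reference egg-deposition depth distribution, built in code so tests of the
# curve construction do not depend on the packaged CSV fixture
ref_counts <- c(1, 7, 27, 54, 41, 26, 7)
ref_lower <- c(0, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7)
ref_upper <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)

ref_table <- function() depth_frequency_table(ref_lower, ref_upper, ref_counts)

# stage series declining at a constant rate (m/day)
constant_decline <- function(rate, days, start = "2019-05-01", level0 = 170) {
  stage_series(as.Date(start) + seq_len(days) - 1, level0 - rate * (seq_len(days) - 1))
}

# independent brute-force oracle for the forward-window drop
brute_drop <- function(levels, t, window) {
  max(0, levels[t] - min(levels[(t + 1):(t + window)]))
}
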