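# shared fixture builders; everything is generated in code at test time

# phantom config with all stochastic texture off: two clean wall echoes
clean_config <- function(seed = 5, ...) {
  phantom_subject_config(speckle_sigma = 0, lumen_echo_sigma = 0,
                         noise_sigma = 0, artifact_bands = list(),
                         seed = seed, ...)
}

# small rendered recording + envelope matrix
clean_recording <- function(n_frames = 30, seed = 5) {
  r <- render_recording(clean_config(seed), n_frames)
  r$env <- envelope_record(r$record, normalize = TRUE)$samples
  r
}

# tiny ROI config (short frames) so network tests stay fast
tiny_roi_config <- function(len = 120L) {
  roi_config(input_length = len, kernel_width = 31L, channels = 3L,
             pool_window = 7L, window_width = 31L)
}
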