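# Small fixtures shared across test files; everything is generated in code.

# a fast low-dimensional forward model for unit tests
tiny_forward <- function(...) {
  forward_model(n_channels = 4, ...)
}

# n attention-fixed construction trials with the given sides
make_construction_trials <- function(sides, forward = tiny_forward(),
                                     trial_len_s = 60) {
  lapply(seq_along(sides), function(i)
    simulate_trial(fixed_schedule(sides[i], trial_len_s), forward,
                   trial_len_s, trial_id = sprintf("c%02d", i),
                   role = "construction"))
}

# a deterministic periodic trial in which every 1 s-hop window holds
# identical data (period = 1 s at 64 Hz)
periodic_trial <- function(trial_len_s = 4, n_channels = 2, rate = 64) {
  period <- seq_len(rate)
  env <- rep(sin(2 * pi * period / rate) + 0.3 * cos(2 * pi * 3 * period / rate),
             trial_len_s)
  dat <- rbind(rep(cos(2 * pi * period / rate), trial_len_s),
               rep(sin(2 * pi * 2 * period / rate), trial_len_s))
  aad_trial(eeg_segment(dat[seq_len(n_channels), , drop = FALSE], rate),
            envelope_signal(env, rate, side = "left"),
            envelope_signal(rev(env), rate, side = "right"),
            fixed_schedule("left", trial_len_s),
            trial_id = "periodic", role = "construction")
}
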