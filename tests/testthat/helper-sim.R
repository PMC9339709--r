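# Shared test fixtures, all built in code.

# Epoch set wrapped around a plain array (trials x channels x samples).
make_epochs <- function(arr, sfreq = 250, tmin = -0.5, ch_names = NULL) {
  d <- dim(arr)
  ch_names <- ch_names %||% paste0("ch", seq_len(d[2]))
  if (d[2] >= 1 && !"Pz" %in% ch_names) ch_names[d[2]] <- "Pz"
  times <- tmin + (seq_len(d[3]) - 1) / sfreq
  structure(list(data = arr, times = times, ch_names = ch_names,
                 sfreq = sfreq,
                 events = data.frame(onset = seq_len(d[1]),
                                     trial_type = rep("target", d[1])),
                 window = c(tmin, times[length(times)] + 1 / sfreq),
                 baseline = NULL, kept = seq_len(d[1]), rejected = integer(0),
                 rejection_log = data.frame(trial = integer(0),
                                            reason = character(0))),
            class = "epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

silent_noise <- function() noise_spec(0, 0, 0, 0, 0, 0)

# One-target noiseless epoch trace on a full epoch grid.
burst_trace <- function(times, lat_s, f, amp = 5, n700 = 0) {
  amp * cos(2 * pi * f * (times - lat_s)) *
    exp(-(times - lat_s)^2 / (2 * (1 / (4 * f))^2)) +
    n700 * exp(-(times - 0.8)^2 / (2 * 0.12^2))
}
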