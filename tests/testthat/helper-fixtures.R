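# Shared fixtures, built in code at test time.

# cache expensive shared objects across test files
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

tiny_config <- function(seed = 7L, ...) {
  session_config(n_participants = 2, trials_easy_per_dof = 8,
                 trials_hard = 16, trials_view = 16,
                 channels = c("Cz", "Pz", "VEOG"), seed = seed, ...)
}

default_gain <- function() {
  cached("gain", function() template_window_gain(default_components()))
}

# sigma_m at 40 epochs/cell, estimated once from the full EEG chain;
# 120 cells keep the relative error of the SD estimate near 6%
measurement_sd <- function() {
  cached("sigma_m", function()
    estimate_measurement_sd(n_cells = 120, n_epochs = 40, seed = 1702))
}

# epoch_set built directly from an array (no rendering)
make_epoch_set <- function(epochs, sfreq = 1000, tmin = -100,
                           channel_labels = NULL, scheme = "DC",
                           condition = "easy", participant = 1L) {
  n <- dim(epochs)[1]
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(dim(epochs)[2]))
  }
  dimnames(epochs) <- list(NULL, channel_labels, NULL)
  times <- (seq_len(dim(epochs)[3]) - 1) * 1000 / sfreq + tmin
  structure(list(epochs = epochs, times = times,
                 keys = data.frame(participant = participant, scheme = scheme,
                                   condition = condition,
                                   trial_id = seq_len(n),
                                   probe_index = seq_len(n)),
                 artifact = rep(FALSE, n),
                 artifact_reason = rep(NA_character_, n),
                 dropped = data.frame(), sfreq = sfreq,
                 channel_labels = channel_labels),
            class = "epoch_set")
}

# random complete amplitude slice for ANOVA oracle tests
random_slice <- function(n, seed) {
  withr::with_seed(seed, {
    d <- expand.grid(participant = seq_len(n),
                     condition = c("view", "easy", "hard"),
                     scheme = c("DC", "PRC"), stringsAsFactors = FALSE)
    d$amplitude <- rnorm(nrow(d))
    d
  })
}
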