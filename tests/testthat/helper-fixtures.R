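# Shared fixtures, built once per test run and cached in this environment.
.fixture_env <- new.env(parent = emptyenv())

# Default-medium photon record set, reused by every optics/pipeline test
# that does not need its own ensemble.
mc_records_fixture <- function(n_photons = 2e5, seed = 301) {
  key <- sprintf("rec_%g_%d", n_photons, seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- run_photon_mc(n_photons = n_photons, seed = seed)
  .fixture_env[[key]]
}

run_template_fixture <- function(acq = acquisition_config()) {
  key <- "template_default"
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- dtof_run_template(mc_records_fixture(), acq)
  .fixture_env[[key]]
}

mtsf_fixture <- function() {
  key <- "mtsf_default"
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- pipeline_sensitivity(mc_records_fixture())
  .fixture_env[[key]]
}

# A small synthetic epoch with known structure: optional plateau over the
# task block plus optional white noise.
epoch_fixture <- function(task_level = 1, pre_level = 0, noise_sd = 0,
                          seed = 1, protocol = build_protocol()) {
  set.seed(seed)
  n <- 200
  tt <- (seq_len(n) - 0.5) * 0.3 - 15
  task <- tt >= 0 & tt < 30
  vals <- ifelse(task, task_level, pre_level) + rnorm(n, sd = noise_sd)
  structure(list(values = vals, se = rep(0, n), time_s = tt, task = task,
                 n_cycles_used = 5, n_channels = 4, sampling_period_s = 0.3,
                 pre_s = 15, task_s = 30),
            class = "epoch")
}

# Feature table with two well-separated classes (gap >> spread).
separable_records_fixture <- function(n_per_class = 10, gap = 50, seed = 2) {
  set.seed(seed)
  n <- 2 * n_per_class
  truth <- rep(c("yes", "no"), each = n_per_class)
  shift <- ifelse(truth == "yes", gap, 0)
  data.frame(participant = sprintf("P%02d", rep(seq_len(n_per_class), 2)),
             question_index = rep(1:4, length.out = n),
             SM = shift + rnorm(n), SS = shift / 10 + rnorm(n),
             CNR = shift / 5 + rnorm(n), r = tanh(shift / 25 + rnorm(n, sd = 0.2)),
             truth = truth)
}

# Uninformative features with random labels, for permutation-null checks.
null_records_fixture <- function(n = 24, seed = 3) {
  set.seed(seed)
  data.frame(participant = rep(sprintf("P%02d", seq_len(ceiling(n / 4))),
                               each = 4, length.out = n),
             question_index = rep(1:4, length.out = n),
             SM = rnorm(n), SS = rnorm(n), CNR = rnorm(n), r = rnorm(n),
             truth = sample(rep(c("yes", "no"), n / 2)))
}
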