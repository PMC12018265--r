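## Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

## A small session for unit-level pipeline checks.
mini_config <- function(...) {
  synth_config(n_channels = 8L, n_participants = 4L,
               n_real = 8L, n_imag = 8L, n_control = 8L, ...)
}

mini_session <- function() {
  cached("mini_session", simulate_session(mini_config(), seed = 42L))
}

## The default-conditions session processed with the full pipeline,
## shared by the acceptance checks.
acc_session <- function() {
  cached("acc_session", simulate_session(synth_config(), seed = 1L))
}

acc_config <- function() {
  pipeline_config(f_range = c(1, 30), n_spectrum_trials = 8)
}

acc_proc <- function() {
  cached("acc_proc", process_session(acc_session(), acc_config()))
}

acc_decode <- function() {
  cached("acc_decode",
         decode_study(acc_session(), acc_config(), seed = 1L,
                      proc = acc_proc()))
}

## Smooth noise helper used by several behavioural fixtures.
gauss_smooth_test <- function(x, fs) thetanav:::gauss_smooth(x, fs, 0.3)

## Ground-truth anchors (start, turns, end) of the real trials.
gt_anchors <- function(session) {
  do.call(rbind, lapply(session$trajectories, trajectory_anchors))
}
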