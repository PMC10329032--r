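# Shared fixtures. Heavy objects are built lazily and cached for the whole
# test run.
.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .cache)) assign(name, builder(), envir = .cache)
  get(name, envir = .cache)
}

# A tiny transformer configuration for fast exact checks.
tiny_config <- function(L = 1L, n_classes = 4L) {
  vit_config(d = 8L, L = L, h = 2L, mlp_hidden = 10L, patch = c(2L, 2L),
             n_classes = n_classes, window = 4L, n_ch = 2L, n_cv = 3L)
}

# Three well-separated motor units in distinct grid territories.
distinct_units <- function() {
  list(motor_unit_spec(c(2, 2), spread = 1.0, template = mu_template(sigma = 1.5),
                       mean_rate = 18),
       motor_unit_spec(c(7, 2), spread = 1.0, template = mu_template(sigma = 2.2),
                       mean_rate = 22),
       motor_unit_spec(c(4, 7), spread = 1.0,
                       template = mu_template(sigma = 1.8, amplitude = 0.9),
                       mean_rate = 20))
}

# One-gesture session dominated by the given units (single repetition).
single_burst_session <- function(units, noise_std, seed, duration = 2) {
  spec <- session_spec(units, activation = matrix(1, 1, length(units)),
                       n_repetitions = 1L, repetition_duration = duration,
                       rest_duration = 0.2, noise_std = noise_std,
                       grid = c(8L, 8L), fs = 2048, seed = seed)
  gen <- generate_session(spec)
  seg <- gen$truth$segments
  list(raw = gen$session$emg[seg$start[1]:seg$end[1], ],
       truth = lapply(seq_along(units), function(m)
         gen$truth$spike_trains[[1]][[1]][[m]] - seg$start[1] + 1L),
       gen = gen)
}

# The 8-gesture separable classification benchmark: ~40 s of active signal
# per gesture (5 repetitions x 8 s), 64 electrodes, W = 64. Built once;
# the repetition-wise CV report is cached alongside.
benchmark_dataset <- function() {
  cached("benchmark_ds", function() {
    spec <- make_separable_benchmark(8L, difficulty = 0, seed = 3,
                                     units_per_gesture = 3L,
                                     repetition_duration = 8,
                                     rest_duration = 1, noise_std = 0.05,
                                     grid = c(8L, 8L))
    gen <- generate_session(spec)
    ds <- preprocess_session(gen$session, window_size = 64L, skip_step = 64L)
    rm(gen)
    ds
  })
}

benchmark_cv_report <- function() {
  cached("benchmark_cv", function() {
    ds <- benchmark_dataset()
    cfg <- standard_config("V1", 64L, 64L, n_classes = 8L)
    crossval_by_repetition(ds, cfg, train_control(seed = 1))
  })
}
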