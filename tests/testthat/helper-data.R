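# Shared synthetic fixtures, generated once per test run and cached.
# Generation parameters follow the planted-structure conditions the
# generator documents (coupling 0.8 vs 0.1, 2-sd peripheral shift);
# trial counts/lengths and the 64 Hz rate are scaled down purely for
# test runtime.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- fn()
  .fixture_cache[[name]]
}

tiny_recordings <- function() fixture("tiny_recs", function() {
  generate_dataset(generator_spec(
    n_subjects = 2L, n_trials = 6L, trial_length_s = 8, rate_hz = 64,
    seed = 101L))
})

tiny_features <- function() fixture("tiny_feats", function() {
  extract_features(tiny_recordings())
})

null_features <- function() fixture("null_feats", function() {
  spec <- generator_spec(
    n_subjects = 4L, n_trials = 24L, trial_length_s = 16, rate_hz = 64,
    coupling_effect = 0, peripheral_effect = 0, seed = 202L)
  extract_features(generate_dataset(spec))
})

planted_shared_features <- function() fixture("planted_shared", function() {
  spec <- generator_spec(
    n_subjects = 4L, n_trials = 12L, trial_length_s = 16, rate_hz = 64,
    mechanism_mode = "shared", seed = 303L)
  extract_features(generate_dataset(spec))
})

planted_idio_features <- function() fixture("planted_idio", function() {
  spec <- generator_spec(
    n_subjects = 4L, n_trials = 12L, trial_length_s = 16, rate_hz = 64,
    mechanism_mode = "idiosyncratic", seed = 304L)
  extract_features(generate_dataset(spec))
})

# 10 informative + 90 noise features: the informative block jointly
# separates the class means by 2 sd (per-feature shift 2/sqrt(10)), so
# held-out accuracy increases with every informative feature recovered
# and the wrapper benchmark has selection pressure over the whole block
informative_noise_data <- function(n = 400L, seed = 42L) {
  set.seed(seed)
  y <- factor(rep(c("low", "high"), length.out = n),
              levels = c("low", "high"))
  X <- matrix(rnorm(n * 100L), n, 100L)
  shift <- ifelse(y == "high", 1, -1) / sqrt(10)
  X[, 1:10] <- X[, 1:10] + shift
  colnames(X) <- paste0(rep(c("inf", "noise"), c(10L, 90L)),
                        c(1:10, 1:90))
  list(X = X, y = y, informative = paste0("inf", 1:10))
}

# the GA benchmark run is expensive; share it between the module test
# and the acceptance criterion
ga_benchmark_run <- function() fixture("ga_benchmark", function() {
  d <- informative_noise_data()
  cfg <- ga_config(n_generations = 50L, population_size = 50L,
                   n_parents = 10L, pool_size = 4L, n_mutations = 3L,
                   fitness_reps = 3L, seed = 5L)
  sel <- ga_select(d$X, d$y, classifier_kind = "svm", cfg = cfg,
                   classifier_config = list(iters = 150L))
  list(data = d, cfg = cfg, sel = sel)
})

# well-separated two-cluster problem (means 3 sd apart per feature)
separable_data <- function(n = 200L, p = 10L, seed = 7L) {
  set.seed(seed)
  y <- factor(rep(c("low", "high"), length.out = n),
              levels = c("low", "high"))
  mu <- ifelse(y == "high", 3, -3)
  X <- matrix(rnorm(n * p), n, p) + mu
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}

make_test_trial <- function(n_eeg = 3L, n_per = 2L, n_samples = 64L,
                            valence = 6, arousal = 3, seed = 1L,
                            trial_id = "t1") {
  set.seed(seed)
  eeg <- matrix(rnorm(n_eeg * n_samples), n_eeg,
                dimnames = list(paste0("E", seq_len(n_eeg)), NULL))
  per <- matrix(rnorm(n_per * n_samples), n_per,
                dimnames = list(paste0("P", seq_len(n_per)), NULL))
  new_trial(trial_id, eeg, per, valence, arousal)
}
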