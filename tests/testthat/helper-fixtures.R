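# Shared fixtures, built once per test run and cached.

with_seed <- grfest:::with_seed

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# one participant with deterministic mid-range characteristics
fixture_profile <- function() {
  fixture("profile", {
    prof <- generate_cohort(1, seed = 401)[1, ]
    prof$stride_cv <- 0.03
    prof
  })
}

# one 20 s flat session with default noise
fixture_session <- function() {
  fixture("session", {
    generate_session(fixture_profile(),
                     list(speed = 11, gradient = 1, duration = 20,
                          condition_id = "C01"),
                     seed = 402)
  })
}

# the session preprocessed end to end
fixture_processed <- function() {
  fixture("processed", suppressMessages(preprocess_session(fixture_session())))
}

fixture_contacts <- function() fixture_processed()$contacts

# a small 3-participant dataset for fold-structure tests (short stages)
fixture_cohort_contacts <- function() {
  fixture("cohort_contacts", {
    cfg <- synth_config(stage_duration_s = 12)
    ds <- simulate_dataset(3, seed = 77, protocol = "quick", config = cfg)
    ds$contacts
  })
}

# the study-condition cohort used by the parameter-recovery check:
# 10 participants, ~200 contacts each over 3 gradients and 3+ speeds
fixture_acceptance_dataset <- function() {
  fixture("acceptance_dataset",
          simulate_dataset(10, seed = 42, protocol = "quick"))
}

# standardized features + BW targets for the single-session contacts
fixture_feature_set <- function() {
  fixture("feature_set", {
    contacts <- fixture_contacts()
    f <- build_features(contacts)
    s <- suppressWarnings(fit_standardizer(f))
    list(features = apply_standardizer(s, f),
         raw = f, standardizer = s,
         targets = build_targets(contacts, "grf_v"),
         contacts = contacts)
  })
}

# random standardized-looking feature array for pure model tests
make_features <- function(n, T_len = 50, C = 5, seed = 1,
                          standardized = TRUE) {
  vals <- with_seed(seed, array(rnorm(n * T_len * C), dim = c(n, T_len, C)))
  channels <- paste0("ch", seq_len(C))
  structure(vals, channel_names = channels,
            contact_index = data.frame(
              participant_id = rep("T01", n), condition_id = "C01",
              contact = seq_len(n)),
            standardized = standardized, class = "grf_features")
}

# small fast model configuration for unit tests
tiny_config <- function(...) {
  defaults <- list(learning_rate = 2e-3, n_epochs = 3, batch_size = 8,
                   lstm_hidden = 6, input_dropout = 0, linear_dropout = 0,
                   linear2_size = 5, linear3_size = 4,
                   activation = "tanh", seed = 99)
  do.call(model_config, modifyList(defaults, list(...)))
}
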