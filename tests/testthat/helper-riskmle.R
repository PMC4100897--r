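# Shared fixtures, built in code at test time.

# a small complete dataset with deterministic-ish responses
tiny_dataset <- function(n_subjects = 6, seed = 421,
                         truth = risk_truth("EUT", "FP",
                                            n_subjects = n_subjects)) {
  simulate_choices(truth, seed = seed)
}

# dataset in which every response is INDIFFERENT: each record's likelihood is
# exactly 0.5 under any parameter value
all_indifferent_dataset <- function(n_subjects = 4) {
  grid <- expand.grid(task_id = c("low", "high"), row_index = 1:10,
                      subject_id = sprintf("S%02d", seq_len(n_subjects)),
                      stringsAsFactors = FALSE)
  grid$response <- "INDIFFERENT"
  choice_data(grid)
}

# fabricate a minimal riskfit-shaped object from a per-record log-likelihood
# vector, for oracle tests of the non-nested tests
fake_fit <- function(loglik_i, k = 2, n_clusters = 2) {
  n <- length(loglik_i)
  structure(list(
    functional = "EUT", error = "FP", k = k,
    loglik_i = loglik_i, logLik = sum(loglik_i), n_obs = n,
    record_key = sprintf("rec%04d", seq_len(n)),
    prep = list(cluster_idx = rep_len(seq_len(n_clusters), n))
  ), class = "riskfit")
}

# all 20 pairs of the two-scale design, as lottery_pair objects
design_pairs <- function() {
  c(hl_design(1)$pairs, hl_design(5)$pairs)
}
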