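# small fixtures shared across test files; everything generated in code

small_dataset <- function(n = 100, p = 20, rho = 0.5, seed = 1) {
  simulate_bwas_data(n_samples = n, n_features = p, rho_true = rho,
                     n_signal = max(1, round(p / 4)), seed = seed)
}

# hand-built replicate records with known positivity counts
constructed_records <- function(n_total = 100, n_disc_pos = 80,
                                n_both_pos = 60, n = 200) {
  # discovery-positive rows get r_disc_cv 0.3 (p < alpha at n = 200),
  # replication-positive rows get r_rep 0.3; the rest sit at ~0
  disc_pos <- c(rep(TRUE, n_disc_pos), rep(FALSE, n_total - n_disc_pos))
  rep_pos <- c(rep(TRUE, n_both_pos), rep(FALSE, n_total - n_both_pos))
  r_cv <- ifelse(disc_pos, 0.3, 0.01)
  r_rep <- ifelse(rep_pos, 0.3, 0.01)
  tibble::tibble(
    n = n,
    replicate = seq_len(n_total),
    r_disc_insample = r_cv + 0.5,
    r_disc_cv = r_cv,
    p_disc_cv = r_p_value(r_cv, n),
    r_rep = r_rep,
    p_rep_value = r_p_value(r_rep, n),
    seed_used = seq_len(n_total)
  )
}
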