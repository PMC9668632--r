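#' Simulated power of the KW/Dunn path for a state-occupancy shift
#'
#' Monte-Carlo power analysis for the group analysis of state-5 fraction
#' time: three groups (controls and two patient subgroups) of equal size are
#' simulated from the default Markov state process, with the third group's
#' state-5 transition diagonal raised by `shift`; ages are drawn with the
#' cohort's group-age structure (the affected subgroup is older). Each
#' replicate computes per-participant window labels (majority vote over
#' 22-TR windows), state-5 fraction time, and the age-residualised
#' Kruskal-Wallis test with Dunn's post-hoc comparisons. Detection requires
#' the omnibus p <= alpha and a BH-corrected Dunn p <= alpha for the
#' subgroup contrast.
#'
#' @param n_per_group Participants per group.
#' @param shift Additive bias on the state-5 transition diagonal for the
#'   affected group.
#' @param n_rep Number of simulation replicates.
#' @param n_timepoints TRs per scan (default 255).
#' @param w Window length in TR (default 22).
#' @param alpha Test level (default 0.05).
#' @param seed Integer seed.
#' @return Proportion of replicates in which the shift is detected.
#' @export
kw_dunn_power <- function(n_per_group = 60, shift = 0.03, n_rep = 50,
                          n_timepoints = 255L, w = 22L, alpha = 0.05,
                          seed = 1L) {
  P0 <- default_transition_matrix(5L)
  P1 <- shift_transition_diagonal(P0, c(0, 0, 0, 0, shift))
  cfg0 <- state_process_config(P0, default_state_centroids(), seed = seed)
  groups <- rep(c("HC", "no_disability", "mild_moderate"),
                each = n_per_group)
  age_mu <- c(HC = 35, no_disability = 31.6, mild_moderate = 40.2)
  age_sd <- c(HC = 10.3, no_disability = 6.1, mild_moderate = 11.6)
  detected <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    base <- seed + 7919L * r
    ft5 <- numeric(length(groups))
    for (i in seq_along(groups)) {
      cfg_i <- cfg0
      if (groups[i] == "mild_moderate") cfg_i$transition_matrix <- P1
      tr <- generate_state_sequence(cfg_i, n_timepoints, seed = base + i)
      wl <- window_truth_labels(tr, w = w)
      ft5[i] <- fraction_time(wl, 5)[5]
    }
    set.seed(base)
    age <- pmax(18, rnorm(length(groups), age_mu[groups], age_sd[groups]))
    gt <- metric_group_test(ft5, age, groups)
    pair <- gt$dunn$group_a == "mild_moderate" |
      gt$dunn$group_b == "mild_moderate"
    contrast <- gt$dunn$p_fdr[pair & (gt$dunn$group_a == "no_disability" |
                                        gt$dunn$group_b == "no_disability")]
    detected[r] <- gt$kw$p <= alpha && length(contrast) == 1 &&
      contrast <= alpha
  }
  mean(detected)
}
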