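# Shared fixtures built in code: small source tables and reduced MCMC
# settings so the mixing tests stay fast.

make_sources <- function(mean_d2H, mean_d18O = (mean_d2H + 20) / 5.5,
                         labels = sprintf("S%d", seq_along(mean_d2H)),
                         sd = 1) {
  data.frame(layer = labels,
             depth_top_cm = seq(0, by = 20, length.out = length(mean_d2H)),
             depth_bottom_cm = seq(20, by = 20, length.out = length(mean_d2H)),
             n = 3L,
             mean_d2H = mean_d2H, sd_d2H = sd,
             mean_d18O = mean_d18O, sd_d18O = sd / 5,
             sd_flagged = FALSE, stringsAsFactors = FALSE)
}

make_mixture <- function(d2H, d18O = (d2H + 20) / 5.5) {
  data.frame(d2H_permil = d2H, d18O_permil = d18O)
}

fast_mixing <- function(seed = 1, ...) {
  mixing_config(iterations = 6000L, burn_in = 3000L, thin = 3L,
                seed = seed, ...)
}

# Build a posterior_proportions object directly from a draw matrix
# (for aggregation/summary unit tests that need exact draws).
fake_posterior <- function(draws, labels = colnames(draws)) {
  colnames(draws) <- labels
  structure(list(source_labels = labels, draws = draws,
                 chain = rep(1:2, length.out = nrow(draws)),
                 residual_sd_draws = NULL,
                 rhat = stats::setNames(rep(1, ncol(draws)), labels),
                 acceptance = NA_real_, config = mixing_config()),
            class = "posterior_proportions")
}

ck_site <- function() {
  cs <- default_chronosequence()
  cs[cs$site_id == "CK", ]
}
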