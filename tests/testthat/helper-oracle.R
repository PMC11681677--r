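# Independent single-year-of-age cohort simulator, used as the oracle for
# the 5-year-group ageing chain. Ages 0..104 with an absorbing terminal age;
# a 21 x 2 group array is spread uniformly within each group at start.
brute_force_cohort <- function(pop_groups, mortality, tfr, shape, srb, steps) {
  n_age <- 105L
  grp <- pmin((0:(n_age - 1L)) %/% 5L + 1L, 21L)
  p <- sapply(c("M", "F"), function(s) pop_groups[grp, s] / 5)
  totals <- numeric(steps + 1L)
  totals[1L] <- sum(p)
  fert <- numeric(n_age)
  in_f <- grp %in% 4:10
  fert[in_f] <- tfr * shape[as.character(grp[in_f])] / 5
  for (t in seq_len(steps)) {
    surv <- p * (1 - mortality[grp, ])
    births <- sum(fert * p[, "F"])
    newp <- rbind(c(births * srb / (1 + srb), births / (1 + srb)),
                  surv[-n_age, ])
    newp[n_age, ] <- newp[n_age, ] + surv[n_age, ]
    p <- newp
    totals[t + 1L] <- sum(p)
  }
  totals
}

# Default three-scenario TFR presets used across tests.
TFR_PRESETS <- c(low = 1.05, medium = 1.45, high = 1.85)
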