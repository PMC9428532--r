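# shared simulation helpers for the test suite

# balanced mixed-design data: 2 groups (between) x rt x noise (within),
# random subject intercept, Gaussian cells; `interact` shifts the
# (HI, hi-rt) cells in units of the residual SD
simdat_anova <- function(seed, interact = 0, n_per_group = 32,
                         sd_subject = 8, sd_resid = 8) {
  set.seed(seed)
  d <- expand.grid(listener = sprintf("S%03d", seq_len(2 * n_per_group)),
                   rt = c("lo", "hi"), noise = c("stat", "mod"),
                   stringsAsFactors = FALSE)
  idx <- as.integer(sub("S", "", d$listener))
  d$group <- ifelse(idx <= n_per_group, "NH", "HI")
  b <- rnorm(2 * n_per_group, 0, sd_subject)
  d$score <- 60 + ifelse(d$group == "NH", 8, -8) +
    ifelse(d$rt == "hi", -15, 0) + ifelse(d$noise == "mod", 5, 0) +
    interact * sd_resid * (d$rt == "hi" & d$group == "HI") * -1 +
    b[idx] + rnorm(nrow(d), 0, sd_resid)
  d
}

# a quick small room for tests that only need *an* RIR
quick_rir <- function(rt = 0.5, seed = 1, fs = 16000) {
  normalize_energy(simulate_rir(virtual_room(rt, fs = fs), seed = seed))
}
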