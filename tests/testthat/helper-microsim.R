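# Independent individual-level oracle for the cohort engine, written
# directly from the competing-risk convention (death drawn first each
# cycle, then one event among survivors) without using the package's
# transition matrices.  Four states: dt, nds, ds, dead.

microsim_4state <- function(n, cycles, q_death, p_dt_nds, p_dt_ds, p_nds_ds,
                            seed, at = c(6, 12, 24)) {
  withr::with_seed(seed, {
    state <- rep.int(1L, n) # 1 dt, 2 nds, 3 ds, 4 dead
    shares <- matrix(NA_real_, length(at), 4,
                     dimnames = list(at, c("dt", "nds", "ds", "dead")))
    for (t in seq_len(cycles)) {
      qd <- unname(q_death[state])
      dies <- runif(n) < qd & state != 4L
      state[dies] <- 4L
      u <- runif(n)
      from_dt <- state == 1L
      from_nds <- state == 2L
      state[from_dt & u < p_dt_nds] <- 2L
      state[from_dt & u >= p_dt_nds & u < p_dt_nds + p_dt_ds] <- 3L
      state[from_nds & u < p_nds_ds] <- 3L
      if (t %in% at) {
        shares[as.character(t), ] <- tabulate(state, nbins = 4) / n
      }
    }
    shares
  })
}
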