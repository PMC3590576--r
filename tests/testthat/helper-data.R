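# Shared small fixtures built in code.

small_dataset <- function(n_chains = 12L, seed = 101L, length_range = c(25L, 40L),
                          ...) {
  simulate_dataset(sim_config(n_chains = n_chains, length_range = length_range,
                              seed = seed, ...))
}

# a 2-chain hand-checkable dataset with deterministic SS strings
tiny_manual_dataset <- function() {
  chains <- data.frame(chain_id = c("c1", "c2"),
                       sequence = c("ACDEFGH", "MKLV"),
                       stringsAsFactors = FALSE)
  class(chains) <- c("chain_set", "data.frame")
  pssms <- list(
    c1 = matrix(0L, 7, 20, dimnames = list(NULL, fsklr:::PSSM_COLUMNS)),
    c2 = matrix(1L, 4, 20, dimnames = list(NULL, fsklr:::PSSM_COLUMNS)))
  mk_ss <- function(states, conf) list(states = states, conf = conf)
  ss <- list(
    c1 = list(psipred = mk_ss("CCCCCCC", rep(9L, 7)),
              jnet = mk_ss("HHHCCCC", rep(5L, 7)),
              transec = mk_ss("CCCCEEC", rep(3L, 7)),
              proteus = mk_ss("CCCCCCC", rep(7L, 7))),
    c2 = list(psipred = mk_ss("HECC", c(1L, 2L, 3L, 4L)),
              jnet = mk_ss("CCCC", rep(9L, 4)),
              transec = mk_ss("HHHH", rep(0L, 4)),
              proteus = mk_ss("EEEE", rep(8L, 4))))
  labels <- c(c1 = "nttttnn", c2 = "nnnn")
  list(chains = chains, pssms = pssms, ss = ss, labels = labels,
       sources = default_ss_sources())
}
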