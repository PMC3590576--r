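# Seeded generator of synthetic chains, PSSM profiles, four-source
# secondary-structure predictions and turn labels carrying the statistical
# structure the predictor assumes, so every pipeline stage is testable
# without external downloads.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the benchmark conditions the method targets: ~25% of
#' residues in turns, turn runs of at least four residues, a one-logit
#' class shift on five PSSM columns, and four secondary-structure sources
#' that emit the correct state 80% of the time.
#'
#' @param n_chains Number of chains (default 100).
#' @param length_range Inclusive (min, max) chain length (default 40-80).
#' @param turn_fraction Target turn prevalence (default 0.25).
#' @param min_run Minimum turn-run length (default 4).
#' @param pssm_effect Mean log-odds shift between turn and non-turn rows on
#'   the signal columns, applied before logistic scaling (default 1.0).
#' @param n_signal_cols Number of PSSM columns carrying the shift (default
#'   5).
#' @param ss_accuracy Probability that a source emits the latent true state
#'   (default 0.8; 1/3 is exactly uninformative).
#' @param confidence_fidelity Probability that the confidence digit reflects
#'   whether the emission matched the latent state (default 0.8).
#' @param seed Integer RNG seed (default 1).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chains = 100L, length_range = c(40L, 80L),
                       turn_fraction = 0.25, min_run = 4L, pssm_effect = 1.0,
                       n_signal_cols = 5L, ss_accuracy = 0.8,
                       confidence_fidelity = 0.8, seed = 1L) {
  if (turn_fraction <= 0 || turn_fraction >= 1) stop("turn_fraction must be in (0,1)")
  if (min_run < 1L) stop("min_run must be at least 1")
  if (ss_accuracy < 1 / 3 || ss_accuracy > 1) {
    stop("ss_accuracy must be in [1/3, 1]")
  }
  if (confidence_fidelity < 0 || confidence_fidelity > 1) {
    stop("confidence_fidelity must be in [0, 1]")
  }
  if (n_signal_cols < 0L || n_signal_cols > 20L) stop("n_signal_cols must be 0-20")
  mean_turn <- min_run + 1          # min_run + Geometric(1/2)
  if (turn_fraction > mean_turn / (mean_turn + 1)) {
    stop("turn_fraction infeasible for this min_run: gaps would need mean < 1")
  }
  structure(list(n_chains = n_chains, length_range = length_range,
                 turn_fraction = turn_fraction, min_run = min_run,
                 pssm_effect = pssm_effect, n_signal_cols = n_signal_cols,
                 ss_accuracy = ss_accuracy,
                 confidence_fidelity = confidence_fidelity, seed = seed),
            class = "sim_config")
}

# two-state renewal label process: turn segments of length min_run +
# Geometric(1/2), gaps of length 1 + Geometric(q) with q set so the
# expected prevalence matches turn_fraction; turns are only started when at
# least min_run residues remain, so every turn run has full length.
sim_labels <- function(L, config) {
  mean_turn <- config$min_run + 1
  mean_gap <- mean_turn * (1 - config$turn_fraction) / config$turn_fraction
  q_gap <- 1 / mean_gap
  lab <- character(0)
  in_turn <- stats::runif(1) < config$turn_fraction
  while (length(lab) < L) {
    remaining <- L - length(lab)
    if (in_turn && remaining >= config$min_run) {
      len <- min(config$min_run + stats::rgeom(1, 0.5), remaining)
      lab <- c(lab, rep("t", len))
    } else {
      len <- min(1 + stats::rgeom(1, q_gap), remaining)
      lab <- c(lab, rep("n", len))
    }
    in_turn <- !in_turn
  }
  paste(lab, collapse = "")
}

#' Generate a complete synthetic dataset
#'
#' Labels come from a two-state renewal process with turn runs of at least
#' `min_run` residues and expected prevalence `turn_fraction`.  Raw PSSM
#' rows are integer-rounded Normal(mu_class, 1) log-odds on the first
#' `n_signal_cols` columns (class means +/- `pssm_effect`/2) and
#' Normal(0, 1) elsewhere.  A latent three-state secondary structure sets
#' turn residues to coil and draws H/E/C at 0.45/0.35/0.20 elsewhere; each
#' of the four sources independently emits the latent state with
#' probability `ss_accuracy` (else the other two states equally), with
#' confidence digits drawn high (5-9) when the emission matches the latent
#' state and low (0-4) otherwise, degraded by `confidence_fidelity`.
#' Fully reproducible from the config seed.
#'
#' @param config A `sim_config`.
#' @return Dataset list with `chains` (a `chain_set`), `pssms` (named list
#'   of L x 20 integer matrices), `ss` (nested per-chain per-source), `
#'   labels` (named \{t,n\} strings), `sources`, and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  sources <- default_ss_sources()
  n <- config$n_chains
  ids <- sprintf("syn%04d", seq_len(n))
  seqs <- character(n)
  pssms <- list()
  ss <- list()
  labels <- character(n)
  for (i in seq_len(n)) {
    lr <- config$length_range
    L <- if (lr[1] == lr[2]) as.integer(lr[1]) else sample(lr[1]:lr[2], 1L)
    seqs[i] <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    lab <- sim_labels(L, config)
    labels[i] <- lab
    is_turn <- strsplit(lab, "")[[1]] == "t"
    mu <- matrix(0, L, 20L)
    if (config$n_signal_cols > 0L) {
      sig <- seq_len(config$n_signal_cols)
      mu[, sig] <- ifelse(is_turn, config$pssm_effect / 2, -config$pssm_effect / 2)
    }
    raw <- round(matrix(stats::rnorm(L * 20L), L, 20L) + mu)
    colnames(raw) <- PSSM_COLUMNS
    pssms[[ids[i]]] <- raw
    latent <- ifelse(is_turn, "C",
                     sample(SS_STATES, L, replace = TRUE,
                            prob = c(0.45, 0.35, 0.20)))
    ss[[ids[i]]] <- list()
    for (src in sources) {
      emit_true <- stats::runif(L) < config$ss_accuracy
      other <- vapply(latent, function(s) sample(setdiff(SS_STATES, s), 1L),
                      character(1))
      states <- ifelse(emit_true, latent, other)
      match <- states == latent
      faithful <- stats::runif(L) < config$confidence_fidelity
      conf <- ifelse(faithful,
                     ifelse(match, sample(5:9, L, replace = TRUE),
                            sample(0:4, L, replace = TRUE)),
                     sample(0:9, L, replace = TRUE))
      ss[[ids[i]]][[src]] <- list(states = paste(states, collapse = ""),
                                  conf = as.integer(conf))
    }
  }
  chains <- data.frame(chain_id = ids, sequence = seqs, stringsAsFactors = FALSE)
  class(chains) <- c("chain_set", "data.frame")
  list(chains = chains, pssms = pssms, ss = ss,
       labels = stats::setNames(labels, ids), sources = sources,
       config = config)
}

#' Write a dataset as fixture files in every supported format
#'
#' Produces `chains.fasta`, one `<chain_id>.pssm` per chain (PSI-BLAST
#' ASCII dialect), `ss_predictions.tsv` and `labels.tsv`, all readable by
#' the package readers with round-trip identity.
#'
#' @param dataset Dataset list from [simulate_dataset()].
#' @param outdir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture_files <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(outdir, "chains.fasta")
  if (nrow(dataset$chains) > 0L) {
    write_fasta(dataset$chains, fasta)
  } else {
    writeLines(character(0), fasta)
  }
  pssm_paths <- character(0)
  for (i in seq_len(nrow(dataset$chains))) {
    cid <- dataset$chains$chain_id[i]
    path <- file.path(outdir, paste0(cid, ".pssm"))
    write_pssm(dataset$pssms[[cid]], dataset$chains$sequence[i], path)
    pssm_paths[cid] <- path
  }
  ss_path <- file.path(outdir, "ss_predictions.tsv")
  write_ss_predictions(dataset$ss, ss_path)
  labels_path <- file.path(outdir, "labels.tsv")
  write_turn_labels(dataset$labels, labels_path)
  invisible(list(fasta = fasta, pssms = pssm_paths, ss = ss_path,
                 labels = labels_path))
}

#' Read a dataset from a fixture directory
#'
#' Counterpart of [write_fixture_files()]: loads chains, per-chain PSSMs,
#' secondary-structure predictions and (when present) labels with full
#' cross-validation of lengths and residues.
#'
#' @param fasta Path to the chains FASTA.
#' @param pssm_dir Directory containing `<chain_id>.pssm` files.
#' @param ss_file Path to the SS predictions TSV.
#' @param labels_file Optional path to the labels TSV.
#' @return Dataset list (chains, pssms, ss, labels, sources).
#' @export
read_dataset <- function(fasta, pssm_dir, ss_file, labels_file = NULL) {
  chains <- read_fasta(fasta)
  pssms <- list()
  for (i in seq_len(nrow(chains))) {
    cid <- chains$chain_id[i]
    path <- file.path(pssm_dir, paste0(cid, ".pssm"))
    pssms[[cid]] <- read_pssm(path, cid, chains$sequence[i])$raw
  }
  ss <- read_ss_predictions(ss_file, chains)
  labels <- if (!is.null(labels_file)) read_turn_labels(labels_file, chains)
  list(chains = chains, pssms = pssms, ss = ss, labels = labels,
       sources = default_ss_sources())
}
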