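# Ordered state-changing rules that make raw per-residue predictions more
# beta-turn like, exploiting that turns occupy runs of at least four
# adjacent residues.

#' Smooth per-residue turn labels with ordered state-changing rules
#'
#' Four passes, in this fixed order:
#' 1. isolated non-turns become turns (tnt -> ttt);
#' 2. isolated turns become non-turns (ntn -> nnn);
#' 3. both flanks of an isolated turn pair become turns (nttn -> tttt);
#' 4. for an isolated turn triplet, the flanking non-turn with the higher
#'    turn probability becomes a turn (ntttn -> ttttn or ntttt; ties go to
#'    the left flank).
#'
#' Within each pass all pattern matches are located on the pass-input
#' string and flipped together, so results do not depend on scan
#' direction.  Patterns must lie fully inside the chain: no virtual
#' residues are assumed beyond the termini, so runs touching a chain end
#' may remain shorter than four residues.
#'
#' @param labels Either a single string or a character vector over \{t,n\}.
#' @param probs Numeric vector of per-position turn probabilities (same
#'   length as the labels); only rule 4's flank comparison reads it.
#' @return Smoothed labels, same type as the input.
#' @export
apply_state_rules <- function(labels, probs) {
  as_string <- length(labels) == 1L && nchar(labels[1]) != 1L
  lab <- if (as_string) strsplit(labels, "")[[1]] else labels
  L <- length(lab)
  if (length(probs) != L) stop("labels and probabilities must have equal length")
  if (any(!lab %in% c("t", "n"))) stop("labels must be over {t,n}")

  if (L >= 3L) {
    core <- 2:(L - 1L)
    # rule 1: tnt -> ttt
    hit <- core[lab[core] == "n" & lab[core - 1L] == "t" & lab[core + 1L] == "t"]
    lab[hit] <- "t"
    # rule 2: ntn -> nnn
    hit <- core[lab[core] == "t" & lab[core - 1L] == "n" & lab[core + 1L] == "n"]
    lab[hit] <- "n"
  }
  if (L >= 4L) {
    # rule 3: nttn -> tttt
    i <- seq_len(L - 3L)
    hit <- i[lab[i] == "n" & lab[i + 1L] == "t" & lab[i + 2L] == "t" & lab[i + 3L] == "n"]
    lab[c(hit, hit + 3L)] <- "t"
  }
  if (L >= 5L) {
    # rule 4: ntttn -> ttttn or ntttt, by the flanks' probabilities
    i <- seq_len(L - 4L)
    hit <- i[lab[i] == "n" & lab[i + 1L] == "t" & lab[i + 2L] == "t" &
               lab[i + 3L] == "t" & lab[i + 4L] == "n"]
    if (length(hit) > 0L) {
      flip <- ifelse(probs[hit] >= probs[hit + 4L], hit, hit + 4L)
      lab[flip] <- "t"
    }
  }
  if (as_string) paste(lab, collapse = "") else lab
}
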