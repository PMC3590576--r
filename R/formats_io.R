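# Readers/writers for every external file the tool touches.
# All file positions are 1-based, matching both the profile dialect and R.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PSSM_COLUMNS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
SS_STATES <- c("H", "E", "C")

#' Default order of the four secondary-structure prediction sources
#'
#' The secondary-structure feature blocks are laid out per source, so the
#' source order is part of the model contract and is enforced on input.
#'
#' @return Character vector of the four source names in canonical order.
#' @export
default_ss_sources <- function() {
  c("psipred", "jnet", "transec", "proteus")
}

#' Read protein chains from a FASTA file
#'
#' Sequences are uppercased; only the 20 standard amino-acid letters plus X
#' are accepted.  Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A data frame of class `chain_set` with columns `chain_id` and
#'   `sequence`, one row per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) stop("FASTA record with empty ID in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate chain IDs in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    letters_i <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!letters_i %in% c(AA_ALPHABET, "X"))
    if (length(bad) > 0L) {
      stop(sprintf("illegal residue character '%s' at position %d of record '%s'",
                   letters_i[bad[1]], bad[1], ids[i]))
    }
  }
  chains <- data.frame(chain_id = ids, sequence = unname(seqs),
                       stringsAsFactors = FALSE)
  class(chains) <- c("chain_set", "data.frame")
  chains
}

#' Write protein chains to a FASTA file
#'
#' @param chains A `chain_set` data frame (`chain_id`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(chains, path) {
  set <- Biostrings::AAStringSet(chains$sequence)
  names(set) <- chains$chain_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the first 20-column log-odds block of the PSI-BLAST ASCII profile
#' dialect: header lines, then one row per residue carrying the 1-based
#' position, the residue letter, and 20 integer log-odds scores.  Any
#' percentage block or trailing statistics are ignored.
#'
#' @param path Path to the profile file.
#' @param chain_id Chain identifier to attach.
#' @param sequence Optional chain sequence; when given, length and residue
#'   letters are cross-checked position by position.
#' @return An object of class `pssm_profile`: list with `chain_id` and the
#'   L x 20 numeric matrix `raw` (columns in PSI-BLAST amino-acid order).
#' @export
read_pssm <- function(path, chain_id, sequence = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)
  rows <- list()
  letters_seen <- character(0)
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 22L) next
    if (!grepl("^[0-9]+$", tok[1])) next
    pos <- as.integer(tok[1])
    res <- tok[2]
    scores <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(scores)) {
      stop(sprintf("non-numeric score in PSSM row for position %d of '%s'",
                   pos, chain_id))
    }
    if (pos != length(rows) + 1L) {
      stop(sprintf("non-contiguous PSSM rows near position %d of '%s'", pos, chain_id))
    }
    rows[[pos]] <- scores
    letters_seen[pos] <- res
  }
  if (length(rows) == 0L) stop("no score rows found in PSSM file: ", path)
  raw <- do.call(rbind, rows)
  colnames(raw) <- PSSM_COLUMNS
  if (!is.null(sequence)) {
    if (nrow(raw) != nchar(sequence)) {
      stop(sprintf("PSSM for '%s' has %d rows but chain length is %d",
                   chain_id, nrow(raw), nchar(sequence)))
    }
    seq_letters <- strsplit(sequence, "")[[1]]
    mism <- which(letters_seen != seq_letters)
    if (length(mism) > 0L) {
      stop(sprintf("PSSM residue mismatch for '%s' at position %d ('%s' vs '%s')",
                   chain_id, mism[1], letters_seen[mism[1]], seq_letters[mism[1]]))
    }
  }
  structure(list(chain_id = chain_id, raw = raw), class = "pssm_profile")
}

#' Write a PSSM profile in the PSI-BLAST ASCII dialect
#'
#' @param raw L x 20 numeric matrix of (integer) log-odds scores.
#' @param sequence Chain sequence of length L.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(raw, sequence, path) {
  stopifnot(nrow(raw) == nchar(sequence), ncol(raw) == 20L)
  seq_letters <- strsplit(sequence, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               paste0("      ", paste(sprintf("%3s", PSSM_COLUMNS), collapse = ""))),
             con)
  for (i in seq_len(nrow(raw))) {
    writeLines(paste0(sprintf("%5d %s ", i, seq_letters[i]),
                      paste(sprintf("%3d", as.integer(round(raw[i, ]))), collapse = "")),
               con)
  }
  invisible(path)
}

#' Read secondary-structure predictions from columnar TSV
#'
#' One row per (chain, source, position) with columns `chain_id`, `source`,
#' `pos` (1-based), `state` (H/E/C) and `conf` (digit 0-9).  Positions must
#' be contiguous from 1 to the chain length for every (chain, source) pair.
#'
#' @param path Path to the TSV file.
#' @param chains Optional `chain_set` for length cross-checking.
#' @return Nested list `ss[[chain_id]][[source]]`, each element a list with
#'   `states` (character string over H/E/C) and `conf` (integer vector 0-9).
#' @export
read_ss_predictions <- function(path, chains = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain_id", "source", "pos", "state", "conf")
  if (!all(need %in% names(df))) {
    stop("SS prediction file must have columns: ", paste(need, collapse = ", "))
  }
  bad_state <- which(!df$state %in% SS_STATES)
  if (length(bad_state) > 0L) {
    stop(sprintf("SS state outside {H,E,C} at data row %d ('%s')",
                 bad_state[1], df$state[bad_state[1]]))
  }
  if (any(df$conf < 0 | df$conf > 9 | df$conf != floor(df$conf))) {
    stop("SS confidence values must be integer digits 0-9")
  }
  out <- list()
  for (cid in unique(df$chain_id)) {
    sub_c <- df[df$chain_id == cid, , drop = FALSE]
    out[[cid]] <- list()
    for (src in unique(sub_c$source)) {
      sub <- sub_c[sub_c$source == src, , drop = FALSE]
      sub <- sub[order(sub$pos), , drop = FALSE]
      if (!identical(as.integer(sub$pos), seq_len(nrow(sub)))) {
        stop(sprintf("non-contiguous positions for chain '%s', source '%s'", cid, src))
      }
      if (!is.null(chains)) {
        L <- nchar(chains$sequence[match(cid, chains$chain_id)])
        if (!is.na(L) && nrow(sub) != L) {
          stop(sprintf("SS prediction for '%s'/'%s' has %d positions, chain length %d",
                       cid, src, nrow(sub), L))
        }
      }
      out[[cid]][[src]] <- list(states = paste(sub$state, collapse = ""),
                                conf = as.integer(sub$conf))
    }
  }
  out
}

#' Write secondary-structure predictions to columnar TSV
#'
#' @param ss Nested list as returned by [read_ss_predictions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ss_predictions <- function(ss, path) {
  rows <- list()
  for (cid in names(ss)) {
    for (src in names(ss[[cid]])) {
      el <- ss[[cid]][[src]]
      L <- nchar(el$states)
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = cid, source = src, pos = seq_len(L),
        state = strsplit(el$states, "")[[1]], conf = el$conf,
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(chain_id = character(0), source = character(0),
               pos = integer(0), state = character(0), conf = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-chain beta-turn labels from TSV
#'
#' Columns `chain_id` and `labels`, the latter a string over \{t, n\} of the
#' chain length ('t' marks a beta-turn residue).
#'
#' @param path Path to the TSV file.
#' @param chains Optional `chain_set` for length cross-checking.
#' @return Named character vector of label strings.
#' @export
read_turn_labels <- function(path, chains = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chain_id", "labels") %in% names(df))) {
    stop("labels file must have columns chain_id, labels")
  }
  bad <- grepl("[^tn]", df$labels)
  if (any(bad)) {
    stop("labels for chain '", df$chain_id[which(bad)[1]],
         "' contain characters outside {t,n}")
  }
  if (!is.null(chains)) {
    idx <- match(df$chain_id, chains$chain_id)
    L <- nchar(chains$sequence[idx])
    mism <- which(!is.na(idx) & nchar(df$labels) != L)
    if (length(mism) > 0L) {
      stop(sprintf("label string for '%s' has length %d, chain length %d",
                   df$chain_id[mism[1]], nchar(df$labels[mism[1]]), L[mism[1]]))
    }
  }
  stats::setNames(df$labels, df$chain_id)
}

#' Write per-chain beta-turn labels to TSV
#'
#' @param labels Named character vector of \{t,n\} strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_turn_labels <- function(labels, path) {
  df <- data.frame(chain_id = names(labels), labels = unname(labels),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-residue predictions to TSV
#'
#' @param records Data frame with columns `chain_id`, `pos` (1-based),
#'   `prob` (turn probability in \[0,1\], printed with 6 decimals), `raw`
#'   and `smoothed` (labels in \{t,n\}).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, path) {
  need <- c("chain_id", "pos", "prob", "raw", "smoothed")
  if (!all(need %in% names(records))) {
    stop("prediction records must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(records) > 0L &&
      (any(!is.finite(records$prob)) || any(records$prob < 0 | records$prob > 1))) {
    stop("refusing to write probabilities outside [0,1]")
  }
  out <- records[, need, drop = FALSE]
  out$prob <- sprintf("%.6f", out$prob)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predictions TSV written by [write_predictions()]
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `chain_id`, `pos`, `prob`, `raw`,
#'   `smoothed`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(pos = "integer", prob = "numeric"))
  df
}
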