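# shared internal helpers

# Truncate (not round) to one decimal, the convention used for all reported
# percentages; a tiny epsilon guards against values like 87.5 stored as
# 87.4999... in floating point.
trunc1 <- function(x) floor(x * 10 + 1e-9) / 10

ALLOWED_CHARS <- c("A", "C", "G", "T", "-", "N")
BASE_STATES <- c("A", "C", "G", "T", "-")  # tie-break order for consensus

# Split aligned sequences (character vector) into an n x L character matrix.
seq_matrix <- function(seqs) {
  if (length(seqs) == 0L) abort("no sequences supplied", class = "clonevar_empty_input")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) {
    abort(
      paste0("aligned sequences must share one length; found lengths ",
             paste(sort(L), collapse = ", ")),
      class = "clonevar_alignment_error"
    )
  }
  m <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  bad <- setdiff(unique(as.vector(m)), ALLOWED_CHARS)
  if (length(bad) > 0L) {
    abort(paste0("illegal sequence character(s): ", paste(bad, collapse = ", "),
                 " (allowed: A,C,G,T,-,N)"),
          class = "clonevar_format_error")
  }
  m
}

collapse_chars <- function(m) apply(m, 1L, paste, collapse = "")

# Single aligned sequence -> character vector
seq_chars <- function(seq) strsplit(toupper(seq), "", fixed = TRUE)[[1L]]

# Consensus state of one alignment column: most frequent state among
# {A,C,G,T,-}; ties broken in the fixed order A < C < G < T < -; N never wins.
column_consensus <- function(col) {
  col <- col[col != "N"]
  if (length(col) == 0L) return("N")
  counts <- table(factor(col, levels = BASE_STATES))
  BASE_STATES[which.max(counts)]  # which.max takes the first max, i.e. tie order
}
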