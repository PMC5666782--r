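# in-code fixtures: tiny clone sets built from sequence vectors

make_clones <- function(seqs, individual_id = "I1", sex = "F",
                        species = "Test sp.", gene = "ITS2",
                        clone_id = sprintf("c%02d", seq_along(seqs))) {
  clone_tbl(tibble::tibble(
    clone_id = clone_id,
    individual_id = rep_len(individual_id, length(seqs)),
    sex = rep_len(sex, length(seqs)),
    species = species, gene = gene,
    aligned_seq = seqs
  ))
}

# random aligned sequences (possibly with gaps) for property-style tests
random_seqs <- function(n, L, gap_prob = 0.05) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T", "-"), L, replace = TRUE,
                 prob = c(rep((1 - gap_prob) / 4, 4), gap_prob)),
          collapse = "")
  }, character(1))
}

# brute-force p-distance oracle, written independently of p_distance():
# walks the two strings column by column
oracle_pdist <- function(a, b, gap_mode = "fifth_state") {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  num <- 0L
  den <- 0L
  for (k in seq_along(ca)) {
    if (ca[k] == "N" || cb[k] == "N") next
    if (gap_mode == "pairwise_delete" && (ca[k] == "-" || cb[k] == "-")) next
    den <- den + 1L
    if (ca[k] != cb[k]) num <- num + 1L
  }
  num / den
}
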