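# cached invertebrate mitochondrial code (AGA/AGG = Ser, ATA = Met, TGA = Trp;
# stops TAA/TAG only)
mt_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("5")
    code
  }
})

#' Translate under the invertebrate mitochondrial genetic code
#'
#' Walks codons from the given frame of the (degapped) sequence; a trailing
#' partial codon is dropped and any codon containing a non-ACGT character
#' translates to `X`. Stops are `*`.
#'
#' @param seq A sequence string; gaps are removed before translation.
#' @param frame 0, 1 or 2.
#' @return Protein string.
#' @export
#' @examples
#' translate_mt("ATAAGATGATAA")  # "MSW*"
translate_mt <- function(seq, frame = 0L) {
  stopifnot(frame %in% 0:2)
  chars <- seq_chars(seq)
  chars <- chars[chars != "-"]
  if (length(chars) < frame + 3L) {
    abort("sequence too short to translate in this frame",
          class = "clonevar_insufficient_data")
  }
  chars <- chars[(frame + 1L):length(chars)]
  n_codons <- length(chars) %/% 3L
  if (n_codons == 0L) return("")
  codons <- vapply(seq_len(n_codons), function(k) {
    paste(chars[(3L * k - 2L):(3L * k)], collapse = "")
  }, character(1))
  aa <- unname(mt_code()[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

count_stops <- function(seq, frame) {
  sum(seq_chars(translate_mt(seq, frame)) == "*")
}

#' Choose the reading frame of a coding clone set
#'
#' The frame (applied to the degapped dominant haplotype) minimising the
#' number of stop codons; ties go to the lowest frame. If every frame
#' contains stops a warning is issued and the minimising frame is still
#' returned. The chosen frame is applied to all haplotypes of the set.
#'
#' @param dominant_seq Aligned sequence of the dominant haplotype.
#' @return Integer frame in 0..2.
#' @export
choose_frame <- function(dominant_seq) {
  stops <- vapply(0:2, function(f) count_stops(dominant_seq, f), numeric(1))
  f <- which.min(stops) - 1L
  if (min(stops) > 0) {
    warn(sprintf("all frames contain stop codons in the dominant haplotype (min %d in frame %d)",
                 as.integer(min(stops)), f))
  }
  f
}

# indel events of one haplotype relative to the dominant: maximal runs of
# columns whose gap status differs, split by direction (gap in haplotype vs
# gap in dominant)
indel_events <- function(hap_chars, dom_chars) {
  dir <- ifelse(hap_chars == "-" & dom_chars != "-", 1L,
                ifelse(dom_chars == "-" & hap_chars != "-", 2L, 0L))
  r <- rle(dir)
  lens <- r$lengths[r$values > 0L]
  list(n_columns = sum(lens), run_lengths = lens)
}

#' Screen haplotypes for numts, heteroplasmy and pseudogene signals
#'
#' Applies the diagnostic signals used to interpret variant haplotypes in
#' cloned marker libraries. For `mtCO1`: a haplotype with an in-frame stop
#' codon or a frameshift indel (a gap run, relative to the dominant
#' haplotype, whose length is not a multiple of 3) is a `numt_suspect`; a
#' non-dominant haplotype that is stop- and frameshift-free with at least
#' `min_support` supporting clones is a `heteroplasmy_candidate`; anything
#' else is `clean`. Point mutations alone never trigger a numt call — every
#' variant has them and they cannot separate numts from heteroplasmy — but
#' their counts are reported. For `ITS2`: a haplotype with at least
#' `indel_threshold` indel columns relative to the dominant is a
#' `pseudogene_suspect` (indels in this normally length-conserved spacer
#' disrupt its secondary structure).
#'
#' @param x A `haplotype_tbl` from [collapse_haplotypes()].
#' @param gene Gene of the set; defaults to the table's own gene attribute.
#' @param min_support Minimum clone support for a heteroplasmy call.
#' @param indel_threshold Minimum indel columns for an ITS2 pseudogene call.
#' @param frame `"auto"` (choose from the dominant haplotype) or 0/1/2.
#' @return A tibble with per-haplotype counts and a `classification` column.
#' @export
screen_haplotypes <- function(x, gene = NULL, min_support = 5L,
                              indel_threshold = 3L, frame = "auto") {
  if (nrow(x) == 0L) abort("empty haplotype table", class = "clonevar_empty_input")
  gene <- gene %||% attr(x, "gene")
  if (is.null(gene) || !gene %in% c("mtCO1", "ITS2")) {
    abort("screening supports genes 'mtCO1' and 'ITS2' only",
          class = "clonevar_unsupported_gene")
  }
  if (min_support < 2L) abort("min_support must be >= 2", class = "clonevar_config_error")
  dom <- x$sequence[1L]  # H1 by construction
  dom_chars <- seq_chars(dom)

  use_frame <- NA_integer_
  if (gene == "mtCO1") {
    use_frame <- if (identical(frame, "auto")) choose_frame(dom) else as.integer(frame)
  }

  rows <- purrr::map(seq_len(nrow(x)), function(i) {
    hap_chars <- seq_chars(x$sequence[i])
    ev <- indel_events(hap_chars, dom_chars)
    n_frameshift <- sum(ev$run_lengths %% 3L != 0L)
    both_base <- hap_chars != "-" & dom_chars != "-" &
      hap_chars != "N" & dom_chars != "N"
    n_point <- sum(hap_chars[both_base] != dom_chars[both_base])
    n_stops <- if (gene == "mtCO1") count_stops(x$sequence[i], use_frame) else NA_integer_

    classification <- if (gene == "mtCO1") {
      if (n_stops >= 1L || n_frameshift >= 1L) "numt_suspect"
      else if (i > 1L && x$total_count[i] >= min_support) "heteroplasmy_candidate"
      else "clean"
    } else {
      if (ev$n_columns >= indel_threshold) "pseudogene_suspect" else "clean"
    }
    tibble(hap_id = x$hap_id[i], gene = gene, total_count = x$total_count[i],
           n_point_mutations_vs_dominant = n_point,
           indel_columns_vs_dominant = ev$n_columns,
           n_frameshift_indels = n_frameshift,
           n_inframe_stops = as.integer(n_stops),
           classification = classification)
  })
  out <- bind_rows(rows)
  attr(out, "frame") <- use_frame
  out
}
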