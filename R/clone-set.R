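#' Construct a clone set
#'
#' A clone set is a tibble with one row per sequenced clone, joining an aligned
#' sequence to its metadata. It is the common currency of the package: every
#' analysis function takes a clone set as its first argument.
#'
#' @param x A data frame with columns `clone_id`, `individual_id`, `sex`
#'   (`"F"`/`"M"`), `species`, `gene` (`"mtCO1"`, `"ITS2"` or `"other"`), and
#'   `aligned_seq` (equal-length strings over `A`,`C`,`G`,`T`,`-`,`N`).
#'
#' @return A tibble of class `clone_tbl` with attribute `alignment_length`.
#' @export
#' @examples
#' clones <- clone_tbl(tibble::tibble(
#'   clone_id = c("c1", "c2"), individual_id = "I1", sex = "F",
#'   species = "Example sp.", gene = "ITS2",
#'   aligned_seq = c("ACGT", "AC-T")
#' ))
#' alignment_length(clones)
clone_tbl <- function(x) {
  needed <- c("clone_id", "individual_id", "sex", "species", "gene", "aligned_seq")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0L) {
    abort(paste0("clone table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "clonevar_format_error")
  }
  x <- as_tibble(x)[needed]
  if (nrow(x) == 0L) abort("clone table has no rows", class = "clonevar_empty_input")
  if (anyDuplicated(x$clone_id)) {
    dup <- unique(x$clone_id[duplicated(x$clone_id)])
    abort(paste0("duplicated clone_id: ", paste(dup, collapse = ", ")),
          class = "clonevar_format_error")
  }
  if (!all(x$sex %in% c("F", "M"))) {
    abort("sex must be 'F' or 'M'", class = "clonevar_format_error")
  }
  if (!all(x$gene %in% c("mtCO1", "ITS2", "other"))) {
    abort("gene must be 'mtCO1', 'ITS2' or 'other'", class = "clonevar_format_error")
  }
  if (length(unique(x$species)) > 1L || length(unique(x$gene)) > 1L) {
    abort("all clones in a clone set must share species and gene",
          class = "clonevar_format_error")
  }
  m <- seq_matrix(x$aligned_seq)  # validates length + alphabet
  x$aligned_seq <- toupper(x$aligned_seq)
  structure(x,
            alignment_length = ncol(m),
            class = c("clone_tbl", class(as_tibble(x))))
}

#' @rdname clone_tbl
#' @param clones A `clone_tbl`.
#' @export
alignment_length <- function(clones) {
  attr(clones, "alignment_length") %||% unique(nchar(clones$aligned_seq))
}

# keep class/attribute through dplyr-style subsetting used internally
restore_clone_tbl <- function(x, template) {
  structure(as_tibble(x),
            alignment_length = attr(template, "alignment_length"),
            class = class(template))
}

#' Read an aligned clone library from FASTA plus metadata
#'
#' Reads an aligned FASTA (gap character `-`) and a tab-separated metadata
#' table with header `clone_id individual_id sex species gene`, validates the
#' join, and returns a [clone_tbl()]. When `metadata_path` is `NULL` the FASTA
#' headers are expected to carry the metadata inline as
#' `clone_id|individual_id|sex|species|gene`.
#'
#' @param fasta_path Path to an aligned FASTA file.
#' @param metadata_path Path to the metadata TSV, or `NULL` for the
#'   header-encoded dialect.
#' @return A [clone_tbl()].
#' @export
read_clone_set <- function(fasta_path, metadata_path = NULL) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  seq_chr <- as.character(seqs)

  if (is.null(metadata_path)) {
    # header-encoded dialect: the whole header is the record, fields may
    # contain spaces (species names)
    parts <- strsplit(names(seqs), "|", fixed = TRUE)
    if (any(lengths(parts) != 5L)) {
      abort("header-encoded metadata requires 'clone_id|individual_id|sex|species|gene' FASTA ids",
            class = "clonevar_join_error")
    }
    meta <- as_tibble(do.call(rbind, parts), .name_repair = "minimal")
    names(meta) <- c("clone_id", "individual_id", "sex", "species", "gene")
  } else {
    meta <- readr::read_tsv(metadata_path, col_types = readr::cols(.default = "c"),
                            progress = FALSE)
    needed <- c("clone_id", "individual_id", "sex", "species", "gene")
    if (!all(needed %in% names(meta))) {
      abort(paste0("metadata must have columns: ", paste(needed, collapse = ", ")),
            class = "clonevar_format_error")
    }
    missing_meta <- setdiff(ids, meta$clone_id)
    if (length(missing_meta) > 0L) {
      abort(paste0("FASTA id(s) absent from metadata: ",
                   paste(missing_meta, collapse = ", ")),
            class = "clonevar_join_error")
    }
    if (anyDuplicated(meta$clone_id)) {
      abort("metadata clone_id values must be unique", class = "clonevar_join_error")
    }
    extra <- setdiff(meta$clone_id, ids)
    if (length(extra) > 0L) {
      warn(paste0("metadata row(s) without a FASTA record ignored: ",
                  paste(extra, collapse = ", ")))
    }
  }

  seq_tbl <- tibble(clone_id = if (is.null(metadata_path)) meta$clone_id else ids,
                    aligned_seq = unname(seq_chr))
  out <- left_join(seq_tbl,
                   if (is.null(metadata_path)) meta else meta[meta$clone_id %in% ids, ],
                   by = "clone_id")
  clone_tbl(out)
}

#' Write a clone set as aligned FASTA plus metadata TSV
#'
#' @param clones A [clone_tbl()].
#' @param fasta_path,metadata_path Output paths.
#' @return `clones`, invisibly.
#' @export
write_clone_set <- function(clones, fasta_path, metadata_path) {
  ss <- Biostrings::BStringSet(setNames(clones$aligned_seq, clones$clone_id))
  Biostrings::writeXStringSet(ss, fasta_path, width = 70L)
  meta <- as_tibble(clones)[c("clone_id", "individual_id", "sex", "species", "gene")]
  readr::write_tsv(meta, metadata_path, progress = FALSE)
  invisible(clones)
}

#' Column-wise consensus sequence of a clone set
#'
#' Per column, the most frequent state among `A`,`C`,`G`,`T`,`-`; ties broken
#' in the fixed order `A < C < G < T < -`. `N` is treated as missing and never
#' wins a column (a column of only `N` yields `N`).
#'
#' @param clones A [clone_tbl()] (or data frame with `aligned_seq`).
#' @return A single consensus string of length [alignment_length()].
#' @export
consensus <- function(clones) {
  if (nrow(clones) == 0L) abort("empty clone set", class = "clonevar_empty_input")
  m <- seq_matrix(clones$aligned_seq)
  paste(apply(m, 2L, column_consensus), collapse = "")
}

#' GC content of a sequence, in percent
#'
#' Gaps and `N` are excluded from both numerator and denominator.
#'
#' @param seq A single sequence string.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' gc_content("AC-GT")  # 50
gc_content <- function(seq) {
  chars <- seq_chars(seq)
  chars <- chars[chars %in% c("A", "C", "G", "T")]
  if (length(chars) == 0L) {
    abort("sequence has no unambiguous bases", class = "clonevar_empty_input")
  }
  100 * sum(chars %in% c("G", "C")) / length(chars)
}
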