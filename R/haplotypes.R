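#' Find variable alignment columns
#'
#' A column is variable when it carries at least two distinct states among
#' `A`,`C`,`G`,`T`,`-`; a gap is an ordinary state, `N` is ignored.
#'
#' @param clones A [clone_tbl()].
#' @return A list with `sites` (1-based column indices) and
#'   `variable_site_pct`, the percentage of variable columns truncated to one
#'   decimal as in all reported percentages.
#' @export
find_variable_sites <- function(clones) {
  if (nrow(clones) < 2L) {
    abort("need at least 2 clones to assess variability",
          class = "clonevar_insufficient_data")
  }
  m <- seq_matrix(clones$aligned_seq)
  variable <- apply(m, 2L, function(col) {
    length(unique(col[col != "N"])) >= 2L
  })
  sites <- which(variable)
  list(sites = sites,
       variable_site_pct = trunc1(100 * length(sites) / ncol(m)))
}

#' Filter single-unique ("singleton") mutations
#'
#' Character states observed at a site in only one clone of the pool are the
#' signature expected of random polymerase error; this filter removes them
#' before haplotype collapsing. Two readings are supported:
#'
#' * `"column_mask"` (default): at each column, a state carried by exactly one
#'   clone is replaced by that column's consensus state. After masking, every
#'   remaining column state occurs zero or at least two times.
#' * `"clone_merge"`: a clone that differs from some other clone at exactly one
#'   column, where its state at that column is unique in the pool, is rewritten
#'   to match that clone. Single-clone haplotypes carrying one unique mutation
#'   are thereby merged into their neighbour instead of being edited per column.
#' * `"off"`: identity.
#'
#' Filtering scope is always the whole pool (all individuals of the
#' species-by-gene clone set), matching how the rule is applied during a
#' dataset-wide alignment.
#'
#' @param clones A [clone_tbl()].
#' @param mode One of `"column_mask"`, `"clone_merge"`, `"off"`.
#' @return A [clone_tbl()] with filtered `aligned_seq`.
#' @export
filter_singletons <- function(clones, mode = c("column_mask", "clone_merge", "off")) {
  mode <- match.arg(mode)
  if (mode == "off") return(clones)
  if (nrow(clones) < 2L) {
    abort("need at least 2 clones to filter singletons",
          class = "clonevar_insufficient_data")
  }
  m <- seq_matrix(clones$aligned_seq)

  if (mode == "column_mask") {
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      obs <- col[col != "N"]
      if (length(unique(obs)) < 2L) next
      counts <- table(obs)
      single_states <- names(counts)[counts == 1L]
      if (length(single_states) == 0L) next
      cons <- column_consensus(col)
      m[col %in% single_states, j] <- cons
    }
  } else {  # clone_merge
    n <- nrow(m)
    seqs0 <- collapse_chars(m)
    seq_freq <- table(seqs0)
    # per-column state counts over the original pool
    new_seqs <- seqs0
    for (i in seq_len(n)) {
      best <- NULL
      for (j in seq_len(n)[-i]) {
        ok <- m[i, ] != "N" & m[j, ] != "N"
        diffs <- which(ok & m[i, ] != m[j, ])
        if (length(diffs) != 1L) next
        col <- m[, diffs]
        state <- m[i, diffs]
        if (sum(col == state) != 1L) next  # state must be unique in the pool
        cand <- seqs0[j]
        if (is.null(best) ||
            seq_freq[cand] > seq_freq[best] ||
            (seq_freq[cand] == seq_freq[best] && cand < best)) {
          best <- cand
        }
      }
      if (!is.null(best)) new_seqs[i] <- best
    }
    m <- seq_matrix(new_seqs)
  }

  out <- as_tibble(clones)
  out$aligned_seq <- collapse_chars(m)
  restore_clone_tbl(out, clones)
}

#' Collapse clones into paralogous haplotypes
#'
#' Partitions the clone set by exact aligned-sequence identity. Haplotypes are
#' numbered `H1..Hk` in descending total count, ties broken by lexicographic
#' sequence order, so numbering is invariant under record order.
#'
#' @param clones A [clone_tbl()], typically after [filter_singletons()].
#' @return A `haplotype_tbl`: a tibble with one row per haplotype (`hap_id`,
#'   `sequence`, `total_count`, `n_individuals`, `shared`, `freq_pct`) and a
#'   long per-individual count table in `attr(, "counts")`. Summary scalars are
#'   available via [glance()].
#' @export
collapse_haplotypes <- function(clones) {
  if (nrow(clones) == 0L) abort("empty clone set", class = "clonevar_empty_input")
  df <- as_tibble(clones)
  hap <- df |>
    group_by(sequence = .data$aligned_seq) |>
    summarise(total_count = n(),
              member_clone_ids = list(.data$clone_id),
              n_individuals = length(unique(.data$individual_id)),
              .groups = "drop") |>
    arrange(desc(.data$total_count), .data$sequence) |>
    mutate(hap_id = paste0("H", dplyr::row_number()),
           shared = .data$n_individuals >= 2L,
           freq_pct = trunc1(100 * .data$total_count / nrow(df))) |>
    select("hap_id", "sequence", "total_count", "n_individuals",
           "shared", "freq_pct", "member_clone_ids")

  counts <- df |>
    left_join(hap[c("hap_id", "sequence")],
              by = c(aligned_seq = "sequence")) |>
    group_by(hap_id = .data$hap_id, individual_id = .data$individual_id) |>
    summarise(n = n(), .groups = "drop")

  nvs <- if (nrow(df) >= 2L) find_variable_sites(clones) else
    list(sites = integer(0), variable_site_pct = 0)

  structure(hap,
            counts = counts,
            n_clones = nrow(df),
            species = df$species[1L],
            gene = df$gene[1L],
            alignment_length = alignment_length(clones),
            n_variable_sites = length(nvs$sites),
            variable_site_pct = nvs$variable_site_pct,
            clone_to_hap = setNames(
              hap$hap_id[match(df$aligned_seq, hap$sequence)], df$clone_id),
            class = c("haplotype_tbl", class(hap)))
}

#' @export
glance.haplotype_tbl <- function(x, ...) {
  tibble(
    n_clones = attr(x, "n_clones"),
    n_haplotypes = nrow(x),
    n_singleton_haplotypes = sum(x$total_count == 1L),
    n_shared_haplotypes = sum(x$shared),
    n_variable_sites = attr(x, "n_variable_sites"),
    variable_site_pct = attr(x, "variable_site_pct"),
    dominant_freq_pct = trunc1(100 * max(x$total_count) / attr(x, "n_clones")),
    alignment_length = attr(x, "alignment_length"),
    species = attr(x, "species"),
    gene = attr(x, "gene")
  )
}

#' Dominant-haplotype frequency (single-pass sequencing likelihood proxy)
#'
#' The frequency of the most common haplotype estimates the probability that a
#' single-pass sequencing effort recovers the dominant sequence. Percentages
#' are truncated to one decimal for reporting; full precision is kept in the
#' `freq_raw` column.
#'
#' @param x A `haplotype_tbl` from [collapse_haplotypes()].
#' @param scope `"pooled"` for the whole clone set or `"by_individual"`.
#' @return For `"pooled"`, a one-row tibble; for `"by_individual"`, one row per
#'   individual with a `tie` flag when the maximum count is not unique.
#' @export
dominant_likelihood <- function(x, scope = c("pooled", "by_individual")) {
  scope <- match.arg(scope)
  if (nrow(x) == 0L) abort("empty haplotype table", class = "clonevar_empty_input")
  if (scope == "pooled") {
    n <- attr(x, "n_clones")
    top <- max(x$total_count)
    return(tibble(scope = "pooled", n_clones = n,
                  dominant_hap = x$hap_id[which.max(x$total_count)],
                  freq_raw = 100 * top / n,
                  dominant_freq_pct = trunc1(100 * top / n),
                  tie = sum(x$total_count == top) > 1L))
  }
  counts <- attr(x, "counts")
  counts |>
    group_by(individual_id = .data$individual_id) |>
    summarise(n_clones = sum(.data$n),
              dominant_hap = .data$hap_id[which.max(.data$n)],
              freq_raw = 100 * max(.data$n) / sum(.data$n),
              tie = sum(.data$n == max(.data$n)) > 1L,
              .groups = "drop") |>
    mutate(dominant_freq_pct = trunc1(.data$freq_raw)) |>
    select("individual_id", "n_clones", "dominant_hap",
           "freq_raw", "dominant_freq_pct", "tie")
}

#' Per-individual and pooled clone-library summary
#'
#' Produces the standard library summary: one row per individual plus an
#' `"All clones"` row, giving clones sequenced, number of distinct haplotypes,
#' and the dominant-haplotype frequency. When `mode != "off"` the unfiltered
#' haplotype counts are reported alongside (`n_haplotypes_raw`), since summary
#' tables in the literature may be computed before or after singleton
#' filtering.
#'
#' @param clones A [clone_tbl()].
#' @param mode Singleton filter mode passed to [filter_singletons()].
#' @return A tibble with columns `individual_id`, `n_clones`, `n_haplotypes`,
#'   `dominant_freq_pct` (and `n_haplotypes_raw` when filtering is on).
#' @export
summarize_clone_library <- function(clones,
                                    mode = c("column_mask", "clone_merge", "off")) {
  mode <- match.arg(mode)
  filtered <- filter_singletons(clones, mode = mode)
  ht <- collapse_haplotypes(filtered)
  by_ind <- dominant_likelihood(ht, "by_individual")
  counts <- attr(ht, "counts")

  per_ind <- counts |>
    group_by(individual_id = .data$individual_id) |>
    summarise(n_clones = sum(.data$n),
              n_haplotypes = dplyr::n_distinct(.data$hap_id),
              .groups = "drop") |>
    left_join(by_ind[c("individual_id", "dominant_freq_pct")],
              by = "individual_id")

  pooled <- tibble(individual_id = "All clones",
                   n_clones = attr(ht, "n_clones"),
                   n_haplotypes = nrow(ht),
                   dominant_freq_pct = glance(ht)$dominant_freq_pct)
  out <- bind_rows(arrange(per_ind, .data$individual_id), pooled)

  if (mode != "off") {
    ht_raw <- collapse_haplotypes(clones)
    raw_counts <- attr(ht_raw, "counts") |>
      group_by(individual_id = .data$individual_id) |>
      summarise(n_haplotypes_raw = dplyr::n_distinct(.data$hap_id), .groups = "drop")
    raw_counts <- bind_rows(raw_counts,
                            tibble(individual_id = "All clones",
                                   n_haplotypes_raw = nrow(ht_raw)))
    out <- left_join(out, raw_counts, by = "individual_id")
  }
  out
}

#' Reconstruct a pooled dominant frequency from per-individual summary rows
#'
#' Given per-individual clone counts and dominant-haplotype percentages
#' (truncated to one decimal, as printed in summary tables), recovers the
#' integer per-individual dominant counts and, under the assumption that the
#' dominant haplotype is shared by all individuals, the pooled dominant
#' frequency.
#'
#' @param n_clones Integer vector of clones sequenced per individual.
#' @param dominant_freq_pct Per-individual dominant frequencies in percent.
#' @return A list with `counts` (recovered integer dominant counts) and
#'   `pooled_pct` (truncated to one decimal).
#' @export
#' @examples
#' pool_dominant_frequency(c(33, 44, 24, 31), c(90.9, 77.2, 87.5, 87.0))
pool_dominant_frequency <- function(n_clones, dominant_freq_pct) {
  stopifnot(length(n_clones) == length(dominant_freq_pct))
  counts <- round(dominant_freq_pct * n_clones / 100)
  # sanity: the recovered count must reproduce the printed truncated percentage
  ok <- trunc1(100 * counts / n_clones) == dominant_freq_pct
  if (!all(ok)) {
    warn(paste0("recovered count inconsistent with printed percentage for row(s) ",
                paste(which(!ok), collapse = ", ")))
  }
  list(counts = as.integer(counts),
       pooled_pct = trunc1(100 * sum(counts) / sum(n_clones)))
}
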