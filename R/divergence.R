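#' Gap-aware p-distance between two aligned sequences
#'
#' Uncorrected proportion of differing aligned positions. Under
#' `gap_mode = "fifth_state"` (default) the gap character `-` is an ordinary
#' fifth state: every gapped column counts independently regardless of indel
#' length, and a gap aligned to a gap is a match that stays in the
#' denominator. Under `"pairwise_delete"` columns where either sequence is
#' gapped are dropped. Columns where either sequence is `N` are always
#' excluded from numerator and denominator.
#'
#' @param a,b Aligned sequences of equal length.
#' @param gap_mode `"fifth_state"` or `"pairwise_delete"`.
#' @return Proportion in `[0, 1]`.
#' @export
#' @examples
#' p_distance("AC-T", "ACGT")   # 0.25
#' p_distance("A--T", "AGGT")   # 0.5: a 2-column gap counts twice
p_distance <- function(a, b, gap_mode = c("fifth_state", "pairwise_delete")) {
  gap_mode <- match.arg(gap_mode)
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  if (length(ca) != length(cb)) {
    abort("sequences must have equal aligned length",
          class = "clonevar_alignment_error")
  }
  valid <- ca != "N" & cb != "N"
  if (gap_mode == "pairwise_delete") valid <- valid & ca != "-" & cb != "-"
  denom <- sum(valid)
  if (denom == 0L) abort("no comparable columns", class = "clonevar_empty_input")
  sum(ca[valid] != cb[valid]) / denom
}

# integer-encoded pairwise distance matrix over a character vector of
# sequences; same semantics as p_distance()
pdist_matrix_seqs <- function(seqs, gap_mode = "fifth_state") {
  m <- seq_matrix(seqs)
  n <- nrow(m)
  isN <- m == "N"
  isgap <- m == "-"
  D <- matrix(0, n, n)
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      valid <- !isN[i, ] & !isN[j, ]
      if (gap_mode == "pairwise_delete") valid <- valid & !isgap[i, ] & !isgap[j, ]
      denom <- sum(valid)
      D[i, j] <- D[j, i] <-
        if (denom == 0L) NA_real_ else sum(m[i, valid] != m[j, valid]) / denom
    }
  }
  D
}

#' Pairwise distance matrix for a clone set
#'
#' @param clones A [clone_tbl()].
#' @param gap_mode Passed to [p_distance()].
#' @param unit `"unique_haplotypes"` (rows are the distinct haplotypes of the
#'   pool, labelled `H1..Hk`) or `"all_clones"` (rows are clones, labelled by
#'   `clone_id` in input order).
#' @return A symmetric numeric matrix with zero diagonal and labelled dimnames.
#' @seealso [write_phylip_dist()]
#' @export
distance_matrix <- function(clones,
                            gap_mode = c("fifth_state", "pairwise_delete"),
                            unit = c("unique_haplotypes", "all_clones")) {
  gap_mode <- match.arg(gap_mode)
  unit <- match.arg(unit)
  if (nrow(clones) < 2L) {
    abort("need at least 2 sequences", class = "clonevar_insufficient_data")
  }
  if (unit == "unique_haplotypes") {
    ht <- collapse_haplotypes(clones)
    seqs <- ht$sequence
    labels <- ht$hap_id
  } else {
    seqs <- clones$aligned_seq
    labels <- clones$clone_id
  }
  D <- pdist_matrix_seqs(seqs, gap_mode)
  dimnames(D) <- list(labels, labels)
  D
}

#' Write a square distance matrix in PHYLIP format
#'
#' Relaxed PHYLIP: the taxon count on the first line, then one row per taxon
#' with its label followed by whitespace-separated distances.
#'
#' @param D Symmetric matrix with dimnames, e.g. from [distance_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(D, path) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  labels <- rownames(D) %||% paste0("U", seq_len(nrow(D)))
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i) {
               paste(c(labels[i], sprintf("%.6f", D[i, ])), collapse = "  ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Partition divergence into intragenomic and intergenomic components
#'
#' Computes per-pair p-distances and splits them into intragenomic variation
#' (pairs of units within one individual) and intergenomic variation (pairs of
#' units from different individuals of the same species). By default the unit
#' of comparison is the unique haplotype within each individual; set
#' `unit = "all_clones"` to use every clone (a sensitivity analysis that
#' upweights dominant haplotypes).
#'
#' Grand means and standard errors are taken over the pooled per-pair value
#' lists (`SE = sd / sqrt(n_pairs)`); pair counts are recorded so alternative
#' conventions can be audited. An individual with a single unique unit
#' contributes no intragenomic pairs; its intragenomic mean is 0 and flagged
#' degenerate. The exceedance percentage is the fraction, over all ordered
#' (individual `i`, individual pair `ij`) comparisons (`n * (n - 1)` of them),
#' where the intragenomic mean of `i` strictly exceeds the intergenomic mean
#' of `ij`.
#'
#' @inheritParams distance_matrix
#' @return A `divergence_summary` object; see [tidy()] / [glance()] methods.
#' @export
partition_divergence <- function(clones,
                                 gap_mode = c("fifth_state", "pairwise_delete"),
                                 unit = c("unique_haplotypes", "all_clones")) {
  gap_mode <- match.arg(gap_mode)
  unit <- match.arg(unit)
  inds <- unique(clones$individual_id)
  if (length(inds) < 2L) {
    abort("need at least 2 individuals to partition divergence",
          class = "clonevar_insufficient_data")
  }
  ht <- collapse_haplotypes(clones)
  hap_idx <- match(attr(ht, "clone_to_hap")[clones$clone_id], ht$hap_id)
  D <- pdist_matrix_seqs(ht$sequence, gap_mode)
  parts <- divergence_parts(hap_idx, clones$individual_id, D, unit)

  sex_by_ind <- clones |>
    as_tibble() |>
    dplyr::distinct(.data$individual_id, .data$sex)

  intra_tbl <- tibble(
    individual_id = names(parts$intra_by_ind),
    mean_pct = unname(100 * vapply(parts$intra_by_ind, function(p) {
      if (length(p) == 0L) 0 else mean(p)
    }, numeric(1))),
    n_pairs = lengths(parts$intra_by_ind),
    degenerate = lengths(parts$intra_by_ind) == 0L
  ) |>
    left_join(sex_by_ind, by = "individual_id")

  inter_tbl <- parts$inter_pairs |>
    mutate(mean_pct = 100 * .data$mean_raw) |>
    select("individual_i", "individual_j", "mean_pct", "n_pairs")

  # ordered (individual, pair) exceedance: intra_i > inter_ij, strictly
  exceed <- 0L
  total <- 0L
  intra_means <- setNames(intra_tbl$mean_pct, intra_tbl$individual_id)
  for (k in seq_len(nrow(inter_tbl))) {
    i <- inter_tbl$individual_i[k]
    j <- inter_tbl$individual_j[k]
    exceed <- exceed + (intra_means[[i]] > inter_tbl$mean_pct[k]) +
      (intra_means[[j]] > inter_tbl$mean_pct[k])
    total <- total + 2L
  }

  se <- function(v) if (length(v) >= 2L) sd(v) / sqrt(length(v)) else NA_real_
  structure(
    list(intra = intra_tbl,
         inter = inter_tbl,
         intra_values = parts$intra_values,
         inter_values = parts$inter_values,
         exceedance_pct = trunc1(100 * exceed / total),
         n_exceed = exceed, n_comparisons = total,
         gap_mode = gap_mode, unit = unit,
         species = attr(ht, "species"), gene = attr(ht, "gene")),
    class = "divergence_summary"
  )
}

# grand intra/inter means only, without building tibbles: the hot path of
# the label-permutation null
grand_means <- function(hap_idx, individual_id, D, unit) {
  inds <- unique(individual_id)
  units <- lapply(inds, function(i) {
    u <- hap_idx[individual_id == i]
    if (unit == "unique_haplotypes") unique(u) else u
  })
  intra_sum <- 0; intra_n <- 0L
  for (u in units) {
    if (length(u) < 2L) next
    pr <- combn(seq_along(u), 2L)
    v <- D[cbind(u[pr[1L, ]], u[pr[2L, ]])]
    intra_sum <- intra_sum + sum(v); intra_n <- intra_n + length(v)
  }
  inter_sum <- 0; inter_n <- 0L
  n_ind <- length(units)
  for (i in seq_len(n_ind - 1L)) {
    for (j in (i + 1L):n_ind) {
      v <- D[cbind(rep(units[[i]], times = length(units[[j]])),
                   rep(units[[j]], each = length(units[[i]])))]
      inter_sum <- inter_sum + sum(v); inter_n <- inter_n + length(v)
    }
  }
  c(intra = if (intra_n) intra_sum / intra_n else 0,
    inter = if (inter_n) inter_sum / inter_n else 0)
}

# pooled per-pair distance values, given hap index per clone and a hap-level
# distance matrix; shared with the permutation machinery
divergence_parts <- function(hap_idx, individual_id, D, unit) {
  inds <- unique(individual_id)
  units <- lapply(inds, function(i) {
    u <- hap_idx[individual_id == i]
    if (unit == "unique_haplotypes") unique(u) else u
  })
  names(units) <- inds

  intra_by_ind <- lapply(units, function(u) {
    if (length(u) < 2L) return(numeric(0))
    pr <- combn(seq_along(u), 2L)
    D[cbind(u[pr[1L, ]], u[pr[2L, ]])]
  })

  inter_rows <- list()
  inter_values <- numeric(0)
  if (length(inds) >= 2L) {
    combs <- combn(length(inds), 2L)
    inter_rows <- lapply(seq_len(ncol(combs)), function(k) {
      ui <- units[[combs[1L, k]]]
      uj <- units[[combs[2L, k]]]
      vals <- D[cbind(rep(ui, times = length(uj)), rep(uj, each = length(ui)))]
      tibble(individual_i = inds[combs[1L, k]],
             individual_j = inds[combs[2L, k]],
             mean_raw = mean(vals), n_pairs = length(vals),
             values = list(vals))
    })
  }
  inter_pairs <- bind_rows(inter_rows)
  list(intra_by_ind = intra_by_ind,
       intra_values = unlist(intra_by_ind, use.names = FALSE),
       inter_pairs = inter_pairs,
       inter_values = unlist(inter_pairs$values, use.names = FALSE))
}

#' @export
print.divergence_summary <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Divergence summary (%s, %s; gaps: %s, unit: %s)\n",
              x$species %||% "?", x$gene %||% "?", x$gap_mode, x$unit))
  cat(sprintf("  intragenomic: %.2f%% +/- %.2f (n pairs = %d)\n",
              g$intra_mean_pct, g$intra_se_pct, g$intra_n_pairs))
  cat(sprintf("  intergenomic: %.2f%% +/- %.2f (n pairs = %d)\n",
              g$inter_mean_pct, g$inter_se_pct, g$inter_n_pairs))
  cat(sprintf("  intra > inter in %.1f%% of %d individual comparisons\n",
              x$exceedance_pct, x$n_comparisons))
  invisible(x)
}

#' @export
tidy.divergence_summary <- function(x, ...) {
  bind_rows(
    x$intra |>
      mutate(type = "intragenomic", unit_i = .data$individual_id,
             unit_j = .data$individual_id) |>
      select("type", "unit_i", "unit_j", "mean_pct", "n_pairs"),
    x$inter |>
      mutate(type = "intergenomic", unit_i = .data$individual_i,
             unit_j = .data$individual_j) |>
      select("type", "unit_i", "unit_j", "mean_pct", "n_pairs")
  )
}

#' @export
glance.divergence_summary <- function(x, ...) {
  se <- function(v) if (length(v) >= 2L) 100 * sd(v) / sqrt(length(v)) else NA_real_
  tibble(
    intra_mean_pct = if (length(x$intra_values)) 100 * mean(x$intra_values) else 0,
    intra_se_pct = se(x$intra_values),
    intra_n_pairs = length(x$intra_values),
    inter_mean_pct = if (length(x$inter_values)) 100 * mean(x$inter_values) else 0,
    inter_se_pct = se(x$inter_values),
    inter_n_pairs = length(x$inter_values),
    exceedance_pct = x$exceedance_pct,
    n_individuals = nrow(x$intra),
    gap_mode = x$gap_mode, unit = x$unit
  )
}
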