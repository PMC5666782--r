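new_perm_result <- function(statistic_name, observed, p_value, mode, n_used,
                            seed = NA_integer_, ...) {
  structure(list(statistic_name = statistic_name, observed = observed,
                 p_value = p_value, mode = mode, n_used = n_used,
                 seed = seed, ...),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation test: %s\n", x$statistic_name))
  cat(sprintf("  observed = %.4g, p = %.4g (%s, n = %d)\n",
              x$observed, x$p_value, x$mode, x$n_used))
  if (!is.null(x$degenerate) && isTRUE(x$degenerate)) {
    cat("  note: degenerate data (no variation); p fixed at 1\n")
  }
  if (!is.null(x$min_attainable_p)) {
    cat(sprintf("  minimum attainable p for this design: %.4g\n",
                x$min_attainable_p))
  }
  invisible(x)
}

#' @export
tidy.perm_result <- function(x, ...) {
  tibble(statistic_name = x$statistic_name, observed = x$observed,
         p.value = x$p_value, mode = x$mode, n_used = x$n_used,
         seed = x$seed)
}

#' @export
glance.perm_result <- function(x, ...) tidy(x)

# two-sided comparison with a floating-point guard so exact ties (including
# the identity permutation) always count
count_extreme <- function(null_stats, observed) {
  sum(abs(null_stats) >= abs(observed) - 1e-12)
}

#' Permutation test for a difference of two group means
#'
#' Statistic: `mean(values_a) - mean(values_b)`, two-sided. When the number of
#' distinct group relabellings `choose(na + nb, na)` is at most
#' `exact_threshold`, all relabellings are enumerated and the exact p-value
#' `#( |stat| >= |observed| ) / total` is returned; otherwise a Monte-Carlo
#' test with the add-one rule `p = (b + 1) / (n_perm + 1)` is used (so `p > 0`
#' always).
#'
#' @param values_a,values_b Numeric vectors (each of length at least 2).
#' @param n_perm Monte-Carlo replicates (default 9999; minimum 99).
#' @param seed Integer seed for the Monte-Carlo mode (recorded in the result).
#' @param exact_threshold Largest enumeration size for exact mode.
#' @return A `perm_result`; see [tidy()].
#' @export
#' @examples
#' perm_test_two_groups(c(90.9, 77.2, 87.5, 87.0), c(21.7, 23.0, 33.3, 26.0))
perm_test_two_groups <- function(values_a, values_b, n_perm = 9999, seed = 1L,
                                 exact_threshold = 1e5) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    abort("each group needs at least 2 values", class = "clonevar_insufficient_data")
  }
  if (n_perm < 99) abort("n_perm must be at least 99", class = "clonevar_config_error")
  pool <- c(values_a, values_b)
  na <- length(values_a)
  n <- length(pool)
  observed <- mean(values_a) - mean(values_b)
  n_splits <- choose(n, na)

  if (n_splits <= exact_threshold) {
    idx <- combn(n, na)
    stats <- apply(idx, 2L, function(ii) mean(pool[ii]) - mean(pool[-ii]))
    p <- count_extreme(stats, observed) / n_splits
    new_perm_result("mean(a) - mean(b)", observed, p, "exact", as.integer(n_splits))
  } else {
    stats <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(k) {
        ii <- sample.int(n, na)
        mean(pool[ii]) - mean(pool[-ii])
      }, numeric(1))
    })
    p <- (count_extreme(stats, observed) + 1) / (n_perm + 1)
    new_perm_result("mean(a) - mean(b)", observed, p, "monte_carlo",
                    as.integer(n_perm), seed = seed)
  }
}

#' Permutation test: intergenomic vs intragenomic divergence
#'
#' Statistic: grand intergenomic mean minus grand intragenomic mean (in
#' percent), as computed by [partition_divergence()]. The null is built by
#' permuting the clone-to-individual assignment (preserving each individual's
#' clone count) and recomputing both grand means — the natural exchangeability
#' null for "does individual identity structure the clones". Monte-Carlo only,
#' add-one p-value rule.
#'
#' @param clones A [clone_tbl()] with at least 2 individuals.
#' @inheritParams perm_test_two_groups
#' @inheritParams partition_divergence
#' @return A `perm_result`; for fully identical clone sets, `p = 1` with a
#'   `degenerate` flag.
#' @export
perm_test_intra_vs_inter <- function(clones, n_perm = 999, seed = 1L,
                                     gap_mode = c("fifth_state", "pairwise_delete"),
                                     unit = c("unique_haplotypes", "all_clones")) {
  gap_mode <- match.arg(gap_mode)
  unit <- match.arg(unit)
  if (length(unique(clones$individual_id)) < 2L) {
    abort("need at least 2 individuals", class = "clonevar_insufficient_data")
  }
  if (n_perm < 99) abort("n_perm must be at least 99", class = "clonevar_config_error")
  ht <- collapse_haplotypes(clones)
  if (nrow(ht) == 1L) {
    return(new_perm_result("inter_mean - intra_mean (%)", 0, 1, "monte_carlo",
                           0L, seed = seed, degenerate = TRUE))
  }
  hap_idx <- match(attr(ht, "clone_to_hap")[clones$clone_id], ht$hap_id)
  D <- pdist_matrix_seqs(ht$sequence, gap_mode)
  ind <- clones$individual_id

  stat_fun <- function(ind_labels) {
    gm <- grand_means(hap_idx, ind_labels, D, unit)
    100 * (gm[["inter"]] - gm[["intra"]])
  }
  observed <- stat_fun(ind)
  null_stats <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(k) stat_fun(sample(ind)), numeric(1))
  })
  p <- (count_extreme(null_stats, observed) + 1) / (n_perm + 1)
  new_perm_result("inter_mean - intra_mean (%)", observed, p, "monte_carlo",
                  as.integer(n_perm), seed = seed,
                  null_mean = mean(null_stats), null_sd = sd(null_stats))
}

#' Exact permutation test for sex differences in intragenomic variation
#'
#' Statistic: mean female intragenomic divergence minus mean male intragenomic
#' divergence, with individuals as the exchangeable units. All assignments of
#' the sex labels to individuals (preserving the female/male counts) are
#' enumerated — `choose(4, 2) = 6` for the standard 2 + 2 design — so the test
#' is exact but coarse: the minimum attainable two-sided p is reported
#' alongside as a design caveat.
#'
#' @param intra_by_individual Named numeric vector of per-individual
#'   intragenomic means (e.g. from `partition_divergence()$intra`).
#' @param sexes Named character vector (`"F"`/`"M"`) over the same individuals.
#' @return A `perm_result` with extra field `min_attainable_p`.
#' @export
perm_test_sex <- function(intra_by_individual, sexes) {
  ids <- names(intra_by_individual)
  if (is.null(ids) || is.null(names(sexes))) {
    abort("both inputs must be named by individual_id", class = "clonevar_format_error")
  }
  sexes <- sexes[ids]
  if (!all(c("F", "M") %in% sexes)) {
    abort("need at least one individual of each sex",
          class = "clonevar_insufficient_data")
  }
  vals <- as.numeric(intra_by_individual)
  nF <- sum(sexes == "F")
  n <- length(vals)
  idx <- combn(n, nF)
  stats <- apply(idx, 2L, function(ii) mean(vals[ii]) - mean(vals[-ii]))
  observed <- mean(vals[sexes == "F"]) - mean(vals[sexes == "M"])
  total <- ncol(idx)
  p <- count_extreme(stats, observed) / total
  max_abs <- max(abs(stats))
  min_p <- sum(abs(stats) >= max_abs - 1e-12) / total
  new_perm_result("mean(F intra) - mean(M intra)", observed, p, "exact",
                  as.integer(total), min_attainable_p = min_p)
}
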