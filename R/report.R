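# run `expr`, relabelling any error with the pipeline stage that failed
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", stage, "': ", conditionMessage(e)),
          class = "clonevar_stage_error", parent = e)
  })
}

read_flat_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "clonevar_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) paste(x[-1L], collapse = "="))
  setNames(vals, vapply(kv, `[[`, character(1), 1L))
}

#' Run the clone-library analysis pipeline end to end
#'
#' Orchestrates singleton filtering, haplotype collapsing, divergence
#' partitioning, permutation tests and artifact screening, and (optionally)
#' writes the full report set. Input is either a simulator preset
#' (`preset_species` + `preset_gene`) or an aligned FASTA + metadata TSV
#' (`fasta`, `metadata`). `config` may be a named list or the path of a flat
#' `key=value` file. Recognised keys: `preset_species`, `preset_gene`,
#' `fasta`, `metadata`, `seed`, `out_dir`, `mode`, `unit`, `gap_mode`,
#' `n_perm`, `min_support`, `indel_threshold`.
#'
#' @param config Named list or path to a flat `key=value` config file.
#' @return A `report_bundle` list: `table1` (per-individual + pooled summary),
#'   `table2` (divergence glance), `divergence`, `tests` (perm results),
#'   `screen`, `haplotypes`, `clones`, and `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_flat_config(config)
  }
  cfg <- config
  seed <- as.integer(cfg$seed %||% 1L)
  mode <- cfg$mode %||% "column_mask"
  unit <- cfg$unit %||% "unique_haplotypes"
  gap_mode <- cfg$gap_mode %||% "fifth_state"
  n_perm <- as.integer(cfg$n_perm %||% 999L)
  min_support <- as.integer(cfg$min_support %||% 5L)
  indel_threshold <- as.integer(cfg$indel_threshold %||% 3L)

  sim <- NULL
  clones <- with_stage("input", {
    if (!is.null(cfg$preset_species)) {
      sc <- preset_paperlike(cfg$preset_species, cfg$preset_gene %||% "ITS2",
                             seed = seed)
      sim <- simulate_clone_library(sc)
      sim$clones
    } else if (!is.null(cfg$fasta)) {
      if (!file.exists(cfg$fasta)) {
        abort(paste0("FASTA not found: ", cfg$fasta), class = "clonevar_io_error")
      }
      read_clone_set(cfg$fasta, cfg$metadata)
    } else {
      abort("config must name either preset_species/preset_gene or fasta/metadata",
            class = "clonevar_config_error")
    }
  })

  filtered <- with_stage("filter", filter_singletons(clones, mode = mode))
  ht <- with_stage("collapse", collapse_haplotypes(filtered))
  table1 <- with_stage("collapse", summarize_clone_library(clones, mode = mode))
  div <- with_stage("divergence",
                    partition_divergence(filtered, gap_mode = gap_mode, unit = unit))

  tests <- with_stage("permtests", {
    intra_inter <- perm_test_intra_vs_inter(filtered, n_perm = n_perm,
                                            seed = seed + 1L,
                                            gap_mode = gap_mode, unit = unit)
    sexes <- setNames(div$intra$sex, div$intra$individual_id)
    sex_test <- if (all(c("F", "M") %in% sexes)) {
      perm_test_sex(setNames(div$intra$mean_pct, div$intra$individual_id), sexes)
    } else NULL
    list(intra_vs_inter = intra_inter, sex = sex_test)
  })

  screen <- with_stage("screen", {
    gene <- attr(ht, "gene")
    if (gene %in% c("mtCO1", "ITS2")) {
      screen_haplotypes(ht, min_support = min_support,
                        indel_threshold = indel_threshold)
    } else NULL
  })

  bundle <- structure(list(
    table1 = table1,
    table2 = glance(div),
    divergence = div,
    tests = tests,
    screen = screen,
    haplotypes = ht,
    clones = clones,
    truth = if (!is.null(sim)) sim$truth else NULL,
    provenance = list(seed = seed, mode = mode, unit = unit,
                      gap_mode = gap_mode, n_perm = n_perm,
                      min_support = min_support,
                      indel_threshold = indel_threshold,
                      species = attr(ht, "species"), gene = attr(ht, "gene"),
                      package_version = as.character(utils::packageVersion("clonevar")))
  ), class = "report_bundle")

  if (!is.null(cfg$out_dir)) {
    with_stage("report", write_report_bundle(bundle, cfg$out_dir))
  }
  bundle
}

#' Write a report bundle to disk
#'
#' Emits `table1.tsv`, `table2.tsv`, `screen.tsv`, `tests.jsonl` (one JSON
#' object per test) and `provenance.txt`. Regenerating from the same bundle
#' is byte-identical.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(bundle$table1, file.path(dir, "table1.tsv"), progress = FALSE)
  readr::write_tsv(bundle$table2, file.path(dir, "table2.tsv"), progress = FALSE)
  if (!is.null(bundle$screen)) {
    readr::write_tsv(bundle$screen, file.path(dir, "screen.tsv"), progress = FALSE)
  }
  tests <- Filter(Negate(is.null), bundle$tests)
  lines <- vapply(names(tests), function(nm) {
    t <- tests[[nm]]
    jsonlite::toJSON(list(test = nm, species = bundle$provenance$species,
                          gene = bundle$provenance$gene,
                          statistic = t$statistic_name, observed = t$observed,
                          p = t$p_value, mode = t$mode, n = t$n_used,
                          seed = t$seed),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, file.path(dir, "tests.jsonl"))
  prov <- bundle$provenance
  writeLines(paste0(names(prov), "=", vapply(prov, paste, character(1),
                                             collapse = ",")),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Clone-library report: %s %s\n",
              x$provenance$species, x$provenance$gene))
  cat("\nLibrary summary (per individual + pooled):\n")
  print(x$table1)
  cat("\nDivergence partition:\n")
  print(x$divergence)
  if (!is.null(x$tests$intra_vs_inter)) {
    cat("\n"); print(x$tests$intra_vs_inter)
  }
  if (!is.null(x$tests$sex)) {
    cat("\n"); print(x$tests$sex)
  }
  invisible(x)
}

#' Fold ratio of mean dominant-haplotype frequencies between two genes
#'
#' Given two per-individual library summaries (from
#' [summarize_clone_library()] or the bundled reference summary), returns the
#' ratio of the per-individual mean dominant frequencies, gene A over gene B —
#' the "how much more likely is single-pass sequencing to recover the dominant
#' haplotype" comparison.
#'
#' @param table1_gene_a,table1_gene_b Tibbles with `individual_id` and
#'   `dominant_freq_pct`; any `"All clones"` row is ignored. Both must cover
#'   the same individuals.
#' @return A single fold ratio.
#' @export
dominant_ratio <- function(table1_gene_a, table1_gene_b) {
  a <- filter(table1_gene_a, .data$individual_id != "All clones")
  b <- filter(table1_gene_b, .data$individual_id != "All clones")
  if (!setequal(a$individual_id, b$individual_id)) {
    abort("the two summaries must cover the same individuals",
          class = "clonevar_join_error")
  }
  mean(a$dominant_freq_pct) / mean(b$dominant_freq_pct)
}

#' Bundled reference clone-library summary for three pest thrips
#'
#' Per-individual clone-library summary rows (clones sequenced, distinct
#' haplotypes, dominant-haplotype frequency in percent, truncated to one
#' decimal) for mtCO1 and ITS2 libraries of *Scirtothrips dorsalis* (SD),
#' *Thrips palmi* (TP) and *Frankliniella occidentalis* (FO); individuals 1-2
#' are female, 3-4 male. Used in the worked examples and as input to
#' [pool_dominant_frequency()] and [dominant_ratio()].
#'
#' @return A tibble with columns `species`, `gene`, `individual_id`, `sex`,
#'   `n_clones`, `n_haplotypes`, `dominant_freq_pct`.
#' @export
thrips_clone_summary <- function() {
  path <- system.file("extdata", "thrips_clone_summary.tsv",
                      package = "clonevar", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cccciid", progress = FALSE)
}

#' Numt screening performance against simulator truth
#'
#' Applies the Taq-error singleton guard, collapses a simulated mtCO1
#' library, screens it, and scores the `numt_suspect` calls against the truth
#' table: a haplotype's true class is `numt` when the majority of its member
#' clones derive from a numt template. The default guard is
#' `mode = "column_mask"`: polymerase-error states — including the occasional
#' error that spuriously creates a stop codon — are single-unique in the pool
#' and get reverted to the column consensus, while numt states recur across
#' the clones that co-amplified the shared numt and therefore survive.
#'
#' @param sim A `clone_sim` from [simulate_clone_library()] (gene mtCO1).
#' @param min_support Passed to [screen_haplotypes()].
#' @param mode Singleton filter applied before collapsing.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
numt_screen_performance <- function(sim, min_support = 5L,
                                    mode = c("column_mask", "clone_merge", "off")) {
  stopifnot(inherits(sim, "clone_sim"))
  mode <- match.arg(mode)
  ht <- collapse_haplotypes(filter_singletons(sim$clones, mode = mode))
  flags <- screen_haplotypes(ht, min_support = min_support)
  clone_hap <- attr(ht, "clone_to_hap")
  truth_by_hap <- sim$truth |>
    mutate(hap_id = clone_hap[.data$clone_id]) |>
    group_by(hap_id = .data$hap_id) |>
    summarise(is_numt = mean(.data$template_class == "numt") > 0.5,
              .groups = "drop")
  joined <- left_join(flags, truth_by_hap, by = "hap_id")
  pred <- joined$classification == "numt_suspect"
  truth <- joined$is_numt
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tibble(tp = tp, fp = fp, fn = fn,
         precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
         recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn))
}
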