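#' Configure a cloned amplicon library simulation
#'
#' Builds the parameter set for [simulate_clone_library()]. The simulator
#' emulates the data-generating mechanisms hypothesised for cloned marker
#' libraries: a multicopy rDNA (ITS2) array under tunable concerted evolution
#' in a haplodiploid species (females carry two arrays, males one), or a
#' mitochondrial (mtCO1) template pool with optional heteroplasmy and numts,
#' both overlaid with per-cycle polymerase error.
#'
#' @param seed Integer seed; every random choice derives from it.
#' @param species Species label used in identifiers (e.g. `"SD"`).
#' @param gene `"mtCO1"` or `"ITS2"`.
#' @param n_females,n_males Individuals per sex (default 2 + 2).
#' @param clones_per_individual Single count or a length-2 range sampled per
#'   individual.
#' @param seq_length Amplicon alignment length `L` (>= 100).
#' @param gc_target Expected GC proportion of the species master, in (0, 1).
#' @param copies_per_array rDNA copies per array (`C`; ITS2 only).
#' @param homogenization Concerted-evolution strength `h` in `[0, 1]`: the
#'   fraction of copies per array forced identical to the array master.
#' @param copy_snp_rate Expected substitutions per non-homogenised copy.
#' @param copy_indel_rate Expected indel events per non-homogenised copy
#'   (deletion runs of 1..`indel_max_len` columns).
#' @param indel_max_len Maximum indel length (default 5).
#' @param between_array_divergence Expected substitutions separating a
#'   female's two array masters (`d`).
#' @param individual_divergence Expected substitutions separating each
#'   individual's template lineage from the species master; 0 gives a single
#'   common template pool (the exchangeable null), larger values give
#'   individual-specific structure.
#' @param heteroplasmy_freq Proportion `f` of mitochondrial templates carrying
#'   the heteroplasmic variant (mtCO1 only).
#' @param heteroplasmy_divergence Substitutions separating the heteroplasmic
#'   variant from the functional template (kept stop-free).
#' @param n_numts Number of nuclear-mitochondrial pseudogene templates.
#' @param numt_divergence Substitutions separating each numt from the
#'   functional template.
#' @param numt_has_stop If `TRUE` every numt carries a guaranteed in-frame
#'   stop codon; if `FALSE` a frameshift deletion (1-2 columns) is injected
#'   instead, so numts are detectable either way.
#' @param numt_weight Relative amplification weight `w` of each numt template.
#' @param cycles PCR cycles (default 35).
#' @param error_rate Per-base per-cycle polymerase error `eps`, in
#'   `[0, 1e-4]`; the empirical Taq range is 1e-5..1e-4 and 0 is allowed for
#'   calibration runs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       species = "SIM",
                       gene = c("mtCO1", "ITS2"),
                       n_females = 2L, n_males = 2L,
                       clones_per_individual = c(16L, 46L),
                       seq_length = 655L,
                       gc_target = 0.35,
                       copies_per_array = 50L,
                       homogenization = 0.9,
                       copy_snp_rate = 1,
                       copy_indel_rate = 0.1,
                       indel_max_len = 5L,
                       between_array_divergence = 1,
                       individual_divergence = 0,
                       heteroplasmy_freq = 0,
                       heteroplasmy_divergence = 2L,
                       n_numts = 0L,
                       numt_divergence = 5L,
                       numt_has_stop = TRUE,
                       numt_weight = 0.05,
                       cycles = 35L,
                       error_rate = 1e-5) {
  gene <- match.arg(gene)
  if (seq_length < 100L) abort("seq_length must be >= 100", class = "clonevar_config_error")
  if (gc_target <= 0 || gc_target >= 1) {
    abort("gc_target must be strictly inside (0, 1)", class = "clonevar_config_error")
  }
  if (homogenization < 0 || homogenization > 1) {
    abort("homogenization must be in [0, 1]", class = "clonevar_config_error")
  }
  if (error_rate < 0 || error_rate > 1e-4) {
    abort("error_rate must be in [0, 1e-4]", class = "clonevar_config_error")
  }
  if (heteroplasmy_freq < 0 || heteroplasmy_freq >= 1) {
    abort("heteroplasmy_freq must be in [0, 1)", class = "clonevar_config_error")
  }
  if (heteroplasmy_freq + n_numts * numt_weight >= 1) {
    abort("heteroplasmy_freq + n_numts * numt_weight must be < 1 (the functional template needs positive weight)",
          class = "clonevar_config_error")
  }
  if (n_females + n_males < 1L) abort("need at least one individual", class = "clonevar_config_error")
  if (length(clones_per_individual) == 1L) {
    clones_per_individual <- rep(clones_per_individual, 2L)
  }
  structure(list(
    seed = as.integer(seed), species = species, gene = gene,
    n_females = as.integer(n_females), n_males = as.integer(n_males),
    clones_per_individual = as.integer(clones_per_individual),
    seq_length = as.integer(seq_length), gc_target = gc_target,
    copies_per_array = as.integer(copies_per_array),
    homogenization = homogenization, copy_snp_rate = copy_snp_rate,
    copy_indel_rate = copy_indel_rate, indel_max_len = as.integer(indel_max_len),
    between_array_divergence = between_array_divergence,
    individual_divergence = individual_divergence,
    heteroplasmy_freq = heteroplasmy_freq,
    heteroplasmy_divergence = as.integer(heteroplasmy_divergence),
    n_numts = as.integer(n_numts), numt_divergence = as.integer(numt_divergence),
    numt_has_stop = isTRUE(numt_has_stop), numt_weight = numt_weight,
    cycles = as.integer(cycles), error_rate = error_rate
  ), class = "sim_config")
}

#' Generate a random master sequence
#'
#' @param seq_length Length `L` (>= 100).
#' @param gc_target Expected GC proportion, strictly inside (0, 1).
#' @param seed Optional seed; when supplied the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @param coding If `TRUE`, the sequence is built codon-wise with stop codons
#'   (TAA/TAG under the invertebrate mitochondrial code) rejected in frame 0,
#'   yielding an open reading frame as for a functional mtCO1 fragment.
#' @return A sequence string of length `seq_length`.
#' @export
make_master <- function(seq_length, gc_target = 0.5, seed = NULL, coding = FALSE) {
  if (seq_length < 100L) abort("seq_length must be >= 100", class = "clonevar_config_error")
  if (gc_target <= 0 || gc_target >= 1) {
    abort("gc_target must be strictly inside (0, 1)", class = "clonevar_config_error")
  }
  draw <- function() {
    probs <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
               G = gc_target / 2, T = (1 - gc_target) / 2)
    if (!coding) {
      return(paste(sample(names(probs), seq_length, replace = TRUE, prob = probs),
                   collapse = ""))
    }
    n_codons <- seq_length %/% 3L
    codons <- character(n_codons)
    for (k in seq_len(n_codons)) {
      repeat {
        cd <- paste(sample(names(probs), 3L, replace = TRUE, prob = probs),
                    collapse = "")
        if (!cd %in% c("TAA", "TAG")) break
      }
      codons[k] <- cd
    }
    tail_len <- seq_length - 3L * n_codons
    tail <- if (tail_len > 0L) {
      paste(sample(names(probs), tail_len, replace = TRUE, prob = probs),
            collapse = "")
    } else ""
    paste0(paste(codons, collapse = ""), tail)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# -- internal mutation operators (operate on character vectors, use the
#    current RNG state) ------------------------------------------------------

substitute_bases <- function(chars, n) {
  if (n <= 0L) return(chars)
  pos <- which(chars %in% c("A", "C", "G", "T"))
  if (length(pos) == 0L) return(chars)
  n <- min(n, length(pos))
  hit <- sample(pos, n)
  for (p in hit) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  chars
}

# substitutions that keep frame-0 translation stop-free (functional mt
# templates and heteroplasmic variants)
substitute_stop_free <- function(chars, n, max_tries = 100L) {
  if (n <= 0L) return(chars)
  for (try in seq_len(max_tries)) {
    cand <- substitute_bases(chars, n)
    if (count_stops(paste(cand, collapse = ""), 0L) == 0L) return(cand)
  }
  warn("could not avoid stop codons while mutating; returning last candidate")
  cand
}

apply_deletion <- function(chars, len) {
  L <- length(chars)
  for (try in 1:20) {
    start <- sample.int(L - len + 1L, 1L)
    run <- start:(start + len - 1L)
    if (all(chars[run] != "-")) {
      chars[run] <- "-"
      return(chars)
    }
  }
  chars
}

inject_stop <- function(chars) {
  n_codons <- length(chars) %/% 3L
  k <- sample(2:(n_codons - 1L), 1L)  # internal codon
  chars[(3L * k - 2L):(3L * k)] <- c("T", "A", "A")
  chars
}

#' Build the weighted template pool of one individual
#'
#' For ITS2: one rDNA array for males, two for females, each of
#' `copies_per_array` copies; `ceiling(h * C)` copies are identical to the
#' array master and the remainder are mutated at the copy SNP/indel rates;
#' a female's array masters are separated by `between_array_divergence`
#' expected substitutions. For mtCO1: a functional template (weight
#' `1 - f - n_numts * w`), an optional heteroplasmic variant (weight `f`,
#' stop-free by construction), and `n_numts` numt templates (weight `w` each)
#' carrying a guaranteed in-frame stop or frameshift.
#'
#' Numts are germline insertions carried by the population, not per-individual
#' events: [simulate_clone_library()] draws them once from the species master
#' and passes them in via `shared_numts`, so every individual co-amplifies the
#' same numt templates. When `shared_numts` is `NULL` (standalone use) they
#' are generated on the spot.
#'
#' Uses the current RNG state; [simulate_clone_library()] seeds it from the
#' config.
#'
#' @param cfg A [sim_config()].
#' @param sex `"F"` or `"M"`.
#' @param master The species master sequence (for mtCO1, a coding master).
#' @param shared_numts Optional tibble of pre-built numt templates.
#' @return A tibble with `template_id`, `sequence`, `template_class`, `weight`.
#' @export
build_individual_templates <- function(cfg, sex, master, shared_numts = NULL) {
  mchars <- seq_chars(master)
  if (cfg$gene == "ITS2") {
    base <- substitute_bases(mchars, rpois(1L, cfg$individual_divergence))
    n_arrays <- if (sex == "F") 2L else 1L
    rows <- list()
    for (a in seq_len(n_arrays)) {
      amaster <- if (a == 1L) base else
        substitute_bases(base, rpois(1L, cfg$between_array_divergence))
      C <- cfg$copies_per_array
      n_hom <- ceiling(cfg$homogenization * C)
      for (cc in seq_len(C)) {
        copy <- amaster
        if (cc > n_hom) {
          copy <- substitute_bases(copy, rpois(1L, cfg$copy_snp_rate))
          n_indels <- rpois(1L, cfg$copy_indel_rate)
          if (n_indels > 0L) {
            for (e in seq_len(n_indels)) {
              copy <- apply_deletion(copy, sample.int(cfg$indel_max_len, 1L))
            }
          }
        }
        rows[[length(rows) + 1L]] <- tibble(
          template_id = sprintf("A%d.C%02d", a, cc),
          sequence = paste(copy, collapse = ""),
          template_class = "rdna_copy", weight = 1)
      }
    }
    return(bind_rows(rows))
  }

  # mtCO1 branch
  func <- substitute_stop_free(mchars, rpois(1L, cfg$individual_divergence))
  w_func <- 1 - cfg$heteroplasmy_freq - cfg$n_numts * cfg$numt_weight
  rows <- list(tibble(template_id = "mt.func",
                      sequence = paste(func, collapse = ""),
                      template_class = "mt_functional", weight = w_func))
  if (cfg$heteroplasmy_freq > 0) {
    het <- substitute_stop_free(func, cfg$heteroplasmy_divergence)
    rows[[length(rows) + 1L]] <- tibble(
      template_id = "mt.het", sequence = paste(het, collapse = ""),
      template_class = "mt_heteroplasmic", weight = cfg$heteroplasmy_freq)
  }
  if (cfg$n_numts > 0L) {
    numts <- shared_numts %||% build_numt_templates(cfg, mchars)
    rows[[length(rows) + 1L]] <- numts
  }
  bind_rows(rows)
}

# species-level numt templates, derived from the species master
build_numt_templates <- function(cfg, master_chars) {
  rows <- lapply(seq_len(cfg$n_numts), function(k) {
    numt <- substitute_bases(master_chars, cfg$numt_divergence)
    numt <- if (cfg$numt_has_stop) inject_stop(numt) else
      apply_deletion(numt, sample(1:2, 1L))
    tibble(template_id = sprintf("numt%d", k),
           sequence = paste(numt, collapse = ""),
           template_class = "numt", weight = cfg$numt_weight)
  })
  bind_rows(rows)
}

#' Amplify and clone from a template pool
#'
#' Each clone samples one template with probability proportional to its
#' weight, then acquires substitutions independently at each non-gap site
#' with the endpoint probability `q = 1 - (1 - error_rate)^cycles`, the
#' expected per-site error load of the full amplification. Indels arise only
#' in template construction, so the emitted clones remain a true alignment.
#'
#' Uses the current RNG state; [simulate_clone_library()] seeds it.
#'
#' @param templates Template pool from [build_individual_templates()].
#' @param cfg A [sim_config()].
#' @param n_clones Number of clones to draw.
#' @param clone_prefix Prefix for clone identifiers.
#' @return A list with `sequences`, and per-clone truth columns
#'   (`template_id`, `template_class`, `n_pcr_errors`, `error_positions`).
#' @export
pcr_and_clone <- function(templates, cfg, n_clones, clone_prefix = "c") {
  if (nrow(templates) == 0L) abort("empty template pool", class = "clonevar_empty_input")
  q <- 1 - (1 - cfg$error_rate)^cfg$cycles
  pick <- sample.int(nrow(templates), n_clones, replace = TRUE,
                     prob = templates$weight)
  seqs <- character(n_clones)
  n_err <- integer(n_clones)
  err_pos <- vector("list", n_clones)
  for (k in seq_len(n_clones)) {
    chars <- seq_chars(templates$sequence[pick[k]])
    errs <- integer(0)
    if (q > 0) {
      base_pos <- which(chars != "-")
      hit <- base_pos[stats::runif(length(base_pos)) < q]
      for (p in hit) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
      errs <- hit
    }
    seqs[k] <- paste(chars, collapse = "")
    n_err[k] <- length(errs)
    err_pos[[k]] <- errs
  }
  list(clone_id = sprintf("%s%03d", clone_prefix, seq_len(n_clones)),
       sequences = seqs,
       template_id = templates$template_id[pick],
       template_class = templates$template_class[pick],
       n_pcr_errors = n_err, error_positions = err_pos)
}

#' Simulate a full cloned amplicon library with ground truth
#'
#' Draws the species master, builds each individual's template pool (females
#' first), amplifies and clones, and returns both the [clone_tbl()] and a
#' truth table recording, for every clone, its template of origin, template
#' class, and the injected PCR errors.
#'
#' @param cfg A [sim_config()].
#' @return A `clone_sim` list with elements `clones` (a [clone_tbl()]),
#'   `truth` (tibble), and `config`.
#' @export
simulate_clone_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    master <- make_master(cfg$seq_length, cfg$gc_target,
                          coding = cfg$gene == "mtCO1")
    sexes <- c(rep("F", cfg$n_females), rep("M", cfg$n_males))
    ind_ids <- sprintf("%s-%d", cfg$species, seq_along(sexes))
    shared_numts <- if (cfg$gene == "mtCO1" && cfg$n_numts > 0L) {
      build_numt_templates(cfg, seq_chars(master))
    } else NULL
    rng <- cfg$clones_per_individual
    clone_rows <- list()
    truth_rows <- list()
    for (i in seq_along(ind_ids)) {
      templates <- build_individual_templates(cfg, sexes[i], master,
                                              shared_numts = shared_numts)
      n_clones <- if (rng[1L] == rng[2L]) rng[1L] else
        sample(rng[1L]:rng[2L], 1L)
      res <- pcr_and_clone(templates, cfg, n_clones,
                           clone_prefix = paste0(ind_ids[i], "_c"))
      clone_rows[[i]] <- tibble(
        clone_id = res$clone_id, individual_id = ind_ids[i], sex = sexes[i],
        species = cfg$species, gene = cfg$gene, aligned_seq = res$sequences)
      truth_rows[[i]] <- tibble(
        clone_id = res$clone_id, individual_id = ind_ids[i], sex = sexes[i],
        template_id = ifelse(res$template_class == "numt",
                             paste(cfg$species, res$template_id, sep = "."),
                             paste(ind_ids[i], res$template_id, sep = ".")),
        template_class = res$template_class,
        n_pcr_errors = res$n_pcr_errors,
        error_positions = res$error_positions)
    }
    structure(list(clones = clone_tbl(bind_rows(clone_rows)),
                   truth = bind_rows(truth_rows),
                   master = master,
                   config = cfg),
              class = "clone_sim")
  })
}

#' Write a simulated library to disk
#'
#' Emits the aligned FASTA, the metadata TSV, the truth TSV (error positions
#' comma-joined), and the flat `key=value` config used, for provenance.
#'
#' @param sim A `clone_sim` from [simulate_clone_library()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_clone_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_clone_set(sim$clones, file.path(dir, "clones.fasta"),
                  file.path(dir, "metadata.tsv"))
  truth <- sim$truth |>
    mutate(error_positions = vapply(.data$error_positions, paste,
                                    character(1), collapse = ","))
  readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
  cfg <- sim$config
  scalar <- vapply(cfg, function(v) paste(v, collapse = ","), character(1))
  writeLines(paste0(names(cfg), "=", scalar), file.path(dir, "config.txt"))
  invisible(dir)
}

#' Library presets bracketing the published thrips clone studies
#'
#' Returns a [sim_config()] whose emergent summaries bracket the ranges
#' reported for the three pest thrips species: the `"FO"`-like preset (strong
#' concerted evolution, `h` near 1) yields a high pooled ITS2
#' dominant-haplotype frequency, while `"SD"`/`"TP"`-like presets (weak
#' homogenisation) yield low ITS2 dominant frequencies and substantially more
#' ITS2 than mtCO1 intragenomic divergence. All presets use 2 females + 2
#' males and per-individual clone counts in the published ranges; the
#' polymerase error rate sits at the low end of the empirical Taq range.
#'
#' @param species `"SD"`, `"TP"` or `"FO"`.
#' @param gene `"mtCO1"` or `"ITS2"`.
#' @param seed Seed stored in the config.
#' @return A [sim_config()].
#' @export
preset_paperlike <- function(species = c("SD", "TP", "FO"),
                             gene = c("mtCO1", "ITS2"), seed = 1L) {
  species <- match.arg(species)
  gene <- match.arg(gene)
  args <- switch(paste(species, gene),
    "SD mtCO1" = list(seq_length = 655L, gc_target = 0.306,
                      clones_per_individual = c(24L, 44L),
                      n_numts = 1L, numt_divergence = 4L, numt_weight = 0.03),
    "SD ITS2" = list(seq_length = 502L, gc_target = 0.554,
                     clones_per_individual = c(23L, 46L),
                     homogenization = 0.35, copy_snp_rate = 2.2,
                     copy_indel_rate = 0.3, between_array_divergence = 3,
                     individual_divergence = 2),
    "TP mtCO1" = list(seq_length = 655L, gc_target = 0.32,
                      clones_per_individual = c(24L, 42L),
                      heteroplasmy_freq = 0.15, heteroplasmy_divergence = 2L,
                      n_numts = 1L, numt_divergence = 4L, numt_weight = 0.03),
    "TP ITS2" = list(seq_length = 564L, gc_target = 0.551,
                     clones_per_individual = c(16L, 28L),
                     homogenization = 0.35, copy_snp_rate = 2.2,
                     copy_indel_rate = 0.25, between_array_divergence = 3,
                     individual_divergence = 2),
    "FO mtCO1" = list(seq_length = 434L, gc_target = 0.343,
                      clones_per_individual = c(31L, 46L),
                      n_numts = 1L, numt_divergence = 4L, numt_weight = 0.03),
    "FO ITS2" = list(seq_length = 454L, gc_target = 0.506,
                     clones_per_individual = c(17L, 36L),
                     homogenization = 0.97, copy_snp_rate = 0.4,
                     copy_indel_rate = 0.05, between_array_divergence = 0,
                     individual_divergence = 0)
  )
  do.call(sim_config, c(list(seed = seed, species = species, gene = gene,
                             error_rate = 1e-5, cycles = 35L), args))
}
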