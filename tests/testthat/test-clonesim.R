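test_that("master sequences hit the GC target and are seed-reproducible", {
  m <- make_master(10000, 0.5, seed = 4)
  gc <- gc_content(m)
  expect_gt(gc, 48); expect_lt(gc, 52)
  expect_identical(make_master(500, 0.3, seed = 9), make_master(500, 0.3, seed = 9))
  expect_false(identical(make_master(500, 0.3, seed = 9),
                         make_master(500, 0.3, seed = 10)))
  expect_error(make_master(500, 1.0), class = "clonevar_config_error")
  expect_error(make_master(50, 0.5), class = "clonevar_config_error")
  # coding masters are stop-free in frame 0
  orf <- make_master(655, 0.31, seed = 2, coding = TRUE)
  expect_false(grepl("\\*", translate_mt(orf, 0)))
})

test_that("configuration ranges are validated", {
  expect_error(sim_config(error_rate = 5e-4), class = "clonevar_config_error")
  expect_error(sim_config(homogenization = 1.2), class = "clonevar_config_error")
  expect_error(sim_config(heteroplasmy_freq = 0.5, n_numts = 10L,
                          numt_weight = 0.06), class = "clonevar_config_error")
  expect_error(sim_config(gc_target = 0), class = "clonevar_config_error")
})

test_that("template pools reflect sex, homogenization and artifact settings", {
  withr::with_seed(6, {
    master <- make_master(300, 0.5)
    cfg <- sim_config(gene = "ITS2", seq_length = 300, homogenization = 1,
                      copies_per_array = 20L, between_array_divergence = 0)
    tf <- build_individual_templates(cfg, "F", master)
    tm <- build_individual_templates(cfg, "M", master)
    expect_equal(nrow(tf), 40L)   # two arrays for females
    expect_equal(nrow(tm), 20L)   # one array for males
    # h = 1: every copy identical to its array master
    expect_equal(length(unique(tm$sequence)), 1L)

    cfg_mt <- sim_config(gene = "mtCO1", seq_length = 300,
                         heteroplasmy_freq = 0, n_numts = 0L)
    orf <- make_master(300, 0.4, coding = TRUE)
    t1 <- build_individual_templates(cfg_mt, "F", orf)
    expect_equal(t1$template_class, "mt_functional")

    cfg_mt2 <- sim_config(gene = "mtCO1", seq_length = 300,
                          heteroplasmy_freq = 0.2, n_numts = 3L,
                          numt_divergence = 5L, numt_has_stop = TRUE,
                          numt_weight = 0.05)
    t2 <- build_individual_templates(cfg_mt2, "M", orf)
    expect_setequal(unique(t2$template_class),
                    c("mt_functional", "mt_heteroplasmic", "numt"))
    expect_equal(sum(t2$weight), 1)
    for (s in t2$sequence[t2$template_class == "numt"]) {
      expect_true(grepl("\\*", translate_mt(s, 0)))
    }
    for (s in t2$sequence[t2$template_class != "numt"]) {
      expect_false(grepl("\\*", translate_mt(s, 0)))
    }
    # frameshift numts when no stop is injected
    cfg_mt3 <- sim_config(gene = "mtCO1", seq_length = 300, n_numts = 1L,
                          numt_has_stop = FALSE, numt_weight = 0.05)
    t3 <- build_individual_templates(cfg_mt3, "M", orf)
    numt_seq <- t3$sequence[t3$template_class == "numt"]
    gap_run <- nchar(gsub("[^-]", "", numt_seq))
    expect_true(gap_run %in% c(1L, 2L))
  })
})

test_that("error-free amplification reproduces the sampled templates exactly", {
  cfg <- sim_config(seed = 20, gene = "ITS2", seq_length = 200,
                    homogenization = 0.6, copy_snp_rate = 1.5,
                    copy_indel_rate = 0.2, error_rate = 0,
                    clones_per_individual = 25L)
  sim <- simulate_clone_library(cfg)
  expect_equal(sim$truth$n_pcr_errors, rep(0L, nrow(sim$truth)))
  # each clone equals its template: haplotype count == distinct sampled seqs
  ht <- collapse_haplotypes(sim$clones)
  expect_equal(nrow(ht), length(unique(sim$clones$aligned_seq)))
})

test_that("PCR error load matches the closed-form expectation", {
  cfg <- sim_config(seed = 30, gene = "mtCO1", seq_length = 655,
                    gc_target = 0.31, error_rate = 1e-4, cycles = 35L,
                    n_numts = 0L, clones_per_individual = 150L)
  sim <- simulate_clone_library(cfg)
  n <- nrow(sim$truth)
  expected <- 655 * (1 - (1 - 1e-4)^35)
  se <- sqrt(expected / n)  # Poisson-scale spread of the mean
  expect_lt(abs(mean(sim$truth$n_pcr_errors) - expected), 4 * se)
  # error positions land on non-gap columns and are recorded faithfully
  expect_equal(lengths(sim$truth$error_positions), sim$truth$n_pcr_errors)
})

test_that("simulation is byte-reproducible and re-ingests through seqio", {
  cfg <- preset_paperlike("TP", "ITS2", seed = 13)
  sim1 <- simulate_clone_library(cfg)
  sim2 <- simulate_clone_library(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_clone_sim(sim1, d1); write_clone_sim(sim2, d2)
  expect_identical(readLines(file.path(d1, "clones.fasta")),
                   readLines(file.path(d2, "clones.fasta")))
  back <- read_clone_set(file.path(d1, "clones.fasta"),
                         file.path(d1, "metadata.tsv"))
  expect_equal(as.data.frame(back), as.data.frame(sim1$clones))
  # every clone has exactly one truth row
  expect_setequal(sim1$truth$clone_id, sim1$clones$clone_id)
})

test_that("full homogenization with no array divergence removes ITS2 variation", {
  cfg <- sim_config(seed = 40, gene = "ITS2", seq_length = 300,
                    homogenization = 1, between_array_divergence = 0,
                    individual_divergence = 0, error_rate = 0,
                    clones_per_individual = 20L)
  sim <- simulate_clone_library(cfg)
  expect_equal(nrow(collapse_haplotypes(sim$clones)), 1L)
  g <- glance(partition_divergence(sim$clones))
  expect_equal(g$intra_mean_pct, 0)
})

test_that("intragenomic ITS2 divergence rises as homogenization falls", {
  intra_at_h <- function(h) {
    vals <- vapply(1:2, function(k) {
      cfg <- sim_config(seed = 50 + k, gene = "ITS2", seq_length = 250,
                        homogenization = h, copy_snp_rate = 2,
                        copy_indel_rate = 0.1, between_array_divergence = 1,
                        individual_divergence = 0, error_rate = 1e-5,
                        clones_per_individual = 25L)
      glance(partition_divergence(simulate_clone_library(cfg)$clones))$intra_mean_pct
    }, numeric(1))
    mean(vals)
  }
  v <- vapply(c(0.95, 0.6, 0.2), intra_at_h, numeric(1))
  expect_true(v[1] < v[2] && v[2] < v[3])
})

test_that("females carry at least as much ITS2 variation as males when arrays diverge", {
  diffs <- vapply(1:3, function(k) {
    cfg <- sim_config(seed = 60 + k, gene = "ITS2", seq_length = 250,
                      homogenization = 0.7, copy_snp_rate = 1,
                      copy_indel_rate = 0, between_array_divergence = 6,
                      individual_divergence = 0, error_rate = 0,
                      clones_per_individual = 30L)
    ds <- partition_divergence(simulate_clone_library(cfg)$clones)
    mean(ds$intra$mean_pct[ds$intra$sex == "F"]) -
      mean(ds$intra$mean_pct[ds$intra$sex == "M"])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("presets keep the published design and emergent orderings", {
  for (sp in c("SD", "TP", "FO")) {
    cfg <- preset_paperlike(sp, "ITS2", seed = 1)
    expect_equal(cfg$n_females, 2L)
    expect_equal(cfg$n_males, 2L)
    expect_gte(cfg$error_rate, 1e-5)
    expect_lte(cfg$error_rate, 1e-4)
  }
  dom_fo <- glance(collapse_haplotypes(
    simulate_clone_library(preset_paperlike("FO", "ITS2", seed = 2))$clones
  ))$dominant_freq_pct
  dom_sd <- glance(collapse_haplotypes(
    simulate_clone_library(preset_paperlike("SD", "ITS2", seed = 2))$clones
  ))$dominant_freq_pct
  expect_gt(dom_fo, dom_sd)
  expect_gte(dom_fo, 60)
  expect_lte(dom_sd, 35)
  intra_co1 <- glance(partition_divergence(
    simulate_clone_library(preset_paperlike("SD", "mtCO1", seed = 2))$clones
  ))$intra_mean_pct
  intra_its <- glance(partition_divergence(
    simulate_clone_library(preset_paperlike("SD", "ITS2", seed = 2))$clones
  ))$intra_mean_pct
  expect_lt(intra_co1, intra_its)
})
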