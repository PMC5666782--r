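test_that("variable sites count gaps as a state and ignore N", {
  expect_equal(find_variable_sites(make_clones(c("ACGT", "ACGT")))$sites,
               integer(0))
  expect_equal(find_variable_sites(make_clones(c("ACGT", "AGGT")))$sites, 2L)
  expect_equal(find_variable_sites(make_clones(c("AC-T", "ACGT")))$sites, 3L)
  expect_equal(find_variable_sites(make_clones(c("ACNT", "ACAT")))$sites,
               integer(0))
  expect_error(find_variable_sites(make_clones("ACGT")),
               class = "clonevar_insufficient_data")
})

test_that("variable-site percentage is truncated and matches a column scan", {
  withr::with_seed(11, {
    cl <- make_clones(random_seqs(8, 40))
    res <- find_variable_sites(cl)
    brute <- sum(vapply(1:40, function(j) {
      col <- substr(cl$aligned_seq, j, j)
      length(unique(col[col != "N"])) >= 2
    }, logical(1)))
    expect_equal(res$sites, which(vapply(1:40, function(j) {
      col <- substr(cl$aligned_seq, j, j)
      length(unique(col[col != "N"])) >= 2
    }, logical(1))))
    expect_equal(res$variable_site_pct, floor(1000 * brute / 40) / 10)
  })
})

test_that("column_mask replaces single-unique states by the column consensus", {
  cl <- make_clones(c("AAT", "AAT", "AAT", "GAT"))
  out <- filter_singletons(cl, "column_mask")
  expect_equal(out$aligned_seq, rep("AAT", 4))
  # a state carried twice is kept
  cl2 <- make_clones(c("AAT", "AAT", "GAT", "GAT"))
  expect_equal(filter_singletons(cl2, "column_mask")$aligned_seq,
               cl2$aligned_seq)
  expect_equal(filter_singletons(cl2, "off")$aligned_seq, cl2$aligned_seq)
})

test_that("after column_mask every column state occurs zero or >= 2 times", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      cl <- make_clones(random_seqs(10, 25))
      out <- filter_singletons(cl, "column_mask")
      for (j in 1:25) {
        col <- substr(out$aligned_seq, j, j)
        counts <- table(col[col != "N"])
        expect_true(all(counts == 0 | counts >= 2))
      }
    }
  })
})

test_that("clone_merge rewrites only single-unique-mutation neighbours", {
  # c4 differs from the triple at one column with a pool-unique state: merged
  cl <- make_clones(c("AACCT", "AACCT", "AACCT", "AACCG"))
  out <- filter_singletons(cl, "clone_merge")
  expect_equal(out$aligned_seq, rep("AACCT", 4))
  # a clone two mutations away survives
  cl2 <- make_clones(c("AACCT", "AACCT", "AACCT", "AACGG"))
  out2 <- filter_singletons(cl2, "clone_merge")
  expect_equal(out2$aligned_seq, cl2$aligned_seq)
  # a unique state shared... a state carried by two clones is never merged
  cl3 <- make_clones(c("AACCT", "AACCT", "AACCG", "AACCG"))
  expect_equal(filter_singletons(cl3, "clone_merge")$aligned_seq,
               cl3$aligned_seq)
})

test_that("collapsing partitions by identity with canonical numbering", {
  ht <- collapse_haplotypes(make_clones(c("ACGT", "ACGT", "AGGT")))
  expect_equal(nrow(ht), 2L)
  expect_equal(ht$hap_id, c("H1", "H2"))
  expect_equal(ht$total_count, c(2L, 1L))
  expect_equal(glance(ht)$dominant_freq_pct, 66.6)

  ht1 <- collapse_haplotypes(make_clones(rep("ACGT", 4)))
  expect_equal(nrow(ht1), 1L)
  expect_equal(glance(ht1)$dominant_freq_pct, 100)
})

test_that("collapsing is invariant under record order", {
  withr::with_seed(9, {
    seqs <- sample(c(rep("ACGTA", 5), rep("ACCTA", 3), "AGGTA", "AGCTA"))
    inds <- sample(rep(c("I1", "I2"), 5))
    base <- collapse_haplotypes(make_clones(seqs, individual_id = inds))
    for (r in 1:3) {
      ord <- sample(10)
      shuffled <- collapse_haplotypes(
        make_clones(seqs[ord], individual_id = inds[ord],
                    clone_id = sprintf("c%02d", ord)))
      expect_equal(shuffled$sequence, base$sequence)
      expect_equal(shuffled$hap_id, base$hap_id)
      expect_equal(shuffled$total_count, base$total_count)
    }
  })
})

test_that("column_mask never increases the haplotype count", {
  withr::with_seed(21, {
    for (rep in 1:6) {
      cl <- make_clones(random_seqs(12, 30, gap_prob = 0.1))
      n_raw <- nrow(collapse_haplotypes(cl))
      n_filt <- nrow(collapse_haplotypes(filter_singletons(cl, "column_mask")))
      expect_lte(n_filt, n_raw)
    }
  })
})

test_that("pooled dominant frequency reproduces summary-table arithmetic", {
  # a four-individual library whose dominant haplotype is shared by all:
  # per-individual dominant counts 30, 34, 21, 27 over 132 clones -> 84.8%
  counts <- c(30, 34, 21, 27)
  others <- c(3, 10, 3, 4)  # remaining clones split over minor haplotypes
  seqs <- character(0); inds <- character(0)
  for (i in 1:4) {
    seqs <- c(seqs, rep("AAAA", counts[i]),
              vapply(seq_len(others[i]), function(k) {
                s <- c("A", "A", "A", "A")
                s[(i + k) %% 4 + 1] <- c("C", "G", "T")[k %% 3 + 1]
                paste(s, collapse = "")
              }, character(1)))
    inds <- c(inds, rep(paste0("I", i), counts[i] + others[i]))
  }
  cl <- make_clones(seqs, individual_id = inds,
                    sex = rep(c("F", "M"), each = 2)[as.integer(substr(inds, 2, 2))],
                    clone_id = sprintf("c%03d", seq_along(seqs)))
  expect_equal(sum(counts + others), 132)
  ht <- collapse_haplotypes(cl)
  expect_equal(glance(ht)$dominant_freq_pct, 84.8)
  by_ind <- dominant_likelihood(ht, "by_individual")
  expect_equal(by_ind$n_clones, counts + others)
})

test_that("dominant likelihood truncates to one decimal and flags ties", {
  ht <- collapse_haplotypes(make_clones(c(rep("AAAA", 38), rep("AAAT", 4))))
  expect_equal(dominant_likelihood(ht, "pooled")$dominant_freq_pct, 90.4)
  tied <- collapse_haplotypes(make_clones(c(rep("AAAA", 3), rep("AAAT", 3))))
  pooled <- dominant_likelihood(tied, "pooled")
  expect_equal(pooled$dominant_freq_pct, 50)
  expect_true(pooled$tie)
})

test_that("library summary has one row per individual plus a pooled row", {
  cl <- make_clones(c("AAAA", "AAAA", "AAAT", "AAAA", "AATA", "AATA"),
                    individual_id = c("I1", "I1", "I1", "I2", "I2", "I2"),
                    sex = c("F", "F", "F", "M", "M", "M"))
  tb <- summarize_clone_library(cl, mode = "off")
  expect_equal(tb$individual_id, c("I1", "I2", "All clones"))
  expect_equal(tb$n_clones, c(3L, 3L, 6L))
  tb2 <- summarize_clone_library(cl, mode = "column_mask")
  expect_true("n_haplotypes_raw" %in% names(tb2))
  expect_true(all(tb2$n_haplotypes <= tb2$n_haplotypes_raw))
})

test_that("integer dominant counts are recovered from truncated percentages", {
  rec <- pool_dominant_frequency(c(33, 44, 24, 31), c(90.9, 77.2, 87.5, 87.0))
  expect_equal(rec$counts, c(30L, 34L, 21L, 27L))
  expect_equal(rec$pooled_pct, 84.8)
})
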