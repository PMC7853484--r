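test_that("presence requires min_reads in min_replicates of some treatment", {
  # 2 of 3 replicates at or above 5 reads: present
  counts <- one_replicate_counts(c(AC = 6), treatment = "33")
  counts <- rbind(counts,
                  one_replicate_counts(c(AC = 5), treatment = "33", replicate = 2),
                  one_replicate_counts(c(AC = 0), treatment = "33", replicate = 3))
  pres <- presence_call(counts, expected_species = "AC")
  expect_identical(pres$present, 1L)

  # only one replicate reaches the threshold anywhere: absent
  counts <- do.call(rbind, lapply(c("0", "33", "67", "100"), function(tr) {
    rbind(one_replicate_counts(c(AC = 5), tr, 1),
          one_replicate_counts(c(AC = 4), tr, 2),
          one_replicate_counts(c(AC = 4), tr, 3))
  }))
  pres <- presence_call(counts, expected_species = "AC")
  expect_identical(pres$present, 0L)

  # all-zero species: absent
  counts$reads <- 0L
  expect_identical(presence_call(counts, expected_species = "AC")$present, 0L)
})

test_that("presence ignores non-rupture treatments by default but is configurable", {
  counts <- rbind(one_replicate_counts(c(AC = 50), "24h", 1),
                  one_replicate_counts(c(AC = 50), "24h", 2),
                  one_replicate_counts(c(AC = 0), "33", 1),
                  one_replicate_counts(c(AC = 0), "33", 2))
  expect_identical(presence_call(counts, expected_species = "AC")$present, 0L)
  expect_identical(presence_call(counts, expected_species = "AC",
                                 treatments = "24h")$present, 1L)
})

test_that("presence calling is monotone in its thresholds", {
  set.seed(31)
  counts <- random_read_counts(n_species = 6, max_reads = 8)
  for (i in 1:5) {
    mr <- sample(2:8, 1)
    p_strict <- presence_call(counts, cfg = exine_config(min_reads = mr,
                                                         min_replicates = 3))
    p_reads <- presence_call(counts, cfg = exine_config(min_reads = mr - 1,
                                                        min_replicates = 3))
    p_reps <- presence_call(counts, cfg = exine_config(min_reads = mr,
                                                       min_replicates = 2))
    expect_true(all(p_reads$present >= p_strict$present))
    expect_true(all(p_reps$present >= p_strict$present))
  }
})

test_that("retrieval counts on the bundled grid match the study pattern", {
  grid <- reference_retrieval()
  expect_identical(retrieval_count(grid, "rbcL_2_aR"), 5L)
  expect_identical(retrieval_count(grid, "ITS1"), 9L)
  expect_identical(retrieval_count(grid, "rbcL_aF_r506"), 12L)
  expect_identical(retrieval_count(grid, "ITS2_universal"), 13L)
  expect_identical(retrieval_count(grid, "ITS2_plant"), 13L)
  expect_identical(retrieval_count(grid[0, ], "ITS1"), 0L)
  # the dropout species is retrieved by no marker at all
  expect_true(all(grid$present[grid$species_code == "ZM"] == 0L))
})

test_that("read proportions are computed over expected species only", {
  p <- read_proportions(c(A = 10, B = 10, C = 20), c("A", "B", "C"))
  expect_equal(as.numeric(p), c(0.25, 0.25, 0.5))

  # off-target taxa are excluded from the denominator
  p <- read_proportions(c(A = 10, B = 10, X = 1000), c("A", "B"))
  expect_equal(as.numeric(p), c(0.5, 0.5))

  # singletons count at this stage (no presence threshold here)
  p <- read_proportions(c(A = 1, B = 99), c("A", "B"))
  expect_equal(p[["A"]], 0.01)

  p <- read_proportions(c(A = 7, B = 0), c("A", "B"))
  expect_equal(as.numeric(p), c(1, 0))

  empty <- read_proportions(c(A = 0, B = 0), c("A", "B"))
  expect_true(all(is.na(empty)))
  expect_true(attr(empty, "empty"))
  expect_true(is.na(deviation_score(empty)))
})

test_that("expected proportion is the equimolar fraction", {
  expect_equal(round(expected_proportion(14), 4), 0.0714)
  expect_equal(expected_proportion(1), 1)
  expect_equal(expected_proportion(2), 0.5)
  expect_error(expected_proportion(0))
})

test_that("deviation scores match hand-computed cases and closed forms", {
  expect_equal(deviation_score(rep(1 / 14, 14)), 0)
  # all reads in one of 14 species: D = 2 (1 - 1/S) = 26/14
  expect_equal(deviation_score(c(1, rep(0, 13))), 26 / 14)
  expect_equal(deviation_score(c(0.5, 0.5, 0, 0), e = 0.25), 1.0)
})

test_that("signed deviations sum to zero and D stays within its bounds", {
  set.seed(99)
  for (i in 1:200) {
    S <- sample(2:20, 1)
    p <- random_composition(S)
    e <- expected_proportion(S)
    expect_lt(abs(sum(p - e)), 1e-12)
    D <- deviation_score(p, e)
    expect_gte(D, 0)
    expect_lte(D, 2 * (1 - 1 / S) + 1e-12)
  }
})

test_that("treatment summaries reproduce self-consistent published rows", {
  s <- treatment_summary(c(1.0824, 1.0136, 1.0129))
  expect_equal(round(s[["mean"]], 4), 1.0363)
  expect_equal(round(s[["sd"]], 4), 0.0399)

  s <- treatment_summary(c(0.6455, 0.6748, 0.6386))
  expect_equal(round(s[["mean"]], 4), 0.6530)
  expect_equal(round(s[["sd"]], 4), 0.0192)

  s <- treatment_summary(c(1.1, 1.1, 1.1))
  expect_equal(s[["mean"]], 1.1)
  expect_equal(s[["sd"]], 0)

  expect_warning(s <- treatment_summary(c(0.8, NA, NA)), "SD omitted")
  expect_equal(s[["mean"]], 0.8)
  expect_true(is.na(s[["sd"]]))
})

test_that("the optimal treatment minimises mean deviation with low-rupture ties", {
  expect_identical(as.character(optimal_treatment(
    c(`0` = 0.9572, `33` = 1.0547, `67` = 0.9622, `100` = 1.4309))), "0")
  expect_identical(as.character(optimal_treatment(
    c(`0` = 0.9602, `33` = 0.6530, `67` = 0.7738, `100` = 0.7949))), "33")
  expect_identical(as.character(optimal_treatment(c(`67` = 1.2))), "67")
  expect_identical(as.character(optimal_treatment(
    c(`100` = 0.5, `33` = 0.5))), "33")
  expect_identical(as.character(optimal_treatment(
    c(`0` = NA, `33` = 0.7, `67` = 0.6))), "67")
  expect_error(optimal_treatment(c(`0` = NA_real_)), "no treatment")
})

test_that("trend classification follows the ordered rule set", {
  tau <- 0.0357
  d <- function(...) stats::setNames(c(...), c("0", "33", "67", "100"))
  expect_identical(classify_trend(d(0, 0, 0, 0), tau = tau), "NEAR_ALL")
  expect_identical(classify_trend(d(0.05, 0.06, 0.05, 0.04), tau = tau),
                   "ABOVE_ALL")
  expect_identical(classify_trend(d(-0.05, -0.06, -0.05, -0.04), tau = tau),
                   "BELOW_ALL")
  expect_identical(classify_trend(d(-0.06, -0.03, -0.01, -0.005),
                                  tau = tau, rho = 0.5), "CONVERGENT")
  expect_identical(classify_trend(d(0.06, -0.06, 0.06, 0.06), tau = tau),
                   "MIXED")
  expect_error(classify_trend(c(`0` = 0.1, `33` = 0.1, `67` = 0.1)),
               "all rupture treatments")
})

test_that("replicate order and uniform count scaling change nothing", {
  set.seed(55)
  counts <- random_read_counts(n_species = 6, markers = "ITS1")
  base <- suppressWarnings(deviation_report(counts))

  # permute replicate labels within a treatment
  sw <- counts
  idx1 <- sw$treatment_code == "33" & sw$replicate == 1L
  idx2 <- sw$treatment_code == "33" & sw$replicate == 2L
  sw$replicate[idx1] <- 2L
  sw$replicate[idx2] <- 1L
  perm <- suppressWarnings(deviation_report(sw))
  expect_equal(perm$summary, base$summary)
  expect_identical(perm$optimal, base$optimal)

  # double every count in one replicate: proportions, D, presence unchanged
  dbl <- counts
  idx <- dbl$treatment_code == "67" & dbl$replicate == 3L
  dbl$reads[idx] <- dbl$reads[idx] * 2L
  expect_equal(suppressWarnings(deviation_report(dbl))$scores$D,
               base$scores$D)
  expect_identical(presence_call(dbl)$present, presence_call(counts)$present)
})

test_that("deviation_report summarises the bundled replicate scores like the study", {
  dev <- reference_deviation_scores()
  means <- tapply(dev$D, list(dev$marker, dev$treatment_code), mean)
  opt <- vapply(rownames(means), function(m)
    as.character(optimal_treatment(means[m, ])), character(1))
  expect_identical(opt[["ITS1"]], "0")
  expect_identical(opt[["ITS2_universal"]], "33")
  expect_identical(opt[["ITS2_plant"]], "33")
  expect_identical(opt[["rbcL_aF_r506"]], "67")
})

test_that("empty replicates are excluded from treatment means with a warning", {
  counts <- rbind(one_replicate_counts(c(A = 50, B = 50), "33", 1),
                  one_replicate_counts(c(A = 60, B = 40), "33", 2),
                  one_replicate_counts(c(A = 0, B = 0), "33", 3))
  expect_warning(rep_ <- deviation_report(counts, treatments = "33"),
                 "excluded")
  row <- rep_$summary[rep_$summary$treatment_code == "33", ]
  expect_identical(row$n_used, 2L)
  expect_equal(row$mean_D, mean(c(0, 0.2)))
})
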