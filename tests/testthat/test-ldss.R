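test_that("target sizes follow the requested rounding rule", {
  expect_equal(target_size(208, 0.20), 42L)
  expect_equal(target_size(208, 0.25), 52L)
  expect_equal(target_size(10, 1.0), 10L)
  expect_equal(target_size(208, 0.30), 62L)             # 62.4 rounds down
  expect_equal(target_size(208, 0.30, "ceil"), 63L)
  expect_equal(target_size(208, 0.35), 73L)             # 72.8 rounds up
  expect_equal(target_size(3, 0.1), 1L)                 # never below 1
  expect_equal(target_size(5, 0.5, "floor"), 2L)
  expect_error(target_size(10, 0), "ratio")
})

make_ldss_fixture <- function() {
  ids <- c("A", "B", "C")
  D <- matrix(c(0, 0.1, 0.5,
                0.1, 0, 0.7,
                0.5, 0.7, 0), 3, 3, dimnames = list(ids, ids))
  m <- metabolite_table(matrix(c(2.0, 1.5, 3.0), ncol = 1,
                               dimnames = list(ids, "cmp")))
  list(D = D, m = m)
}

test_that("the minimum-distance pair loses its lower-scoring member", {
  fx <- make_ldss_fixture()
  cc <- ldss_sample(fx$D, fx$m, sizes = c(final = 2))
  expect_identical(cc$removal_log$removed, "B")
  expect_identical(cc$removal_log$partner, "A")
  expect_equal(cc$removal_log$pair_distance, 0.1)
  expect_equal(cc$removal_log$removed_total, 1.5)
  expect_setequal(cc$checkpoints$final, c("A", "C"))
})

test_that("a target equal to the panel size removes nothing", {
  fx <- make_ldss_fixture()
  cc <- ldss_sample(fx$D, fx$m, sizes = c(all = 3))
  expect_equal(nrow(cc$removal_log), 0L)
  expect_setequal(cc$checkpoints$all, c("A", "B", "C"))
})

test_that("score ties remove the lexicographically larger accession", {
  fx <- make_ldss_fixture()
  m_tie <- metabolite_table(matrix(c(2, 2, 3), ncol = 1,
                                   dimnames = list(c("A", "B", "C"), "cmp")))
  cc <- ldss_sample(fx$D, m_tie, sizes = 2)
  expect_identical(cc$removal_log$removed, "B")
  expect_identical(ldss_sample(fx$D, m_tie, sizes = 2)$removal_log,
                   cc$removal_log)
})

test_that("input validation catches mismatched metabolites and bad sizes", {
  fx <- make_ldss_fixture()
  m_short <- metabolite_table(matrix(1:2, ncol = 1,
                                     dimnames = list(c("A", "B"), "cmp")))
  expect_error(ldss_sample(fx$D, m_short, sizes = 2), "metabolite score missing.*C")
  expect_error(ldss_sample(fx$D, fx$m, sizes = c(2, 2)), "duplicate")
  expect_error(ldss_sample(fx$D, fx$m, sizes = 5), "target sizes")
})

test_that("checkpoints are nested and each removal was a then-minimal pair", {
  g <- random_geno(n = 60, L = 5, max_alleles = 6, seed = 8)
  m <- random_metabolites(g, seed = 8)
  d <- genetic_distance(g)
  cc <- ldss_sample(d, m, ratios = c(0.5, 0.25))
  expect_true(all(cc$checkpoints[[2]] %in% cc$checkpoints[[1]]))
  expect_equal(length(cc$checkpoints[[1]]), 30L)
  expect_equal(length(cc$checkpoints[[2]]), 15L)
  # replay the log against a masked copy of the distance matrix
  M <- unclass(d)
  diag(M) <- Inf
  for (k in seq_len(nrow(cc$removal_log))) {
    expect_equal(cc$removal_log$pair_distance[k], min(M))
    pair <- c(cc$removal_log$removed[k], cc$removal_log$partner[k])
    expect_equal(unname(M[pair[1], pair[2]]), min(M))
    M[pair[1], ] <- Inf
    M[, pair[1]] <- Inf
  }
  # removed and retained accessions partition the panel
  expect_setequal(c(cc$checkpoints[[2]], cc$removal_log$removed),
                  g$accession_ids)
  # identical inputs reproduce the identical log
  expect_identical(ldss_sample(d, m, ratios = c(0.5, 0.25))$removal_log,
                   cc$removal_log)
})

test_that("a duplicated accession pair is resolved first, by metabolite score", {
  g0 <- random_geno(n = 10, L = 4, seed = 13)
  # duplicate accession 1's genotype into accession 2 -> distance 0 pair
  a1 <- g0$a1; a2 <- g0$a2
  a1[2, ] <- a1[1, ]; a2[2, ] <- a2[1, ]
  g <- genotype_matrix(a1, a2)
  m <- random_metabolites(g, seed = 13)
  low <- which.min(total_score(m)[g$accession_ids[1:2]])
  cc <- ldss_sample(genetic_distance(g), m, sizes = 9)
  expect_identical(cc$removal_log$removed[1], g$accession_ids[1:2][low])
  expect_equal(cc$removal_log$pair_distance[1], 0)
})

test_that("the ladder reports Ra and metabolite means per checkpoint", {
  g <- random_geno(n = 20, L = 4, seed = 21)
  m <- random_metabolites(g, seed = 21)
  lad <- ldss_ladder(g, m, ratios = 1.0)
  row <- lad$table[lad$table$name != "original", ]
  expect_equal(row$Ra, 100)
  expect_equal(row$total_coumarin,
               lad$table$total_coumarin[lad$table$name == "original"])

  lad2 <- ldss_ladder(g, m, ratios = c(0.5, 0.25))
  expect_true(all(lad2$core$checkpoints[["25CC"]] %in%
                  lad2$core$checkpoints[["50CC"]]))
  expect_equal(lad2$table$size, c(20L, 10L, 5L))
  expect_true(all(diff(lad2$table$Ra) <= 1e-9))
  # whenever the removed member scored below the retained mean, the
  # retained mean cannot decrease at that step
  totals <- total_score(m)
  retained <- g$accession_ids
  for (k in seq_len(nrow(lad2$core$removal_log))) {
    pre_mean <- mean(totals[retained])
    rm_id <- lad2$core$removal_log$removed[k]
    retained <- setdiff(retained, rm_id)
    if (totals[rm_id] < pre_mean)
      expect_gte(mean(totals[retained]), pre_mean)
  }
})
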