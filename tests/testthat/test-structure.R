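test_that("band matrix collapses dosage and flags missing loci", {
  g <- make_geno(L1 = c("150/152", "150/150", "0/0"),
                 L2 = c("200/204", "202/202", "200/202"))
  b <- band_matrix(g)
  # L1 has alleles {150, 152}; L2 has {200, 202, 204}
  expect_equal(colnames(b),
               c("L1.150", "L1.152", "L2.200", "L2.202", "L2.204"))
  expect_equal(unname(b[1, 1:2]), c(1, 1))
  expect_equal(unname(b[2, 1:2]), c(1, 0))    # homozygote: dosage collapsed
  expect_true(all(is.na(b[3, 1:2])))          # missing call: all columns NA
  expect_equal(unname(b[3, 3:5]), c(1, 1, 0))
})

test_that("simple-matching distance counts mismatches over known columns", {
  b <- rbind(x = c(1, 0, 1, 0, 1, 1),
             y = c(1, 0, 1, 0, 1, 1),
             z = c(0, 1, 0, 1, 0, 0),
             w = c(1, 0, 1, 0, 0, 0))
  d <- simple_matching_distance(b)
  expect_equal(d["x", "y"], 0)
  expect_equal(d["x", "z"], 1)          # complementary vectors
  expect_equal(d["x", "w"], 2 / 6)      # agree on 4 of 6 columns
  expect_true(all(diag(d) == 0) && isSymmetric(unclass(d)))
  # metric bounded in [0, 1] and triangle inequality on complete data
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  # a pair with no mutually known columns errors
  b2 <- rbind(a = c(1, NA), b = c(NA, 0))
  expect_error(simple_matching_distance(b2), "no mutually typed")
})

test_that("UPGMA merges minimum pairs at half distance with hand traces", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(t2$height, 0.2)

  ids <- c("A", "B", "C")
  d3 <- matrix(0, 3, 3, dimnames = list(ids, ids))
  d3["A", "B"] <- d3["B", "A"] <- 0.2
  d3["A", "C"] <- d3["C", "A"] <- 0.6
  d3["B", "C"] <- d3["C", "B"] <- 0.4
  t3 <- upgma(d3)
  expect_equal(t3$height, c(0.1, 0.25))
  expect_equal(cophenetic_matrix(t3)["A", "B"], 0.2)
  expect_equal(cophenetic_matrix(t3)["A", "C"], 0.5)

  # tie: two equal minima resolve to the lowest (row, column) pair
  ids4 <- c("A", "B", "C", "D")
  d4 <- matrix(0.8, 4, 4, dimnames = list(ids4, ids4))
  diag(d4) <- 0
  d4["A", "B"] <- d4["B", "A"] <- 0.2
  d4["C", "D"] <- d4["D", "C"] <- 0.2
  t4 <- upgma(d4)
  expect_equal(t4$merge[1, ], c(-1L, -2L))
  expect_identical(upgma(d4)$merge, t4$merge)
})

test_that("UPGMA agrees with a naive recomputation oracle and with hclust", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:12, 1)
    p <- matrix(runif(n * 3), n)
    D <- as.matrix(dist(p))
    dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
    tree <- upgma(D)
    expect_equal(cophenetic_matrix(tree), oracle_upgma_cophenetic(D),
                 tolerance = 1e-10, info = paste("seed", seed))
    hc <- hclust(as.dist(D), method = "average")
    expect_equal(sort(tree$height), sort(hc$height) / 2, tolerance = 1e-10)
    expect_equal(cophenetic_matrix(tree)[rownames(D), rownames(D)],
                 as.matrix(cophenetic(hc))[rownames(D), rownames(D)],
                 tolerance = 1e-10)
  }
  # ties from a discrete value set still match the naive oracle
  set.seed(77)
  for (seed in 1:4) {
    n <- 8
    D <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
    vals <- sample(c(0.2, 0.4, 0.6), n * (n - 1) / 2, replace = TRUE)
    D[upper.tri(D)] <- vals
    D <- D + t(D)
    expect_equal(cophenetic_matrix(upgma(D)), oracle_upgma_cophenetic(D),
                 tolerance = 1e-10)
  }
})

test_that("PCoA embeds Euclidean configurations exactly", {
  # collinear points at coordinates 0, 1, 2
  ids <- c("p0", "p1", "p2")
  D <- as.matrix(dist(matrix(c(0, 1, 2), ncol = 1)))
  dimnames(D) <- list(ids, ids)
  res <- pcoa(D, n_axes = 2)
  expect_equal(res$percent_variance[1], 100)
  got <- unname(sort(res$coordinates[, 1]))
  expect_equal(got - got[1], c(0, 1, 2), tolerance = 1e-9)

  # random 3-D configuration: pairwise distances reconstructed from 3 axes
  set.seed(9)
  p <- matrix(rnorm(18), 6, 3)
  D6 <- as.matrix(dist(p))
  dimnames(D6) <- list(paste0("s", 1:6), paste0("s", 1:6))
  r6 <- pcoa(D6, n_axes = 3)
  expect_equal(unname(as.matrix(dist(r6$coordinates))), unname(D6),
               tolerance = 1e-9)
  # eigenvalue sum equals the trace of the centered Gower matrix
  expect_equal(sum(r6$eigenvalues), r6$trace, tolerance = 1e-9)
  # agreement with the classical-scaling reference in base R
  ref <- cmdscale(as.dist(D6), k = 3)
  for (ax in 1:3)
    expect_equal(unname(abs(r6$coordinates[, ax])), unname(abs(ref[, ax])),
                 tolerance = 1e-8)

  # duplicated accessions land on identical coordinates
  Ddup <- rbind(cbind(D6, D6[, 1]), c(D6[1, ], 0))
  ids7 <- c(paste0("s", 1:6), "s1b")
  dimnames(Ddup) <- list(ids7, ids7)
  r7 <- pcoa(Ddup, n_axes = 2)
  expect_equal(r7$coordinates["s1", ], r7$coordinates["s1b", ],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_warning(pcoa(D, n_axes = 10), "clipped")
})

test_that("AMOVA partitions squared distances and matches brute-force sums", {
  # two populations, all within distances 0, all between > 0
  ids <- paste0("s", 1:6)
  pops <- setNames(rep(c("P1", "P2"), each = 3), ids)
  D <- matrix(1, 6, 6, dimnames = list(ids, ids))
  D[1:3, 1:3] <- 0
  D[4:6, 4:6] <- 0
  a <- amova(D, pops)
  expect_equal(a$percent[["among"]], 100)
  expect_equal(a$phi_pt, 1)

  # identical individuals: all components zero, PhiPT 0 with warning
  D0 <- matrix(0, 6, 6, dimnames = list(ids, ids))
  expect_warning(a0 <- amova(D0, pops), "zero")
  expect_equal(a0$phi_pt, 0)

  # random toy matrix vs direct-summation oracle
  for (seed in 1:5) {
    set.seed(seed)
    p <- matrix(rnorm(12 * 2), 12)
    D2m <- as.matrix(dist(p))^2
    ids12 <- paste0("s", 1:12)
    dimnames(D2m) <- list(ids12, ids12)
    dd <- structure(D2m, class = c("gen_dist", "matrix"),
                    kind = "band_sq_euclidean", squared = TRUE)
    pp <- setNames(sample(rep(c("P1", "P2"), c(5, 7))), ids12)
    res <- amova(dd, pp)
    ss <- oracle_amova_ss(D2m, unname(pp[ids12]))
    expect_equal(res$table$SS, unname(ss[c("among", "within", "total")]),
                 tolerance = 1e-10)
    expect_equal(sum(res$percent), 100)
    # relabeling populations leaves PhiPT unchanged
    relab <- setNames(c(P1 = "X", P2 = "Y")[pp], names(pp))
    expect_equal(amova(dd, relab)$phi_pt, res$phi_pt)
  }
  # single-member population rejected
  expect_error(amova(D, setNames(c("P1", rep("P2", 5)), ids)), "size 1")
})

test_that("AMOVA permutation p-values behave under null and structured data", {
  set.seed(123)
  ids <- paste0("s", 1:20)
  # structured: two tight clusters far apart
  p <- rbind(matrix(rnorm(10 * 2, 0, 0.1), 10), matrix(rnorm(10 * 2, 5, 0.1), 10))
  D <- as.matrix(dist(p))
  dimnames(D) <- list(ids, ids)
  pops <- setNames(rep(c("P1", "P2"), each = 10), ids)
  expect_lt(amova(D, pops, n_permutations = 199, seed = 7)$p_value, 0.05)
  # identical seeds give identical p-values
  expect_equal(amova(D, pops, n_permutations = 99, seed = 3)$p_value,
               amova(D, pops, n_permutations = 99, seed = 3)$p_value)
  # null labels: p-values spread out rather than clustering near 0
  pnull <- replicate(12, {
    lab <- setNames(sample(rep(c("P1", "P2"), each = 10)), ids)
    amova(D, lab, n_permutations = 99, seed = 11)$p_value
  })
  expect_gte(mean(pnull > 0.1), 0.5)
})

test_that("pairwise PhiPT equals per-pair AMOVA and hits its bounds", {
  ids <- paste0("s", 1:9)
  pops <- setNames(rep(c("P1", "P2", "P3"), each = 3), ids)
  # P1 and P2 identical point clouds, P3 disjoint bands
  b <- rbind(matrix(rep(c(1, 0, 1, 0), 3), 3, byrow = TRUE),
             matrix(rep(c(1, 0, 1, 0), 3), 3, byrow = TRUE),
             matrix(rep(c(0, 1, 0, 1), 3), 3, byrow = TRUE))
  rownames(b) <- ids
  d <- band_sq_euclidean_distance(b)
  expect_warning(pw <- pairwise_phipt(d, pops), "zero")
  expect_equal(pw$phi_pt["P1", "P2"], 0)
  expect_equal(pw$phi_pt["P1", "P3"], 1)
  expect_true(all(diag(pw$phi_pt) == 0))

  # consistency against amova() restricted to each pair on a random panel
  g <- random_geno(n = 12, L = 3, seed = 55)
  d2 <- genetic_distance(g)
  pops2 <- setNames(rep(c("A", "B", "C"), each = 4), g$accession_ids)
  pw2 <- pairwise_phipt(d2, pops2)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    idx <- names(pops2)[pops2 %in% pair]
    sub <- structure(unclass(d2)[idx, idx], class = c("gen_dist", "matrix"),
                     kind = "band_sq_euclidean", squared = TRUE)
    expect_equal(pw2$phi_pt[pair[1], pair[2]],
                 amova(sub, pops2[idx])$phi_pt, tolerance = 1e-12)
  }
})
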