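test_that("simple TSV genotypes parse, with 0/0 as a missing call", {
  path <- temp_path()
  writeLines(c("accession\tAbssr01",
               "a1\t150/150",
               "a2\t150/152",
               "a3\t152/152",
               "a4\t150/154"), path)
  g <- read_genotypes(path, dialect = "simple_tsv")
  expect_equal(dim(g), c(4L, 1L))
  expect_equal(length(unique(c(g$a1, g$a2))), 3L)

  writeLines(c("accession\tAbssr01", "a1\t150/152", "a2\t0/0"), path)
  g <- read_genotypes(path, dialect = "simple_tsv")
  expect_equal(g$accession_ids, c("a1", "a2"))
  expect_true(is.na(g$a1[2, 1]) && is.na(g$a2[2, 1]))
})

test_that("malformed genotype tables are rejected with named cells", {
  path <- temp_path()
  writeLines(c("accession\tL1", "a1\t150/0"), path)
  expect_error(read_genotypes(path, dialect = "simple_tsv"),
               "half-missing.*a1.*L1")
  writeLines(c("accession\tL1", "a1\t150/152", "a1\t150/152"), path)
  expect_error(read_genotypes(path, dialect = "simple_tsv"), "duplicate accession")
  writeLines(c("accession\tL1", "a1\t150.5/152"), path)
  expect_error(read_genotypes(path, dialect = "simple_tsv"), "malformed|non-integer")

  csv <- temp_path()
  writeLines(c("accession,L1,", "a1,150,0"), csv)
  expect_error(read_genotypes(csv, dialect = "genalex_csv"), "half-missing.*a1.*L1")
})

test_that("genotype round-trips are the identity in both dialects", {
  g <- random_geno(n = 5, L = 3, missing_rate = 0.2, seed = 42)
  for (dialect in c("genalex_csv", "simple_tsv")) {
    path <- temp_path()
    write_genotypes(g, path, dialect = dialect)
    g2 <- read_genotypes(path, dialect = dialect)
    expect_equal(g2$a1, g$a1)
    expect_equal(g2$a2, g$a2)
    expect_identical(g2$accession_ids, g$accession_ids)
    expect_identical(g2$locus_ids, g$locus_ids)
  }
})

test_that("GenAlEx dialect skips metadata rows and reads the Pop column", {
  path <- temp_path()
  writeLines(c("2,3,2",
               "some title row",
               "accession,Pop,L1,,L2,",
               "a1,P1,150,152,200,200",
               "a2,P1,150,150,0,0",
               "a3,P2,152,154,202,204"), path)
  g <- read_genotypes(path, dialect = "genalex_csv")
  expect_equal(dim(g), c(3L, 2L))
  expect_identical(g$locus_ids, c("L1", "L2"))
  pops <- attr(g, "populations")
  expect_identical(as.character(unclass(pops)), c("P1", "P1", "P2"))
  # round-trip including populations
  out <- temp_path()
  write_genotypes(g, out, dialect = "genalex_csv", populations = pops)
  g2 <- read_genotypes(out, dialect = "genalex_csv")
  expect_equal(g2$a1, g$a1)
  expect_identical(as.character(unclass(attr(g2, "populations"))),
                   c("P1", "P1", "P2"))
})

test_that("metabolite CSV reads, totals are row sums, bad values error", {
  path <- temp_path()
  writeLines(c("accession,c1,c2,c3,c4,c5,c6",
               "a1,0.1,0.2,0.3,0.4,0.5,0.6",
               "a2,1,0,2,0,3,0"), path)
  m <- read_metabolites(path)
  expect_equal(ncol(m), 6L)
  expect_equal(unname(total_score(m)), c(2.1, 6))

  writeLines(c("accession,c1", "a1,-0.1"), path)
  expect_error(read_metabolites(path), "negative")
  writeLines(c("accession,c1,c2", "a1,0.5,"), path)
  expect_error(read_metabolites(path), "non-numeric|empty")
  writeLines(c("accession,c1", "a1,abc"), path)
  expect_error(read_metabolites(path), "non-numeric")
})

test_that("metabolite CSV round-trips", {
  g <- random_geno(n = 4, seed = 7)
  m <- random_metabolites(g, seed = 7)
  path <- temp_path()
  write_metabolites(m, path)
  m2 <- read_metabolites(path)
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12)
})

test_that("Newick output is ultrametric and parseable", {
  # two leaves merged at height 0.2
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  nwk <- write_tree_newick(upgma(d))
  expect_identical(nwk, "(A:0.2,B:0.2);")

  skip_if_not_installed("ape")
  g <- random_geno(n = 7, L = 3, seed = 11)
  tree <- upgma(genetic_distance(g, "simple_matching"))
  path <- temp_path()
  write_tree_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_equal(sort(phy$tip.label), sort(g$accession_ids))
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  expect_equal(depths, rep(max(tree$height), 7), tolerance = 1e-9)
})

test_that("diversity reports serialise all statistics and round-trip", {
  g <- random_geno(n = 6, L = 2, seed = 3)
  s <- diversity_summary(g)
  path <- temp_path()
  write_report(s, path, format = "json")
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(names(back$means), c("Na", "Ne", "Ho", "He", "I", "H", "PIC"))
  expect_equal(back$means$PIC, unname(s$means["PIC"]), tolerance = 1e-12)
  expect_equal(back$total_alleles, s$total_alleles)
})
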