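test_that("design reader validates the pairing invariant", {
  path <- write_toy_design()
  d <- read_design(path)
  expect_s3_class(d, "PairedDesign")
  expect_equal(nrow(d), 20)
  expect_length(design_patients(d), 10)
  expect_length(design_patients(d, "IDC"), 5)

  # duplicated tumor sample for one patient
  bad <- as.data.frame(toy_design())
  bad$sample[1] <- "X_T2"; bad$patient[1] <- "P02"; bad$tissue[1] <- "tumor"
  f <- tempfile(); utils::write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_design(f), "P02")

  empty <- tempfile(); writeLines("sample\tpatient\ttissue\tsubtype", empty)
  expect_error(read_design(empty), "no samples")

  weird <- as.data.frame(toy_design()); weird$tissue[3] <- "stroma"
  f2 <- tempfile(); utils::write.table(weird, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_design(f2), "tissue")
})

test_that("protein reader drops flagged rows, converts zeros, orders columns", {
  design <- toy_design()
  grid <- matrix(seq_len(3 * 20) * 1000, 3, 20,
                 dimnames = list(c("A1;A2", "B1", "C1"), design$sample))
  grid[2, 5] <- 0
  path <- write_toy_protein_file(grid, design, reverse = c("", "", "+"))
  X <- read_protein_table(path, design)
  expect_equal(rownames(X$values), c("A1", "B1"))   # reverse row gone, first accession
  expect_equal(colnames(X$values), design$sample)
  expect_true(is.na(X$values["B1", design$sample[5]]))  # 0 -> missing, not 0
  expect_equal(X$scale, "linear")

  # hand-parsed grid comparison on the surviving rows
  expected <- grid[1:2, , drop = FALSE]
  expected[expected == 0] <- NA
  rownames(expected) <- c("A1", "B1")
  expect_equal(X$values, expected)

  expect_error(read_protein_table(path, toy_design(6)), "intensity column")
})

test_that("intensity TSV round trip preserves cells and missingness", {
  design <- toy_design(2)
  X <- toy_matrix(design, 10)
  X$values[cbind(c(1, 4, 7), c(2, 3, 1))] <- NA
  p <- tempfile(fileext = ".tsv")
  write_intensity_tsv(X, p)
  Y <- read_intensity_tsv(p)
  expect_equal(Y$values, X$values)
  # MaxQuant-dialect round trip likewise never turns missing into zero
  p2 <- tempfile(); write_protein_table(X, p2)
  Z <- read_protein_table(p2, design)
  expect_equal(Z$values, X$values)
})

test_that("phospho reader splits multiplicity, keeps low-prob rows, flags errors", {
  design <- toy_design(2)
  ns <- nrow(design)
  sites <- list(
    list(protein = "Q1", gene = "G1", aa = "S", pos = 15, prob = 0.95,
         intensities = list(`1` = rep(1000, ns), `2` = rep(500, ns))),
    list(protein = "Q2", gene = "G2", aa = "T", pos = 88, prob = 0.5,
         intensities = list(`1` = c(2000, rep(0, ns - 1)))),
    list(protein = "Q3", gene = "G3", aa = "Y", pos = 7, prob = 0.99,
         intensities = list(`3` = rep(300, ns))))
  path <- write_toy_phospho_file(sites, design)
  tab <- read_phospho_table(path, design)
  expect_equal(nrow(tab), 4)  # Q1 mult 1+2, Q2 mult 1, Q3 mult 3
  expect_setequal(tab$multiplicity[tab$protein == "Q1"], c(1, 2))
  expect_true(0.5 %in% tab$localization_prob)  # no probability filter at read time
  q2 <- phospho_intensities(tab[tab$protein == "Q2", ])
  expect_true(is.na(q2[1, 2]) && q2[1, 1] == 2000)

  # hand-tabulated row-for-row check
  q1 <- tab[tab$protein == "Q1" & tab$multiplicity == 2, ]
  expect_equal(q1$position, 15)
  expect_equal(unname(phospho_intensities(q1)[1, ]), rep(500, ns))

  bad <- sites; bad[[1]]$pos <- "15b"
  expect_error(read_phospho_table(write_toy_phospho_file(bad, design), design),
               "malformed position")
})

test_that("phospho writer round-trips through the reader", {
  design <- toy_design(2)
  sim <- simulate_phospho_dataset(
    sim_params(n_pairs_per_subtype = 2, n_sites = 30, seed = 3),
    simulate_kinase_substrates(n_kinases = 3, substrates_per_kinase = 4,
                               n_genes = 10, seed = 3))
  p <- tempfile()
  write_phospho_table(sim$sites, p)
  back <- read_phospho_table(p, sim$design)
  key <- function(t) paste(t$protein, t$position, t$multiplicity)
  o1 <- order(key(sim$sites)); o2 <- order(key(back))
  expect_equal(key(back)[o2], key(sim$sites)[o1])
  expect_equal(phospho_intensities(back)[o2, ], phospho_intensities(sim$sites)[o1, ],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("kinase-substrate reader deduplicates and filters by organism", {
  path <- system.file("extdata", "kinase_substrates_toy.tsv", package = "phosphopair")
  ks <- read_kinase_substrates(path)
  expect_false(any(duplicated(ks)))
  expect_equal(nrow(ks), 9)
  hum <- read_kinase_substrates(path, organism_filter = "human")
  expect_equal(nrow(hum), 8)
  expect_false("CSNK2A1" %in% hum$kinase)

  # duplicate triples collapse; hand-built comparison
  f <- tempfile()
  writeLines(c("GENE\tSUB_GENE\tSUB_MOD_RSD", "K1\tS1\tS10", "K1\tS1\tS10",
               "K1\tS2\tT20", "K2\tS1\tS10"), f)
  got <- read_kinase_substrates(f)
  expect_equal(got, data.frame(kinase = c("K1", "K1", "K2"),
                               substrate = c("S1", "S2", "S1"),
                               site = c("S10", "T20", "S10"),
                               stringsAsFactors = FALSE))
  f2 <- tempfile(); writeLines("GENE\tSUB_GENE", f2)
  expect_error(read_kinase_substrates(f2), "SUB_MOD_RSD")
})

test_that("printed dual-layer fixture has the published values", {
  t2 <- load_table2_fixture()
  expect_equal(nrow(t2), 13)
  expect_equal(sum(is.na(t2$phos_fc_idc)), 3)
  h1x <- t2[t2$protein_label == "H1X_HUMAN", ]
  expect_equal(c(h1x$prot_fc_idc, h1x$prot_fc_ilc), c(1.78, 0.56))
  expect_true(is.na(h1x$phos_fc_idc) && is.na(h1x$phos_fc_ilc))
  ktn1 <- t2[t2$protein_label == "KTN1_HUMAN", ]
  expect_equal(c(ktn1$phos_fc_idc, ktn1$phos_fc_ilc), c(3.36, 0.41))
  sept2 <- t2[t2$protein_label == "SEPT2_HUMAN", ]
  expect_equal(unlist(sept2[, -1], use.names = FALSE), c(1.83, 2.43, 3.82, 0.67))
})
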