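# independent brute-force evaluation of the kinase z score used as the
# oracle: z = (s_bar - p_bar) * sqrt(m) / delta over deduplicated site keys
brute_ksea <- function(site_fc, annotations) {
  key <- paste(toupper(site_fc$gene), site_fc$site, sep = "|")
  ok <- is.finite(site_fc$log2fc)
  fc <- c(); for (k in unique(key[ok])) fc[k] <- mean(site_fc$log2fc[ok][key[ok] == k])
  p_bar <- mean(fc); delta <- sd(fc)
  res <- list()
  for (kin in unique(toupper(annotations$kinase))) {
    rows <- toupper(annotations$kinase) == kin
    keys <- unique(paste(toupper(annotations$substrate[rows]),
                         annotations$site[rows], sep = "|"))
    keys <- keys[keys %in% names(fc)]
    if (!length(keys)) next
    m <- length(keys); s_bar <- mean(fc[keys])
    z <- (s_bar - p_bar) * sqrt(m) / delta
    res[[kin]] <- c(m = m, z = z, p = 2 * pnorm(-abs(z)))
  }
  res
}

test_that("ksea z matches the worked example and the formula structure", {
  site_fc <- data.frame(gene = paste0("g", 1:6), site = "S1",
                        log2fc = c(1.0, -1.0, 0.5, -0.5, 2.0, 0.0))
  ann <- data.frame(kinase = "K", substrate = c("g5", "g1", "g3"), site = "S1")
  res <- ksea_scores(site_fc, ann)
  expect_equal(res$m, 3L)
  expect_equal(res$mean_substrate_log2fc, 3.5 / 3, tolerance = 1e-12)
  expect_equal(res$global_mean_log2fc, 1 / 3, tolerance = 1e-12)
  expect_equal(res$global_sd_log2fc, sqrt(sum((site_fc$log2fc - 1 / 3)^2) / 5),
               tolerance = 1e-12)
  expect_equal(res$z, 1.336, tolerance = 1e-3)
  expect_equal(res$p, 0.181, tolerance = 1e-2)

  # a kinase whose substrate set is all sites scores exactly zero
  ann_all <- data.frame(kinase = "ALL", substrate = paste0("g", 1:6), site = "S1")
  res_all <- ksea_scores(site_fc, ann_all)
  expect_equal(res_all$z, 0)
  expect_equal(res_all$p, 1)

  # duplicating every substrate multiplies z by sqrt(2)
  sf2 <- rbind(site_fc,
               data.frame(gene = paste0("h", 1:3), site = "S1",
                          log2fc = c(2.0, 1.0, 0.5)))
  ann2 <- data.frame(kinase = "K",
                     substrate = c("g5", "g1", "g3", "h1", "h2", "h3"),
                     site = "S1")
  # same s_bar, same 3 values duplicated; background must stay fixed for the
  # pure sqrt(m) scaling, so compare against the formula directly
  r2 <- ksea_scores(sf2, ann2)
  pb <- mean(sf2$log2fc); dl <- sd(sf2$log2fc)
  expect_equal(r2$z, (3.5 / 3 - pb) * sqrt(6) / dl, tolerance = 1e-12)

  expect_error(ksea_scores(data.frame(gene = c("a", "b"), site = "S1",
                                      log2fc = c(1, 1)), ann),
               "degenerate")
})

test_that("ksea matches the brute-force oracle on random instances", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    site_fc <- data.frame(gene = sprintf("g%03d", sample(40, n, TRUE)),
                          site = paste0("S", sample(1:5, n, TRUE)),
                          log2fc = rnorm(n))
    ann <- data.frame(kinase = sprintf("K%d", sample(1:6, 30, TRUE)),
                      substrate = sprintf("g%03d", sample(40, 30, TRUE)),
                      site = paste0("S", sample(1:5, 30, TRUE)))
    got <- ksea_scores(site_fc, ann)
    oracle <- brute_ksea(site_fc, ann)
    expect_setequal(got$kinase, names(oracle))
    for (k in got$kinase) {
      expect_equal(got$z[got$kinase == k], unname(oracle[[k]]["z"]),
                   tolerance = 1e-10)
      expect_equal(got$m[got$kinase == k], unname(oracle[[k]]["m"]),
                   ignore_attr = TRUE)
      expect_equal(got$p[got$kinase == k], unname(oracle[[k]]["p"]),
                   tolerance = 1e-10)
    }
  }
})

test_that("ksea z is invariant to shifting and positive scaling of log2 FCs", {
  set.seed(77)
  site_fc <- data.frame(gene = sprintf("g%03d", 1:100), site = "S1",
                        log2fc = rnorm(100))
  ann <- data.frame(kinase = rep(c("K1", "K2", "K3"), each = 8),
                    substrate = sprintf("g%03d", sample(100, 24)), site = "S1")
  base <- ksea_scores(site_fc, ann)
  shifted <- site_fc; shifted$log2fc <- shifted$log2fc + 3.7
  scaled <- site_fc; scaled$log2fc <- scaled$log2fc * 2.5
  expect_equal(ksea_scores(shifted, ann)$z, base$z, tolerance = 1e-12)
  expect_equal(ksea_scores(scaled, ann)$z, base$z, tolerance = 1e-12)
})

test_that("significance filter enforces p < 0.05 and m >= 3 jointly", {
  res <- data.frame(kinase = c("a", "b", "c", "d"),
                    m = c(5L, 2L, 3L, 10L),
                    z = c(3, 3, 1, -3),
                    p = c(0.01, 0.01, 0.3, 0.002))
  kept <- significant_kinases(res)
  expect_setequal(kept$kinase, c("a", "d"))
  # brute-force re-filter on a random list
  set.seed(3)
  rnd <- data.frame(kinase = paste0("k", 1:50), m = sample(1:8, 50, TRUE),
                    z = rnorm(50), p = runif(50, 0, 0.2))
  expect_equal(significant_kinases(rnd)$kinase,
               rnd$kinase[rnd$p < 0.05 & rnd$m >= 3])
})

test_that("kinome-group annotation maps known kinases and tallies groups", {
  res <- data.frame(kinase = c("MAPK3", "AURKB", "NOVELKIN1"), m = 3L,
                    z = c(2, -2, 1), p = 0.01, stringsAsFactors = FALSE)
  ann <- annotate_kinome_group(res)
  expect_equal(ann$kinome_group, c("CMGC", "AGC", "unknown"))
  tally <- kinome_group_tally(ann)
  expect_equal(sum(tally$n), 3L)
  expect_true(all(c("CMGC", "AGC", "unknown") %in% tally$kinome_group))
})

test_that("subtype kinome comparison does exact set arithmetic", {
  r1 <- data.frame(kinase = c("A", "B", "C"), z = c(1, -2, 3))
  r2 <- data.frame(kinase = c("B", "C", "D"), z = c(2, 3, -1))
  cmp <- compare_subtype_kinomes(r1, r2)
  expect_equal(cmp$n_common, 2L)
  expect_equal(cmp$n_idc_only, 1L)
  expect_equal(cmp$n_ilc_only, 1L)
  expect_equal(cmp$direction_table$kinase, "B")   # z flips sign

  same <- compare_subtype_kinomes(r1, r1)
  expect_equal(same$n_common, 3L)
  expect_equal(same$n_idc_only + same$n_ilc_only, 0L)
  disj <- compare_subtype_kinomes(r1, data.frame(kinase = "Z", z = 1))
  expect_equal(disj$n_common, 0L)
})

test_that("a planted kinase dominates the activated set", {
  ann <- simulate_kinase_substrates(n_kinases = 15, substrates_per_kinase = 15,
                                    n_genes = 400, seed = 61)
  sim <- simulate_phospho_dataset(
    sim_params(n_sites = 1500, planted_kinases = c(KIN007 = 1.0), seed = 62),
    ann)
  X <- patient_coverage_filter(
    global_normalize(to_log2(site_matrix(filter_sites(sim$sites))))$matrix,
    sim$design)
  d <- differential_screen(X, sim$design, "IDC")
  res <- ksea_scores(site_fc_for_ksea(d[!is.na(d$mean_fc), ]), ann)
  expect_equal(res$kinase[which.max(abs(res$z))], "KIN007")
  expect_lt(res$p[res$kinase == "KIN007"], 0.05)
  expect_equal(res$direction[res$kinase == "KIN007"], "activated")
})
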