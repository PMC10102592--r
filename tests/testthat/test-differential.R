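test_that("patient coverage filter applies a strict >60% rule over all pairs", {
  design <- toy_design(5)            # 10 pairs
  X <- toy_matrix(design, 3, seed = 1)
  pr <- design$patient[design$tissue == "tumor"]
  # feature 1: complete in 7 pairs; feature 2: 6 pairs; feature 3: all 10
  kill <- function(X, feat, patients) {
    for (p in patients) X$values[feat, paste0(p, "_T")] <- NA
    X
  }
  X <- kill(X, 1, pr[1:3])
  X <- kill(X, 2, pr[1:4])
  kept <- patient_coverage_filter(X, design)
  expect_setequal(rownames(kept$values), c("F001", "F003"))  # 6/10 = 0.60 not > 0.60

  # brute-force recount on random missingness
  set.seed(7)
  Y <- toy_matrix(design, 100, seed = 7)
  Y$values[sample(length(Y$values), 300)] <- NA
  kept2 <- patient_coverage_filter(Y, design)
  tum <- paste0(pr, "_T"); nat <- paste0(pr, "_N")
  brute <- rownames(Y$values)[vapply(seq_len(100), function(i) {
    sum(!is.na(Y$values[i, tum]) & !is.na(Y$values[i, nat])) > 6
  }, logical(1))]
  expect_gt(length(brute), 0)
  expect_identical(sort(rownames(kept2$values)), sort(brute))
})

test_that("pair fold changes divide tumor by NAT and propagate missingness", {
  design <- toy_design(5)
  X <- toy_matrix(design, 5, seed = 2)
  X$values[1, "P01_T"] <- 20; X$values[1, "P01_N"] <- 10
  X$values[2, "P02_N"] <- NA
  fc <- pair_fold_changes(X, design, "IDC")
  expect_equal(fc[1, "P01"], 2.0, ignore_attr = TRUE)
  expect_true(is.na(fc[2, "P02"]))
  # element-wise hand division on the whole grid
  tum <- X$values[, paste0(colnames(fc), "_T")]
  nat <- X$values[, paste0(colnames(fc), "_N")]
  expect_equal(unname(fc), unname(tum / nat))
  expect_error(pair_fold_changes(to_log2(X), design, "IDC"), "linear")
})

test_that("welch test matches its closed form and the stats::t.test oracle", {
  design <- toy_design(3)
  X <- intensity_matrix(matrix(2, 1, 12, dimnames = list("F1", toy_design(3)$sample)),
                        "linear")
  # frozen worked example: tumor log2 (1,2,3) vs NAT log2 (4,5,6)
  v <- matrix(NA_real_, 2, 12, dimnames = list(c("F1", "F2"), design$sample))
  v["F1", c("P01_T", "P02_T", "P03_T")] <- c(1, 2, 3)
  v["F1", c("P01_N", "P02_N", "P03_N")] <- c(4, 5, 6)
  v["F2", c("P01_T", "P02_T", "P03_T")] <- c(1, 2, 3)
  v["F2", c("P01_N", "P02_N", "P03_N")] <- c(1, 2, 3)
  Xl <- intensity_matrix(v, "log2")
  p <- welch_test(Xl, design, "IDC")
  expect_equal(unname(p["F1"]), 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  expect_equal(unname(p["F1"]), 0.02131164, tolerance = 1e-6)
  expect_equal(unname(p["F2"]), 1.0)  # identical groups

  # oracle agreement on 100 random small instances
  set.seed(123)
  for (i in 1:100) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- rnorm(na); b <- rnorm(nb, sd = runif(1, 0.5, 2))
    pts <- sprintf("Q%02d", seq_len(max(na, nb)))
    dd <- paired_design(data.frame(
      sample = c(paste0(pts, "_T"), paste0(pts, "_N")),
      patient = c(pts, pts),
      tissue = rep(c("tumor", "NAT"), each = length(pts)),
      subtype = "IDC", stringsAsFactors = FALSE))
    mm <- matrix(NA_real_, 1, nrow(dd), dimnames = list("F1", dd$sample))
    mm[1, paste0(pts[seq_len(na)], "_T")] <- a
    mm[1, paste0(pts[seq_len(nb)], "_N")] <- b
    got <- welch_test(intensity_matrix(mm, "log2"), dd, "IDC")
    expect_equal(unname(got), t.test(a, b)$p.value, tolerance = 1e-10)
  }

  # label symmetry and the <2-present rule
  swap <- design; swap$tissue <- ifelse(swap$tissue == "tumor", "NAT", "tumor")
  expect_equal(welch_test(Xl, design, "IDC"), welch_test(Xl, paired_design(swap), "IDC"))
  v2 <- v; v2["F1", c("P02_N", "P03_N")] <- NA
  expect_true(is.na(welch_test(intensity_matrix(v2, "log2"), design, "IDC")["F1"]))
})

test_that("concordance fractions count pairs at or beyond the threshold", {
  cfg <- screen_config()
  fc <- rbind(a = c(1.6, 1.7, 1.52, 1.1, 0.9),
              b = c(2.0, 1.8, 1.6, 1.55, 0.9),
              c = rep(1.0, 5))
  res <- concordance_fractions(fc, cfg)
  expect_equal(res$frac_up, c(3 / 5, 4 / 5, 0))
  expect_equal(res$frac_down, c(0, 0, 0))
  # present pairs are the denominator
  fc2 <- rbind(d = c(1.6, 1.7, NA, NA, 0.5))
  res2 <- concordance_fractions(fc2, cfg)
  expect_equal(res2$frac_up, 2 / 3)
  expect_equal(res2$frac_down, 1 / 3)
  res3 <- concordance_fractions(rbind(e = rep(NA_real_, 5)), cfg)
  expect_true(is.na(res3$frac_up) && is.na(res3$frac_down))
})

test_that("three-criterion call uses strict thresholds jointly", {
  cfg <- screen_config()
  expect_equal(call_differential(2.0, 0.01, 0.8, 0, cfg), "up")
  # 0.6 concordance is NOT more than 60%: 3/5 pairs is not enough
  expect_equal(call_differential(2.0, 0.01, 0.6, 0, cfg), "ns")
  expect_equal(call_differential(1.4, 0.001, 0.8, 0, cfg), "ns")
  expect_equal(call_differential(0.4, 0.01, 0, 0.8, cfg), "down")
  expect_equal(call_differential(2.0, 0.05, 0.8, 0, cfg), "ns")   # p not < 0.05
  expect_equal(call_differential(NA, 0.01, 0.8, 0, cfg), "ns")
})

test_that("raising any threshold never grows the called set", {
  sim <- simulate_protein_dataset(sim_params(n_proteins = 400, seed = 21))
  X <- patient_coverage_filter(global_normalize(to_log2(sim$matrix))$matrix,
                               sim$design)
  base_cfg <- screen_config()
  base <- differential_screen(X, sim$design, "IDC", base_cfg)
  called <- function(d) d$feature[d$call != "ns"]
  tighter <- list(
    screen_config(p_threshold = 0.01),
    screen_config(fc_up = 2.0, fc_down = 0.5),
    screen_config(concordance_fraction = 0.79))
  for (cfg in tighter) {
    d <- differential_screen(X, sim$design, "IDC", cfg)
    expect_true(all(called(d) %in% called(base)))
  }
})

test_that("screen is conservative on null data and powerful on planted effects", {
  # null control: fraction called stays below the nominal 5% over seeds
  null_rate <- vapply(1:20, function(s) {
    sim <- simulate_protein_dataset(
      sim_params(n_proteins = 200, frac_differential = 0, seed = 100 + s))
    X <- patient_coverage_filter(global_normalize(to_log2(sim$matrix))$matrix,
                                 sim$design)
    d <- differential_screen(X, sim$design, "IDC")
    mean(d$call != "ns")
  }, numeric(1))
  expect_lt(mean(null_rate), 0.05)

  # power: planted FC 3.0, sd 0.5, 5 pairs, fully observed
  power <- vapply(1:5, function(s) {
    sim <- simulate_protein_dataset(
      sim_params(n_proteins = 500, missing_rate = 0, seed = 200 + s))
    X <- patient_coverage_filter(global_normalize(to_log2(sim$matrix))$matrix,
                                 sim$design)
    d <- differential_screen(X, sim$design, "IDC")
    tl <- sim$truth$feature_log2fc[d$feature, "IDC"]
    hit <- (d$call == "up" & tl > 0) | (d$call == "down" & tl < 0)
    sum(hit) / sum(sim$truth$feature_log2fc[, "IDC"] != 0)
  }, numeric(1))
  expect_gte(median(power), 0.80)
})
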