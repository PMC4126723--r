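# Scalar volumetrics: global gray-matter adjustment, group comparisons,
# case z-scores on adjusted volumes.

make_records <- function(n_ws = 10, n_td = 10, seed = 31,
                         slope = 0.002, noise = 0.05) {
  set.seed(seed)
  n <- n_ws + n_td
  gm <- c(rnorm(n_ws, 620, 60), rnorm(n_td, 700, 65))
  data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = c(rep("WS", n_ws), rep("TD", n_td)),
    total_gm = gm,
    lt_amygdala = 1.7 + slope * (gm - 660) + rnorm(n, 0, noise),
    stringsAsFactors = FALSE)
}

test_that("adjustment is the identity when total GM does not vary the trend", {
  rec <- make_records()
  rec$total_gm <- 650  # constant
  expect_error(adjust_volume(rec, "lt_amygdala"), "zero variance")
  # near-constant: slope is irrelevant, residual + mean restores raw values
  rec2 <- make_records(slope = 0)
  adj <- adjust_volume(rec2, "lt_amygdala")
  # raw and adjusted agree up to the (tiny, noise-fit) slope term
  expect_equal(mean(adj), mean(rec2$lt_amygdala), tolerance = 1e-10)
})

test_that("a volume exactly proportional to total GM adjusts to a constant", {
  rec <- make_records()
  rec$lt_amygdala <- 0.0025 * rec$total_gm
  adj <- adjust_volume(rec, "lt_amygdala")
  ref <- rec$group %in% c("WS", "TD")
  expect_equal(diff(range(adj[ref])), 0, tolerance = 1e-12)
  expect_equal(adj[1], mean(rec$lt_amygdala[ref]), tolerance = 1e-12)
})

test_that("a case at the reference mean total GM keeps its raw volume", {
  rec <- make_records()
  ref <- rec$group %in% c("WS", "TD")
  case <- data.frame(subject_id = "case", group = "AWSdel",
                     total_gm = mean(rec$total_gm[ref]), lt_amygdala = 2.2,
                     stringsAsFactors = FALSE)
  all_rec <- rbind(rec, case)
  adj <- adjust_volume(all_rec, "lt_amygdala")
  # regression identity at the centroid: prediction equals the grand mean
  expect_equal(adj[nrow(all_rec)], 2.2, tolerance = 1e-10)
})

test_that("residual adjustment preserves the reference mean and decorrelates", {
  rec <- make_records(n_ws = 25, n_td = 25, seed = 32)
  adj <- adjust_volume(rec, "lt_amygdala")
  ref <- rec$group %in% c("WS", "TD")
  expect_equal(mean(adj[ref]), mean(rec$lt_amygdala[ref]), tolerance = 1e-10)
  expect_lt(abs(cor(adj[ref], rec$total_gm[ref])), 1e-10)
})

test_that("ratio adjustment scales by the reference mean total GM", {
  rec <- make_records()
  adj <- adjust_volume(rec, "lt_amygdala", method = "ratio")
  ref <- rec$group %in% c("WS", "TD")
  gm_ref <- mean(rec$total_gm[ref])
  expect_equal(adj, rec$lt_amygdala * gm_ref / rec$total_gm)
})

test_that("missing values propagate as NA and small references error", {
  rec <- make_records()
  rec$lt_amygdala[3] <- NA
  adj <- adjust_volume(rec, "lt_amygdala")
  expect_true(is.na(adj[3]))
  expect_false(anyNA(adj[-3]))
  expect_error(adjust_volume(rec[1:2, ], "lt_amygdala"), "at least 3")
})

test_that("group comparison matches a hand-computed Welch formula", {
  set.seed(33)
  rec <- data.frame(subject_id = sprintf("s%d", 1:100),
                    group = rep(c("WS", "TD"), each = 50),
                    score = c(rnorm(50, 0, 1), rnorm(50, 1, 1)),
                    stringsAsFactors = FALSE)
  out <- compare_groups(rec, "score")
  ws <- rec$score[1:50]; td <- rec$score[51:100]
  t_hand <- (mean(ws) - mean(td)) / sqrt(var(ws) / 50 + var(td) / 50)
  expect_equal(out$statistic, t_hand, tolerance = 1e-12)
  expect_equal(out$test, "welch_t")

  # identical group distributions: t = 0, p = 1
  rec2 <- rec; rec2$score <- rep(rec$score[1:50], 2)
  out2 <- compare_groups(rec2, "score")
  expect_equal(out2$statistic, 0)
  expect_equal(out2$p, 1)
})

test_that("group comparison is antisymmetric under label exchange", {
  rec <- make_records(seed = 34)
  a <- compare_groups(rec, "lt_amygdala")
  rec_sw <- rec
  rec_sw$group <- ifelse(rec$group == "WS", "TD", "WS")
  b <- compare_groups(rec_sw, "lt_amygdala")
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("sex distributions reproduce the published chi-square", {
  # 19M/23F WS vs 16M/24F TD -> continuity-corrected chi-square 0.07, p 0.79
  rec <- data.frame(
    subject_id = sprintf("s%d", 1:82),
    group = c(rep("WS", 42), rep("TD", 40)),
    sex = c(rep("M", 19), rep("F", 23), rep("M", 16), rep("F", 24)),
    stringsAsFactors = FALSE)
  out <- compare_groups(rec, "sex")
  expect_equal(out$test, "chi_square")
  expect_equal(round(out$statistic, 2), 0.07)
  # computed p is 0.798; the published table prints 0.79 (unrounded chi2)
  expect_lt(abs(out$p - 0.79), 0.011)
})

test_that("case z on adjusted amygdala volume matches the published value", {
  # adjusted case volume 2.27 ml against the TD adjusted law (1.60 +/- 0.33):
  # z = 2.03; the published table prints 2.01 from unrounded summaries
  z <- zscore_scalar(2.27, list(mean = 1.60, sd = 0.33))
  expect_equal(z, 2.03, tolerance = 0.05)
})

test_that("case_volume_z recovers a known generative z within sampling error", {
  set.seed(35)
  n <- 400
  rec <- data.frame(
    subject_id = sprintf("s%03d", 1:n),
    group = rep(c("WS", "TD"), each = n / 2),
    total_gm = rnorm(n, 660, 60),
    stringsAsFactors = FALSE)
  # volume independent of total_gm; TD law N(1.6, 0.3), WS law N(1.8, 0.3)
  rec$lt_amygdala <- ifelse(rec$group == "WS", rnorm(n, 1.8, 0.3),
                            rnorm(n, 1.6, 0.3))
  case <- data.frame(subject_id = "case", group = "AWSdel",
                     total_gm = 660, lt_amygdala = 1.6 + 2 * 0.3,
                     stringsAsFactors = FALSE)
  out <- case_volume_z(rbind(rec, case), "case", "lt_amygdala")
  expect_equal(out$z_vs_TD, 2, tolerance = 2 / sqrt(n / 2) + 0.15)
  # case at the reference mean scores ~0
  case0 <- data.frame(subject_id = "c0", group = "AWSdel", total_gm = 660,
                      lt_amygdala = mean(rec$lt_amygdala[rec$group == "TD"]),
                      stringsAsFactors = FALSE)
  out0 <- case_volume_z(rbind(rec, case0), "c0", "lt_amygdala")
  expect_lt(abs(out0$z_vs_TD), 0.2)
})

test_that("the Welch t-map is near the closed-form t on iid groups", {
  dim3 <- c(5, 5, 5)
  mask <- full_mask(dim3)
  set.seed(36)
  ws <- rand_cohort(12, dim3, mu = 1)
  td <- rand_cohort(12, dim3, mu = 0)
  tm <- group_tmap(ws, td, mask)
  # oracle at one voxel via t.test
  v <- c(2, 3, 4)
  a <- sapply(ws, function(im) im$data[v[1], v[2], v[3]])
  b <- sapply(td, function(im) im$data[v[1], v[2], v[3]])
  tt <- t.test(a, b, var.equal = FALSE)
  expect_equal(tm$t[v[1], v[2], v[3]], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(tm$df[v[1], v[2], v[3]], unname(tt$parameter), tolerance = 1e-8)
})
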