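test_that("confusion counts match a per-pixel loop and sum to the pixel count", {
  set.seed(1)
  for (k in 1:5) {
    pr <- random_mask_pair(k)
    cc <- confusion(pr$a, pr$b)
    bc <- brute_confusion(pr$a, pr$b)
    expect_identical(cc$tp, bc$tp)
    expect_identical(cc$fp, bc$fp)
    expect_identical(cc$fn, bc$fn)
    expect_identical(cc$tn, bc$tn)
    expect_identical(cc$tp + cc$fp + cc$fn + cc$tn, length(pr$a))
  }
  expect_error(confusion(matrix(0.5, 2, 2), matrix(0L, 2, 2)), "binary")
  expect_error(confusion(matrix(0L, 2, 2), matrix(0L, 3, 3)), "identical dimensions")
})

test_that("dsc and voe handle exact, disjoint and degenerate cases", {
  m <- matrix(0L, 32, 32); m[5:10, 5:10] <- 1L
  expect_equal(dsc(confusion(m, m)), 1)
  expect_equal(voe(m, m), 0)
  m2 <- matrix(0L, 32, 32); m2[20:25, 20:25] <- 1L
  expect_equal(dsc(confusion(m, m2)), 0)
  expect_equal(voe(m, m2), 100)
  # arithmetic example: tp=50, fp=10, fn=10
  expect_equal(dsc(list(tp = 50, fp = 10, fn = 10, tn = 0)), 100 / 120)
  # both-empty conventions
  z <- matrix(0L, 8, 8)
  expect_equal(dsc(confusion(z, z)), 1)
  expect_equal(voe(z, z), 0)
})

test_that("voe satisfies the algebraic identity with dsc", {
  for (k in 1:20) {
    pr <- random_mask_pair(100 + k)
    d <- dsc(confusion(pr$a, pr$b))
    expect_equal(voe(pr$a, pr$b), (1 - d / (2 - d)) * 100, tolerance = 1e-12)
  }
})

test_that("surface extraction matches hand enumeration", {
  m <- matrix(0L, 5, 5); m[2:4, 2:4] <- 1L
  s <- surface(m)
  expect_equal(nrow(s$coords), 8)              # 3x3 square: all but the centre
  expect_false(any(s$coords[, 1] == 3 & s$coords[, 2] == 3))
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  expect_equal(unname(surface(one)$coords), matrix(c(3, 3), 1))
  expect_equal(nrow(surface(matrix(0L, 5, 5))$coords), 0)
  # border pixels count as surface (image border is background)
  full <- matrix(1L, 4, 4)
  expect_equal(nrow(surface(full)$coords), 12)
  # 8-connectivity marks at least as many pixels as 4-connectivity
  pr <- random_mask_pair(7)
  expect_gte(nrow(surface(pr$a, connectivity = 8L)$coords),
             nrow(surface(pr$a, connectivity = 4L)$coords))
  s4 <- unname(surface(pr$a)$coords)
  b4 <- brute_surface(pr$a, 4L)
  expect_equal(s4[order(s4[, 1], s4[, 2]), , drop = FALSE],
               b4[order(b4[, 1], b4[, 2]), , drop = FALSE])
})

test_that("asd agrees with the all-pairs oracle, including anisotropic spacing", {
  m <- matrix(0L, 20, 20); m[4:13, 4:13] <- 1L
  expect_equal(asd(m, m), 0)
  # two single pixels 5 px apart at 1 mm spacing
  a <- matrix(0L, 12, 12); a[3, 3] <- 1L
  b <- matrix(0L, 12, 12); b[3, 8] <- 1L
  expect_equal(asd(a, b), 5)
  # shifted square vs oracle
  m2 <- matrix(0L, 20, 20); m2[7:16, 4:13] <- 1L
  expect_equal(asd(m, m2), brute_asd(m, m2), tolerance = 1e-12)
  for (k in 1:6) {
    pr <- random_mask_pair(200 + k)
    expect_equal(asd(pr$a, pr$b), brute_asd(pr$a, pr$b), tolerance = 1e-9)
    sp <- c(1.6, 0.7)
    expect_equal(asd(pr$a, pr$b, spacing = sp), brute_asd(pr$a, pr$b, sp),
                 tolerance = 1e-9)
    # symmetry
    expect_equal(asd(pr$a, pr$b), asd(pr$b, pr$a), tolerance = 1e-12)
  }
  expect_warning(v <- asd(matrix(0L, 4, 4), a[1:4, 1:4]), "empty")
  expect_true(is.na(v))
})

test_that("accuracy, sensitivity, specificity follow their definitions", {
  c1 <- list(tp = 100, tn = 800, fp = 50, fn = 50)
  expect_equal(unname(acc_sen_spe(c1)), c(0.9, 2 / 3, 800 / 850))
  m <- matrix(0L, 8, 8); m[2:3, 2:3] <- 1L
  expect_equal(unname(acc_sen_spe(confusion(m, m))), c(1, 1, 1))
  # truth all background, predicted correctly: SEN undefined, SPE = 1
  z <- matrix(0L, 8, 8)
  r <- acc_sen_spe(confusion(z, z))
  expect_true(is.na(r[["sen"]]))
  expect_equal(r[["spe"]], 1)
})

test_that("aggregation reports mean/sd/max/min and is permutation invariant", {
  row1 <- tibble::tibble(dsc = 0.8, voe = 10, asd = 0.5, acc = 0.9, sen = 0.7,
                         spe = 0.95, both_empty = FALSE)
  rep1 <- aggregate_metrics(row1)
  s <- rep1$summary
  expect_equal(s$mean[s$metric == "dsc"], 0.8)
  expect_equal(s$sd[s$metric == "dsc"], 0)
  expect_equal(s$max[s$metric == "dsc"], s$min[s$metric == "dsc"])

  rows <- tibble::tibble(dsc = c(0.8, 0.9, 1.0), voe = c(20, 10, 0),
                         asd = c(1, 0.5, 0), acc = c(0.9, 0.95, 1),
                         sen = c(0.7, 0.8, 0.9), spe = c(0.9, 0.95, 1),
                         both_empty = FALSE)
  r <- aggregate_metrics(rows)$summary
  expect_equal(r$mean[r$metric == "dsc"], 0.9)
  expect_equal(r$max[r$metric == "dsc"], 1.0)
  expect_equal(r$min[r$metric == "dsc"], 0.8)
  expect_equal(r$sd[r$metric == "dsc"], sd(c(0.8, 0.9, 1.0)))
  shuffled <- aggregate_metrics(rows[c(3, 1, 2), ])$summary
  expect_equal(r, shuffled)
  # min <= mean <= max throughout
  expect_true(all(r$min <= r$mean & r$mean <= r$max))
  # NA handling
  rows$asd[2] <- NA
  r2 <- aggregate_metrics(rows)$summary
  expect_equal(r2$n[r2$metric == "asd"], 2L)
  expect_equal(r2$n_missing[r2$metric == "asd"], 1L)
})

test_that("paired Wilcoxon behaves at the degenerate and shifted extremes", {
  a <- c(0.8, 0.85, 0.9, 0.82, 0.88)
  expect_warning(r0 <- wilcoxon_paired(a, a), "zero")
  expect_equal(r0$p_value, 1)
  set.seed(42)
  b <- runif(20, 0.5, 0.9)
  r1 <- wilcoxon_paired(b + 0.3, b)
  expect_lt(r1$p_value, 0.05)
  r2 <- wilcoxon_paired(b, b + 0.3)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, -r2$statistic)
  expect_error(wilcoxon_paired(1:3, 1:3), "length")
})

test_that("metric report files carry the benchmark-table fields", {
  dir <- withr::local_tempdir()
  rows <- tibble::tibble(dsc = c(0.9, 0.95), voe = c(18, 9), asd = c(0.8, 0.4),
                         acc = c(0.97, 0.98), sen = c(0.93, 0.96),
                         spe = c(0.96, 0.97), both_empty = FALSE)
  rep <- aggregate_metrics(rows)
  csvp <- file.path(dir, "r.csv"); jsp <- file.path(dir, "r.json")
  write_metric_report(rep, csvp, jsp)
  back <- read.csv(csvp)
  expect_equal(nrow(back), 2)
  js <- jsonlite::read_json(jsp, simplifyVector = TRUE)
  expect_true(all(c("VOE", "ASD_mm", "DSC_max", "DSC_min", "DSC_mean",
                    "ACC", "SEN", "SPE") %in% names(js)))
  expect_equal(js$DSC_mean, 0.925)
})
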