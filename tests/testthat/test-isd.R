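test_that("ISD ESV matching accepts near-identical variants, rejects unrelated ones", {
  set.seed(4)
  isd <- random_seq(170)
  two_sub <- isd
  substr(two_sub, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                     substr(isd, 30, 30))[1]
  substr(two_sub, 120, 120) <- setdiff(c("A", "C", "G", "T"),
                                       substr(isd, 120, 120))[1]
  feats <- c(exact = isd, near = two_sub, other = random_seq(170),
             short = substr(isd, 1, 60))
  hit <- match_isd_esvs(feats, isd)
  expect_setequal(hit, c("exact", "near"))  # ~98.8% identity passes 0.95
  expect_error(match_isd_esvs(feats, ""), "empty")
})

test_that("collapse_isd sums matched features and conserves sample totals", {
  cnt <- matrix(c(5, 90, 10, 2, 30, 0, 0, 7), 2, 4, byrow = TRUE,
                dimnames = list(c("s1", "s2"),
                                c("A", "esv1", "esv2", "B")))
  ft <- feature_table(cnt)
  out <- collapse_isd(ft, c("esv1", "esv2"))
  expect_equal(unname(out$counts[, "ISD"]), c(100, 0))
  expect_equal(rowSums(out$counts), rowSums(cnt))
  expect_equal(out$isd_features, "ISD")
  expect_warning(collapse_isd(ft, character()), "zero-count")
  # conservation across random tables
  set.seed(10)
  for (k in 1:50) {
    m <- matrix(rpois(5 * 8, 20), 5, 8,
                dimnames = list(paste0("s", 1:5), paste0("f", 1:8)))
    picked <- sample(colnames(m), sample(1:3, 1))
    out <- collapse_isd(feature_table(m), picked)
    expect_equal(rowSums(out$counts), rowSums(m))
  }
})

test_that("ISD ratios are correct, scale-invariant, and flag zero-ISD samples", {
  cnt <- matrix(c(10, 30, 10, 5, 0, 0), 2, 3, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("A", "B", "ISD")))
  rt <- isd_normalize(feature_table(cnt, isd_features = "ISD"))
  expect_equal(rt$ratios["s1", ], c(A = 1, B = 3))
  expect_equal(unname(rt$status), c("ok", "no_isd"))
  expect_true(all(is.na(rt$ratios["s2", ])))
  # proportions give identical ratios (scale invariance, exact)
  prop <- cnt / rowSums(cnt)
  rt2 <- isd_normalize(feature_table(prop, isd_features = "ISD"))
  expect_equal(rt2$ratios["s1", ], rt$ratios["s1", ])
  set.seed(20)
  for (k in 1:25) {
    m <- matrix(rpois(3 * 6, 30) + 1, 3, 6,
                dimnames = list(paste0("s", 1:3),
                                c(paste0("f", 1:5), "ISD")))
    r1 <- isd_normalize(feature_table(m, isd_features = "ISD"))$ratios
    c_ <- runif(1, 0.1, 10)
    r2 <- isd_normalize(feature_table(m * c_, isd_features = "ISD"))$ratios
    expect_equal(r1, r2)
  }
})

test_that("ratios are unchanged by adding or dropping non-ISD features", {
  set.seed(21)
  m <- matrix(rpois(4 * 7, 25) + 1, 4, 7,
              dimnames = list(paste0("s", 1:4),
                              c(paste0("f", 1:6), "ISD")))
  base <- isd_normalize(feature_table(m, isd_features = "ISD"))$ratios
  drop1 <- isd_normalize(feature_table(m[, -3], isd_features = "ISD"))$ratios
  expect_equal(drop1, base[, colnames(drop1)])
  extra <- cbind(m, new = rpois(4, 40))
  add1 <- isd_normalize(feature_table(extra, isd_features = "ISD"))$ratios
  expect_equal(add1[, colnames(base)], base)
})

test_that("coligo features are excluded from normalized output", {
  cnt <- matrix(c(10, 4, 2, 10), 1, 4,
                dimnames = list("s1", c("A", "coligo01", "coligo02", "ISD")))
  rt <- isd_normalize(feature_table(cnt, isd_features = "ISD",
                                    coligo_features = c("coligo01",
                                                        "coligo02")))
  expect_equal(colnames(rt$ratios), "A")
})

test_that("absolute abundance scales ratios by the spike amount with unit propagation", {
  cnt <- matrix(c(30, 10), 1, 2, dimnames = list("s1", c("A", "ISD")))
  rt <- isd_normalize(feature_table(cnt, isd_features = "ISD"))
  est <- absolute_abundance(rt, spike_design("s1", 100, unit = "copies"))
  expect_equal(unname(est["s1", "A"]), 300)
  expect_equal(attr(est, "unit"), "copies")
  expect_warning(absolute_abundance(rt, spike_design("s1", 0)), "zero")
  expect_error(absolute_abundance(rt, spike_design("other", 10)), "missing")
})

test_that("absolute abundance recovers known copy numbers under a fixed spike", {
  # wells differ in total biomass; the same absolute ISD amount is spiked
  # into each, so the ratio-times-amount chain must recover true copies
  set.seed(51)
  n_w <- 10; n_t <- 15; spike <- 100
  copies <- matrix(rlnorm(n_w * n_t, meanlog = 3, sdlog = 1), n_w, n_t,
                   dimnames = list(sprintf("w%02d", 1:n_w),
                                   sprintf("taxon_%02d", 1:n_t)))
  cnt <- t(vapply(1:n_w, function(w)
    rmultinom(1, 2e5, c(copies[w, ], ISD = spike))[, 1],
    integer(n_t + 1)))
  rownames(cnt) <- rownames(copies)
  rt <- isd_normalize(feature_table(cnt, isd_features = "ISD"))
  est <- absolute_abundance(rt, spike_design(rownames(cnt),
                                             rep(spike, n_w)))
  ok <- est > 0
  r <- cor(log(est[ok]), log(copies[ok]))
  expect_gt(r, 0.99)
  fit <- lm(log(est[ok]) ~ log(copies[ok]))
  expect_gt(coef(fit)[2], 0.95)
  expect_lt(coef(fit)[2], 1.05)
})

test_that("dilution check recovers slope 1 on exact data and 0 on flat data", {
  amounts <- 10^(0:4)
  p <- 0.001 * amounts / (1 + 0.001 * amounts)
  chk <- isd_dilution_check(p, amounts)
  expect_equal(chk$slope, 1, tolerance = 1e-10)
  expect_true(chk$monotone)
  flat <- isd_dilution_check(rep(0.05, 5), amounts)
  expect_equal(flat$slope, 0, tolerance = 1e-10)
  expect_false(flat$monotone)
  expect_error(isd_dilution_check(p[1:2], amounts[1:2]), "3 dilution")
  expect_error(isd_dilution_check(p[1:3], c(1, 2, 3)), "order of magnitude")
})

test_that("feature tables round-trip through TSV in both orientations", {
  cnt <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3,
                dimnames = list(c("s1", "s2"), c("fA", "fB", "ISD")))
  ft <- feature_table(cnt, isd_features = "ISD")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back <- read_feature_table(path, isd_features = "ISD")
  expect_equal(back$counts, ft$counts)
  # features-as-rows orientation
  path2 <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(feature_id = colnames(cnt), t(cnt), check.names = FALSE)
  write_tsv(df, path2)
  back2 <- read_feature_table(path2)
  expect_equal(back2$counts, cnt)
})
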