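test_that("the worked-example confusion counts give the textbook metrics", {
  cc <- ConfusionCounts(TP = 3L, FP = 2L, TN = 4L, FN = 1L, H = 6L)
  expect_equal(precision(cc), 0.6)
  expect_equal(recall(cc), 0.75)
  expect_equal(fScore(cc), 2 * 0.6 * 0.75 / (0.6 + 0.75))
  expect_equal(efficiency(cc), 0.5)
})

test_that("metric edge cases: zeros are zeros, empty denominators are NA", {
  z <- ConfusionCounts(TP = 0L, FP = 3L, TN = 2L, FN = 4L, H = 5L)
  expect_equal(precision(z), 0)
  expect_equal(recall(z), 0)
  expect_equal(fScore(z), 0)

  noHits <- ConfusionCounts(TP = 0L, FP = 0L, TN = 5L, FN = 3L, H = 0L)
  expect_message(p <- precision(noHits), "undefined")
  expect_true(is.na(p))
  expect_message(e <- efficiency(noHits), "undefined")
  expect_true(is.na(e))
  expect_message(f <- fScore(noHits), "undefined")
  expect_true(is.na(f))

  noOligos <- ConfusionCounts(TP = 0L, FP = 2L, TN = 5L, FN = 0L, H = 2L)
  expect_message(r <- recall(noOligos), "undefined")
  expect_true(is.na(r))

  expect_error(ConfusionCounts(2L, 1L, 1L, 1L, 2L), "TP \\+ FP")
})

test_that("F is the harmonic mean and is bracketed by P and R", {
  set.seed(14)
  for (rep in 1:25) {
    tp <- sample(1:20, 1); fp <- sample(0:20, 1)
    cc <- ConfusionCounts(tp, fp, sample(0:20, 1), sample(0:20, 1),
                          tp + fp + sample(0:10, 1))
    p <- precision(cc); r <- recall(cc); f <- fScore(cc)
    expect_equal(f, 2 / (1 / p + 1 / r), tolerance = 1e-12)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
    expect_lte(efficiency(cc), p + 1e-12)  # since H >= TP + FP
  }
})

test_that("confusion counts aggregate group hits and conserve totals", {
  ds <- tinyDataset(seed = 42)
  s <- SeedSet("11111111")
  cc <- confusionCounts(s, ds)
  nsec <- sum(vapply(oligoGroups(ds), function(g)
    length(secondarySequences(g)), integer(1)))
  expect_equal(cc@TP + cc@FP + cc@TN + cc@FN, nsec)
  expect_gte(cc@H, cc@TP + cc@FP)

  # independent recount from per-group reports
  tp <- fp <- tn <- fn <- h <- 0L
  for (grp in oligoGroups(ds)) {
    hr <- groupHits(s, grp)
    ol <- secondaryLabels(grp) == "oligo"
    tp <- tp + sum(hr@hit & ol); fp <- fp + sum(hr@hit & !ol)
    tn <- tn + sum(!hr@hit & !ol); fn <- fn + sum(!hr@hit & ol)
    h <- h + hr@totalHits
  }
  expect_equal(c(cc@TP, cc@FP, cc@TN, cc@FN, cc@H), c(tp, fp, tn, fn, h))

  # a weight-1 seed hits every secondary that shares any base with main
  all1 <- confusionCounts(SeedSet("1"), ds)
  expect_equal(all1@TP + all1@FP, nsec)
  expect_equal(all1@TN + all1@FN, 0L)
})

test_that("catalogue sweeps produce one row per (seed set, dataset)", {
  dir <- withr::local_tempdir()
  cat <- tinyCatalog(dir)
  ds <- list(ds1 = tinyDataset(1), ds2 = tinyDataset(2))
  tab <- suppressWarnings(sweepSeedCatalog(cat, ds, weights = 7:10))
  expect_equal(nrow(tab), nrow(cat@index) * 2L)
  expect_setequal(unique(tab$dataset), c("ds1", "ds2"))
  expect_true(all(tab$TP + tab$FP + tab$TN + tab$FN ==
                  4 * 8))  # groups x secondaries of the fixture
  ok <- !is.na(tab$efficiency) & !is.na(tab$precision)
  expect_true(all(tab$efficiency[ok] <= tab$precision[ok] + 1e-12))

  expect_warning(sweepSeedCatalog(cat, ds, weights = 7:12), "weight")
  single <- sweepSeedCatalog(cat, ds["ds1"], weights = 8)
  expect_equal(nrow(single), sum(cat@index$weight == 8))
})

test_that("best accuracy picks the argmax weight with lower-weight tie-break", {
  tab <- data.frame(
    seed_type = rep("contiguous", 6), k = 1L,
    weight = rep(c(9L, 10L, 11L), each = 2),
    dataset = rep(c("ds1", "ds2"), 3),
    TP = 1L, FP = 1L, TN = 1L, FN = 1L, H = 2L,
    precision = 0.5, recall = 0.5,
    fscore = c(0.80, 0.82, 0.90, 0.92, 0.90, 0.92),
    efficiency = 0.4)
  best <- bestAccuracy(tab)
  expect_equal(nrow(best), 1L)
  expect_equal(best$weight, 10L)        # ties at weights 10 and 11 -> lower
  expect_equal(best$mean_fscore, 0.91)
  expect_equal(best$sd_fscore, sd(c(0.90, 0.92)))

  one <- bestAccuracy(tab[tab$dataset == "ds1", ])
  expect_equal(one$sd_fscore, 0)        # single dataset -> stdev 0
})

test_that("bounded recall restricts and degrades gracefully", {
  tab <- data.frame(
    seed_type = rep(c("contiguous", "1seed"), each = 3),
    k = 1L, weight = rep(c(9L, 10L, 11L), 2), dataset = "ds1",
    TP = 1L, FP = 1L, TN = 1L, FN = 1L, H = 2L,
    precision = 0.5,
    recall = c(0.95, 0.90, 0.85, 0.99, 0.93, 0.88),
    fscore = c(0.80, 0.85, 0.90, 0.82, 0.88, 0.93),
    efficiency = c(0.40, 0.45, 0.50, 0.42, 0.47, 0.52))
  br <- boundedRecall(tab, bounds = c(0.9, 0.97, 0.999))
  expect_equal(nrow(br), 6L)
  # at bound 0.9 the best qualifying weights are 10 (contig) and 10 (1seed)
  b1 <- br[br$bound == 0.9, ]
  expect_equal(b1$weight[b1$seed_type == "contiguous"], 10L)
  expect_equal(b1$mean_fscore[b1$seed_type == "1seed"], 0.88)
  # bound above every recall -> NA cells, no crash
  b3 <- br[br$bound == 0.999, ]
  expect_true(all(is.na(b3$weight)))
  # a tiny bound imposes no restriction: same as the unrestricted best
  b0 <- boundedRecall(tab, bounds = 0.01)
  best <- bestAccuracy(tab)
  expect_equal(b0$mean_fscore[order(b0$seed_type)],
               best$mean_fscore[order(best$seed_type)])
})
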