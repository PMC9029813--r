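# A small screening fixture: class A molecules share a prototype bit
# pattern, decoys are disjoint from it, so TAN screening separates them.
make_separable_db <- function(n_active = 6, n_decoy = 20, f = 24) {
  proto <- c(rep(1, 8), rep(0, f - 8))
  act <- matrix(rep(proto, each = n_active), n_active)
  set.seed(100)
  dec <- matrix(0, n_decoy, f)
  for (i in seq_len(n_decoy)) {
    dec[i, sample(9:f, 5)] <- 1  # on-bits disjoint from the prototype
  }
  fingerprint_dataset(
    c(sprintf("act%02d", seq_len(n_active)), sprintf("dec%02d", seq_len(n_decoy))),
    c(rep("A", n_active), rep(background_label(), n_decoy)),
    rbind(act, dec))
}

test_that("reference selection is seeded and respects class size", {
  ds <- make_toy_dataset(12, 8, labels = c(rep("A", 10), "B", "B"), seed = 2)
  cfg <- screening_config(n_references = 10, seed = 3)
  expect_setequal(select_references(ds, "A", cfg), ds$ids[1:10])
  expect_identical(select_references(ds, "A", cfg),
                   select_references(ds, "A", cfg))
  expect_warning(r <- select_references(ds, "B", cfg), "using all")
  expect_setequal(r, c("m11", "m12"))
  expect_error(select_references(ds, "C", cfg), "unknown")
  # a larger class is actually subsampled
  ds2 <- make_toy_dataset(30, 8, labels = rep("A", 30), seed = 4)
  expect_length(select_references(ds2, "A", cfg), 10)
})

test_that("ranking orders by score with id tie-break and exclusion", {
  counts <- rbind(q = c(1, 1, 0, 0),
                  b = c(1, 1, 0, 0),
                  a = c(1, 1, 0, 0),
                  c = c(0, 0, 1, 1))
  ds <- fingerprint_dataset(c("q", "b", "a", "c"), rep("A", 4), counts)
  cfg <- screening_config(variant = "binary", seed = 1)
  rk <- rank_database("q", binarize(ds), cfg)
  # a and b tie at 1.0 -> id ascending; query excluded
  expect_identical(rk$id, c("a", "b", "c"))
  expect_equal(rk$score[1:2], c(1, 1))
  expect_false("q" %in% rk$id)
  cfg$exclude_reference <- FALSE
  expect_true("q" %in% rank_database("q", binarize(ds), cfg)$id)
  expect_error(rank_database("zz", ds, cfg), "unknown")
})

test_that("recall at a cutoff does the stated arithmetic", {
  ranked <- sprintf("m%04d", 1:1000)
  actives <- c(sprintf("m%04d", c(2, 5, 9)), sprintf("x%02d", 1:17))
  # k = 10 at 1% of 1000; 3 of the 20 actives are in the top 10
  expect_equal(recall_at_cutoff(ranked, actives, 1, 1000), 15)
  expect_equal(recall_at_cutoff(ranked, actives, 100, 1000), 15)
  expect_equal(recall_at_cutoff(ranked, sprintf("m%04d", 1:20), 100, 1000), 100)
  # k never drops below one molecule
  expect_equal(recall_at_cutoff(c("a", "b"), "a", 0.001, 2), 100)
  expect_error(recall_at_cutoff(ranked, character(0), 1, 1000), "nonempty")
  expect_error(recall_at_cutoff(ranked, "a", 1, 999), "db_size")
})

test_that("recall equals a brute-force oracle and is monotone in cutoff", {
  set.seed(55)
  for (rep in 1:25) {
    db <- sample(500:1500, 1)
    ranked <- sample(sprintf("m%05d", seq_len(db)))
    actives <- sample(ranked, 25)
    cuts <- sort(runif(4, 0.5, 60))
    recs <- vapply(cuts, function(p) {
      recall_at_cutoff(ranked, actives, p, db)
    }, numeric(1))
    # brute force: literal count of actives above the cutoff position
    k <- max(1, round(cuts[2] * db / 100))
    hits <- 0
    for (id in actives) if (match(id, ranked) <= k) hits <- hits + 1
    expect_equal(recs[2], 100 * hits / 25)
    expect_true(all(diff(recs) >= 0))
  }
})

test_that("mean recall under random ranking concentrates at the cutoff", {
  # hypergeometric mean: E[recall%] = cutoff% for a random ranking
  set.seed(77)
  db <- 400; n_act <- 20; cutoff <- 5
  ids <- sprintf("m%04d", seq_len(db))
  actives <- ids[1:n_act]
  recs <- replicate(10000, {
    recall_at_cutoff(sample(ids), actives, cutoff, db)
  })
  expect_lt(abs(mean(recs) - cutoff), 1)
})

test_that("screening a class averages per-reference recalls", {
  db <- make_separable_db()
  dbb <- binarize(db)
  cfg <- screening_config(n_references = 1, cutoffs = c(25, 50),
                          variant = "binary", seed = 8)
  # separable class: all remaining actives duplicate the query pattern,
  # k at 25% of 25 molecules is >= class size -> full recall
  expect_no_warning(res <- screen_class(dbb, "A", cfg))
  expect_equal(unname(res), c(100, 100))

  # per-reference recalls average: two explicit references with known
  # recalls produce their mean
  half <- dbb
  half$counts["act02", ] <- dbb$counts["dec01", ]  # act02 now looks decoy-like
  m2 <- screen_class(half, "A", screening_config(n_references = 2,
                                                 cutoffs = 20,
                                                 variant = "binary"),
                     references = c("act01", "act03"))
  r_each <- vapply(c("act01", "act03"), function(rf) {
    screen_class(half, "A",
                 screening_config(n_references = 1, cutoffs = 20,
                                  variant = "binary"),
                 references = rf)
  }, numeric(1))
  expect_equal(unname(m2), mean(r_each))

  r1 <- screen_class(dbb, "A", screening_config(n_references = 3,
                                                cutoffs = 25,
                                                variant = "binary", seed = 9))
  r2 <- screen_class(dbb, "A", screening_config(n_references = 3,
                                                cutoffs = 25,
                                                variant = "binary", seed = 9))
  expect_identical(r1, r2)  # seed-reproducible
  expect_error(screen_class(dbb, background_label(), cfg), "background")
})

test_that("the benchmark table composes per-class screening runs", {
  set.seed(60)
  labels <- c(rep("A", 8), rep("B", 8), rep(background_label(), 30))
  ds <- make_toy_dataset(46, 20, labels = labels, seed = 61)
  dsb <- binarize(ds)
  cfg <- screening_config(n_references = 4, cutoffs = c(5, 20),
                          variant = "binary", seed = 62)
  tabs <- run_benchmark(list(TAN = list(dataset = dsb)), cfg)
  expect_named(tabs, c("5%", "20%"))
  expect_equal(rownames(tabs[["5%"]]$recalls), c("A", "B"))

  # compositional oracle: each cell equals its own screen_class call
  for (cl in c("A", "B")) {
    refs <- select_references(dsb, cl, cfg)
    manual <- screen_class(dsb, cl, cfg, references = refs)
    expect_equal(tabs[["5%"]]$recalls[cl, "TAN"], unname(manual["5%"]))
    expect_equal(tabs[["20%"]]$recalls[cl, "TAN"], unname(manual["20%"]))
  }

  # mismatched ids across methods are refused
  other <- make_toy_dataset(10, 20, labels = rep("A", 10), seed = 63)
  expect_error(run_benchmark(list(a = list(dataset = dsb),
                                  b = list(dataset = other)), cfg),
               "share ids")
})

test_that("summary rows recompute means and best counts with ties", {
  m <- matrix(c(10, 30, 25, 30, 20, 15), 2, 3,
              dimnames = list(c("c1", "c2"), c("X", "Y", "Z")))
  s <- summarize_table(m)
  expect_equal(unname(s$mean_row), c(20, 27.5, 17.5))
  # row c2: X and Y tie at 30 -> both credited
  expect_equal(unname(s$best_counts), c(1, 2, 0))
  # strictly distinct rows: counts sum to the number of rows
  set.seed(3)
  m2 <- matrix(runif(28), 7, 4,
               dimnames = list(paste0("r", 1:7), paste0("m", 1:4)))
  expect_equal(sum(summarize_table(m2)$best_counts), 7)
})

test_that("recall tables round-trip through CSV, dropping summary rows", {
  t4 <- benchmark_recall_table("ds1", 1)
  p <- withr::local_tempfile(fileext = ".csv")
  write_recall_table(t4, p)
  back <- read_recall_table(p, cutoff = 1)
  expect_equal(back$recalls, t4$recalls)
  # summary rows present in a file are ignored and recomputed
  writeLines(c("class,X,Y", "c1,10,20", "c2,30,5", "Mean,99,99"), p)
  tb <- read_recall_table(p)
  expect_equal(nrow(tb$recalls), 2)
  expect_equal(unname(tb$mean_row), c(20, 12.5))
})
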