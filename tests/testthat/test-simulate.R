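# Planted-module generator: structural guarantees and closed-form checks.

test_that("config invariants are enforced", {
  expect_error(simulation_config(n_modules = 10, module_size = 10, n_genes = 50),
               "exceeds n_genes")
  expect_error(simulation_config(flip_noise = 0.5), "flip_noise")
  expect_error(simulation_config(module_expression_rho = 1), "rho")
})

test_that("module membership partitions exactly n_modules x module_size genes", {
  cfg <- small_config()
  sim <- simulate_profiles(cfg)
  mem <- sim$membership
  mod_genes <- unlist(mem$modules, use.names = FALSE)
  expect_length(mod_genes, cfg$n_modules * cfg$module_size)
  expect_false(anyDuplicated(mod_genes) > 0)
  expect_length(intersect(mod_genes, mem$background), 0L)
  expect_setequal(c(mod_genes, mem$background), rownames(sim$profiles))
  expect_equal(dim(sim$profiles), c(cfg$n_genes, cfg$n_species))
})

test_that("flip_noise = 0 makes modules internally identical", {
  cfg <- simulation_config(n_species = 30, n_genes = 20, n_modules = 2,
                           module_size = 5, flip_noise = 0, seed = 3)
  sim <- simulate_profiles(cfg)
  for (m in sim$membership$modules) {
    rows <- unclass(sim$profiles)[m, ]
    expect_true(all(apply(rows, 2, function(col) length(unique(col)) == 1L)))
  }
})

test_that("within-module Hamming distance matches its closed form", {
  # two independently flipped copies of one template differ per coordinate
  # with probability 2p(1-p): expectation 2 n p (1-p)
  cfg <- simulation_config(n_species = 182, n_genes = 250, n_modules = 10,
                           module_size = 10, flip_noise = 0.02, seed = 101)
  sim <- simulate_profiles(cfg)
  dm <- hamming_matrix(sim$profiles)
  d <- unlist(lapply(sim$membership$modules, function(m) {
    sub <- dm[m, m]
    sub[upper.tri(sub)]
  }))
  p <- cfg$flip_noise
  expected <- 2 * cfg$n_species * p * (1 - p)
  per_coord <- 2 * p * (1 - p)
  se <- sqrt(cfg$n_species * per_coord * (1 - per_coord)) / sqrt(length(d))
  expect_gt(length(d), 400)  # 45 pairs x 10 modules
  expect_lt(abs(mean(d) - expected), 3 * se)
})

test_that("within-module expression correlation matches the latent-factor rho", {
  cfg <- simulation_config(n_species = 30, n_genes = 120, n_modules = 8,
                           module_size = 10, n_samples = 200,
                           module_expression_rho = 0.8, seed = 57)
  sim <- simulate_profiles(cfg)
  expr <- simulate_expression(cfg, sim$membership)
  expect_equal(dim(expr), c(cfg$n_genes, cfg$n_samples))
  rs <- unlist(lapply(sim$membership$modules, function(m) {
    cm <- stats::cor(t(unclass(expr)[m, ]))
    cm[upper.tri(cm)]
  }))
  # Fisher-z standard error of a sample correlation at rho = 0.8
  se_r <- (1 - 0.8^2) / sqrt(cfg$n_samples - 1)
  expect_lt(abs(mean(rs) - 0.8), 3 * se_r / sqrt(length(rs)) + 0.01)

  # rho = 0: within-module correlations behave like background noise
  cfg0 <- simulation_config(n_species = 30, n_genes = 120, n_modules = 8,
                            module_size = 10, n_samples = 200,
                            module_expression_rho = 0, seed = 58)
  sim0 <- simulate_profiles(cfg0)
  expr0 <- simulate_expression(cfg0, sim0$membership)
  rs0 <- unlist(lapply(sim0$membership$modules, function(m) {
    cm <- stats::cor(t(unclass(expr0)[m, ]))
    cm[upper.tri(cm)]
  }))
  se0 <- 1 / sqrt(cfg0$n_samples - 1)
  expect_lt(abs(mean(rs0)), 3 * se0 / sqrt(length(rs0)))
})

test_that("simulate_hits inverts build_profiles, decoys included", {
  cfg <- small_config(seed = 71)
  sim <- simulate_profiles(cfg)
  hits <- simulate_hits(sim$profiles, decoy_fraction = 0.3, seed = 72)
  rebuilt <- build_profiles(hits, colnames(sim$profiles),
                            genes = rownames(sim$profiles))
  expect_identical(unclass(rebuilt)[rownames(sim$profiles), ],
                   unclass(sim$profiles)[, ])
  # decoys exist, sit at/above threshold, and some sit exactly at it
  thr <- attr(sim$profiles, "evalue_threshold")
  decoys <- hits[hits$domain_evalue >= thr, ]
  expect_gt(nrow(decoys), 0)
  expect_true(any(decoys$domain_evalue == thr))
  # file round-trip through the domtblout dialect preserves the hit multiset
  path <- tempfile(fileext = ".domtblout")
  write_domtblout(hits, path)
  back <- read_domtblout(path)
  key <- function(h) sort(paste(h$query_gene, h$target_species,
                                signif(h$domain_evalue, 5)))
  expect_identical(key(back), key(hits))
})

test_that("simulate_annotations covers modules and sprinkles noise genes", {
  cfg <- small_config(seed = 81)
  sim <- simulate_profiles(cfg)
  ann0 <- simulate_annotations(sim$membership, terms_per_module = 3,
                               annotation_noise = 0, seed = 82)
  expect_length(ann0, cfg$n_modules * 3)
  for (term in names(ann0)) {
    mod <- sub("_term\\d+$", "", term)
    expect_setequal(ann0[[term]], sim$membership$modules[[mod]])
  }
  ann <- simulate_annotations(sim$membership, terms_per_module = 2,
                              annotation_noise = 0.5, seed = 83)
  extra <- setdiff(unlist(ann), unlist(sim$membership$modules))
  expect_equal(length(extra), floor(0.5 * length(sim$membership$background)))
  expect_true(all(extra %in% sim$membership$background))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 91)
  a <- simulate_benchmark(cfg)
  b <- simulate_benchmark(cfg)
  expect_identical(unclass(a$profiles)[, ], unclass(b$profiles)[, ])
  expect_identical(unclass(a$expression)[, ], unclass(b$expression)[, ])
  expect_identical(a$hits, b$hits)
  expect_identical(a$annotations, b$annotations)
})
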