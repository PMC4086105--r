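# Synthetic data with planted structure.  Gene modules emulate the method's
# core premise: genes acting in the same cellular process experience similar
# selection pressure (similar phyletic profiles) and are expressed in the
# same tissues (correlated expression).  Each module copies a random profile
# template with independent per-coordinate bit flips, and loads a shared
# latent expression factor; background genes get i.i.d. profiles and pure
# noise expression.  Annotations assign module-specific terms, optionally
# sprinkling background genes into terms as noise.  Everything is seeded and
# reproducible; no phylogenetic tree is simulated because the method itself
# is tree-free (raw Hamming distance).

#' Simulation configuration
#'
#' Defaults describe the benchmark conditions used throughout the package's
#' validation: a 182-species universe (the size of the eukaryotic proteome
#' set the method was built against), 20 planted modules of 10 genes among
#' 500 genes total, 2\% profile bit-flip noise, background presence density
#' 0.5, within-module expression correlation 0.7 over 100 samples.
#'
#' @param n_species number of taxa in the universe (default 182).
#' @param n_genes total genes, modules plus background (default 500).
#' @param n_modules number of planted modules (default 20).
#' @param module_size genes per module (default 10).
#' @param profile_template_density Bernoulli presence probability of module
#'   template profiles (default 0.5).
#' @param flip_noise per-coordinate bit-flip probability applied to each
#'   module member's copy of its template, in [0, 0.5) (default 0.02).
#' @param background_density presence probability for background-gene
#'   profile coordinates (default 0.5).
#' @param n_samples expression samples/tissues (default 100).
#' @param module_expression_rho latent-factor loading; the theoretical
#'   within-module Pearson correlation, in [0, 1) (default 0.7).
#' @param noise_sd expression noise scale (default 1).
#' @param seed master seed (default 1).
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(n_species = 182L, n_genes = 500L,
                              n_modules = 20L, module_size = 10L,
                              profile_template_density = 0.5,
                              flip_noise = 0.02, background_density = 0.5,
                              n_samples = 100L, module_expression_rho = 0.7,
                              noise_sd = 1, seed = 1L) {
  cfg <- list(
    n_species = assert_count(n_species, "n_species"),
    n_genes = assert_count(n_genes, "n_genes"),
    n_modules = assert_count(n_modules, "n_modules", min = 0L),
    module_size = assert_count(module_size, "module_size"),
    profile_template_density = assert_prob(profile_template_density,
                                           "profile_template_density",
                                           lo_open = TRUE, hi_open = TRUE),
    flip_noise = assert_prob(flip_noise, "flip_noise", hi = 0.5, hi_open = TRUE),
    background_density = assert_prob(background_density, "background_density",
                                     lo_open = TRUE, hi_open = TRUE),
    n_samples = assert_count(n_samples, "n_samples"),
    module_expression_rho = assert_prob(module_expression_rho,
                                        "module_expression_rho", hi_open = TRUE),
    noise_sd = assert_prob(noise_sd, "noise_sd", hi = Inf, lo_open = TRUE),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    stopf("n_modules * module_size (%d) exceeds n_genes (%d)",
          cfg$n_modules * cfg$module_size, cfg$n_genes)
  structure(cfg, class = "simulation_config")
}

sim_gene_names <- function(cfg) {
  sprintf("g%0*d", nchar(cfg$n_genes), seq_len(cfg$n_genes))
}

#' Simulate phyletic profiles with planted modules
#'
#' Each module draws a template profile with Bernoulli(profile_template_density)
#' presence; members copy the template with independent per-coordinate flips
#' at rate \code{flip_noise}.  Background genes draw i.i.d.
#' Bernoulli(background_density) coordinates.  The expected within-module
#' pairwise Hamming distance is \eqn{2 n p (1-p)} for \eqn{n} species and
#' flip rate \eqn{p} (two independently flipped copies of one template).
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{profiles} (a \code{phyletic_profiles} object) and
#'   \code{membership}: list with \code{modules} (named list module ->
#'   member genes) and \code{background} (character vector).
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  genes <- sim_gene_names(cfg)
  taxa <- sprintf("taxon%03d", seq_len(cfg$n_species))
  n_mod_genes <- cfg$n_modules * cfg$module_size
  bits <- matrix(0L, cfg$n_genes, cfg$n_species,
                 dimnames = list(genes, taxa))
  with_seed(cfg$seed, {
    modules <- list()
    for (m in seq_len(cfg$n_modules)) {
      template <- stats::rbinom(cfg$n_species, 1L, cfg$profile_template_density)
      rows <- (m - 1L) * cfg$module_size + seq_len(cfg$module_size)
      flips <- matrix(stats::rbinom(cfg$module_size * cfg$n_species, 1L,
                                    cfg$flip_noise),
                      cfg$module_size, cfg$n_species)
      bits[rows, ] <- abs(sweep(flips, 2L, template, "-"))  # template xor flip
      modules[[sprintf("m%02d", m)]] <- genes[rows]
    }
    if (cfg$n_genes > n_mod_genes) {
      bg_rows <- (n_mod_genes + 1L):cfg$n_genes
      bits[bg_rows, ] <- stats::rbinom(length(bg_rows) * cfg$n_species, 1L,
                                       cfg$background_density)
    }
    storage.mode(bits) <- "integer"
    list(profiles = new_phyletic_profiles(bits, taxa, 1e-7),
         membership = list(modules = modules,
                           background = genes[setdiff(seq_len(cfg$n_genes),
                                                      seq_len(n_mod_genes))]))
  })
}

#' Simulate a co-expressed expression matrix for planted modules
#'
#' Module members load a shared per-module latent factor:
#' \code{value = noise_sd * (sqrt(rho) * factor + sqrt(1 - rho) * eps)} with
#' standard normal factor and noise, giving theoretical within-module Pearson
#' correlation exactly \code{rho}.  Background genes are pure noise.  Values
#' emulate a normalized tissue atlas, so the matrix is tagged
#' \code{"log2+quantile"}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param membership module membership as returned by
#'   \code{\link{simulate_profiles}}.
#' @return an \code{expression_matrix} (genes x samples).
#' @export
simulate_expression <- function(config, membership) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  genes <- sim_gene_names(cfg)
  samples <- sprintf("tissue%03d", seq_len(cfg$n_samples))
  rho <- cfg$module_expression_rho
  with_seed(cfg$seed + 1L, {
    vals <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, sd = cfg$noise_sd),
                   cfg$n_genes, cfg$n_samples, dimnames = list(genes, samples))
    for (m in names(membership$modules)) {
      members <- membership$modules[[m]]
      latent <- stats::rnorm(cfg$n_samples)
      eps <- matrix(stats::rnorm(length(members) * cfg$n_samples),
                    length(members), cfg$n_samples)
      vals[members, ] <- cfg$noise_sd *
        (sqrt(rho) * matrix(latent, length(members), cfg$n_samples,
                            byrow = TRUE) + sqrt(1 - rho) * eps)
    }
    expression_matrix(vals, state = "log2+quantile")
  })
}

#' Simulate homology hits consistent with a profile matrix
#'
#' Inverse of \code{\link{build_profiles}} for round-trip testing: every
#' 1-cell emits a hit with per-domain E-value drawn log-uniformly below the
#' threshold; a configurable fraction of 0-cells emit decoy hits with
#' E-values at or above the threshold (a quarter of decoys sit exactly AT
#' the threshold, exercising the strict-'<' presence rule).  Decoys can
#' therefore never flip a 0-cell to 1.
#'
#' @param profiles a \code{phyletic_profiles} object.
#' @param evalue_threshold presence cutoff (default: the matrix's recorded
#'   threshold).
#' @param decoy_fraction fraction of 0-cells receiving an above-threshold
#'   decoy hit (default 0.1).
#' @param seed integer seed.
#' @return hit data frame (\code{query_gene}, \code{target_species},
#'   \code{domain_evalue}, \code{full_evalue}); serialize with
#'   \code{\link{write_domtblout}}.
#' @export
simulate_hits <- function(profiles, evalue_threshold = NULL,
                          decoy_fraction = 0.1, seed = 1L) {
  thr <- evalue_threshold %||% attr(profiles, "evalue_threshold") %||% 1e-7
  decoy_fraction <- assert_prob(decoy_fraction, "decoy_fraction")
  m <- unclass(profiles)
  ones <- which(m == 1L)
  zeros <- which(m == 0L)
  with_seed(seed, {
    n_decoy <- floor(decoy_fraction * length(zeros))
    decoys <- if (n_decoy) sort(sample(zeros, n_decoy)) else integer()
    cells <- c(ones, decoys)
    ij <- arrayInd(cells, dim(m))
    e_present <- 10^stats::runif(length(ones), log10(thr) - 23, log10(thr))
    e_decoy <- 10^stats::runif(length(decoys), log10(thr), log10(thr) + 3)
    if (length(decoys)) {
      at_thr <- stats::runif(length(decoys)) < 0.25
      e_decoy[at_thr] <- thr  # exactly at the cutoff: must stay absent
    }
    ev <- c(e_present, e_decoy)
    data.frame(query_gene = rownames(m)[ij[, 1L]],
               target_species = colnames(m)[ij[, 2L]],
               domain_evalue = ev, full_evalue = ev / 2,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a GMT-style annotation collection for planted modules
#'
#' Each module receives \code{terms_per_module} dedicated terms covering all
#' of its members; a fraction \code{annotation_noise} of background genes is
#' sprinkled into randomly chosen terms.
#'
#' @param membership module membership from \code{\link{simulate_profiles}}.
#' @param terms_per_module dedicated terms per module (default 3).
#' @param annotation_noise fraction of background genes annotated to random
#'   terms (default 0.1).
#' @param seed integer seed.
#' @return gene-set collection (named list term -> genes with a
#'   \code{"description"} attribute), writable with \code{\link{write_gmt}}.
#' @export
simulate_annotations <- function(membership, terms_per_module = 3L,
                                 annotation_noise = 0.1, seed = 1L) {
  terms_per_module <- assert_count(terms_per_module, "terms_per_module")
  annotation_noise <- assert_prob(annotation_noise, "annotation_noise")
  sets <- list()
  for (m in names(membership$modules)) {
    for (t in seq_len(terms_per_module)) {
      sets[[sprintf("%s_term%d", m, t)]] <- membership$modules[[m]]
    }
  }
  with_seed(seed, {
    bg <- membership$background
    n_noise <- floor(annotation_noise * length(bg))
    if (n_noise && length(sets)) {
      noisy <- sample(bg, n_noise)
      targets <- sample(names(sets), n_noise, replace = TRUE)
      for (i in seq_len(n_noise))
        sets[[targets[i]]] <- c(sets[[targets[i]]], noisy[i])
    }
    attr(sets, "description") <- stats::setNames(
      rep("synthetic planted-module term", length(sets)), names(sets))
    sets
  })
}

#' Simulate a full benchmark data set
#'
#' Convenience wrapper producing profiles, membership, expression, hits and
#' annotations from one configuration in a single call.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param terms_per_module,annotation_noise passed to
#'   \code{\link{simulate_annotations}}.
#' @param decoy_fraction passed to \code{\link{simulate_hits}}.
#' @return list with \code{profiles}, \code{membership}, \code{expression},
#'   \code{hits}, \code{annotations} and the \code{config}.
#' @export
simulate_benchmark <- function(config = simulation_config(),
                               terms_per_module = 3L, annotation_noise = 0.1,
                               decoy_fraction = 0.1) {
  prof <- simulate_profiles(config)
  expr <- simulate_expression(config, prof$membership)
  hits <- simulate_hits(prof$profiles, seed = config$seed + 2L,
                        decoy_fraction = decoy_fraction)
  ann <- simulate_annotations(prof$membership, terms_per_module,
                              annotation_noise, seed = config$seed + 3L)
  list(profiles = prof$profiles, membership = prof$membership,
       expression = expr, hits = hits, annotations = ann, config = config)
}
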