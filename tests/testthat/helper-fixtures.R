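# Fixture builders shared across test files.  Everything is generated in
# code; no binary or stored fixtures.

# One HMMER3 per-domain (domtblout) data line with 23 columns.  E-values are
# placed in the full-sequence (col 7) and best-domain conditional (col 12)
# slots; remaining columns carry plausible filler.
domtbl_line <- function(target, query, dom_evalue, full_evalue = dom_evalue,
                        extra = "-") {
  paste(target, "-", "300", query, "-", "250",
        format(full_evalue), "120.5", "0.1",
        "1", "1",
        format(dom_evalue), format(dom_evalue),
        "118.2", "0.1", "5", "240", "10", "260", "8", "265", "0.97", extra)
}

write_domtbl_fixture <- function(lines, path = tempfile(fileext = ".domtblout")) {
  writeLines(c("# comment header", lines, "#"), path)
  path
}

# Independent brute-force oracles ------------------------------------------

# Pairwise Hamming by explicit coordinate loop.
brute_hamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- 0L
  for (i in seq_along(a)) if (a[i] != b[i]) n <- n + 1L
  n
}

# Full-sort ranking oracle: filter then order by the documented three keys
# using a naive repeated-minimum selection (independent of order()).
oracle_rank <- function(cand, min_corr = 0.2, top_n = 125,
                        use_corr = TRUE) {
  if (use_corr) cand <- cand[!is.na(cand$r) & cand$r >= min_corr, , drop = FALSE]
  key_less <- function(i, j) {
    if (cand$hamming[i] != cand$hamming[j]) return(cand$hamming[i] < cand$hamming[j])
    if (use_corr && !isTRUE(all.equal(cand$r[i], cand$r[j])) &&
        cand$r[i] != cand$r[j]) return(cand$r[i] > cand$r[j])
    cand$gene[i] < cand$gene[j]
  }
  idx <- seq_len(nrow(cand))
  out <- integer()
  while (length(idx) && length(out) < top_n) {
    best <- idx[1L]
    for (j in idx[-1L]) if (key_less(j, best)) best <- j
    out <- c(out, best)
    idx <- setdiff(idx, best)
  }
  cand[out, , drop = FALSE]
}

# KS D by explicit ECDF scan at every pooled point.
brute_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  best <- 0
  for (x in pts) {
    d <- abs(mean(a <= x) - mean(b <= x))
    if (d > best) best <- d
  }
  best
}

# small benchmark used by several files (cheap, deterministic)
small_config <- function(seed = 11L) {
  simulation_config(n_species = 40L, n_genes = 60L, n_modules = 4L,
                    module_size = 5L, n_samples = 30L, seed = seed)
}

# numeric values of an expression_matrix, shorn of class and state tag
expr_values <- function(m) {
  x <- unclass(m)
  attr(x, "normalization_state") <- NULL
  x
}
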