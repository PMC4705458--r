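# In-code fixture builders shared across test files.

# minimal alignment from named aligned sequences plus metadata overrides
make_aln <- function(seqs, ...) {
  over <- list(...)
  records <- data.frame(
    id = names(seqs),
    organism_name = "uncultured archaeon clone x",
    strain = "", isolation_source = "surface seawater, 5 m",
    pintail = 90, seq_quality = 90, align_quality = 95,
    domain = "Archaea", aligned_seq = unname(seqs),
    stringsAsFactors = FALSE)
  for (nm in names(over)) records[[nm]] <- over[[nm]]
  ctuscope:::new_alignment(records)
}

# random ungapped alignment of n sequences x len columns
random_aln <- function(n, len, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
  names(seqs) <- sprintf("r%02d", seq_len(n))
  make_aln(seqs)
}

# random symmetric percent-distance matrix (continuous, ties a.s. absent)
random_dist <- function(n, seed) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, 40)
  d <- d + t(d)
  dimnames(d) <- list(sprintf("x%02d", 1:n), sprintf("x%02d", 1:n))
  d
}

# Independent brute-force complete-linkage oracle: greedy agglomeration,
# re-scanning ALL pairwise member distances at every step (no cached
# linkage updates), first-found pair on ties.
oracle_complete_linkage <- function(d, cutoff) {
  labels <- rownames(d)
  clusters <- as.list(labels)
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- Inf; bi <- bj <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    if (best > cutoff + 1e-9) break
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  out <- integer(length(labels)); names(out) <- labels
  for (i in seq_along(clusters)) out[clusters[[i]]] <- i
  out
}

# partitions agree up to label bijection
same_partition <- function(a, b) {
  stopifnot(setequal(names(a), names(b)))
  adjusted_rand_index(a, b[names(a)]) == 1
}

# small rooted tree fixture from a newick string
tree_from_newick <- function(txt, outgroup = character()) {
  f <- tempfile(fileext = ".nwk")
  writeLines(txt, f)
  read_tree_newick(f, outgroup)
}

# smaller, faster smoke world for tests that loop over many fixtures
fast_params <- function(seed, ...) {
  sim_params(seed = seed, leaves_per_genus = 5L, n_samples = 24L,
             seq_length = 1200L, ...)
}
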