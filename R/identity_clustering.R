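## Conservation masking, pairwise identity, hierarchical furthest-neighbor
## (complete-linkage) clustering, and nested rank partitions cut at the
## five identity thresholds.

BASES <- c("A", "C", "G", "T")

# tolerance for "merge height at exactly the cutoff belongs to the cluster"
CUT_TOL <- 1e-9

#' Build a base conservation column mask
#'
#' Retains an alignment column iff its most frequent unambiguous base
#' (T and U equated) occurs in at least `min_fraction` of ALL records —
#' gaps and ambiguity codes count in the denominator but never in the
#' numerator. This is the positional-variability style filter applied
#' before distance computation (default 10%).
#'
#' @param aln a `ctu_alignment` with >= 2 records.
#' @param min_fraction minimum majority-base fraction, inclusive.
#' @return a logical vector of length `n_columns` (class `column_mask`)
#'   with attribute `n_retained`.
#' @export
build_conservation_mask <- function(aln, min_fraction = 0.10) {
  if (n_records(aln) < 2) stop2("need >= 2 records to build a mask")
  m <- alignment_matrix(aln)
  n <- nrow(m)
  counts <- vapply(BASES, function(b) colSums(m == b), numeric(ncol(m)))
  top <- apply(counts, 1, max)
  keep <- top / n >= min_fraction
  if (!any(keep)) stop2("empty mask: all columns removed by conservation filter")
  structure(keep, n_retained = sum(keep), class = "column_mask")
}

#' Pairwise percent-distance matrix over masked columns
#'
#' For each sequence pair, identity is `100 * matches / comparable`, where
#' comparable columns are retained mask columns in which both sequences
#' carry unambiguous bases (terminal gap runs trimmed; internal gap columns
#' and ambiguity codes excluded). Distance is `100 - identity`; a pair with
#' zero comparable columns gets distance 100.
#'
#' @param aln a `ctu_alignment` with >= 2 records.
#' @param mask optional `column_mask`; default keeps all columns.
#' @return symmetric numeric matrix of percent distances (diagonal 0) with
#'   record ids as dimnames.
#' @export
pairwise_identity_matrix <- function(aln, mask = NULL) {
  if (n_records(aln) < 2) stop2("need >= 2 records")
  m <- alignment_matrix(aln)
  if (!is.null(mask)) {
    stopifnot(length(mask) == ncol(m))
    m <- m[, as.logical(mask), drop = FALSE]
  }
  # validity: unambiguous base (gaps/ambiguity excluded; terminal gaps are
  # gaps, so explicit trimming is subsumed)
  valid <- m %in% BASES
  dim(valid) <- dim(m)
  storage.mode(valid) <- "double"
  comparable <- tcrossprod(valid)
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in BASES) {
    ind <- (m == b) & valid
    storage.mode(ind) <- "double"
    matches <- matches + tcrossprod(ind)
  }
  d <- ifelse(comparable > 0, 100 * (1 - matches / comparable), 100)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Hierarchical furthest-neighbor (complete-linkage) dendrogram
#'
#' Agglomerative clustering where the distance between two clusters is the
#' MAXIMUM pairwise distance between their members; at each step the pair
#' of clusters at smallest inter-cluster distance is merged. Ties are
#' broken deterministically: among equal-distance candidate merges, the
#' pair whose smallest member id sorts first wins, then the other
#' cluster's smallest member id. Complete linkage is monotone, so merge
#' heights never decrease.
#'
#' @param dist symmetric numeric matrix of percent distances with unique
#'   dimnames, n >= 2.
#' @return an `fn_dendrogram`: list with `labels`, `merge` (hclust-style
#'   n-1 x 2 matrix: negative = singleton index, positive = earlier merge)
#'   and `height`.
#' @export
furthest_neighbor_dendrogram <- function(dist) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n < 2) stop2("need >= 2 items")
  labels <- rownames(dist) %||% as.character(seq_len(n))
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-8)))
    stop2("distance matrix is not symmetric")

  d <- dist                         # working complete-linkage distances
  active <- seq_len(n)              # indices of live clusters (rows of d)
  cl_id <- -seq_len(n)              # hclust coding of each live cluster
  # lexicographically least member label per cluster, for tie-breaking
  cl_min <- labels
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    da <- d[active, active, drop = FALSE]
    da[lower.tri(da, diag = TRUE)] <- Inf
    best <- min(da)
    cand <- which(da == best, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      key1 <- pmin(cl_min[active][cand[, 1]], cl_min[active][cand[, 2]])
      key2 <- pmax(cl_min[active][cand[, 1]], cl_min[active][cand[, 2]])
      cand <- cand[order(key1, key2)[1], , drop = FALSE]
    }
    i <- active[cand[1, 1]]; j <- active[cand[1, 2]]
    merge[step, ] <- sort(c(cl_id[i], cl_id[j]))
    height[step] <- best
    # fold j into i with complete-linkage update
    d[i, ] <- pmax(d[i, ], d[j, ])
    d[, i] <- d[i, ]
    d[i, i] <- 0
    cl_min[i] <- min(cl_min[i], cl_min[j])
    cl_id[i] <- step
    active <- setdiff(active, j)
  }
  structure(list(labels = labels, merge = merge, height = height),
            class = "fn_dendrogram")
}

#' @export
print.fn_dendrogram <- function(x, ...) {
  cat("fn_dendrogram:", length(x$labels), "items,",
      length(x$height), "merges, heights [",
      format(min(x$height)), ",", format(max(x$height)), "]\n")
  invisible(x)
}

#' Convert to a stats::hclust object
#' @param dendro an `fn_dendrogram`.
#' @return an object of class `hclust` (for plotting or [stats::cutree()]).
#' @export
as_hclust <- function(dendro) {
  structure(list(merge = dendro$merge, height = dendro$height,
                 order = seq_along(dendro$labels), labels = dendro$labels,
                 method = "complete"),
            class = "hclust")
}

#' Cut nested OTU partitions at the rank thresholds
#'
#' For each rank, applies every merge with height <= `100 - identity
#' threshold` (inclusive, with 1e-9 absolute tolerance) and reads off the
#' resulting flat partition. OTU integer ids are assigned in order of each
#' OTU's first member under the input record order, so ids are
#' deterministic and start at 1 per rank.
#'
#' @param dendro an `fn_dendrogram`.
#' @param thresholds a [rank_thresholds()] object.
#' @return a `rank_partitions`: named list (rank -> integer vector of OTU
#'   ids named by record id), with attribute `cutoffs`.
#' @export
cut_partitions <- function(dendro, thresholds = rank_thresholds()) {
  cutoffs <- attr(thresholds, "cutoffs")
  out <- lapply(cutoffs, function(cut) cut_dendrogram(dendro, cut))
  names(out) <- names(thresholds)
  structure(out, cutoffs = cutoffs, class = "rank_partitions")
}

# flat partition of a dendrogram at one distance cutoff (inclusive)
cut_dendrogram <- function(dendro, cutoff) {
  n <- length(dendro$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  members <- vector("list", n - 1L)  # one representative per merged cluster
  for (s in seq_len(n - 1L)) {
    if (dendro$height[s] > cutoff + CUT_TOL) break
    pick <- function(code) if (code < 0) -code else members[[code]]
    a <- find(pick(dendro$merge[s, 1]))
    b <- find(pick(dendro$merge[s, 2]))
    parent[b] <- a
    members[[s]] <- a
  }
  reps <- vapply(seq_len(n), find, 1L)
  ids <- match(reps, unique(reps))  # first-member order
  stats::setNames(as.integer(ids), dendro$labels)
}
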