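## Reconciling OTU partitions with tree topology into monophyletic,
## standardly named candidate taxonomic units (CTUs): outgroup rooting,
## maximal monochromatic clade recognition per rank, nested hierarchy
## construction, name assignment, and known-clade marking.

# tip-index sets below every node of a phylo (tips 1..Ntip, then internals)
node_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    sets[[eo[k, 1]]] <- c(sets[[eo[k, 1]]], sets[[eo[k, 2]]])
  sets
}

# node indices in preorder (root first, then cladewise edge order)
preorder_nodes <- function(phy) {
  eo <- ape::reorder.phylo(phy, "cladewise")$edge
  c(eo[1, 1], eo[, 2])
}

#' Root a tree on its designated outgroup
#'
#' Roots the tree on the edge separating the outgroup's most recent common
#' ancestor from the in-group. If the outgroup is not monophyletic in the
#' unrooted tree, the tree is instead rooted on the bipartition placing
#' the largest number of outgroup leaves (fewest in-group leaves on ties)
#' on one side, with a warning. Outgroup leaves are excluded from all
#' downstream CTU membership.
#'
#' @param tree a `ctu_tree` with >= 1 outgroup leaf (and at least one
#'   in-group leaf).
#' @return a rooted `ctu_tree`.
#' @export
root_with_outgroup <- function(tree) {
  og <- tree$outgroup
  if (!length(og)) stop2("no outgroup leaves designated")
  tips <- tree$phy$tip.label
  if (length(setdiff(tips, og)) == 0)
    stop2("outgroup includes every leaf; nothing to root")
  phy <- if (length(tips) > 2) ape::unroot(tree$phy) else tree$phy
  rooted <- tryCatch(
    ape::root(phy, outgroup = og, resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(rooted)) {
    warn2("outgroup is not monophyletic; rooting on the best split")
    sets <- node_tip_sets(phy)
    og_idx <- match(og, phy$tip.label)
    ntip <- length(phy$tip.label)
    best <- NULL; best_key <- c(-1, Inf)
    for (child in phy$edge[, 2]) {
      for (side in list(sets[[child]], setdiff(seq_len(ntip), sets[[child]]))) {
        n_og <- sum(side %in% og_idx)
        n_in <- length(side) - n_og
        if (n_og == 0 || n_in == length(side)) next
        if (length(side) == ntip) next
        if (n_og > best_key[1] ||
            (n_og == best_key[1] && n_in < best_key[2])) {
          best_key <- c(n_og, n_in); best <- side
        }
      }
    }
    rooted <- ape::root(phy, outgroup = phy$tip.label[best],
                        resolve.root = TRUE)
  }
  new_ctu_tree(rooted, og)
}

#' Recognize rank-level CTUs on a rooted tree
#'
#' Colors each in-group leaf by its OTU id and extracts the MAXIMAL
#' monochromatic clades: tree nodes all of whose in-group descendant
#' leaves share one OTU id, and whose parent's in-group leaf set does not.
#' A phylogenetically coherent OTU yields a single clade; a polyphyletic
#' OTU splits into several components, numbered in preorder. Only whole
#' tree nodes count as clades, so a monochromatic subset of a polytomy's
#' children is never silently grouped.
#'
#' @param rooted_tree a rooted `ctu_tree` (see [root_with_outgroup()]).
#' @param partition integer vector of OTU ids named by leaf id, covering
#'   every in-group leaf (one rank of [cut_partitions()]).
#' @return data.frame with one row per CTU: `otu`, `component`,
#'   `n_components`, `node`, and list-column `members` (in-group leaf
#'   labels, in tree tip order). Rows are in preorder.
#' @export
recognize_rank_ctus <- function(rooted_tree, partition) {
  phy <- rooted_tree$phy
  if (!ape::is.rooted(phy)) stop2("tree must be rooted first")
  tips <- phy$tip.label
  ingroup <- setdiff(tips, rooted_tree$outgroup)
  missing <- setdiff(ingroup, names(partition))
  if (length(missing))
    stop2("leaf without OTU assignment: '", missing[1], "'")
  ntip <- length(tips)
  in_idx <- which(tips %in% ingroup)
  otu_of_tip <- rep(NA_integer_, ntip)
  otu_of_tip[in_idx] <- as.integer(partition[tips[in_idx]])

  sets <- node_tip_sets(phy)
  n_nodes <- ntip + phy$Nnode
  n_colors <- integer(n_nodes)  # distinct OTU ids among in-group leaves
  color <- rep(NA_integer_, n_nodes)
  for (v in seq_len(n_nodes)) {
    ids <- unique(otu_of_tip[sets[[v]]])
    ids <- ids[!is.na(ids)]
    n_colors[v] <- length(ids)
    if (length(ids) == 1L) color[v] <- ids
  }
  parent <- rep(NA_integer_, n_nodes)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]

  is_ctu <- n_colors == 1L &
    (seq_len(n_nodes) == root | is.na(parent) | n_colors[parent] != 1L)
  ctu_nodes <- intersect(preorder_nodes(phy), which(is_ctu))
  out <- data.frame(otu = color[ctu_nodes], component = NA_integer_,
                    n_components = NA_integer_, node = ctu_nodes)
  out$members <- lapply(ctu_nodes, function(v) {
    s <- sets[[v]]
    tips[sort(s[s %in% in_idx])]
  })
  for (o in unique(out$otu)) {
    k <- which(out$otu == o)
    out$component[k] <- seq_along(k)
    out$n_components[k] <- length(k)
  }
  out
}

#' Build the nested five-rank CTU hierarchy
#'
#' Links each CTU to the unique CTU at the next coarser rank whose member
#' set contains it, and computes per-rank summary counts (total, with at
#' least two member sequences, unknown). Requires CTUs recognized from the
#' same rooted tree and nested partitions; a CTU overlapping two parents
#' indicates upstream corruption and is a hard error.
#'
#' @param per_rank_ctus named list `Phylum` ... `Genus` of data.frames from
#'   [recognize_rank_ctus()].
#' @return a `ctu_hierarchy`: list with `ctus` (one row per CTU over all
#'   ranks, preorder within rank, with parent indices), `leaves` (in-group
#'   leaf ids) and `ranks`.
#' @export
build_hierarchy <- function(per_rank_ctus) {
  if (!identical(names(per_rank_ctus), RANKS))
    stop2("per_rank_ctus must be named ", paste(RANKS, collapse = ", "))
  pieces <- lapply(RANKS, function(rk) {
    x <- per_rank_ctus[[rk]]
    x$rank <- rk
    x
  })
  ctus <- do.call(rbind, pieces)
  ctus$name <- NA_character_
  ctus$parent <- ""
  ctus$parent_index <- NA_integer_
  ctus$status <- "unknown"
  ctus$known_labels <- replicate(nrow(ctus), character(), simplify = FALSE)

  leaves <- sort(unique(unlist(per_rank_ctus[["Phylum"]]$members)))
  for (rk in RANKS) {
    mem <- unlist(per_rank_ctus[[rk]]$members)
    if (anyDuplicated(mem) || !setequal(mem, leaves))
      stop2("CTUs at rank ", rk, " do not partition the in-group leaves")
  }
  for (ri in seq_along(RANKS)[-1]) {
    child_rows <- which(ctus$rank == RANKS[ri])
    parent_rows <- which(ctus$rank == RANKS[ri - 1])
    leaf2parent <- integer(0)
    for (p in parent_rows)
      leaf2parent[ctus$members[[p]]] <- p
    for (cr in child_rows) {
      pr <- unique(leaf2parent[ctus$members[[cr]]])
      if (length(pr) != 1L || is.na(pr))
        stop2("CTU at rank ", RANKS[ri],
              " spans multiple parents; upstream corruption")
      ctus$parent_index[cr] <- pr
    }
  }
  structure(list(ctus = ctus, leaves = leaves, ranks = RANKS),
            class = "ctu_hierarchy")
}

#' @export
print.ctu_hierarchy <- function(x, ...) {
  s <- summary(x)
  cat("ctu_hierarchy over", length(x$leaves), "in-group leaves\n")
  print(s, row.names = FALSE)
  invisible(x)
}

#' Summarize a CTU hierarchy
#'
#' @param object a `ctu_hierarchy`.
#' @param ... unused.
#' @return data.frame with per-rank counts: total CTUs, CTUs with >= 2
#'   member sequences, unknown CTUs, and sequences inside unknown CTUs.
#' @export
summary.ctu_hierarchy <- function(object, ...) {
  ct <- object$ctus
  sizes <- vapply(ct$members, length, 1L)
  unknown <- ct$status == "unknown"
  do.call(rbind, lapply(object$ranks, function(rk) {
    k <- ct$rank == rk
    data.frame(rank = rk, n_ctus = sum(k),
               n_ctus_min2 = sum(k & sizes >= 2),
               n_unknown = sum(k & unknown),
               n_unknown_min2 = sum(k & unknown & sizes >= 2),
               n_seqs_unknown = sum(sizes[k & unknown]),
               stringsAsFactors = FALSE)
  }))
}

#' Assign standardized CTU names
#'
#' Names follow `<Context>.<Rank><otu>` for single-component OTUs and
#' `<Context>.<Rank><otu>-<component>` for OTUs split into several
#' monophyletic components (e.g. `Bacteroidetes.Order20-4`). When no
#' context name is given, top-rank CTUs are named `Phylum<k>` and serve as
#' the context for their descendants, yielding names like `Phylum1.Order1`.
#' OTU numbers used in names are renumbered in preorder of the rooted tree
#' (first-encountered leaf), making names independent of input record
#' order; components are numbered in preorder as well.
#'
#' @param hierarchy a `ctu_hierarchy`.
#' @param context_name host phylum/class label for the whole input set
#'   (e.g. `"Bacteroidetes"`), or `""` when the set is not attached to a
#'   known taxon.
#' @return the hierarchy with `name` and `parent` filled in.
#' @export
assign_names <- function(hierarchy, context_name = "") {
  ct <- hierarchy$ctus
  for (rk in hierarchy$ranks) {
    rows <- which(ct$rank == rk)  # preorder within rank
    renum <- match(ct$otu[rows], unique(ct$otu[rows]))
    suffix <- ifelse(ct$n_components[rows] > 1L,
                     paste0("-", ct$component[rows]), "")
    if (context_name == "" && rk == "Phylum") {
      ct$name[rows] <- paste0("Phylum", renum, suffix)
    } else {
      ctx <- if (context_name != "") context_name else {
        # context = this CTU's ancestral phylum-rank CTU name
        anc <- rows
        for (step in seq_len(match(rk, hierarchy$ranks) - 1L))
          anc <- ct$parent_index[anc]
        ct$name[anc]
      }
      ct$name[rows] <- paste0(ctx, ".", rk, renum, suffix)
    }
  }
  if (anyDuplicated(ct$name))
    stop2("CTU name collision: '", ct$name[duplicated(ct$name)][1], "'")
  ct$parent <- ifelse(is.na(ct$parent_index), "", ct$name[ct$parent_index])
  hierarchy$ctus <- ct
  hierarchy
}

#' Mark known clades in a CTU hierarchy
#'
#' A CTU is `known` iff at least one member sequence carries a known-clade
#' annotation (e.g. SAR11, SAR202, Marine Group I); the labels found are
#' recorded. Everything else stays `unknown` — the candidate novel taxa
#' that remain after "fishing out" the known clades. Annotations for ids
#' that are not in-group leaves are ignored with a warning.
#'
#' @param hierarchy a `ctu_hierarchy`.
#' @param annotations named character vector (leaf id -> known-clade
#'   label), or a data.frame with columns `id` and `label`; may be empty.
#' @return the hierarchy with `status` and `known_labels` filled in.
#' @export
flag_known_clades <- function(hierarchy, annotations = character()) {
  if (is.data.frame(annotations))
    annotations <- stats::setNames(as.character(annotations$label),
                                   annotations$id)
  if (length(annotations)) {
    if (is.null(names(annotations)) || any(annotations == ""))
      stop2("annotations must be labeled, non-empty strings named by leaf id")
    stray <- setdiff(names(annotations), hierarchy$leaves)
    if (length(stray)) {
      warn2("annotations for non-leaf ids ignored: ",
            paste(head(stray, 5), collapse = ", "))
      annotations <- annotations[setdiff(names(annotations), stray)]
    }
  }
  ct <- hierarchy$ctus
  ct$known_labels <- lapply(ct$members, function(m)
    sort(unique(unname(annotations[intersect(m, names(annotations))]))))
  ct$status <- ifelse(vapply(ct$known_labels, length, 1L) > 0,
                      "known", "unknown")
  hierarchy$ctus <- ct
  hierarchy
}

#' Full CTU recognition across all ranks
#'
#' Convenience wrapper: roots the tree, recognizes CTUs at every rank,
#' builds the hierarchy, assigns names and flags known clades.
#'
#' @param tree a `ctu_tree`.
#' @param partitions a `rank_partitions` from [cut_partitions()].
#' @param context_name see [assign_names()].
#' @param annotations see [flag_known_clades()].
#' @return a named, flagged `ctu_hierarchy`.
#' @export
recognize_ctus <- function(tree, partitions, context_name = "",
                           annotations = character()) {
  rooted <- if (ape::is.rooted(tree$phy) && length(tree$outgroup) == 0)
    tree else root_with_outgroup(tree)
  per_rank <- lapply(partitions, function(p) recognize_rank_ctus(rooted, p))
  h <- build_hierarchy(per_rank[RANKS])
  h <- assign_names(h, context_name)
  flag_known_clades(h, annotations)
}
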