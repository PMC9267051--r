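#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, the
#' usual rooting for gene/TE trees without a designated outgroup.
#'
#' @param tree An [ape::phylo] (branch lengths required) or a `genus_tree`;
#'   a `genus_tree` keeps its genus labels.
#' @return The rooted tree, same class as the input.
#' @export
midpoint_root <- function(tree) {
  if (inherits(tree, "genus_tree")) {
    rooted <- midpoint_root(tree$tree)
    return(genus_tree(rooted, tree$genera[rooted$tip.label]))
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    abort("midpoint rooting requires branch lengths")
  }
  phangorn::midpoint(tree)
}

#' Extract maximal single-genus ("multiplied") clusters from a tree
#'
#' In a gene or transposable-element tree spanning several genera, genes
#' that multiplied after the genera diverged sit in clades whose leaves all
#' come from one genus.  This function reports every *maximal* such clade
#' with at least `min_size` leaves (a clade contained in a larger qualifying
#' clade is not reported separately, so the reported leaf sets are disjoint)
#' and summarises, per genus, the fraction of its leaves that fall inside
#' these multiplied clusters.
#'
#' @param tree A `genus_tree` (see [read_genus_tree()], [genus_tree()]) or
#'   an [ape::phylo] plus a `genera` mapping.
#' @param genera Optional named character vector (leaf label to genus) when
#'   `tree` is a bare `phylo`.
#' @param min_size Minimum cluster size (default 2: a lone leaf is not
#'   evidence of multiplication).
#' @param collapse_below Optional support threshold: internal nodes whose
#'   support value (numeric node labels) is below it are collapsed into
#'   polytomies before cluster extraction.
#' @return A `cluster_summary`: list with `per_genus` (tibble `genus`,
#'   `total_leaves`, `multiplied_leaves`, `fraction`) and `clusters`
#'   (tibble `cluster_id`, `genus`, `leaf`).  Has [tidy()] and [autoplot()]
#'   methods.
#' @examples
#' gt <- genus_tree(ape::read.tree(text = "((A_1,A_2),(B_1,B_2));"))
#' find_multiplied_clusters(gt)$per_genus
#' @export
find_multiplied_clusters <- function(tree, genera = NULL, min_size = 2,
                                     collapse_below = NULL) {
  if (inherits(tree, "genus_tree")) {
    genera <- tree$genera
    tree <- tree$tree
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(genera)) abort("supply genus labels (a genus_tree or `genera`)")
  if (min_size < 2) abort("min_size must be >= 2")
  if (!ape::is.rooted(tree)) {
    abort("tree is unrooted; root it first (e.g. midpoint_root())")
  }
  if (!is.null(collapse_below)) tree <- collapse_low_support(tree, collapse_below)

  tips <- tree$tip.label
  genera <- genera[tips]
  if (anyNA(genera)) abort("every leaf needs a genus label")
  n_tip <- length(tips)
  n_node <- tree$Nnode
  root <- n_tip + 1L

  # postorder sweep: per node, the single genus of its subtree (NA if mixed)
  node_genus <- c(unname(genera), rep(NA_character_, n_node))
  mixed <- c(rep(FALSE, n_tip), rep(FALSE, n_node))
  n_leaves <- c(rep(1L, n_tip), rep(0L, n_node))
  eo <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    parent <- eo$edge[i, 1L]; child <- eo$edge[i, 2L]
    n_leaves[parent] <- n_leaves[parent] + n_leaves[child]
    if (mixed[child]) {
      mixed[parent] <- TRUE
    } else if (is.na(node_genus[parent]) && !mixed[parent]) {
      node_genus[parent] <- node_genus[child]
    } else if (!mixed[parent] && !identical(node_genus[parent], node_genus[child])) {
      mixed[parent] <- TRUE
    }
  }
  node_genus[mixed] <- NA_character_

  internal <- seq(n_tip + 1L, n_tip + n_node)
  pure <- internal[!is.na(node_genus[internal]) & n_leaves[internal] >= min_size]
  parent_of <- rep(NA_integer_, n_tip + n_node)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  # maximal: the parent's subtree is mixed (or the node is the root)
  maximal <- pure[vapply(pure, function(nd) {
    p <- parent_of[nd]
    is.na(p) || is.na(node_genus[p])
  }, logical(1))]

  clusters <- purrr::map_dfr(seq_along(maximal), function(j) {
    nd <- maximal[j]
    leaves <- tips[clade_tips(tree, nd, n_tip)]
    tibble(cluster_id = j, genus = node_genus[nd], leaf = leaves)
  })
  if (nrow(clusters) == 0L) {
    clusters <- tibble(cluster_id = integer(), genus = character(), leaf = character())
  }

  totals <- tibble(genus = unname(genera)) %>% count(.data$genus, name = "total_leaves")
  mult <- clusters %>% count(.data$genus, name = "multiplied_leaves")
  per_genus <- left_join(totals, mult, by = "genus") %>%
    mutate(multiplied_leaves = ifelse(is.na(.data$multiplied_leaves), 0L,
                                      .data$multiplied_leaves),
           fraction = .data$multiplied_leaves / .data$total_leaves) %>%
    arrange(.data$genus)

  structure(list(per_genus = per_genus, clusters = clusters,
                 min_size = min_size, collapse_below = collapse_below),
            class = "cluster_summary")
}

# Tip indices of the clade rooted at an internal node.
clade_tips <- function(tree, node, n_tip) {
  stack <- node
  out <- integer()
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  while (length(stack) > 0L) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    if (nd <= n_tip) out <- c(out, nd)
    else stack <- c(stack, children[[as.character(nd)]])
  }
  sort(out)
}

# Collapse internal nodes with numeric support below a threshold into
# polytomies (root kept; leaves untouched; NA/empty supports kept).
collapse_low_support <- function(tree, threshold) {
  if (is.null(tree$node.label)) {
    abort("collapse_below given but the tree has no node support labels")
  }
  support <- suppressWarnings(as.numeric(tree$node.label))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  work <- tree
  # indicator branch lengths: 0 on edges subtending a low-support node
  child <- work$edge[, 2L]
  child_support <- rep(NA_real_, length(child))
  internal_child <- child > n_tip
  child_support[internal_child] <- support[child[internal_child] - n_tip]
  low <- internal_child & !is.na(child_support) & child_support < threshold
  work$edge.length <- ifelse(low, 0, 1)
  collapsed <- ape::di2multi(work, tol = 0.5)
  collapsed$edge.length <- NULL
  collapsed
}

#' Per-genus multiplied-cluster report
#'
#' @param summary A `cluster_summary` from [find_multiplied_clusters()].
#' @return A tibble with columns `genus`, `total`, `multiplied`, `percent`
#'   (integer percentage, rounded half away from zero).
#' @export
multiplied_report <- function(summary) {
  stopifnot(inherits(summary, "cluster_summary"))
  summary$per_genus %>%
    mutate(percent = as.integer(round_half_away(100 * .data$fraction, 0))) %>%
    select(genus = "genus", total = "total_leaves",
           multiplied = "multiplied_leaves", "percent")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("<cluster_summary> %d multiplied cluster(s), min size %d\n",
              n_distinct(x$clusters$cluster_id), x$min_size))
  print(x$per_genus)
  invisible(x)
}

#' @rdname find_multiplied_clusters
#' @param x A `cluster_summary` object.
#' @param ... Unused.
#' @export
tidy.cluster_summary <- function(x, ...) x$per_genus

#' @rdname find_multiplied_clusters
#' @param object A `cluster_summary` object.
#' @export
autoplot.cluster_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_genus,
                  ggplot2::aes(x = .data$genus, y = 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(x = NULL, y = "% leaves in single-genus clusters",
                  title = "Genus-specific multiplication")
}
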