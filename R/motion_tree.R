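#' Inter-residue distance-fluctuation matrix
#'
#' For every residue pair `(m, n)` the population standard deviation of the
#' C-alpha distance `d_mn` over all pooled frames:
#' `D_mn = sqrt(<(d_mn - <d_mn>)^2>)`. Closed and open ensembles are pooled
#' so that `D` reflects the relative domain motion between the two states.
#'
#' @param ensembles A [trajectory_ensemble()] or a list of them with
#'   identical residue sets; frames are pooled.
#' @return Object of class `fluctuation_matrix`: `$D` (symmetric, zero
#'   diagonal, Angstrom), `$residue_ids`, `$n_frames`.
#' @export
fluctuation_matrix <- function(ensembles) {
  if (inherits(ensembles, "trajectory_ensemble")) ensembles <- list(ensembles)
  ids <- ensembles[[1]]$residue_ids
  for (e in ensembles) {
    if (!identical(e$residue_ids, ids))
      stop("all ensembles must share the same residue set and ordering")
  }
  n <- length(ids)
  nf_tot <- sum(vapply(ensembles, function(e) dim(e$coords)[1], numeric(1)))
  if (nf_tot < 2) stop("fluctuation is undefined for fewer than 2 pooled frames")
  s1 <- matrix(0, n, n)
  s2 <- matrix(0, n, n)
  for (e in ensembles) {
    nf <- dim(e$coords)[1]
    for (f in seq_len(nf)) {
      dm <- as.matrix(stats::dist(e$coords[f, , ]))
      s1 <- s1 + dm
      s2 <- s2 + dm^2
    }
  }
  mu <- s1 / nf_tot
  v <- s2 / nf_tot - mu^2
  v[v < 0] <- 0          # guard tiny negative round-off
  D <- sqrt(v)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  structure(list(D = D, residue_ids = ids, n_frames = nf_tot),
            class = "fluctuation_matrix")
}

#' Build a Motion Tree by hierarchical clustering of distance fluctuations
#'
#' Agglomerative clustering of residues with the fluctuation matrix as the
#' dissimilarity. Internal nodes are numbered from the root down by
#' decreasing merge height (node 1 = root), matching the convention that the
#' top node defines the largest-amplitude domain motion.
#'
#' @param fl A [fluctuation_matrix()] (or a bare symmetric matrix).
#' @param linkage Agglomeration rule for [stats::hclust()]; default
#'   `"average"` (UPGMA).
#' @return Object of class `motion_tree`: `$hclust`, `$residue_ids`,
#'   `$linkage`, `$heights` (per node id, Angstrom).
#' @export
build_motion_tree <- function(fl, linkage = "average") {
  D <- if (inherits(fl, "fluctuation_matrix")) fl$D else as.matrix(fl)
  ids <- if (inherits(fl, "fluctuation_matrix")) fl$residue_ids
         else seq_len(nrow(D))
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("fluctuation matrix must be symmetric")
  if (any(D < 0)) stop("fluctuation matrix must be nonnegative")
  if (any(!is.finite(D))) stop("fluctuation matrix must be finite")
  n <- nrow(D)
  if (n == 1L) {
    return(structure(list(hclust = NULL, residue_ids = ids,
                          linkage = linkage, heights = numeric(0)),
                     class = "motion_tree"))
  }
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  hc$labels <- as.character(ids)
  # node id k = k-th merge counted from the root (hclust orders by height)
  heights <- rev(hc$height)
  structure(list(hclust = hc, residue_ids = ids,
                 linkage = linkage, heights = heights),
            class = "motion_tree")
}

#' @export
print.motion_tree <- function(x, ...) {
  cat(sprintf("<motion_tree> %d residues, %s linkage", length(x$residue_ids), x$linkage))
  if (length(x$heights))
    cat(sprintf(", root height %.3f A", x$heights[1]))
  cat("\n")
  invisible(x)
}

# hclust merge row for node id (1 = root)
node_to_merge_row <- function(tree, node) {
  m <- length(tree$heights)
  if (node < 1 || node > m) stop("node id out of range (1 = root)")
  ord <- order(tree$hclust$height, decreasing = TRUE)
  ord[node]
}

# residue ids under one entry of an hclust merge row
merge_entry_members <- function(tree, entry) {
  if (entry < 0) return(tree$residue_ids[-entry])
  rows <- entry
  leaves <- integer(0)
  while (length(rows)) {
    r <- rows[1]; rows <- rows[-1]
    for (e in tree$hclust$merge[r, ]) {
      if (e < 0) leaves <- c(leaves, -e) else rows <- c(rows, e)
    }
  }
  tree$residue_ids[leaves]
}

#' Members and children of a Motion Tree node
#'
#' @param tree A [build_motion_tree()] result.
#' @param node Node id, 1 = root (decreasing height order).
#' @return List with `$height`, `$members`, `$children` (list of two residue
#'   id vectors).
#' @export
motion_tree_node <- function(tree, node) {
  r <- node_to_merge_row(tree, node)
  ch <- lapply(tree$hclust$merge[r, ], merge_entry_members, tree = tree)
  ch <- lapply(ch, sort)
  list(height = tree$hclust$height[r],
       members = sort(unlist(ch)),
       children = ch)
}

#' Extract two dynamic domains from a Motion Tree node
#'
#' The chosen node's two children become domain candidates; residues in
#' subtrees that split off between the root and the chosen node (the
#' flexible tails and loops that merge only at large fluctuation), and any
#' explicitly flagged flexible nodes, are moved to the removed set. Children
#' smaller than `min_domain_size` cannot form a domain.
#'
#' When `node` is `NULL` the domain node is located automatically: descend
#' from the root, shedding any side branch smaller than `min_domain_size`,
#' until a split with two children of at least `min_domain_size` is reached.
#'
#' @param tree A [build_motion_tree()] result.
#' @param node Node id (1 = root) or `NULL` for automatic descent.
#' @param min_domain_size Smallest residue count accepted as a rigid domain.
#' @param flexible_nodes Optional node ids whose members are removed as
#'   flexible regions (the by-inspection removals at lower nodes).
#' @return A [domain_definition()]; domain 1 is the child containing the
#'   smaller minimum residue id.
#' @export
extract_domains <- function(tree, node = NULL, min_domain_size = 5L,
                            flexible_nodes = integer(0)) {
  if (is.null(tree$hclust)) stop("tree has no internal nodes")
  removed <- integer(0)

  find_row_auto <- function() {
    r <- node_to_merge_row(tree, 1L)     # root merge row
    repeat {
      ch <- lapply(tree$hclust$merge[r, ], merge_entry_members, tree = tree)
      sizes <- lengths(ch)
      if (all(sizes >= min_domain_size)) return(r)
      if (all(sizes < min_domain_size))
        stop("no split with two domains of at least min_domain_size residues")
      small <- which.min(sizes)
      removed <<- c(removed, ch[[small]])
      e <- tree$hclust$merge[r, -small]
      if (e < 0) stop("no split with two domains of at least min_domain_size residues")
      r <- e
    }
  }

  if (is.null(node)) {
    r <- find_row_auto()
  } else {
    r <- node_to_merge_row(tree, node)
    # residues that split off at merges above the chosen node
    here <- merge_entry_members(tree, r)
    removed <- setdiff(tree$residue_ids, here)
  }
  ch <- lapply(tree$hclust$merge[r, ], merge_entry_members, tree = tree)
  if (any(lengths(ch) < min_domain_size))
    stop("chosen node has a child smaller than min_domain_size; ",
         "pick a lower node or reduce min_domain_size")
  for (fn in flexible_nodes) {
    fm <- motion_tree_node(tree, fn)$members
    ch <- lapply(ch, setdiff, y = fm)
    removed <- c(removed, fm)
  }
  if (any(lengths(ch) == 0L))
    stop("flexible_nodes removed an entire domain")
  ord <- order(vapply(ch, min, numeric(1)))
  domain_definition(residues_to_ranges(ch[[ord[1]]]),
                    residues_to_ranges(ch[[ord[2]]]),
                    residues_to_ranges(removed))
}

#' Export a Motion Tree to Newick
#'
#' Branch lengths encode merge-height differences so node depths equal the
#' fluctuation magnitude at each merge.
#'
#' @param tree A `motion_tree`.
#' @param file Output path.
#' @export
write_motion_tree_newick <- function(tree, file) {
  if (is.null(tree$hclust)) stop("tree has no internal nodes")
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = file)
  invisible(file)
}

#' Write a domain definition as delimited text
#'
#' One interval per row with columns `part`, `lo`, `hi`.
#'
#' @param domains A [domain_definition()].
#' @param file Output path (TSV).
#' @export
write_domains_tsv <- function(domains, file) {
  rows <- function(part, rs) if (length(rs))
    data.frame(part = part,
               lo = vapply(rs, `[`, numeric(1), 1),
               hi = vapply(rs, `[`, numeric(1), 2))
  df <- rbind(rows("domain1", domains$domain1),
              rows("domain2", domains$domain2),
              rows("removed", domains$removed))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
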