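#' Neighbor-joining tree from a distance matrix
#'
#' Saitou & Nei agglomeration under the Q-criterion. Ties among minimal-Q
#' pairs are broken by the lexicographically smallest pair of cluster
#' representative labels (the smallest leaf label inside each cluster), making
#' the result independent of input order. Negative intermediate branch lengths
#' are clamped to 0 without redistribution.
#'
#' @param dm a `k2p_dist` or a complete symmetric numeric matrix with
#'   dimnames (substitutions/site).
#' @return An unrooted ape `phylo` over all labels (for n = 2, a single-edge
#'   cherry is returned with a warning).
#' @examples
#' d <- matrix(c(0,3,5,6, 3,0,6,7, 5,6,0,7, 6,7,7,0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' nj_build(d)
#' @export
nj_build <- function(dm) {
  D <- if (inherits(dm, "k2p_dist")) dm$distance else as.matrix(dm)
  labs <- rownames(D)
  stopifnot(!is.null(labs), nrow(D) == ncol(D))
  if (anyNA(D)) {
    und <- which(upper.tri(D) & is.na(D), arr.ind = TRUE)
    stop_ba("distance matrix has %d undefined pair(s) (first: %s / %s); drop or impute before NJ",
            nrow(und), labs[und[1, 1]], labs[und[1, 2]], class = "undefined_distance_error")
  }
  n0 <- length(labs)
  if (n0 < 2L) stop_ba("need at least 2 labels", class = "input_error")
  if (n0 == 2L) {
    warning("only 2 labels: returning a single-edge tree", call. = FALSE)
    h <- max(D[1, 2] / 2, 0)
    txt <- sprintf("(%s:%.10g,%s:%.10g);", quote_label(labs[1]), h, quote_label(labs[2]), h)
    return(ape::read.tree(text = txt))
  }
  frag <- vapply(labs, quote_label, character(1))   # newick fragment per cluster
  rep_lab <- labs                                   # smallest leaf label per cluster
  while (length(rep_lab) > 3L) {
    n <- length(rep_lab)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1L) {
      a <- pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
      b <- pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
      cand <- cand[order(a, b)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], vi, frag[j], vj)
    new_rep <- min(rep_lab[i], rep_lab[j])
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], new_rep)
  }
  # final three-point join
  v1 <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  v2 <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  v3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], v1, frag[2], v2, frag[3], v3)
  ape::read.tree(text = txt)
}

# Tip labels descending from a node.
desc_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  stack <- node; tips <- integer()
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= n) tips <- c(tips, v) else stack <- c(stack, kids[[as.character(v)]])
  }
  tree$tip.label[tips]
}

# Canonical keys for the nontrivial bipartitions of a tree (unrooted sense).
# Each key is the sorted side NOT containing the alphabetically first leaf.
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  anchor <- min(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  keys
}

#' Nonparametric bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, recomputes the K2P matrix
#' and NJ tree per replicate, and annotates each internal bipartition of the
#' original NJ tree with its recovery frequency (percent) as a node label.
#' Replicates whose resampled matrix contains undefined distances are
#' discarded (and counted); more than 50% discarded is an error.
#'
#' @param lib a `reference_library`.
#' @param replicates number of bootstrap replicates (>= 1; default 100).
#' @param seed integer RNG seed; same seed gives identical supports.
#' @param min_overlap passed to the distance computation.
#' @return The original NJ `phylo` with percent supports in `node.label`
#'   (empty for the root and trivial splits) and attributes
#'   `replicates_used` and `replicates_discarded`.
#' @export
bootstrap_support <- function(lib, replicates = 100, seed = 1, min_overlap = 100) {
  stopifnot(inherits(lib, "reference_library"), replicates >= 1)
  dm <- k2p_matrix(lib, min_overlap = min_overlap)
  tree <- nj_build(dm)
  n <- length(tree$tip.label)
  keys <- tree_splits(tree)
  counts <- setNames(numeric(sum(!is.na(keys))), keys[!is.na(keys)])
  m <- encode_sequences(lib$records$sequence, lib$records$specimen_id)
  L <- ncol(m)
  set.seed(seed)
  used <- 0L; discarded <- 0L
  for (b in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    mb <- m[, cols, drop = FALSE]
    db <- k2p_codes(mb)
    if (anyNA(db)) { discarded <- discarded + 1L; next }
    tb <- nj_build(db)
    kb <- tree_splits(tb)
    hit <- intersect(names(counts), kb)
    counts[hit] <- counts[hit] + 1
    used <- used + 1L
  }
  if (discarded > replicates / 2) {
    stop_ba("%d of %d bootstrap replicates produced undefined distances",
            discarded, replicates, class = "bootstrap_error")
  }
  support <- 100 * counts / used
  node_lab <- character(tree$Nnode)
  for (k in seq_along(keys)) {
    if (!is.na(keys[k])) node_lab[k] <- sprintf("%g", support[[keys[k]]])
  }
  tree$node.label <- node_lab
  attr(tree, "replicates_used") <- used
  attr(tree, "replicates_discarded") <- discarded
  tree
}

# Distance matrix straight from an encoded n x L code matrix (bootstrap core).
k2p_codes <- function(m) {
  X <- lapply(1:4, function(b) (m == b) * 1)
  V <- X[[1]] + X[[2]] + X[[3]] + X[[4]]
  sites <- tcrossprod(V)
  matches <- Reduce(`+`, lapply(X, tcrossprod))
  t_ag <- tcrossprod(X[[1]], X[[3]])
  t_ct <- tcrossprod(X[[2]], X[[4]])
  S <- t_ag + t(t_ag) + t_ct + t(t_ct)
  W <- sites - matches - S
  P <- S / sites; Q <- W / sites
  d <- suppressWarnings(-0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q))
  d[!is.finite(d)] <- NA_real_
  d[sites == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path. Ties are
#' broken by the lexicographically smallest leaf pair. If all branch lengths
#' are zero the root is placed on the edge incident to the lexicographically
#' first leaf, with a warning. Support labels are re-attached by bipartition,
#' so the unrooted split set (and its annotation) is unchanged.
#'
#' @param tree an unrooted ape `phylo` with >= 2 leaves.
#' @return A rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 2L) stop_ba("tree has fewer than 2 leaves", class = "tree_error")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  support <- split_support_map(tree)
  Dn <- ape::dist.nodes(tree)
  Dt <- Dn[seq_len(n), seq_len(n), drop = FALSE]
  if (max(Dt) == 0) {
    warning("all leaf-to-leaf distances are zero: rooting on the edge of the first leaf",
            call. = FALSE)
    tip <- order(tree$tip.label)[1]
    parent <- tree$edge[tree$edge[, 2] == tip, 1]
    rooted <- reroot_at_edge(tree, parent, tip, pos = 0)
    return(apply_support_map(rooted, support))
  }
  dmax <- max(Dt)
  cand <- which(Dt == dmax, arr.ind = TRUE)
  cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
  a <- pmin(tree$tip.label[cand[, 1]], tree$tip.label[cand[, 2]])
  b <- pmax(tree$tip.label[cand[, 1]], tree$tip.label[cand[, 2]])
  pick <- cand[order(a, b)[1], ]
  i <- pick[[1]]; j <- pick[[2]]
  half <- dmax / 2
  path <- ape::nodepath(tree, i, j)
  cum <- 0
  for (k in seq_len(length(path) - 1L)) {
    u <- path[k]; v <- path[k + 1L]
    len <- Dn[u, v]
    if (cum + len >= half - 1e-12) {
      rooted <- reroot_at_edge(tree, u, v, pos = min(max(half - cum, 0), len))
      return(apply_support_map(rooted, support))
    }
    cum <- cum + len
  }
  stop_ba("midpoint not found on diameter path (internal error)", class = "tree_error")
}

split_support_map <- function(tree) {
  if (is.null(tree$node.label)) return(NULL)
  keys <- tree_splits(tree)
  ok <- !is.na(keys) & nzchar(tree$node.label)
  setNames(tree$node.label[ok], keys[ok])
}

apply_support_map <- function(tree, support) {
  if (is.null(support)) return(tree)
  keys <- tree_splits(tree)
  lab <- character(tree$Nnode)
  hit <- !is.na(keys) & keys %in% names(support)
  lab[hit] <- support[keys[hit]]
  tree$node.label <- lab
  tree
}

# Root a phylo on edge (u, v) at distance `pos` from u, via adjacency DFS.
reroot_at_edge <- function(tree, u, v, pos) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  adj <- vector("list", nn + 1L)            # slot nn+1 is the new root
  add <- function(a, b, w) {
    adj[[a]][[length(adj[[a]]) + 1L]] <<- c(b, w)
    adj[[b]][[length(adj[[b]]) + 1L]] <<- c(a, w)
  }
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c_ <- tree$edge[e, 2]
    if ((p == u && c_ == v) || (p == v && c_ == u)) next
    add(p, c_, tree$edge.length[e])
  }
  len_uv <- tree$edge.length[which((tree$edge[, 1] == u & tree$edge[, 2] == v) |
                                   (tree$edge[, 1] == v & tree$edge[, 2] == u))]
  root <- nn + 1L
  add(root, u, pos)
  add(root, v, len_uv - pos)
  # iterative DFS from root; tips keep ids 1..n, internal nodes renumbered
  new_id <- integer(nn + 1L)
  n_internal <- 0L
  edges <- matrix(0L, 0L, 2L); lens <- numeric(0)
  # count internal nodes first (root + all original internal nodes on tree)
  is_tip <- function(x) x <= n
  # preorder traversal
  stack <- list(c(root, 0))
  order_nodes <- list()
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- top[1]; parent <- top[2]
    order_nodes[[length(order_nodes) + 1L]] <- c(node, parent)
    if (!is_tip(node)) {
      nbrs <- adj[[node]]
      for (kk in rev(seq_along(nbrs))) {
        nb <- nbrs[[kk]]
        if (nb[1] != parent) stack[[length(stack) + 1L]] <- c(nb[1], node, nb[2])
      }
    }
  }
  # assign ids in preorder: internal nodes get n+1, n+2, ... in first-visit order
  for (rec in order_nodes) {
    node <- rec[1]
    if (!is_tip(node) && new_id[node] == 0L) {
      n_internal <- n_internal + 1L
      new_id[node] <- n + n_internal
    } else if (is_tip(node)) new_id[node] <- node
  }
  # second pass to emit edges with lengths (redo DFS carrying lengths)
  stack <- list(c(root, 0, 0))
  first <- TRUE
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- top[1]; parent <- top[2]; wlen <- top[3]
    if (!first) {
      edges <- rbind(edges, c(new_id[parent], new_id[node]))
      lens <- c(lens, wlen)
    }
    first <- FALSE
    if (!is_tip(node)) {
      nbrs <- adj[[node]]
      for (kk in rev(seq_along(nbrs))) {
        nb <- nbrs[[kk]]
        if (nb[1] != parent) stack[[length(stack) + 1L]] <- c(nb[1], node, nb[2])
      }
    }
  }
  out <- list(edge = edges, edge.length = lens, Nnode = n_internal,
              tip.label = tree$tip.label)
  class(out) <- "phylo"
  attr(out, "order") <- "cladewise"
  ape::collapse.singles(out)
}
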