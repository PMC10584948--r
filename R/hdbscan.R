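#' HDBSCAN clustering of planar points
#'
#' Native implementation of hierarchical density-based clustering
#' (HDBSCAN) with Excess-of-Mass cluster selection, the method used to
#' extract individual nuclear pore complexes from localization clouds.
#' Pipeline: core distances (distance to the `min_samples`-th nearest
#' neighbour, the point itself counting as the first) -> minimum spanning
#' tree of the mutual-reachability graph -> single-linkage hierarchy ->
#' condensed tree at `min_cluster_size` -> cluster stabilities ->
#' Excess-of-Mass selection (the root is never selected, so a single
#' all-points cluster is not returned).
#'
#' Deterministic for fixed input; no randomness is involved.
#'
#' @param xy Two-column numeric matrix of coordinates.
#' @param min_cluster_size Smallest admissible cluster (>= 2).
#' @param min_samples Neighbourhood size for core distances; defaults to
#'   `min_cluster_size`.
#' @return Integer vector of labels, one per row of `xy`: `0` marks
#'   noise, clusters are numbered `1..K`.
#' @export
hdbscan_labels <- function(xy, min_cluster_size, min_samples = min_cluster_size) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  n <- nrow(xy)
  stopifnot(ncol(xy) == 2L, min_cluster_size >= 2L, min_samples >= 1L)
  if (n < min_cluster_size) return(integer(n))

  core <- core_distances(xy, as.integer(min_samples))
  mst <- mutual_reachability_mst(xy, core)
  ord <- order(mst[, 3L])
  slt <- single_linkage_tree(as.integer(mst[ord, 1L]),
                             as.integer(mst[ord, 2L]),
                             mst[ord, 3L], n)
  cond <- .condense_tree(slt, n, min_cluster_size)
  if (is.null(cond)) return(integer(n))
  sel <- .eom_select(cond)
  .condensed_labels(cond, sel, n)
}

# Condense the single-linkage hierarchy: clusters smaller than
# min_cluster_size "fall out" of their parent as points at the lambda
# (= 1/distance) of the split. Returns parallel vectors describing the
# condensed tree rows (parent cluster, child cluster-or-point, lambda,
# child size) plus per-cluster birth lambdas.
.condense_tree <- function(slt, n, mcs) {
  left <- slt$left
  right <- slt$right
  dist <- slt$dist
  size <- slt$size
  node_size <- function(v) ifelse(v <= n, 1L, size[v - n])

  # subtree leaf enumeration (iterative)
  leaves_under <- function(v) {
    out <- integer(0)
    stack <- v
    while (length(stack)) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (u <= n) out[length(out) + 1L] <- u
      else stack <- c(stack, left[u - n], right[u - n])
    }
    out
  }

  root <- 2L * n - 1L
  # preallocate generously: at most n point rows + 2n cluster rows
  cap <- 3L * n
  p_par <- integer(cap); p_child <- integer(cap)
  p_lambda <- numeric(cap); p_size <- integer(cap)
  nrows <- 0L
  add_row <- function(par, child, lambda, csize) {
    nrows <<- nrows + 1L
    p_par[nrows] <<- par; p_child[nrows] <<- child
    p_lambda[nrows] <<- lambda; p_size[nrows] <<- csize
  }

  births <- numeric(2L)  # grows; births[1] = 0 for the root cluster
  births[1L] <- 0
  n_clusters <- 1L

  # stack of (hierarchy node, condensed cluster it continues)
  st_node <- root
  st_clus <- 1L
  # cluster ids are point ids offset by n for child encoding:
  # child <= n -> point, child > n -> cluster id (child - n)
  while (length(st_node)) {
    v <- st_node[length(st_node)]
    cl <- st_clus[length(st_clus)]
    st_node <- st_node[-length(st_node)]
    st_clus <- st_clus[-length(st_clus)]
    if (v <= n) next  # lone leaf continuing a cluster: nothing to record
    i <- v - n
    lambda <- if (dist[i] > 0) 1 / max(dist[i], 1e-12) else 1e12
    l <- left[i]; r <- right[i]
    sl <- node_size(l); sr <- node_size(r)
    if (sl >= mcs && sr >= mcs) {
      for (ch in c(l, r)) {
        n_clusters <- n_clusters + 1L
        births[n_clusters] <- lambda
        add_row(cl, n + n_clusters, lambda, node_size(ch))
        st_node <- c(st_node, ch)
        st_clus <- c(st_clus, n_clusters)
      }
    } else if (sl < mcs && sr < mcs) {
      for (p in leaves_under(v)) add_row(cl, p, lambda, 1L)
    } else {
      small <- if (sl < mcs) l else r
      big <- if (sl < mcs) r else l
      for (p in leaves_under(small)) add_row(cl, p, lambda, 1L)
      st_node <- c(st_node, big)
      st_clus <- c(st_clus, cl)
    }
  }
  if (nrows == 0L) return(NULL)
  list(parent = p_par[seq_len(nrows)], child = p_child[seq_len(nrows)],
       lambda = p_lambda[seq_len(nrows)], size = p_size[seq_len(nrows)],
       births = births[seq_len(n_clusters)], n_clusters = n_clusters,
       n_points = n)
}

# Excess-of-Mass selection over the condensed tree. Returns a logical
# vector over cluster ids; the root (id 1) is never selected.
.eom_select <- function(cond) {
  nc <- cond$n_clusters
  n <- cond$n_points
  stability <- numeric(nc)
  lam <- pmin(cond$lambda, 1e12)
  contrib <- (lam - cond$births[cond$parent]) * cond$size
  agg <- rowsum(contrib, cond$parent)
  stability[as.integer(rownames(agg))] <- agg[, 1L]

  is_cluster_child <- cond$child > n
  kids <- split(cond$child[is_cluster_child] - n,
                cond$parent[is_cluster_child])
  children_of <- vector("list", nc)
  children_of[as.integer(names(kids))] <- kids

  selected <- logical(nc)
  subtree_stab <- numeric(nc)
  # the root (id 1) is excluded from the competition: an all-points
  # cluster is never a valid answer, so it cannot absorb its children
  for (c in rev(seq_len(nc)[-1L])) {
    ch <- children_of[[c]]
    if (is.null(ch) || length(ch) == 0L) {
      selected[c] <- TRUE
      subtree_stab[c] <- stability[c]
    } else if (stability[c] >= sum(subtree_stab[ch])) {
      selected[c] <- TRUE
      subtree_stab[c] <- stability[c]
      # deselect all descendants
      stack <- ch
      while (length(stack)) {
        d <- stack[length(stack)]
        stack <- stack[-length(stack)]
        selected[d] <- FALSE
        if (!is.null(children_of[[d]])) stack <- c(stack, children_of[[d]])
      }
    } else {
      selected[c] <- FALSE
      subtree_stab[c] <- sum(subtree_stab[ch])
    }
  }
  selected
}

# Resolve point labels: each point fell out of one condensed cluster;
# walk up the cluster tree to the nearest selected ancestor (inclusive).
.condensed_labels <- function(cond, selected, n) {
  nc <- cond$n_clusters
  parent_of <- integer(nc)  # 0 for root
  is_cl <- cond$child > n
  parent_of[cond$child[is_cl] - n] <- cond$parent[is_cl]

  resolve <- integer(nc)  # 0 = noise, else selected cluster id
  for (c in seq_len(nc)) {
    v <- c
    while (v != 0L && !selected[v]) v <- parent_of[v]
    resolve[c] <- v
  }
  new_id <- integer(nc)
  sel_ids <- which(selected)
  new_id[sel_ids] <- seq_along(sel_ids)

  labels <- integer(n)
  pts <- cond$child <= n
  labels[cond$child[pts]] <- new_id[pmax(resolve[cond$parent[pts]], 1L)] *
    (resolve[cond$parent[pts]] > 0L)
  labels
}
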