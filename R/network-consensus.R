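#' Density-threshold a connectome
#'
#' Zeroes the diagonal, then keeps the `ceiling(density * E)`
#' largest-weight upper-triangle edges (E = P(P-1)/2) and sets all other
#' entries to zero, preserving the weights of kept edges. Edges compete
#' by signed value, not magnitude. Ties at the cutoff are broken by
#' (lower first parcel id, lower second parcel id) lexical order.
#'
#' @param conn a [pearson_connectome()] result or square symmetric matrix.
#' @param density fraction of edges to keep, in (0, 1].
#' @return square matrix with kept weights, zero elsewhere.
#' @export
density_threshold <- function(conn, density) {
  m <- if (inherits(conn, "connectome")) conn$matrix else as.matrix(conn)
  stopifnot(nrow(m) == ncol(m), density > 0, density <= 1)
  P <- nrow(m)
  diag(m) <- 0
  ut <- which(upper.tri(m))
  E <- length(ut)
  n_keep <- ceiling(density * E)
  idx <- arrayInd(ut, c(P, P))
  w <- m[ut]
  ord <- order(-w, idx[, 1], idx[, 2])
  keep <- ord[seq_len(n_keep)]
  if (all(w[keep] <= 0) || n_keep == 0L)
    stop("density_threshold: empty graph at density ", density)
  out <- matrix(0, P, P)
  out[ut[keep]] <- w[keep]
  out <- out + t(out)
  out
}

#' Community detection on a weighted graph
#'
#' Detects a two-level community partition of a thresholded connectome.
#' The default algorithm is the map-equation optimizer (Infomap) with
#' `n_reps` trial repetitions; a deterministic modularity optimizer
#' (Louvain) is available as `method = "louvain"`. Edges with
#' non-positive weight are dropped before detection (flow-based
#' algorithms require positive weights); isolated parcels become
#' singleton communities. Communities are labeled in decreasing size
#' order.
#'
#' @param adj square weighted adjacency matrix (e.g., from
#'   [density_threshold()]).
#' @param n_reps Infomap trial repetitions (default 50; the field
#'   convention at scale is 1000).
#' @param seed integer RNG seed; the same seed yields the same partition.
#' @param method `"infomap"` or `"louvain"`.
#' @return object of class `network_partition`: `membership` (parcel ->
#'   community id, 1..K, sizes descending), `k`, `objective`
#'   (codelength or modularity), `method`, `seed`.
#' @export
detect_communities <- function(adj, n_reps = 50L, seed = 1L,
                               method = c("infomap", "louvain")) {
  method <- match.arg(method)
  adj <- as.matrix(adj)
  stopifnot(nrow(adj) == ncol(adj))
  if (all(adj == 0)) stop("detect_communities: empty graph")
  pos <- adj
  pos[pos < 0] <- 0
  g <- igraph::graph_from_adjacency_matrix(pos, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  cl <- if (method == "infomap")
    igraph::cluster_infomap(g, nb.trials = n_reps)
  else
    igraph::cluster_louvain(g)
  memb <- igraph::membership(cl)
  obj <- if (method == "infomap") igraph::code_len(cl)
  else igraph::modularity(cl)
  # relabel by decreasing community size, ties by smallest member id
  sizes <- table(memb)
  first <- vapply(split(seq_along(memb), memb), min, numeric(1))
  ord <- order(-as.numeric(sizes), first)
  relab <- integer(length(sizes))
  relab[as.integer(names(sizes))[ord]] <- seq_along(ord)
  structure(list(membership = relab[as.integer(memb)],
                 k = length(sizes), objective = obj,
                 method = method, seed = seed),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("<network_partition> %d parcels -> %d communities (%s, objective %.4g)\n",
              length(x$membership), x$k, x$method, x$objective))
  invisible(x)
}

#' Consensus partition across density thresholds
#'
#' Builds the co-assignment probability matrix `p(i,j)` = fraction of
#' input partitions assigning parcels i and j to the same community,
#' then runs the consensus-clustering loop: threshold `p` at
#' `threshold` (default 0.5), re-cluster several times, rebuild the
#' co-assignment matrix, and repeat until the matrix is binary (all
#' clusterings agree) or `max_iter` is reached.
#'
#' @param partitions list of [network_partition]s (or integer membership
#'   vectors) on the same parcel set, one per density threshold.
#' @param threshold consensus probability cutoff (default 0.5).
#' @param n_reps clusterings per consensus iteration (default 10).
#' @param max_iter iteration cap (default 20); non-convergence returns
#'   the last partition with `converged = FALSE`.
#' @param seed integer seed.
#' @param method community algorithm for the consensus loop.
#' @return object of class `consensus_assignment`: `probability`
#'   (initial co-assignment matrix), `partition` (final membership),
#'   `k`, `converged`, `n_iter`.
#' @export
consensus_partition <- function(partitions, threshold = 0.5, n_reps = 10L,
                                max_iter = 20L, seed = 1L,
                                method = c("infomap", "louvain")) {
  method <- match.arg(method)
  stopifnot(length(partitions) >= 2L)
  membs <- lapply(partitions, function(p)
    if (inherits(p, "network_partition")) p$membership else as.integer(p))
  P <- length(membs[[1]])
  stopifnot(all(vapply(membs, length, integer(1)) == P))
  coassign <- function(ms) {
    acc <- matrix(0, P, P)
    for (m in ms) acc <- acc + outer(m, m, "==")
    acc / length(ms)
  }
  prob0 <- coassign(membs)
  prob <- prob0
  converged <- FALSE
  iter <- 0L
  final <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    thr <- prob
    thr[thr < threshold] <- 0
    diag(thr) <- 0
    parts <- lapply(seq_len(n_reps), function(i)
      detect_communities(thr, n_reps = 5L, seed = seed + 1000L * iter + i,
                         method = method)$membership)
    prob <- coassign(parts)
    final <- parts[[1]]
    if (all(prob %in% c(0, 1))) { converged <- TRUE; break }
  }
  diag(prob0) <- 1
  structure(list(probability = prob0, partition = final,
                 k = length(unique(final)), converged = converged,
                 n_iter = iter),
            class = "consensus_assignment")
}

#' @export
print.consensus_assignment <- function(x, ...) {
  cat(sprintf("<consensus_assignment> %d parcels -> %d networks (%s after %d iteration%s)\n",
              length(x$partition), x$k,
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              if (x$n_iter == 1L) "" else "s"))
  invisible(x)
}

#' Reassign parcels from excess communities to neighboring networks
#'
#' Communities are ranked by size (descending). Parcels in communities
#' ranked beyond `max_networks` are ambiguous outputs and are
#' reassigned to the modal network among their spatial neighbors that
#' belong to retained networks; a parcel with no such neighbor joins
#' the globally largest network (counted and reported). Retained
#' communities are relabeled 1..max by descending size; their parcels
#' never move.
#'
#' @param partition integer membership vector or [network_partition].
#' @param max_networks largest allowed number of networks (e.g., 17).
#' @param neighbors two-column matrix/data.frame of undirected parcel
#'   adjacencies (parcel id, neighbor id).
#' @return list: `membership` (relabeled, <= max_networks communities),
#'   `n_reassigned`, `n_fallback` (parcels sent to the largest network).
#' @export
reassign_excess <- function(partition, max_networks, neighbors) {
  memb <- if (inherits(partition, "network_partition"))
    partition$membership else as.integer(partition)
  P <- length(memb)
  nb <- as.matrix(neighbors)[, 1:2, drop = FALSE]
  adj_list <- lapply(seq_len(P), function(i)
    unique(c(nb[nb[, 1] == i, 2], nb[nb[, 2] == i, 1])))
  sizes <- sort(table(memb), decreasing = TRUE)
  comm_ids <- as.integer(names(sizes))
  retained <- comm_ids[seq_len(min(max_networks, length(comm_ids)))]
  excess_parcels <- which(!(memb %in% retained))
  out <- memb
  n_fallback <- 0L
  largest <- comm_ids[1]
  for (p in excess_parcels) {
    nb_comms <- out[adj_list[[p]]]
    nb_comms <- nb_comms[nb_comms %in% retained]
    if (!length(nb_comms)) {
      out[p] <- largest
      n_fallback <- n_fallback + 1L
    } else {
      tab <- sort(table(nb_comms), decreasing = TRUE)
      out[p] <- as.integer(names(tab)[1])
    }
  }
  # relabel retained communities by descending size
  sizes2 <- sort(table(out), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes2), names(sizes2))
  list(membership = as.integer(relab[as.character(out)]),
       n_reassigned = length(excess_parcels),
       n_fallback = n_fallback)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same parcel
#' set; 1 means identical partitions (up to label permutation), 0 the
#' expected agreement of independent random partitions.
#'
#' @param a,b integer membership vectors of equal length.
#' @return scalar adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  igraph::compare(as.integer(a), as.integer(b), method = "adjusted.rand")
}
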