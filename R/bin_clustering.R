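#' @importFrom igraph graph_from_adjacency_matrix components
NULL

# Stable bin labels: "SYN:NNNN", zero-padded ordinal assigned by the input
# order of each bin's first member. Never mints real BOLD BIN URIs.
.relabel_partition <- function(membership, ids) {
  first_seen <- !duplicated(membership)
  ord <- match(membership, membership[first_seen])
  stats::setNames(sprintf("SYN:%04d", ord), ids)
}

.new_bin_partition <- function(assignment, threshold, refined) {
  structure(list(assignment = assignment, threshold = threshold,
                 refined = refined),
            class = "bin_partition")
}

#' @export
print.bin_partition <- function(x, ...) {
  cat("bin_partition: ", length(x$assignment), " sequences in ",
      length(unique(x$assignment)), " bins (threshold ", x$threshold,
      if (x$refined) ", MCL-refined" else "", ")\n", sep = "")
  invisible(x)
}

#' Bins of a partition as a list of member IDs
#' @param partition A `"bin_partition"`.
#' @return Named list: bin id -> character vector of process IDs.
#' @export
bin_members <- function(partition) {
  split(names(partition$assignment), partition$assignment)
}

#' Initial OTU clustering by threshold single linkage
#'
#' Two sequences share a bin iff they are connected by a chain of pairs each
#' at distance <= `threshold` (single-linkage connected components of the
#' thresholded graph). Bins are labelled "SYN:NNNN" in order of each bin's
#' first member in the input.
#'
#' @param matrix Symmetric distance matrix with zero diagonal and ID
#'   dimnames, as from [distance_matrix()].
#' @param threshold Distance threshold (fraction).
#' @return A `"bin_partition"` with fields `assignment` (named character:
#'   process_id -> bin id), `threshold`, `refined = FALSE`.
#' @export
single_linkage_cluster <- function(matrix, threshold) {
  n <- nrow(matrix)
  if (is.null(n) || n == 0L)
    return(.new_bin_partition(stats::setNames(character(0), character(0)),
                              threshold, FALSE))
  stopifnot(isSymmetric(unname(matrix)), all(diag(matrix) == 0))
  ids <- rownames(matrix)
  adj <- (matrix <= threshold) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  .new_bin_partition(.relabel_partition(as.integer(comp), ids),
                     threshold, FALSE)
}

# One Markov-clustering run on a column-stochastic matrix built from a
# similarity matrix (self-loops at weight 1). Returns an integer membership
# vector, or NULL on non-convergence.
.mcl <- function(sim, inflation, max_iter = 100L, tol = 1e-8,
                 prune = 1e-12) {
  n <- nrow(sim)
  diag(sim) <- 1
  norm_cols <- function(m) sweep(m, 2L, colSums(m), "/")
  M <- norm_cols(sim)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    M2 <- M %*% M           # expansion (power 2)
    M2 <- M2^inflation      # inflation
    M2[M2 < prune] <- 0
    M2 <- norm_cols(M2)
    if (max(abs(M2 - M)) < tol) {
      M <- M2
      converged <- TRUE
      break
    }
    M <- M2
  }
  if (!converged) return(NULL)
  # Attractors are rows with mass on the diagonal; each node joins the first
  # attractor whose row gives it positive mass (deterministic in input order).
  attractors <- which(diag(M) > tol)
  if (!length(attractors)) return(NULL)
  membership <- integer(n)
  for (a in attractors) {
    claim <- which(M[a, ] > tol & membership == 0L)
    membership[claim] <- a
  }
  membership[membership == 0L] <- seq_len(n)[membership == 0L]
  membership
}

#' Refine an initial partition by Markov clustering
#'
#' Within each initial cluster of size >= 3, builds a similarity graph with
#' edge weights max(0, 1 - d / similarity_scale), runs Markov clustering
#' (expansion 2, the given inflation, up to 100 iterations) and splits the
#' cluster according to the resulting attractors. Clusters of size < 3 pass
#' through unchanged; refinement never merges across initial clusters. A
#' cluster whose MCL run fails to converge is kept unsplit with a warning.
#'
#' @param partition A `"bin_partition"` from [single_linkage_cluster()].
#' @param matrix The same distance matrix the partition was built from.
#' @param inflation MCL inflation exponent (default 2).
#' @param similarity_scale Distance at which similarity reaches zero;
#'   defaults to the partition's threshold.
#' @return A `"bin_partition"` with `refined = TRUE`; every refined bin is a
#'   subset of an initial bin.
#' @export
mcl_refine <- function(partition, matrix, inflation = 2,
                       similarity_scale = partition$threshold) {
  stopifnot(inherits(partition, "bin_partition"))
  ids <- names(partition$assignment)
  stopifnot(all(ids %in% rownames(matrix)))
  groups <- integer(length(ids))
  names(groups) <- ids
  next_gid <- 0L
  for (bin in unique(partition$assignment)) {
    members <- ids[partition$assignment == bin]
    if (length(members) < 3L) {
      next_gid <- next_gid + 1L
      groups[members] <- next_gid
      next
    }
    d <- matrix[members, members, drop = FALSE]
    sim <- 1 - d / similarity_scale
    sim[sim < 0] <- 0
    membership <- .mcl(sim, inflation = inflation)
    if (is.null(membership)) {
      warning("MCL did not converge for bin ", bin, "; kept unsplit")
      membership <- rep(1L, length(members))
    }
    for (sub in unique(membership)) {
      next_gid <- next_gid + 1L
      groups[members[membership == sub]] <- next_gid
    }
  }
  .new_bin_partition(.relabel_partition(groups, ids),
                     partition$threshold, TRUE)
}

#' Assign sequences to BIN-style OTUs
#'
#' The staged clustering pipeline: uncorrected pairwise distances ->
#' threshold single linkage -> optional Markov-clustering refinement.
#' Deterministic for a fixed input order; no randomness anywhere.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param threshold Single-linkage distance threshold; the default 0.022 is
#'   the published seed threshold for BIN-style clustering of COI barcodes.
#' @param refine Run [mcl_refine()] after single linkage?
#' @param inflation Inflation for the refinement stage.
#' @return A `"bin_partition"`.
#' @export
assign_bins <- function(seqs, threshold = 0.022, refine = TRUE,
                        inflation = 2) {
  if (length(seqs) == 0L) stop("need at least one sequence")
  dm <- distance_matrix(seqs, metric = "p")
  part <- single_linkage_cluster(dm, threshold)
  if (refine) part <- mcl_refine(part, dm, inflation = inflation)
  part
}

#' Rand index between two labellings
#'
#' Proportion of specimen pairs on which two partitions agree (co-clustered
#' in both or separated in both); 1 means identical partitions.
#'
#' @param a,b Label vectors over the same elements (same order).
#' @return Numeric in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L) return(1)
  tab <- table(a, b)
  s_nij <- sum(choose(tab, 2))
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * s_nij - s_a - s_b) / total
}

#' Compare a computed partition against prior bin labels
#'
#' Contingency table and Rand index between a computed partition and, e.g.,
#' the `bin_label` column of an input download. Records lacking a prior
#' label are dropped from the comparison.
#'
#' @param partition A `"bin_partition"`.
#' @param labels Named character vector of prior labels (process_id -> bin).
#' @return list(contingency = table, rand_index = numeric, n_compared).
#' @export
compare_partitions <- function(partition, labels) {
  labels <- labels[nzchar(labels)]
  common <- intersect(names(partition$assignment), names(labels))
  a <- partition$assignment[common]
  b <- labels[common]
  list(contingency = table(computed = a, prior = b),
       rand_index = if (length(common)) rand_index(a, b) else NA_real_,
       n_compared = length(common))
}
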