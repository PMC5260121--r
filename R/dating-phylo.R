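## Kimura 2-parameter distances, insertion-age estimation from 5'-3' LTR
## divergence, neighbor-joining tree construction and bootstrap supports.
##
## At integration the two LTRs of a provirus are identical; both then accrue
## neutral substitutions independently, so the element's age is d / (2*mu).
## A subfamily's age is estimated rho-style: mean K2P distance from each LTR
## to the subfamily consensus, divided by mu (single-lineage accumulation
## from the ancestral sequence).

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Columns containing a gap or N in either sequence are dropped (pairwise
#' deletion). P and Q are the transition and transversion proportions over
#' the remaining columns and
#' d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q).
#'
#' @param seq1,seq2 aligned sequences (equal length).
#' @return list with P, Q, d, n_sites.
#' @export
k2p_distance <- function(seq1, seq2) {
  a <- seq_to_chars(toupper(seq1))
  b <- seq_to_chars(toupper(seq2))
  stopifnot(length(a) == length(b))
  valid <- a %in% DNA_BASES & b %in% DNA_BASES
  n <- sum(valid)
  if (n == 0) stop("no valid columns for K2P distance")
  a <- a[valid]; b <- b[valid]
  diff <- a != b
  ts <- diff & TRANSITION[a] == b
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("distance saturated: K2P undefined")
  list(P = P, Q = Q, d = -0.5 * log(w1) - 0.25 * log(w2), n_sites = n)
}

#' Insertion age from LTR-LTR divergence
#'
#' Both LTRs accumulate substitutions independently after insertion, so
#' age_myr = d / (2 * mu).
#'
#' @param d K2P distance between the 5' and 3' LTR (substitutions/site).
#' @param mu mutation rate in substitutions/site/myr (default 0.0019, i.e.
#'   0.19% per myr).
#' @return age in million years.
#' @export
estimate_age <- function(d, mu = 0.0019) {
  stopifnot(all(d >= 0), mu > 0)
  d / (2 * mu)
}

#' Subfamily age from divergence to the subfamily consensus
#'
#' Rho-style estimator: the column-majority consensus of the aligned LTR set
#' stands in for the ancestral sequence; the mean K2P distance from each LTR
#' to it, divided by mu, is the subfamily age (each lineage accumulates
#' mutations once since the ancestor).
#'
#' @param aligned_ltrs character matrix (rows = aligned LTRs) or named
#'   character vector of equal-length aligned sequences (>= 3).
#' @param mu substitutions/site/myr (default 0.0019).
#' @return list with age_myr, mean_d, consensus.
#' @export
subfamily_age <- function(aligned_ltrs, mu = 0.0019) {
  if (!is.matrix(aligned_ltrs)) {
    stopifnot(length(unique(nchar(aligned_ltrs))) == 1)
    aligned_ltrs <- do.call(rbind, lapply(aligned_ltrs, function(s)
      seq_to_chars(toupper(s))))
  }
  stopifnot(nrow(aligned_ltrs) >= 3)
  cons <- apply(aligned_ltrs, 2, function(col) {
    col <- col[col %in% c(DNA_BASES, "-")]
    if (length(col) == 0) return("N")
    tab <- sort(table(col), decreasing = TRUE)
    sort(names(tab)[tab == max(tab)])[1]
  })
  cons_seq <- chars_to_seq(cons)
  ds <- vapply(seq_len(nrow(aligned_ltrs)), function(i)
    k2p_distance(chars_to_seq(aligned_ltrs[i, ]), cons_seq)$d, numeric(1))
  list(age_myr = mean(ds) / mu, mean_d = mean(ds), consensus = cons_seq)
}

#' Pairwise K2P distance matrix of an alignment
#'
#' Vectorized over indicator matrices; pairwise deletion of gap/N columns.
#'
#' @param msa character matrix (rows = sequences) with rownames.
#' @return symmetric numeric matrix of K2P distances.
#' @export
k2p_matrix <- function(msa) {
  stopifnot(is.matrix(msa))
  n <- nrow(msa)
  ind <- lapply(DNA_BASES, function(b) (msa == b) * 1)
  names(ind) <- DNA_BASES
  V <- ind$A + ind$C + ind$G + ind$T
  nn <- V %*% t(V)
  ts <- ind$A %*% t(ind$G) + ind$G %*% t(ind$A) +
    ind$C %*% t(ind$T) + ind$T %*% t(ind$C)
  R1 <- ind$A + ind$G; Y1 <- ind$C + ind$T
  tv <- R1 %*% t(Y1) + Y1 %*% t(R1)
  P <- ts / nn; Q <- tv / nn
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (any(nn[upper.tri(nn)] == 0)) stop("sequence pair with no valid columns")
  if (any(w1[upper.tri(w1)] <= 0) || any(w2[upper.tri(w2)] <= 0)) {
    stop("distance saturated: K2P undefined for some pair")
  }
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  diag(d) <- 0
  dimnames(d) <- list(rownames(msa), rownames(msa))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration. Negative branch lengths are clamped to zero
#' with the deficit shifted to the sister branch, so path lengths between
#' joined leaves are preserved. Ties in the Q criterion break toward the
#' lowest index pair, making the construction deterministic.
#'
#' @param dist_matrix symmetric matrix with zero diagonal and row/col names
#'   (n >= 3).
#' @return an `ape::phylo` unrooted tree.
#' @export
nj_tree <- function(dist_matrix) {
  D <- as.matrix(dist_matrix)
  n <- nrow(D)
  stopifnot(n >= 3, isTRUE(all.equal(D, t(D))), all(diag(D) == 0))
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  ## each active cluster is a newick fragment
  frags <- labels
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
    i <- min(ij); jx <- max(ij)
    vi <- 0.5 * D[i, jx] + (r[i] - r[jx]) / (2 * (m - 2))
    vj <- D[i, jx] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frags[i], fmt(vi), frags[jx], fmt(vj))
    dk <- 0.5 * (D[i, -c(i, jx)] + D[jx, -c(i, jx)] - D[i, jx])
    keep <- setdiff(seq_len(m), c(i, jx))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk), c(dk, 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], "joined")
    frags <- c(frags[keep], newfrag)
    D <- D2
  }
  ## final three-point resolution
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frags[1], fmt(v1), frags[2], fmt(v2), frags[3], fmt(v3))
  ape::read.tree(text = nwk)
}

## Non-trivial bipartitions of an unrooted tree as canonical keys.
## Each split is represented by the sorted tip set NOT containing the
## alphabetically first label (a tree-order-independent canonical form).
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  anchor <- sort(labs)[1]
  n <- length(labs)
  keys <- vapply(parts, function(p) {
    side <- labs[p]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal bipartition of the reference
#' tree the percentage of replicates containing it. Reproducible given
#' `seed`.
#'
#' @param msa character matrix (rows = aligned sequences, with rownames).
#' @param n_reps number of replicates (default 1000); 0 returns empty
#'   supports.
#' @param seed RNG seed.
#' @param tree optional reference tree; rebuilt from `msa` when NULL.
#' @return list with tree (reference, `node.label` set to supports),
#'   supports (named vector, % per internal split), n_reps.
#' @export
bootstrap_supports <- function(msa, n_reps = 1000, seed = 1, tree = NULL) {
  stopifnot(is.matrix(msa), ncol(msa) >= 2)
  if (is.null(tree)) tree <- nj_tree(k2p_matrix(msa))
  ref_splits <- tree_splits(tree)
  if (n_reps == 0) {
    return(list(tree = tree, supports = stats::setNames(numeric(0),
                                                        character(0)),
                n_reps = 0))
  }
  counts <- stats::setNames(numeric(length(ref_splits)), ref_splits)
  set.seed(seed)
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(ncol(msa), replace = TRUE)
    rep_tree <- nj_tree(k2p_matrix(msa[, cols, drop = FALSE]))
    hit <- intersect(ref_splits, tree_splits(rep_tree))
    counts[hit] <- counts[hit] + 1
  }
  supports <- 100 * counts / n_reps
  list(tree = annotate_supports(tree, supports), supports = supports,
       n_reps = n_reps)
}

## Attach support percentages as internal-node labels of the reference tree.
annotate_supports <- function(tree, supports) {
  tree <- ape::unroot(tree)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  anchor <- sort(labs)[1]
  n <- length(labs)
  node_lab <- character(tree$Nnode)
  for (k in seq_along(parts)) {
    side <- labs[parts[[k]]]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2 || length(side) > n - 2) next
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(supports)) {
      node_lab[k] <- sprintf("%g", supports[[key]])
    }
  }
  tree$node.label <- node_lab
  tree
}

#' Path-length (patristic) distance matrix of a tree
#' @param tree `ape::phylo`.
#' @return matrix of tip-to-tip path lengths.
#' @export
tree_path_lengths <- function(tree) {
  ape::cophenetic.phylo(tree)
}
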