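# Verification phylogenetics: Kimura 2-parameter distances, a
# neighbor-joining tree, and bootstrap supports. This module is not on the
# identification path; it mirrors the assay's use of a Cytb tree to
# cross-validate PCR-RFLP calls. Tree construction, bipartition counting
# and newick I/O are delegated to ape; the K2P computation is local
# because callers need the transition/transversion proportions and an
# explicit saturation flag.

.TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Kimura 2-parameter distance between two sequences
#'
#' Computes the transition proportion P and transversion proportion Q over
#' the sites where both sequences carry an unambiguous A/C/G/T (pairwise
#' deletion of ambiguous sites), and the distance
#' \deqn{d = -\tfrac{1}{2}\,\ln\bigl((1-2P-Q)\sqrt{1-2Q}\bigr).}
#' When \eqn{1-2P-Q \le 0} or \eqn{1-2Q \le 0} the correction is undefined
#' (substitutional saturation); the result carries \code{saturated = TRUE}
#' and an \code{NA} distance rather than an error.
#'
#' @param a,b \code{dna_seq} or residue strings of equal length (treated
#'   as pre-aligned).
#' @return List with \code{distance}, \code{P}, \code{Q}, \code{n_sites}
#'   (included sites) and \code{saturated}.
#' @export
k2p_distance <- function(a, b) {
  ra <- strsplit(.residues(a), "")[[1]]
  rb <- strsplit(.residues(b), "")[[1]]
  if (length(ra) != length(rb)) {
    stop("sequences must have equal length (pre-aligned)")
  }
  keep <- ra %in% names(.TRANSITIONS) & rb %in% names(.TRANSITIONS)
  n <- sum(keep)
  if (n == 0) stop("no unambiguous sites shared by the two sequences")
  ra <- ra[keep]; rb <- rb[keep]
  diff <- ra != rb
  ts <- diff & (.TRANSITIONS[ra] == rb)
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(distance = NA_real_, P = P, Q = Q, n_sites = n,
                saturated = TRUE))
  }
  list(distance = -0.5 * log(w1) - 0.25 * log(w2), P = P, Q = Q,
       n_sites = n, saturated = FALSE)
}

#' Pairwise K2P distance matrix
#'
#' @param seqs List of \code{dna_seq} (equal lengths) or a named character
#'   vector.
#' @return Symmetric numeric matrix with taxon dimnames; saturated pairs
#'   are \code{NA} and listed in the \code{saturated_pairs} attribute.
#' @export
k2p_matrix <- function(seqs) {
  if (is.character(seqs)) {
    seqs <- lapply(seq_along(seqs), function(i) {
      dna_seq(seqs[i], id = names(seqs)[i] %||% paste0("seq", i))
    })
  }
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  ids <- vapply(seqs, function(s) s$id, character(1))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- k2p_distance(seqs[[i]], seqs[[j]])
      m[i, j] <- m[j, i] <- r$distance
      if (r$saturated) sat <- c(sat, paste(ids[i], ids[j], sep = "|"))
    }
  }
  attr(m, "saturated_pairs") <- sat
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor-joining (via \code{ape::nj}), followed by
#' clamping of negative branch lengths to zero with the negative amount
#' transferred to the sibling branch, so paths between the two subtended
#' leaf sets are preserved and all branch lengths stay interpretable.
#'
#' @param m Symmetric distance matrix (>= 3 taxa) with taxon dimnames; may
#'   also be a \code{dist}.
#' @return An \code{ape::phylo} tree (unrooted).
#' @export
nj_tree <- function(m) {
  if (inherits(m, "dist")) m <- as.matrix(m)
  if (nrow(m) < 3) stop("neighbor-joining needs at least 3 taxa")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("distance undefined (saturated?) for pair %s | %s",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  tr <- ape::nj(m)
  neg <- which(tr$edge.length < 0)
  for (i in neg) {
    parent <- tr$edge[i, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), i)
    if (length(sib)) {
      # transfer the negative amount to the sibling so paths between the
      # two subtended leaf sets (and the total tree length) are preserved
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + tr$edge.length[i]
    }
    tr$edge.length[i] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ
#' tree per replicate, and annotates each internal bipartition of the
#' full-data tree with the percentage of replicates containing it.
#' Per-replicate RNG streams are derived from the seed by counter, so the
#' result is reproducible and independent of evaluation order. Replicates
#' in which some pair is saturated are skipped and counted; a warning is
#' issued when more than 5\% are skipped.
#'
#' @param aln List of equal-length \code{dna_seq} (>= 3).
#' @param replicates Number of bootstrap replicates (assay default 1000).
#' @param seed Integer seed.
#' @return An \code{ape::phylo} tree whose \code{node.label} holds the
#'   support percentages (root label empty), with attributes
#'   \code{n_replicates} and \code{n_skipped}.
#' @export
bootstrap_tree <- function(aln, replicates = 1000, seed = 1) {
  stopifnot(replicates >= 1, length(aln) >= 3)
  L <- unique(vapply(aln, function(s) nchar(s$residues), integer(1)))
  if (length(L) != 1) stop("alignment sequences must have equal length")
  chars <- do.call(rbind, lapply(aln, function(s) {
    strsplit(s$residues, "")[[1]]
  }))
  rownames(chars) <- vapply(aln, function(s) s$id, character(1))
  full <- nj_tree(k2p_matrix(aln))

  rep_seeds <- .with_seed(seed, sample.int(2147483647L, replicates))
  boots <- vector("list", replicates)
  skipped <- 0L
  for (r in seq_len(replicates)) {
    cols <- .with_seed(rep_seeds[r], sample.int(L, L, replace = TRUE))
    reps <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
    m <- k2p_matrix(stats::setNames(reps, rownames(chars)))
    if (anyNA(m)) {
      skipped <- skipped + 1L
      next
    }
    boots[[r]] <- nj_tree(m)
  }
  boots <- boots[!vapply(boots, is.null, logical(1))]
  if (skipped > 0.05 * replicates) {
    warning(sprintf("%d of %d bootstrap replicates skipped (saturation)",
                    skipped, replicates))
  }
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supports <- round(100 * counts / max(length(boots), 1), 1)
  full$node.label <- as.character(supports)
  full$node.label[1] <- ""  # root of the unrooted representation
  attr(full, "n_replicates") <- replicates
  attr(full, "n_skipped") <- skipped
  full
}

#' Root a tree on a designated outgroup leaf
#'
#' Rooting preserves all bipartitions; it only fixes the direction of
#' reading, which is how an outgroup (e.g. a distant mammalian Cytb) is
#' used when presenting the verification tree.
#'
#' @param tree An \code{ape::phylo}.
#' @param outgroup Leaf name.
#' @return Rooted \code{ape::phylo}.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) stop("outgroup not in tree: ", outgroup)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Write / read newick
#'
#' Standard newick with branch lengths; internal-node support labels, when
#' present, appear after the closing parentheses.
#'
#' @param tree An \code{ape::phylo}.
#' @param path Output file.
#' @return \code{write_newick}: invisibly, \code{path};
#'   \code{read_newick}: an \code{ape::phylo}.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
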