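#' Minor-allele-frequency summary per group
#'
#' Per-locus alternate-allele frequencies (`sum(codes) / (2 n_called)`) and
#' the minor allele frequency `min(f, 1 - f)`, computed within each group of
#' samples and overall, with the per-group mean and range across loci.
#'
#' @param m a [diplo_matrix()].
#' @param groups optional named character vector or data.frame
#'   (`sample`, `group`) mapping samples to groups (e.g. broad geographical
#'   regions).
#' @return list with `per_locus` (locus x group MAF table) and `summary`
#'   (group, n_samples, n_loci_used, mean_maf, min_maf, max_maf).
#' @export
maf_summary <- function(m, groups = NULL) {
  stopifnot(inherits(m, "diplo_matrix"))
  g <- normalize_groups(groups, sample_names(m))
  group_list <- split(names(g), g)
  group_list$Total <- sample_names(m)
  per_locus <- data.frame(locus = locus_ids(m$loci), stringsAsFactors = FALSE)
  summ <- lapply(names(group_list), function(gn) {
    cols <- match(group_list[[gn]], sample_names(m))
    codes <- m$codes[, cols, drop = FALSE]
    n_called <- rowSums(!is.na(codes))
    f <- rowSums(codes, na.rm = TRUE) / (2 * pmax(n_called, 1L))
    maf <- pmin(f, 1 - f)
    maf[n_called == 0L] <- NA_real_
    per_locus[[gn]] <<- maf
    used <- !is.na(maf)
    data.frame(group = gn, n_samples = length(cols),
               n_loci_used = sum(used), n_loci_skipped = sum(!used),
               mean_maf = mean(maf[used]), min_maf = min(maf[used]),
               max_maf = max(maf[used]), stringsAsFactors = FALSE)
  })
  list(per_locus = per_locus, summary = do.call(rbind, summ))
}

normalize_groups <- function(groups, samples) {
  if (is.null(groups)) return(stats::setNames(rep("all", length(samples)),
                                              samples))
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups[[2]]),
                              as.character(groups[[1]]))
  }
  unknown <- setdiff(names(groups), samples)
  if (length(unknown))
    stop_param("labeled sample(s) not in the genotype matrix: ",
               paste(utils::head(unknown, 5), collapse = ", "))
  groups[intersect(samples, names(groups))]
}

#' Pairwise p-distance between samples
#'
#' The proportion of differing alleles between two samples over their
#' jointly called loci: `d(i,j) = sum |code_i - code_j| / (2 L_called)`.
#' Heterozygote-vs-homozygote pairs contribute one half; loci missing in
#' either sample are excluded pairwise.
#'
#' @param m a [diplo_matrix()].
#' @return square symmetric numeric matrix with zero diagonal, sample names
#'   as dimnames.
#' @export
p_distance <- function(m) {
  stopifnot(inherits(m, "diplo_matrix"))
  g <- m$codes
  called <- !is.na(g)
  ind <- lapply(0:2, function(v) {
    x <- called & g == v
    x[is.na(x)] <- FALSE
    storage.mode(x) <- "numeric"
    x
  })
  # C[a][b][i,j] = number of loci where sample i has code a and j has code b
  C01 <- crossprod(ind[[1]], ind[[2]]); C02 <- crossprod(ind[[1]], ind[[3]])
  C12 <- crossprod(ind[[2]], ind[[3]])
  num <- C01 + t(C01) + 2 * (C02 + t(C02)) + C12 + t(C12)
  storage.mode(called) <- "numeric"
  joint <- crossprod(called)
  if (any(joint[upper.tri(joint)] == 0)) {
    idx <- which(joint == 0 & upper.tri(joint), arr.ind = TRUE)[1, ]
    stop_param("no jointly called loci for samples ",
               colnames(g)[idx[1]], " and ", colnames(g)[idx[2]])
  }
  d <- num / (2 * joint)
  diag(d) <- 0
  dimnames(d) <- list(colnames(g), colnames(g))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (Studier-Keppler criterion) on a symmetric
#' distance matrix; exact on additive matrices. Negative branch lengths —
#' possible on non-additive data — are clamped to zero and counted.
#'
#' @param D square symmetric distance matrix with dimnames (n >= 3).
#' @return an [ape::phylo] unrooted tree; attribute `n_clamped` counts
#'   negative branch lengths clamped to 0.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop_param("neighbor joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-12) stop_param("distance matrix must be symmetric")
  tree <- ape::nj(D)
  neg <- tree$edge.length < 0
  if (any(neg)) tree$edge.length[neg] <- 0
  attr(tree, "n_clamped") <- sum(neg)
  tree
}

# collapse internal edges whose support is below a threshold, keeping leaf
# set and remaining branch lengths; operates on the ape edge table directly
collapse_edges <- function(tree, drop_nodes) {
  while (length(drop_nodes)) {
    node <- drop_nodes[1]
    parent_edge <- which(tree$edge[, 2] == node)
    if (length(parent_edge) == 0) { drop_nodes <- drop_nodes[-1]; next }
    parent <- tree$edge[parent_edge, 1]
    tree$edge[tree$edge[, 1] == node, 1] <- parent
    tree$edge <- tree$edge[-parent_edge, , drop = FALSE]
    tree$edge.length <- tree$edge.length[-parent_edge]
    ntip <- length(tree$tip.label)
    # renumber internal nodes above the removed one
    lab_keep <- tree$node.label[-(node - ntip)]
    shift <- tree$edge > node
    tree$edge[shift] <- tree$edge[shift] - 1L
    tree$node.label <- lab_keep
    tree$Nnode <- tree$Nnode - 1L
    drop_nodes <- drop_nodes[-1]
    drop_nodes[drop_nodes > node] <- drop_nodes[drop_nodes > node] - 1L
  }
  tree
}

#' Neighbor-joining tree with bootstrap interior-branch support
#'
#' Loci are resampled with replacement `n_boot` times; each replicate's
#' p-distance matrix yields a neighbor-joining tree, and the support of an
#' internal branch of the full-data tree is the percentage of replicates
#' containing its bipartition. Branches below `collapse_below` percent are
#' collapsed into polytomies.
#'
#' @param m a [diplo_matrix()].
#' @param n_boot bootstrap replicates (default 1000).
#' @param collapse_below support percentage under which branches collapse
#'   (default 50).
#' @param seed integer seed.
#' @return an [ape::phylo] tree whose `node.label` holds support
#'   percentages (NA at the root), with low-support branches collapsed.
#' @export
interior_branch_support <- function(m, n_boot = 1000, collapse_below = 50,
                                    seed = 1) {
  stopifnot(inherits(m, "diplo_matrix"))
  if (n_boot < 1) stop_param("n_boot must be >= 1")
  main <- neighbor_joining(p_distance(m))
  L <- nrow(m$codes)
  boots <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(L, L, replace = TRUE)
      mb <- diplo_matrix(transform(m$loci[idx, , drop = FALSE],
                                   pos = seq_len(L)),
                         m$codes[idx, , drop = FALSE])
      neighbor_joining(p_distance(mb))
    })
  })
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  support <- 100 * counts / n_boot
  main$node.label <- round(support, 1)
  ntip <- length(main$tip.label)
  internal <- seq_len(main$Nnode) + ntip
  # the root "bipartition" is trivial; never collapse it
  low <- internal[which(!is.na(support) & support < collapse_below)]
  low <- setdiff(low, ntip + 1L)
  collapse_edges(main, sort(low, decreasing = TRUE))
}
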