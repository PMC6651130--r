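# miRNA family evolution: presence/absence across genomes, Dollo-style
# single-gain birth/death reconstruction on dated species trees,
# Poisson-corrected NJ trees of target proteins, and network/overlap
# summaries.

#' Build a miRNA x species presence (locus count) matrix
#'
#' Cell (m, s) is the number of perfect-match genome loci of mature miRNA
#' m in species s (both strands); presence means count >= 1.
#'
#' @param mirnas `seq_set` of mature miRNAs.
#' @param genomes named list of DNA `seq_set` genomes, one per species.
#' @return integer matrix, rows = miRNA ids, columns = species names.
#' @export
build_presence_matrix <- function(mirnas, genomes) {
  mat <- matrix(0L, nrow = nrow(mirnas), ncol = length(genomes),
                dimnames = list(mirnas$id, names(genomes)))
  for (s in names(genomes)) {
    for (i in seq_len(nrow(mirnas))) {
      loci <- find_perfect_loci(mirnas[i, ], genomes[[s]])
      mat[i, s] <- nrow(loci)
    }
  }
  mat
}

#' Dollo-style birth/death reconstruction of one miRNA family
#'
#' Assumes a single gain (birth) and unlimited losses: the origin is the
#' most recent common ancestor of all present leaves, and the losses are
#' the maximal subtrees under the origin whose leaves are all absent.
#' Among all single-gain placements this origin provably minimizes the
#' loss count.  When the tree carries node-age annotations the origin's
#' age interval (mya) is reported.
#'
#' @param presence named logical/numeric vector over the tree's leaves
#'   (count >= 1 or TRUE means present).
#' @param tree an `annotated_tree` (see [read_newick()]) or an
#'   [ape::read.tree()] `phylo`.
#' @return a `birth_death_assignment`: `origin` (node number; for a single
#'   present leaf, that tip), `origin_label`, `origin_age` (c(min, max)
#'   mya or NULL), `loss_nodes` (roots of maximal all-absent subtrees),
#'   `loss_clades` (list of leaf sets lost), `n_losses`, `present_leaves`.
#' @export
dollo_reconstruct <- function(presence, tree) {
  phy <- if (inherits(tree, "annotated_tree")) tree$phylo else tree
  ages <- if (inherits(tree, "annotated_tree")) tree$ages else
    data.frame(node = integer(0), min_mya = numeric(0), max_mya = numeric(0))
  tips <- phy$tip.label
  if (is.null(names(presence)) || !all(tips %in% names(presence)))
    stop("presence vector must be named by all tree leaves")
  pres <- as.logical(presence[tips] >= 1)
  names(pres) <- tips
  if (!any(pres)) stop("all-absent presence row: no assignment")
  present_tips <- unname(which(pres))
  origin <- if (length(present_tips) == 1) present_tips else
    ape::getMRCA(phy, tips[present_tips])
  ntip <- ape::Ntip(phy)
  # maximal all-absent subtrees strictly inside the origin's clade
  loss_nodes <- integer(0)
  if (length(present_tips) > 1) {
    absent_clade <- function(node) {
      lv <- clade_tips(phy, node)
      !any(pres[lv])
    }
    walk <- function(node) {
      kids <- phy$edge[phy$edge[, 1] == node, 2]
      for (k in kids) {
        if (absent_clade(k)) loss_nodes <<- c(loss_nodes, k)
        else if (k > ntip) walk(k)
      }
    }
    walk(origin)
  }
  ai <- match(origin, ages$node)
  structure(list(
    origin = origin,
    origin_label = if (origin <= ntip) tips[origin] else
      paste0("mrca(", paste(range_labels(phy, origin), collapse = ","), ")"),
    origin_age = if (!is.na(ai)) c(min_mya = ages$min_mya[ai],
                                   max_mya = ages$max_mya[ai]) else NULL,
    loss_nodes = loss_nodes,
    loss_clades = lapply(loss_nodes, function(n) clade_tips_labels(phy, n)),
    n_losses = length(loss_nodes),
    present_leaves = tips[pres]), class = "birth_death_assignment")
}

clade_tips <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  if (node <= ntip) return(node)
  unlist(phangorn_free_descendants(phy, node))
}

# tip numbers under a node, plain edge-walk (keeps ape the only dep)
phangorn_free_descendants <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    n <- stack[[1]]; stack <- stack[-1]
    if (n <= ntip) out <- c(out, n)
    else stack <- c(stack, phy$edge[phy$edge[, 1] == n, 2])
  }
  out
}

clade_tips_labels <- function(phy, node) phy$tip.label[clade_tips(phy, node)]

range_labels <- function(phy, node) {
  lv <- clade_tips_labels(phy, node)
  c(lv[1], lv[length(lv)])
}

#' @export
print.birth_death_assignment <- function(x, ...) {
  cat("birth_death_assignment: origin ", x$origin_label,
      if (!is.null(x$origin_age))
        paste0(" [", x$origin_age[1], "-", x$origin_age[2], " mya]") else "",
      ", ", x$n_losses, " loss(es)\n", sep = "")
  invisible(x)
}

#' Reconstruct birth/death assignments for a presence matrix
#'
#' @param presence matrix from [build_presence_matrix()].
#' @param tree an `annotated_tree` whose leaves match the matrix columns.
#' @return named list of [dollo_reconstruct()] results (all-absent rows
#'   are skipped with a warning).
#' @export
reconstruct_family_events <- function(presence, tree) {
  out <- list()
  for (m in rownames(presence)) {
    row <- presence[m, ]
    if (!any(row >= 1)) { warning("miRNA ", m, " absent everywhere; skipped"); next }
    out[[m]] <- dollo_reconstruct(row, tree)
  }
  out
}

# ---- Poisson-distance neighbor joining --------------------------------------

#' Poisson-corrected protein distances and an NJ tree
#'
#' Pairwise deletion: for each sequence pair, columns where either member
#' has a gap (`-`) or missing (`X`, `?`) are dropped; `p` is the differing
#' fraction of the remaining columns and the Poisson-model distance is
#' `d = -ln(1 - p)`.  The tree is built with the classic neighbor-joining
#' algorithm; negative branch lengths are clamped to zero with the
#' deficit moved to the adjacent branch.
#'
#' @param alignment `seq_set` (protein) of equal-length aligned sequences,
#'   or a named character vector.
#' @return a `distance_nj` list: `distances` (symmetric matrix), `tree`
#'   (unrooted `phylo`).
#' @export
poisson_nj <- function(alignment) {
  if (inherits(alignment, "seq_set")) {
    ids <- alignment$id; seqs <- alignment$seq
  } else { ids <- names(alignment); seqs <- unname(alignment) }
  n <- length(seqs)
  if (n < 3) stop("need at least 3 sequences")
  if (length(unique(nchar(seqs))) != 1)
    stop("aligned sequences must have equal length")
  rows <- strsplit(toupper(seqs), "", fixed = TRUE)
  miss <- c("-", "X", "?", ".")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- rows[[i]]; b <- rows[[j]]
    ok <- !(a %in% miss) & !(b %in% miss)
    if (!any(ok)) stop("no comparable columns for pair ", ids[i], "/", ids[j])
    p <- mean(a[ok] != b[ok])
    if (p >= 1) stop("p-distance >= 1 for pair ", ids[i], "/", ids[j],
                     "; Poisson distance undefined")
    D[i, j] <- D[j, i] <- -log(1 - p)
  }
  structure(list(distances = D, tree = nj_tree(D)), class = "distance_nj")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic NJ with deterministic (lexicographic taxon order) input and
#' negative branch lengths clamped to zero, the deficit moved to the
#' adjacent branch.
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  ids <- rownames(D)
  ord <- order(ids)
  tree <- ape::nj(stats::as.dist(D[ord, ord]))
  clamp_negative_branches(tree)
}

# standard practice: negative NJ branch set to 0, deficit added to the
# adjacent branch through the same node so path lengths are preserved
clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[1]
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    child <- tree$edge[e, 2]
    adj <- which(tree$edge[, 1] == child)
    if (length(adj) > 0)
      tree$edge.length[adj] <- tree$edge.length[adj] + deficit
    else break   # terminal edge: clamp only
  }
  tree
}

#' @export
print.distance_nj <- function(x, ...) {
  cat("distance_nj:", nrow(x$distances), "taxa; NJ tree with",
      ape::Ntip(x$tree), "tips\n")
  invisible(x)
}

#' Poisson-model distance from a p-distance
#' @param p differing fraction in (0, 1).
#' @return `-ln(1 - p)`.
#' @export
poisson_distance <- function(p) {
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1)")
  -log(1 - p)
}

# ---- miRNA-target network and overlaps --------------------------------------

#' miRNA-target edge list and k-way target overlaps
#'
#' @param sites data frame from [scan_transcriptome()].
#' @return list with `edges` (data frame `mirna_id`, `transcript_id`) and
#'   `overlaps` (data frame `members`, `k`, `shared`: for every subset of
#'   miRNAs of size >= 2, the number of targets shared by all members).
#' @export
network_and_overlaps <- function(sites) {
  edges <- unique(sites[, c("mirna_id", "transcript_id")])
  rownames(edges) <- NULL
  mirs <- sort(unique(edges$mirna_id))
  tsets <- lapply(mirs, function(m)
    unique(edges$transcript_id[edges$mirna_id == m]))
  names(tsets) <- mirs
  rows <- list()
  if (length(mirs) >= 2) {
    for (k in 2:length(mirs)) {
      combs <- utils::combn(mirs, k, simplify = FALSE)
      for (cc in combs) {
        shared <- Reduce(intersect, tsets[cc])
        rows[[length(rows) + 1L]] <- data.frame(
          members = paste(cc, collapse = "+"), k = k,
          shared = length(shared), stringsAsFactors = FALSE)
      }
    }
  }
  overlaps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(members = character(0), k = integer(0), shared = integer(0))
  list(edges = edges, overlaps = overlaps, target_sets = tsets)
}
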