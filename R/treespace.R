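# Dated species-tree handling: divergence times, clade delineation at age
# thresholds, sister-clade pairs.  Trees are ape "phylo" objects wrapped with
# precomputed node ages; all ages are in millions of years (My) before present.

#' Parse a dated ultrametric species tree from Newick text
#'
#' Branch lengths must be in My.  Tip labels are kept verbatim except for a
#' documented normalization (spaces become underscores) applied identically
#' wherever species names are matched.  The tree must be ultrametric within a
#' relative tolerance of the tree height; it is never rescaled.
#' Multifurcations are allowed.
#'
#' @param newick_text a Newick string, or the path of a file containing one.
#' @param tol relative ultrametricity tolerance (fraction of tree height).
#' @return an object of class `species_tree`: list with `phylo` (the ape
#'   tree), `tips`, `age` (age of every node, tips first, in My) and `div`
#'   (tip-by-tip matrix of MRCA ages).
#' @export
parse_timetree <- function(newick_text, tol = 1e-6) {
  txt <- newick_text
  if (length(txt) == 1L && !grepl("\\(", txt) && file.exists(txt))
    txt <- paste(readLines(txt, warn = FALSE), collapse = "")
  if (length(txt) != 1L || !nzchar(txt))
    stop("malformed Newick: empty input")
  depth <- cumsum(ifelse(strsplit(txt, "")[[1L]] == "(", 1L,
                         ifelse(strsplit(txt, "")[[1L]] == ")", -1L, 0L)))
  if (any(depth < 0L))
    stop("malformed Newick: unmatched ')' at character ",
         which(depth < 0L)[1L])
  if (utils::tail(depth, 1L) != 0L)
    stop("malformed Newick: ", utils::tail(depth, 1L),
         " unclosed '(' at end of text")
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("malformed Newick: ape could not parse the text")
  if (is.null(phy$edge.length))
    stop("Newick text has no branch lengths; a dated tree is required")
  phy$tip.label <- normalize_species(phy$tip.label)

  ntip <- length(phy$tip.label)
  depths <- ape::node.depth.edgelength(phy)     # root = 0
  height <- max(depths)
  tip_dev <- height - depths[seq_len(ntip)]
  if (max(abs(tip_dev)) > tol * height) {
    worst <- which.max(abs(tip_dev))
    stop("tree is not ultrametric: tip '", phy$tip.label[worst],
         "' deviates by ", signif(max(abs(tip_dev)), 4),
         " My from the tree height ", signif(height, 6))
  }
  age <- height - depths
  age[seq_len(ntip)] <- 0

  mrca_mat <- ape::mrca(phy)
  div <- matrix(age[mrca_mat], nrow = ntip,
                dimnames = list(phy$tip.label, phy$tip.label))
  diag(div) <- 0

  structure(list(phylo = phy, tips = phy$tip.label, age = age, div = div),
            class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("Dated species tree: %d tips, root age %.1f My\n",
              length(x$tips), max(x$age)))
  invisible(x)
}

# Species-name normalization used everywhere names are matched.
normalize_species <- function(x) gsub(" ", "_", x, fixed = TRUE)

check_species <- function(tree, sp) {
  sp <- normalize_species(sp)
  bad <- setdiff(sp, tree$tips)
  if (length(bad) > 0L)
    stop("unknown species: ", paste(bad, collapse = ", "))
  sp
}

#' Divergence time between two species
#'
#' @param tree a `species_tree`.
#' @param sp1,sp2 tip labels.
#' @return age of their MRCA in My (0 when `sp1 == sp2`).
#' @export
divergence_my <- function(tree, sp1, sp2) {
  sp1 <- check_species(tree, sp1)
  sp2 <- check_species(tree, sp2)
  tree$div[cbind(sp1, sp2)]
}

#' Partition the tips into maximal clades younger than an age threshold
#'
#' Each clade is a maximal monophyletic group whose crown age is strictly
#' below `threshold` (boundary-age clades count as not younger).  A tip whose
#' smallest non-trivial containing clade is at least as old as the threshold
#' forms a singleton.
#'
#' @param tree a `species_tree`.
#' @param threshold age in My (> 0).
#' @return object of class `clade_partition`: list with `threshold`,
#'   `clade` (named character vector, species -> clade id) and `members`
#'   (list of species per clade).  Clade ids are the alphabetically first
#'   member species.
#' @export
clades_younger_than <- function(tree, threshold) {
  stopifnot(threshold > 0)
  phy <- tree$phylo
  ntip <- length(tree$tips)
  # deepest ancestor of each tip with age < threshold, found by walking up
  parent <- integer(max(phy$edge))
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  assign_node <- integer(ntip)
  for (i in seq_len(ntip)) {
    node <- i
    while (parent[node] != 0L && tree$age[parent[node]] < threshold)
      node <- parent[node]
    assign_node[i] <- node
  }
  members <- split(tree$tips, assign_node)
  ids <- vapply(members, function(m) sort(m)[1L], character(1L))
  names(members) <- ids
  clade <- stats::setNames(rep(ids, lengths(members)), unlist(members))
  clade <- clade[tree$tips]
  structure(list(threshold = threshold, clade = clade,
                 members = members[order(ids)]),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("Clade partition at %g My: %d clades over %d species\n",
              x$threshold, length(x$members), length(x$clade)))
  invisible(x)
}

#' Sister clades separated by the MRCA of two species
#'
#' Returns the two disjoint descendant groups of the MRCA of `sp1` and `sp2`:
#' the subtree of the MRCA child containing `sp1` versus all other children
#' (which contain `sp2`'s lineage); at a polytomy the non-`sp1` children are
#' pooled into one group.
#'
#' @param tree a `species_tree`.
#' @param sp1,sp2 distinct tip labels.
#' @return object of class `clade_pair`: list with `mrca_age`, `clade_a`
#'   (species set containing `sp1`), `clade_b` (containing `sp2`), and
#'   `node` (the MRCA node id, usable as a distribution key).
#' @export
sister_clade_pair <- function(tree, sp1, sp2) {
  sp1 <- check_species(tree, sp1)
  sp2 <- check_species(tree, sp2)
  if (sp1 == sp2) stop("sp1 and sp2 must differ")
  phy <- tree$phylo
  node <- ape::getMRCA(phy, c(sp1, sp2))
  kids <- phy$edge[phy$edge[, 1L] == node, 2L]
  tip_sets <- lapply(kids, function(k) tips_under(phy, k))
  in_a <- vapply(tip_sets, function(s) sp1 %in% s, logical(1L))
  clade_a <- tip_sets[[which(in_a)]]
  clade_b <- sort(unlist(tip_sets[!in_a]))
  structure(list(mrca_age = tree$age[node],
                 clade_a = sort(clade_a), clade_b = clade_b,
                 node = node),
            class = "clade_pair")
}

# Tip labels under a node (the node itself when it is a tip).
tips_under <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  phy$tip.label[unlist(phangorn_free_descendants(phy, node))]
}

# minimal descendant-tip walker (avoids a phangorn dependency)
phangorn_free_descendants <- function(phy, node) {
  ntip <- length(phy$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0L) {
    n <- stack[[1L]]; stack <- stack[-1L]
    if (n <= ntip) out <- c(out, n)
    else stack <- c(stack, phy$edge[phy$edge[, 1L] == n, 2L])
  }
  out
}

#' Count the reciprocal similarity searches implied by a species tree
#'
#' The screening design runs reciprocal nucleotide searches between every
#' pair of species that diverged at least `min_age` My ago, i.e. every
#' cross-clade pair under [clades_younger_than()]; each unordered species
#' pair contributes two searches.
#'
#' @param tree a `species_tree`.
#' @param min_age minimum divergence in My (default 40).
#' @return integer count of ordered cross-clade species pairs.
#' @export
count_reciprocal_searches <- function(tree, min_age = 40) {
  part <- clades_younger_than(tree, min_age)
  n <- length(tree$tips)
  same <- outer(part$clade, part$clade, "==")
  as.integer(sum(!same))  # ordered pairs across clades
}

#' Bundled demonstration timetree
#'
#' A 16-species dated tree emulating the deep structure of a vertebrate
#' screen: two 430-My-diverged major clades (ray-finned-fish-like tips
#' `F1a..F4b`, tetrapod-like tips `T1a..T4b`), each containing four clades
#' younger than 40 My with two species each.  Used in examples and as the
#' default simulation arena.
#'
#' @return a `species_tree`.
#' @export
demo_timetree <- function() {
  parse_timetree(paste0(
    "((((F1a:12,F1b:12):138,(F2a:10,F2b:10):140):130,",
    "((F3a:14,F3b:14):156,(F4a:9,F4b:9):161):110):150,",
    "(((T1a:12,T1b:12):148,(T2a:8,T2b:8):152):140,",
    "((T3a:10,T3b:10):170,(T4a:9,T4b:9):171):120):130);"))
}
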