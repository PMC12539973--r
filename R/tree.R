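#' Read a time-calibrated phylogeny
#'
#' Reads a rooted, fully bifurcating newick tree with branch lengths in
#' millions of years (Ma). Missing branch lengths, unrooted trees and
#' polytomies are rejected. A warning (not an error) is issued if the tree
#' is not ultrametric within tolerance.
#'
#' @param path newick file path, or a newick string via `text`
#' @param text optional newick string (overrides `path`)
#' @param ultrametric_tol relative tolerance for the ultrametricity check
#' @return an [ape::phylo] tree
#' @export
read_time_tree <- function(path = NULL, text = NULL, ultrametric_tol = 1e-6) {
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tree)) abort("could not parse newick input", class = "shaperate_tree_format")
  validate_time_tree(tree, ultrametric_tol = ultrametric_tol)
  tree
}

validate_time_tree <- function(tree, ultrametric_tol = 1e-6) {
  if (!inherits(tree, "phylo")) abort("not a phylo tree", class = "shaperate_tree_format")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("tree has missing branch lengths", class = "shaperate_tree_format")
  }
  if (any(tree$edge.length <= 0)) {
    abort("tree has non-positive branch lengths", class = "shaperate_tree_format")
  }
  if (!ape::is.rooted(tree)) abort("tree must be rooted", class = "shaperate_tree_format")
  if (!ape::is.binary(tree)) abort("polytomies are not supported", class = "shaperate_tree_format")
  if (!ape::is.ultrametric(tree, tol = ultrametric_tol)) {
    warn("tree is not ultrametric within tolerance")
  }
  invisible(tree)
}

node_labels <- function(tree) {
  n <- length(tree$tip.label)
  c(tree$tip.label, paste0("node_", (n + 1):(n + tree$Nnode)))
}

#' Edge table of a phylogeny
#'
#' One row per branch with parent/child node numbers, the child's label
#' (tip name, or `node_<number>` for internal nodes), the branch length and
#' whether the branch is terminal.
#'
#' @param tree an [ape::phylo] tree
#' @return tibble with columns `edge`, `parent`, `child`, `child_label`,
#'   `length`, `terminal`
#' @export
edge_table <- function(tree) {
  labs <- node_labels(tree)
  n_tip <- length(tree$tip.label)
  tibble::tibble(
    edge = seq_len(nrow(tree$edge)),
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    child_label = labs[tree$edge[, 2]],
    length = tree$edge.length,
    terminal = tree$edge[, 2] <= n_tip
  )
}

#' Read a generation-time table
#'
#' CSV with columns `species,generation_time_years`.
#'
#' @param path file path
#' @return named numeric vector (years per generation)
#' @export
read_generation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "generation_time_years") %in% names(df))) {
    abort("generation table must have columns species,generation_time_years",
          class = "shaperate_validation")
  }
  setNames(as.numeric(df$generation_time_years), df$species)
}

#' Rescale a time tree to generations
#'
#' Converts each branch length from Ma to a (real-valued) number of
#' generations. Terminal branches use the tip species' generation time;
#' internal branches use, by default, the arithmetic mean of the generation
#' times of their descendant tips (`internal = "descendant_mean"`), or the
#' mean across all tips (`internal = "tree_mean"`).
#'
#' @param tree time-calibrated [ape::phylo] tree (branch lengths in Ma)
#' @param generation_times named numeric vector (or tibble from
#'   [read_generation_table()]): years per generation for every tip
#' @param internal rule for internal-branch generation times
#' @return object of class `generation_tree`: list with `time_tree`,
#'   `gen_tree` (same topology, branch lengths in generations) and `edges`
#'   (tibble with `t_ma`, `gen_time`, `n_gen` per branch)
#' @export
rescale_to_generations <- function(tree, generation_times,
                                   internal = c("descendant_mean", "tree_mean")) {
  internal <- match.arg(internal)
  validate_time_tree(tree)
  if (is.data.frame(generation_times)) {
    generation_times <- setNames(as.numeric(generation_times$generation_time_years),
                                 generation_times$species)
  }
  missing <- setdiff(tree$tip.label, names(generation_times))
  if (length(missing)) {
    abort(paste0("generation times missing for tips: ", paste(missing, collapse = ", ")),
          class = "shaperate_validation")
  }
  if (any(generation_times <= 0)) abort("generation times must be positive",
                                        class = "shaperate_validation")
  n_tip <- length(tree$tip.label)
  g_tip <- generation_times[tree$tip.label]
  et <- edge_table(tree)
  desc <- descendant_tips(tree)
  g_branch <- vapply(seq_len(nrow(et)), function(i) {
    child <- et$child[i]
    if (child <= n_tip) {
      unname(g_tip[child])
    } else if (internal == "descendant_mean") {
      mean(g_tip[desc[[child]]])
    } else {
      mean(g_tip)
    }
  }, numeric(1))
  et$gen_time <- g_branch
  et$t_ma <- et$length
  et$n_gen <- et$t_ma * 1e6 / g_branch
  gen_tree <- tree
  gen_tree$edge.length <- et$n_gen
  structure(
    list(time_tree = tree, gen_tree = gen_tree,
         edges = et[, c("edge", "parent", "child", "child_label", "terminal",
                        "t_ma", "gen_time", "n_gen")],
         generation_times = g_tip),
    class = "generation_tree"
  )
}

#' @export
print.generation_tree <- function(x, ...) {
  cat(sprintf("<generation_tree> %d tips; total depth %.3g Ma; %.3g generations root-to-tip (max)\n",
              length(x$time_tree$tip.label),
              max(ape::node.depth.edgelength(x$time_tree)),
              max(ape::node.depth.edgelength(x$gen_tree))))
  invisible(x)
}

# list indexed by node number -> integer vector of descendant tip numbers
descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  desc <- vector("list", n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  # postorder: a child's subtree edges are visited before its parent edge
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Assign branches to clades
#'
#' Each branch is assigned the clade containing all of its descendant tips;
#' a clade's stem branch is therefore assigned to that clade. Branches whose
#' descendants span more than one clade are labelled `"mixed"`.
#'
#' @param tree an [ape::phylo] tree
#' @param clade_map named character vector: tip label -> clade name
#' @return character vector of clade labels, one per edge (in edge order)
#' @export
assign_branch_clades <- function(tree, clade_map) {
  missing <- setdiff(tree$tip.label, names(clade_map))
  if (length(missing)) {
    abort(paste0("clade assignment missing for tips: ", paste(missing, collapse = ", ")),
          class = "shaperate_validation")
  }
  desc <- descendant_tips(tree)
  vapply(seq_len(nrow(tree$edge)), function(e) {
    tips <- tree$tip.label[desc[[tree$edge[e, 2]]]]
    cl <- unique(unname(clade_map[tips]))
    if (length(cl) == 1) cl else "mixed"
  }, character(1))
}
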