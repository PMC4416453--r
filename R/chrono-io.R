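# Reading dated ultrametric trees (chronograms) and extracting the ages that
# feed the diversification analysis: crown (MRCA) ages, stem ages, and
# disjunction ages between two named taxon sets. Parsing is delegated to ape;
# this layer adds validation (rooted, unique labels, contemporaneous tips)
# and the age arithmetic.

.chrono_error <- function(class, ...) {
  stop(errorCondition(sprintf(...),
                      class = c(class, "chronogram_error", "error")))
}

#' Read and validate an ultrametric chronogram
#'
#' Accepts newick or NEXUS text (autodetected). BEAST-style bracketed node
#' annotations (`[&rate=...]` and other square-bracket comments) are stripped
#' before parsing; posterior/HPD annotations are not interpreted. NEXUS
#' translate tables are honoured by the ape reader. Node ages are computed as
#' tree height minus root distance, with tips at age 0; trees whose tips are
#' not contemporaneous (beyond `tol`) are rejected rather than re-scaled.
#'
#' @param file Path to a tree file (ignored if `text` given).
#' @param text Tree as a character string.
#' @param tol Ultrametricity tolerance in Myr: maximum allowed spread of
#'   root-to-tip path lengths. Default `1e-4 *` tree height, the rounding
#'   noise typical of dating-software output.
#' @return The tree as an object of class `c("chronogram", "phylo")` with a
#'   `"height"` attribute (Myr).
#' @examples
#' read_chronogram(text = "((A:3,B:3):7,(C:5,D:5):5);")
#' @export
read_chronogram <- function(file = NULL, text = NULL, tol = NULL) {
  if (is.null(text)) {
    if (is.null(file)) .chrono_error("chronogram_input_error",
                                     "supply either 'file' or 'text'")
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  stripped <- gsub("\\[[^]]*\\]", "", text)
  if (grepl("#NEXUS", stripped, ignore.case = TRUE)) {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(stripped, tf)
    tr <- ape::read.nexus(tf)
  } else {
    tr <- ape::read.tree(text = stripped)
  }
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L)
      .chrono_error("chronogram_input_error",
                    "source contains %d trees; supply exactly one", length(tr))
    tr <- tr[[1L]]
  }
  if (is.null(tr) || !inherits(tr, "phylo"))
    .chrono_error("chronogram_input_error", "could not parse a tree from source")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    .chrono_error("chronogram_branch_length_error",
                  "chronogram must carry branch lengths on every edge")
  if (!ape::is.rooted(tr))
    .chrono_error("chronogram_root_error", "chronogram must be rooted")
  if (anyDuplicated(tr$tip.label))
    .chrono_error("chronogram_label_error", "tip labels must be unique")
  depth <- ape::node.depth.edgelength(tr)
  ntip <- length(tr$tip.label)
  height <- max(depth[seq_len(ntip)])
  spread <- diff(range(depth[seq_len(ntip)]))
  if (is.null(tol)) tol <- 1e-4 * height
  if (spread > tol)
    .chrono_error("chronogram_ultrametric_error",
                  "tree is not ultrametric: tip age spread %.6g exceeds tolerance %.6g",
                  spread, tol)
  attr(tr, "height") <- height
  class(tr) <- c("chronogram", "phylo")
  tr
}

# node ages (Myr before present) for every node, tips first
.node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_along(tree$tip.label)]) - depth
}

.match_tips <- function(tree, taxa, what = "taxa") {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    .chrono_error("chronogram_label_error", "%s not in tree: %s",
                  what, paste(missing, collapse = ", "))
  match(taxa, tree$tip.label)
}

#' Crown (MRCA) age of a taxon set
#'
#' @param tree A rooted ultrametric tree (`chronogram` or plain `phylo` with
#'   branch lengths).
#' @param taxa Character vector of tip labels. A single taxon returns age 0
#'   by convention (a tip has no crown).
#' @return Age in Myr before present of the most recent common ancestor.
#' @examples
#' tr <- read_chronogram(text = "((A:3,B:3):7,(C:5,D:5):5);")
#' mrca_age(tr, c("A", "B"))  # 3
#' mrca_age(tr, c("A", "C"))  # 10
#' @export
mrca_age <- function(tree, taxa) {
  .match_tips(tree, taxa)
  if (length(unique(taxa)) < 2L) return(0)
  node <- ape::getMRCA(tree, taxa)
  .node_ages(tree)[node]
}

#' Stem age of a taxon set
#'
#' Age of the parent node of the taxa's MRCA, i.e. the split between the
#' clade and its sister lineage. Undefined (an error) when the MRCA is the
#' root: without an outgroup the stem is not in the tree.
#'
#' @inheritParams mrca_age
#' @return Age in Myr before present.
#' @examples
#' tr <- read_chronogram(text = "((A:3,B:3):7,(C:5,D:5):5);")
#' stem_age(tr, c("A", "B"))  # 10
#' @export
stem_age <- function(tree, taxa) {
  idx <- .match_tips(tree, taxa)
  node <- if (length(unique(taxa)) < 2L) idx[1L] else ape::getMRCA(tree, taxa)
  root <- length(tree$tip.label) + 1L
  if (node == root)
    .chrono_error("chronogram_root_error",
                  "stem age undefined: the MRCA is the root (no outgroup in tree)")
  parent <- tree$edge[tree$edge[, 2L] == node, 1L]
  .node_ages(tree)[parent]
}

#' Age of a dated geographic disjunction
#'
#' The disjunction age between two taxon sets is the age of the MRCA of
#' their union: the dated split separating the two geographic sides. The
#' union need not be monophyletic.
#'
#' @inheritParams mrca_age
#' @param side_a,side_b Non-empty, disjoint sets of tip labels (e.g. the
#'   western and eastern African members of a lineage).
#' @return Age in Myr before present.
#' @examples
#' tr <- read_chronogram(text = "((A:3,B:3):7,(C:5,D:5):5);")
#' disjunction_age(tr, side_a = c("A", "B"), side_b = c("C", "D"))  # 10
#' @export
disjunction_age <- function(tree, side_a, side_b) {
  if (length(side_a) == 0L || length(side_b) == 0L)
    .chrono_error("chronogram_query_error", "both sides must be non-empty")
  if (length(intersect(side_a, side_b)))
    .chrono_error("chronogram_query_error",
                  "sides must be disjoint; shared: %s",
                  paste(intersect(side_a, side_b), collapse = ", "))
  .match_tips(tree, side_a, "side_a labels")
  .match_tips(tree, side_b, "side_b labels")
  mrca_age(tree, union(side_a, side_b))
}
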