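
# ---- Primate phylogeny and mating-system labels -----------------------------

PRIMATE_NEWICK <- paste0(
  "(((((human:0.013,chimpanzee:0.014):0.009,gorilla:0.019):0.016,",
  "orangutan:0.036):0.012,gibbon:0.044):0.025,",
  "(((((rhesus_macaque:0.008,cynomolgus_macaque:0.008):0.012,",
  "(baboon:0.012,drill:0.013):0.008):0.01,vervet:0.025):0.012,",
  "colobus:0.04):0.03,(marmoset:0.04,tamarin:0.038):0.065):0.02):0.0;")

PRIMATE_MATING <- c(
  human = "uni", chimpanzee = "multi", gorilla = "uni", orangutan = "uni",
  gibbon = "uni", rhesus_macaque = "multi", cynomolgus_macaque = "multi",
  baboon = "multi", drill = "uni", vervet = "multi", colobus = "multi",
  marmoset = "uni", tamarin = "uni")

#' Reference primate phylogeny with mating-system labels
#'
#' A 13-species primate tree (apes, Old World monkeys, and two New World
#' monkeys) with every tip labelled as belonging to a uni-male or multi-male
#' mating system: "uni" where females typically mate with a single male per
#' estrous period (e.g. human, gibbon, drill) and "multi" where they mate
#' with several (e.g. chimpanzee, macaques, baboon, vervet, colobus).
#' Branch lengths are plausible configuration defaults in expected
#' substitutions per site, not estimates.
#'
#' @param branch_scale Multiplier applied to all branch lengths; codon-level
#'   simulations typically use a scale around 10-30 so that alignments of a
#'   few hundred codons are informative.
#' @return A rooted `phylo` with a `mating` component (named character
#'   vector, `"uni"`/`"multi"`, one entry per tip).
#' @export
fixed_primate_tree <- function(branch_scale = 1) {
  stopifnot(branch_scale > 0)
  tree <- ape::read.tree(text = PRIMATE_NEWICK)
  tree$edge.length <- tree$edge.length * branch_scale
  tree$mating <- PRIMATE_MATING[tree$tip.label]
  tree
}

#' Mating-system labels of a tree
#'
#' @param tree A `phylo`, typically from [fixed_primate_tree()].
#' @param labels Optional named character vector overriding `tree$mating`.
#' @return A tibble with columns `species` and `mating` (`"uni"`/`"multi"`).
#' @export
mating_labels <- function(tree, labels = NULL) {
  labels <- labels %||% tree$mating
  if (is.null(labels)) stop("tree carries no mating labels", call. = FALSE)
  missing <- setdiff(tree$tip.label, names(labels))
  if (length(missing)) {
    stop("tips without mating label: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(labels), c("uni", "multi"))
  if (length(bad)) stop("mating labels must be 'uni' or 'multi'", call. = FALSE)
  tibble::tibble(species = tree$tip.label,
                 mating = unname(labels[tree$tip.label]))
}

# tips descending from each edge's child node
edge_descendants <- function(tree) {
  ntip <- length(tree$tip.label)
  phy <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  list(phy = phy, desc = desc)
}

#' Assign foreground branches from tip mating labels
#'
#' Partitions the branches of a rooted tree into foreground and background
#' for the branch-site test. Under the default `"all_descendants"` rule a
#' branch is foreground iff every tip descending from it carries the
#' foreground label (tip branches follow their own tip). The `"fitch"` rule
#' reconstructs ancestral labels by Fitch parsimony and marks a branch
#' foreground iff its child node is unambiguously foreground.
#'
#' @param tree Rooted `phylo`.
#' @param labels Named character vector of tip labels (`"uni"`/`"multi"`),
#'   defaults to `tree$mating`.
#' @param foreground Which label is foreground (default `"multi"`).
#' @param rule `"all_descendants"` (default) or `"fitch"`.
#' @return Logical vector over the rows of `reorder(tree, "postorder")$edge`.
#' @export
foreground_edges <- function(tree, labels = NULL, foreground = "multi",
                             rule = c("all_descendants", "fitch")) {
  rule <- match.arg(rule)
  lab <- mating_labels(tree, labels)
  is_fg_tip <- setNames(lab$mating == foreground, lab$species)
  ed <- edge_descendants(tree)
  phy <- ed$phy
  ntip <- length(phy$tip.label)
  if (rule == "all_descendants") {
    fg <- vapply(seq_len(nrow(phy$edge)), function(e) {
      tips <- ed$desc[[phy$edge[e, 2L]]]
      all(is_fg_tip[phy$tip.label[tips]])
    }, logical(1))
  } else {
    # Fitch: bottom-up state sets (1 = bg, 2 = fg), top-down resolution;
    # ambiguous nodes are resolved to background (conservative)
    sets <- vector("list", ntip + phy$Nnode)
    for (i in seq_len(ntip)) sets[[i]] <- if (is_fg_tip[phy$tip.label[i]]) 2L else 1L
    children <- split(phy$edge[, 2L], phy$edge[, 1L])
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1L]
      if (!is.null(sets[[p]])) next
      kids <- children[[as.character(p)]]
      if (any(vapply(kids, function(k) is.null(sets[[k]]), logical(1)))) next
      ss <- lapply(kids, function(k) sets[[k]])
      inter <- Reduce(intersect, ss)
      sets[[p]] <- if (length(inter)) inter else sort(unique(unlist(ss)))
    }
    state <- integer(ntip + phy$Nnode)
    root <- ntip + 1L
    state[root] <- if (identical(sets[[root]], 2L)) 2L else 1L
    for (e in rev(seq_len(nrow(phy$edge)))) {    # preorder
      p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
      s <- sets[[ch]]
      state[ch] <- if (state[p] %in% s) state[p] else if (identical(s, 2L)) 2L else 1L
    }
    fg <- state[phy$edge[, 2L]] == 2L
  }
  if (all(fg) || !any(fg)) {
    warning("foreground/background partition is degenerate (all one side)")
  }
  fg
}
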