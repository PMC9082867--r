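## Cross-lineage comparison of ITS sites: shared-position pairs, and
## binary-character parsimony asking whether a fragmentation character can
## be explained by a single ancestral gain on a supplied phylogeny.

#' Presence matrix of ITS calls
#'
#' @param calls data.frame from [classify_expansions()].
#' @param taxa row labels (tree leaves); defaults to species seen in calls.
#' @param by column grouping: `"region_id"` or `"site_id"`.
#' @return logical matrix taxa x sites.
#' @export
presence_matrix <- function(calls, taxa = NULL,
                            by = c("region_id", "site_id")) {
  by <- match.arg(by)
  keep <- calls$classification %in% c("known_ITS", "novel_candidate")
  calls <- calls[keep, , drop = FALSE]
  if (is.null(taxa)) taxa <- sort(unique(calls$species))
  cols <- sort(unique(calls[[by]]))
  m <- matrix(FALSE, length(taxa), length(cols), dimnames = list(taxa, cols))
  for (i in seq_len(nrow(calls))) {
    if (calls$species[i] %in% taxa)
      m[calls$species[i], calls[[by]][i]] <- TRUE
  }
  m
}

#' Cross-lineage shared ITS sites
#'
#' All pairs of registry sites from different lineages that map to the same
#' inter-anchor region (identical flanking anchor pair), in deterministic
#' order. With `window > 0` an alignment-column tolerance mode pairs sites
#' whose regions start within `window` columns (registry-free comparisons).
#'
#' @param registry data.frame from [read_its_registry()].
#' @param window column tolerance (0 = exact region identity, the default).
#' @param positions optional named numeric vector of region_id -> alignment
#'   column, required when `window > 0`.
#' @return data.frame: site_a, lineage_a, site_b, lineage_b, region_id.
#' @export
shared_sites <- function(registry, window = 0L, positions = NULL) {
  out <- list()
  n <- nrow(registry)
  if (n >= 2) {
    ord <- order(registry$site_id)
    reg <- registry[ord, , drop = FALSE]
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (reg$lineage[i] == reg$lineage[j]) next
      same <- if (window > 0) {
        if (is.null(positions)) stop("positions required when window > 0")
        abs(positions[[reg$region_id[i]]] - positions[[reg$region_id[j]]]) <= window
      } else reg$region_id[i] == reg$region_id[j]
      if (isTRUE(same))
        out[[length(out) + 1]] <- data.frame(
          site_a = reg$site_id[i], lineage_a = reg$lineage[i],
          site_b = reg$site_id[j], lineage_b = reg$lineage[j],
          region_id = reg$region_id[i], stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(site_a = character(0), lineage_a = character(0),
                         site_b = character(0), lineage_b = character(0),
                         region_id = character(0), stringsAsFactors = FALSE)
  res <- res[order(res$site_a, res$site_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## postorder list of (node, children) with children guaranteed processed first
.postorder_nodes <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  # postorder edge order lists each internal node's edges after its
  # descendants'; unique() over parent column in edge order gives a valid
  # child-first node order
  ord <- unique(tr$edge[, 1])
  list(order = ord, children = kids)
}

#' Minimum binary state changes on a tree (small parsimony)
#'
#' Fitch counting, generalized to polytomies (Hartigan): each internal node
#' keeps the states receiving the maximum number of child votes, at a cost
#' of (number of children - maximum vote count). The count is invariant
#' under root placement.
#'
#' @param tree `phylo` tree (rooted or unrooted; polytomies allowed).
#' @param presence named logical vector over all tree leaves.
#' @return integer minimum number of state changes.
#' @export
min_state_changes <- function(tree, presence) {
  miss <- setdiff(tree$tip.label, names(presence))
  if (length(miss)) stop("leaf without state: ", paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  po <- .postorder_nodes(tree)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip))
    sets[[i]] <- if (isTRUE(presence[[tree$tip.label[i]]])) 1L else 0L
  changes <- 0L
  for (node in po$order) {
    kids <- po$children[[as.character(node)]]
    votes <- c(0L, 0L) # states 0, 1
    for (k in kids) votes[sets[[k]] + 1L] <- votes[sets[[k]] + 1L] + 1L
    m <- max(votes)
    sets[[node]] <- which(votes == m) - 1L
    changes <- changes + length(kids) - m
  }
  changes
}

#' Gain/loss scenarios for a binary fragmentation character
#'
#' On a rooted tree: `gains_no_loss` is the number of maximal all-present
#' clades (the minimum number of independent gains when loss is forbidden);
#' `dollo_losses_single_gain` is the minimum number of losses given a single
#' gain at the MRCA of the present leaves; `fitch_changes` is the
#' unconstrained minimum from [min_state_changes()]. A character present in
#' two clades separated by an absent lineage needs at least two independent
#' gains - the machine-checkable form of "cannot be traced to the common
#' ancestor".
#'
#' @param tree rooted `phylo` tree (root the input with an outgroup first if
#'   needed).
#' @param presence named logical vector over leaves.
#' @return list: fitch_changes, gains_no_loss, dollo_losses_single_gain.
#' @export
gain_scenarios <- function(tree, presence) {
  miss <- setdiff(tree$tip.label, names(presence))
  if (length(miss)) stop("leaf without state: ", paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  pres_leaves <- tree$tip.label[vapply(tree$tip.label,
                                       function(l) isTRUE(presence[[l]]), TRUE)]
  if (length(pres_leaves) == 0)
    return(list(fitch_changes = 0L, gains_no_loss = 0L,
                dollo_losses_single_gain = 0L))
  fitch <- min_state_changes(tree, presence)
  po <- .postorder_nodes(tree)
  nv <- ntip + tree$Nnode
  all_present <- logical(nv); all_absent <- logical(nv)
  for (i in seq_len(ntip)) {
    st <- isTRUE(presence[[tree$tip.label[i]]])
    all_present[i] <- st; all_absent[i] <- !st
  }
  for (node in po$order) {
    kids <- po$children[[as.character(node)]]
    all_present[node] <- all(all_present[kids])
    all_absent[node] <- all(all_absent[kids])
  }
  parent <- integer(nv)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  gains <- sum(vapply(seq_len(nv), function(v)
    all_present[v] && (v == root || !all_present[parent[v]]), TRUE))
  # Dollo: single gain at the MRCA of present leaves; losses are the maximal
  # all-absent clades inside that subtree
  mrca <- if (length(pres_leaves) == 1) match(pres_leaves, tree$tip.label)
          else ape::getMRCA(tree, pres_leaves)
  in_mrca <- logical(nv)
  stack <- mrca
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    in_mrca[x] <- TRUE
    kk <- po$children[[as.character(x)]]
    if (!is.null(kk)) stack <- c(stack, kk)
  }
  losses <- sum(vapply(seq_len(nv), function(v)
    in_mrca[v] && all_absent[v] && (v == mrca || !all_absent[parent[v]]),
    TRUE))
  list(fitch_changes = as.integer(fitch), gains_no_loss = as.integer(gains),
       dollo_losses_single_gain = as.integer(losses))
}
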