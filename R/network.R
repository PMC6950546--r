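# Friendship networks: undirected adjacency from nominations, dyad/triad
# clique enumeration, and equal-weight multiple-membership matrices.

#' Build an undirected friendship network from nominations
#'
#' A friendship tie exists between two children if either child nominated
#' the other.  Nominees outside the roster are dropped (they were not study
#' participants); self-nominations are dropped with a warning; duplicate
#' nominations collapse to a single edge.  Every roster child is a node, so
#' isolates (children with no matched friends) are retained.
#'
#' @param noms A data.frame with columns `nominator_id` and `nominee_id`.
#' @param roster Character vector of all study child IDs.
#' @return An object of class `friendship_network`: list with `nodes`
#'   (character vector) and `edges` (two-column character matrix, each row
#'   an unordered pair with the lexicographically smaller ID first).
#' @export
build_adjacency <- function(noms, roster) {
  roster <- as.character(roster)
  if (length(roster) == 0L) stop("roster must be non-empty")
  stopifnot(is.data.frame(noms),
            all(c("nominator_id", "nominee_id") %in% names(noms)))
  a <- as.character(noms$nominator_id)
  b <- as.character(noms$nominee_id)
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-nomination(s) dropped")
    a <- a[!self]; b <- b[!self]
  }
  keep <- a %in% roster & b %in% roster
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  edges <- cbind(lo[!dup], hi[!dup])
  colnames(edges) <- c("a", "b")
  structure(list(nodes = sort(unique(roster)), edges = edges),
            class = "friendship_network")
}

#' @export
print.friendship_network <- function(x, ...) {
  cat(sprintf("<friendship_network> %d children, %d ties\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

.as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$edges[, 1], to = net$edges[, 2],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}

#' Enumerate friendship cliques of a given size
#'
#' Returns all complete subgraphs of exactly `size` nodes: every edge is a
#' dyad (size 2) and every triangle is a triad (size 3), whether or not it
#' is contained in a larger clique.  With `maximal_only = TRUE` only
#' maximal cliques of that size are returned.
#'
#' @param net A [build_adjacency()] network.
#' @param size Clique size, one of 2, 3 or 4.
#' @param maximal_only Restrict to maximal cliques (default `FALSE`).
#' @return A list of character vectors (sorted member IDs), in
#'   lexicographic order; empty list for an empty graph.
#' @export
enumerate_cliques <- function(net, size, maximal_only = FALSE) {
  stopifnot(inherits(net, "friendship_network"), size %in% 2:4)
  if (nrow(net$edges) == 0L) return(list())
  g <- .as_igraph(net)
  cl <- if (maximal_only)
    igraph::max_cliques(g, min = size, max = size)
  else
    igraph::cliques(g, min = size, max = size)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  if (length(cl) == 0L) return(list())
  ord <- order(vapply(cl, paste, "", collapse = "\r"))
  cl[ord]
}

#' Equal-weight multiple-membership matrix from cliques
#'
#' Each child's clique memberships are equally weighted and sum to one: a
#' child in m cliques gets weight 1/m for each.  A child in no cliques has
#' no entries, so its random-effect contribution at this level is exactly
#' zero (friendless children stay in the model).
#'
#' @param net The [build_adjacency()] network the cliques came from.
#' @param cliques A list of cliques from [enumerate_cliques()].
#' @param label Classification label, e.g. `"dyad"` or `"triad"`.
#' @return An object of class `membership_weights`: list with `label`,
#'   `groups` (the clique list), `children` (all network nodes) and
#'   `weights`, a data.frame (`child_id`, `group`, `weight`).
#' @export
build_weight_matrix <- function(net, cliques, label = "clique") {
  stopifnot(inherits(net, "friendship_network"))
  members <- unlist(cliques, use.names = FALSE)
  if (length(members) && !all(members %in% net$nodes))
    stop("clique references a node not present in the network")
  if (length(cliques)) {
    grp <- rep(seq_along(cliques), lengths(cliques))
    m <- table(members)                               # memberships per child
    w <- data.frame(child_id = members,
                    group = grp,
                    weight = 1 / as.numeric(m[members]),
                    stringsAsFactors = FALSE)
  } else {
    w <- data.frame(child_id = character(), group = integer(),
                    weight = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(label = label, groups = cliques,
                 children = net$nodes, weights = w),
            class = "membership_weights")
}

#' @export
print.membership_weights <- function(x, ...) {
  cat(sprintf("<membership_weights> '%s': %d groups, %d children with >=1 membership\n",
              x$label, length(x$groups), length(unique(x$weights$child_id))))
  invisible(x)
}

#' Per-child and per-school network summaries
#'
#' @param net A [build_adjacency()] network.
#' @param cliques2,cliques3 Dyad and triad lists from [enumerate_cliques()].
#' @param schools Optional named vector mapping child ID to school ID, for
#'   per-school aggregates.
#' @return List with `per_child` (child_id, ties, dyads, triads), `overall`
#'   (means and ranges) and, when `schools` is given, `per_school` means.
#' @export
network_summaries <- function(net, cliques2, cliques3, schools = NULL) {
  stopifnot(inherits(net, "friendship_network"))
  ids <- net$nodes
  deg <- table(factor(c(net$edges[, 1], net$edges[, 2]), levels = ids))
  d2 <- table(factor(unlist(cliques2, use.names = FALSE), levels = ids))
  d3 <- table(factor(unlist(cliques3, use.names = FALSE), levels = ids))
  per_child <- data.frame(child_id = ids,
                          ties = as.integer(deg),
                          dyads = as.integer(d2),
                          triads = as.integer(d3),
                          stringsAsFactors = FALSE)
  overall <- data.frame(
    stat = c("ties", "dyads", "triads"),
    mean = c(mean(per_child$ties), mean(per_child$dyads), mean(per_child$triads)),
    min = c(min(per_child$ties), min(per_child$dyads), min(per_child$triads)),
    max = c(max(per_child$ties), max(per_child$dyads), max(per_child$triads)))
  out <- list(per_child = per_child, overall = overall)
  if (!is.null(schools)) {
    sch <- schools[per_child$child_id]
    out$per_school <- stats::aggregate(per_child[c("ties", "dyads", "triads")],
                                by = list(school_id = sch), FUN = mean)
  }
  out
}
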