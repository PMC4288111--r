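# Nested-set labeling of subsumption hierarchies.  Every node of the tree is
# labeled with a (left, right) interval so that transitive descendant and
# ancestor queries become interval-containment tests instead of recursion.
# Multiple inheritance is handled by duplicating the node (and, recursively,
# its whole subtree) under each parent; queries collapse the duplicates back
# to canonical resources.

#' Expand a subsumption DAG into placement trees
#'
#' A resource with k parents receives k node placements, one under each
#' parent, each carrying a full copy of the resource's subtree (the copy is
#' recursive, which is what makes interval queries correct on the result).
#'
#' @param edges A data.frame with integer columns `child` and `parent`
#'   (resource ids); acyclic.
#' @param roots Optional integer vector of root resource ids; defaults to all
#'   resources never appearing as a child.
#' @return A list with `placements` (data.frame `node_id`, `resource_id`,
#'   `parent_node`; `parent_node` is `NA` for placement-tree roots) — the
#'   `node_id` -> `resource_id` mapping is the duplicate map.
#' @export
resolve_multiparent <- function(edges, roots = NULL) {
  edges <- normalize_edges(edges)
  all_res <- sort(unique(c(edges$child, edges$parent, roots)))
  if (is.null(roots)) {
    roots <- sort(setdiff(all_res, edges$child))
    if (!length(roots) && length(all_res)) {
      stop("cycle: no root candidate among ",
           paste(utils::head(all_res, 5L), collapse = ", "))
    }
  } else {
    roots <- sort(unique(as.integer(roots)))
  }
  # children adjacency (ascending resource-id order for determinism);
  # environment-backed for hashed lookup
  kid_of <- split(edges$child, factor(edges$parent, levels = all_res))
  kid_of <- lapply(kid_of, function(v) sort(unique(v)))
  names(kid_of) <- as.character(all_res)
  kid_env <- list2env(kid_of, hash = TRUE, parent = emptyenv())

  n_guess <- max(16L, 4L * length(all_res))
  node_res <- integer(n_guess); node_parent <- integer(n_guess)
  nn <- 0L
  add_node <- function(res, parent) {
    nn <<- nn + 1L
    if (nn > length(node_res)) {
      length(node_res) <<- 2L * length(node_res)
      length(node_parent) <<- 2L * length(node_parent)
    }
    node_res[nn] <<- res; node_parent[nn] <<- parent
    nn
  }
  visited <- logical(if (length(all_res)) max(all_res) else 0L)
  # iterative DFS over the DAG; each (placement) frame expands its children
  for (r in roots) {
    path <- integer(0)   # resources on the current DFS path (cycle guard)
    # frames: list of (resource, parent_node, child cursor)
    frames <- list(list(res = r, pn = NA_integer_, node = NA_integer_, i = 0L))
    while (length(frames)) {
      f <- frames[[length(frames)]]
      if (f$i == 0L) {
        if (f$res %in% path) {
          stop("cycle detected through resource ", f$res, ": ",
               paste(c(path[seq(match(f$res, path), length(path))], f$res),
                     collapse = " -> "))
        }
        path <- c(path, f$res)
        f$node <- add_node(f$res, f$pn)
        if (f$res <= length(visited)) visited[f$res] <- TRUE
      }
      kids <- get0(as.character(f$res), envir = kid_env,
                   ifnotfound = integer(0))
      if (f$i < length(kids)) {
        f$i <- f$i + 1L
        frames[[length(frames)]] <- f
        frames[[length(frames) + 1L]] <-
          list(res = kids[f$i], pn = f$node, node = NA_integer_, i = 0L)
      } else {
        path <- path[-length(path)]
        frames[[length(frames)]] <- NULL
      }
    }
  }
  orphans <- all_res[!vapply(all_res, function(r)
    r <= length(visited) && visited[r], logical(1))]
  if (length(orphans)) {
    stop("orphan resources (no parent path to a root): ",
         paste(utils::head(orphans, 10L), collapse = ", "))
  }
  list(placements = data.frame(node_id = seq_len(nn),
                               resource_id = node_res[seq_len(nn)],
                               parent_node = node_parent[seq_len(nn)]))
}

normalize_edges <- function(edges) {
  if (is.null(edges) || !nrow(as.data.frame(edges))) {
    return(data.frame(child = integer(0), parent = integer(0)))
  }
  edges <- as.data.frame(edges)[, c("child", "parent")]
  edges$child <- as.integer(edges$child); edges$parent <- as.integer(edges$parent)
  if (any(edges$child == edges$parent)) {
    stop("self-loop edge: ", edges$child[edges$child == edges$parent][1L])
  }
  unique(edges)
}

#' Build a nested-set index over a subsumption hierarchy
#'
#' One batch depth-first pass labels every placement with a (left, right)
#' pair; children are visited in ascending resource-id order so identical
#' edge sets always produce identical labelings.  For a pure tree of N
#' placements the 2N labels are exactly 1..2N.
#'
#' @inheritParams resolve_multiparent
#' @return An object of class `nested_set_index`: a data.frame with columns
#'   `node_id`, `resource_id`, `lft`, `rgt`, plus a `stale` attribute.
#' @export
build_nested_set <- function(edges, roots = NULL) {
  rm_ <- resolve_multiparent(edges, roots)
  pl <- rm_$placements
  n <- nrow(pl)
  lft <- integer(n); rgt <- integer(n)
  if (n) {
    kids <- split(pl$node_id, factor(pl$parent_node, levels = pl$node_id))
    root_nodes <- pl$node_id[is.na(pl$parent_node)]
    counter <- 0L
    # iterative DFS with explicit child cursors; placements were created in
    # DFS order with children already ascending, so node order is reusable
    stack <- integer(0); cursor <- integer(n)
    for (rn in root_nodes) {
      stack <- rn
      counter <- counter + 1L; lft[rn] <- counter
      while (length(stack)) {
        top <- stack[length(stack)]
        ch <- kids[[top]]
        if (cursor[top] < length(ch)) {
          cursor[top] <- cursor[top] + 1L
          nxt <- ch[cursor[top]]
          counter <- counter + 1L; lft[nxt] <- counter
          stack <- c(stack, nxt)
        } else {
          counter <- counter + 1L; rgt[top] <- counter
          stack <- stack[-length(stack)]
        }
      }
    }
  }
  idx <- data.frame(node_id = pl$node_id, resource_id = pl$resource_id,
                    lft = lft, rgt = rgt)
  structure(idx, stale = FALSE, class = c("nested_set_index", "data.frame"))
}

#' @export
print.nested_set_index <- function(x, ...) {
  cat("<nested_set_index> ", nrow(x), " placements over ",
      length(unique(x$resource_id)), " resources",
      if (isTRUE(attr(x, "stale"))) " [STALE]", "\n", sep = "")
  invisible(x)
}

check_fresh <- function(index) {
  if (isTRUE(attr(index, "stale"))) {
    stop("nested-set index is stale; rebuild it before querying")
  }
}

placements_of <- function(index, resource_id) {
  p <- index[index$resource_id == resource_id, , drop = FALSE]
  if (!nrow(p)) stop("resource ", resource_id, " is not placed in the index")
  p
}

#' Transitive descendants via interval containment
#'
#' @param index A [build_nested_set()] index.
#' @param resource_id A placed resource id.
#' @return Integer vector of descendant resource ids (duplicates collapsed to
#'   canonical resources), computed by interval comparison only.
#' @export
descendants <- function(index, resource_id) {
  check_fresh(index)
  p <- placements_of(index, resource_id)
  hit <- rep(FALSE, nrow(index))
  for (i in seq_len(nrow(p))) {
    hit <- hit | (index$lft > p$lft[i] & index$lft < p$rgt[i])
  }
  sort(unique(index$resource_id[hit]))
}

#' Transitive ancestors via interval containment
#'
#' @inheritParams descendants
#' @return Integer vector of ancestor resource ids.
#' @export
ancestors <- function(index, resource_id) {
  check_fresh(index)
  p <- placements_of(index, resource_id)
  hit <- rep(FALSE, nrow(index))
  for (i in seq_len(nrow(p))) {
    hit <- hit | (index$lft < p$lft[i] & index$rgt > p$rgt[i])
  }
  sort(unique(index$resource_id[hit]))
}

#' Insert one resource into an existing index
#'
#' `relabel_incremental` splices the new resource in as the last child of
#' every placement of its parent, shifting all labels at or beyond each
#' insertion point by 2; `mark_stale` defers the work to the next batch
#' rebuild (queries on a stale index are refused).
#'
#' @param index A [build_nested_set()] index.
#' @param parent_id Resource id of the parent (must be placed).
#' @param resource_id Resource id to insert.
#' @param policy `"relabel_incremental"` or `"mark_stale"`.
#' @return The updated index.
#' @export
insert_resource <- function(index, parent_id, resource_id,
                            policy = c("relabel_incremental", "mark_stale")) {
  policy <- match.arg(policy)
  if (!any(index$resource_id == parent_id)) {
    stop("cannot insert under unplaced parent resource ", parent_id)
  }
  if (policy == "mark_stale") {
    attr(index, "stale") <- TRUE
    return(index)
  }
  k <- sum(index$resource_id == parent_id)
  for (i in seq_len(k)) {
    p <- index[index$resource_id == parent_id, , drop = FALSE]
    p <- p[order(p$lft), , drop = FALSE][i, , drop = FALSE]
    at <- p$rgt   # insertion point: becomes the new node's left label
    index$lft[index$lft >= at] <- index$lft[index$lft >= at] + 2L
    index$rgt[index$rgt >= at] <- index$rgt[index$rgt >= at] + 2L
    new_row <- data.frame(node_id = max(index$node_id, 0L) + 1L,
                          resource_id = resource_id,
                          lft = at, rgt = at + 1L)
    st <- attr(index, "stale")
    index <- rbind(as.data.frame(index), new_row)
    index <- structure(index, stale = st,
                       class = c("nested_set_index", "data.frame"))
  }
  index
}
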