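# Unrooted-tree machinery for subtree prune-and-regraft (SPR) operations:
# canonical topology keys, SPR neighbourhoods, exact SPR distance by
# (bidirectional) breadth-first search, and the SPR supertree.
#
# Internal representation ("utree"): adjacency list over integer node ids;
# `labels[i]` is the leaf name for leaf nodes and NA for internal nodes.
# Branch lengths are ignored throughout — SPR is a topology-level notion.

utree <- function(adj, labels) {
  structure(list(adj = adj, labels = labels), class = "utree")
}

#' @export
print.utree <- function(x, ...) {
  cat("utree:", sum(!is.na(x$labels)), "leaves | key:", canon_key(x), "\n")
  invisible(x)
}

utree_leaves <- function(t) which(!is.na(t$labels))

utree_from_phylo <- function(phy) {
  phy <- ape::unroot(phy)
  ntip <- length(phy$tip.label)
  N <- ntip + phy$Nnode
  adj <- vector("list", N)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1]; b <- phy$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  labels <- c(phy$tip.label, rep(NA_character_, phy$Nnode))
  utree(adj, labels)
}

utree_from_newick <- function(txt) {
  utree_from_phylo(ape::read.tree(text = txt))
}

#' Canonical topology key of an unrooted leaf-labelled tree
#'
#' Two trees have the same key iff they have the same unrooted topology on
#' the same leaf set. The tree is rooted at the neighbour of the
#' alphabetically smallest leaf and subtree strings are sorted recursively.
#' @param t A tree (`phylo`, Newick string, or internal representation).
#' @return A character key (itself a valid Newick string without lengths).
#' @export
canon_key <- function(t) {
  t <- as_utree(t)
  lv <- utree_leaves(t)
  ref <- lv[order(t$labels[lv])][1]
  if (length(lv) == 1) return(t$labels[ref])
  rec <- function(node, parent) {
    kids <- setdiff(t$adj[[node]], parent)
    if (length(kids) == 0) return(t$labels[node])
    paste0("(", paste(sort(vapply(kids, rec, character(1), parent = node)),
                      collapse = ","), ")")
  }
  nb <- t$adj[[ref]][1]
  paste0("(", t$labels[ref], ",", rec(nb, ref), ");")
}

as_utree <- function(t) {
  if (inherits(t, "utree")) t
  else if (inherits(t, "phylo")) utree_from_phylo(t)
  else if (is.character(t) && length(t) == 1) utree_from_newick(t)
  else stop("cannot interpret tree input")
}

#' @rdname canon_key
#' @export
as_phylo_tree <- function(t) {
  if (inherits(t, "phylo")) return(t)
  ape::read.tree(text = canon_key(as_utree(t)))
}

utree_edges <- function(t, from = NULL) {
  # all edges (u < v) of the component containing `from` (default: the
  # component of the smallest leaf)
  if (is.null(from)) from <- utree_leaves(t)[1]
  seen <- logical(length(t$adj))
  stack <- from; seen[from] <- TRUE
  out <- list()
  while (length(stack)) {
    u <- stack[[1]]; stack <- stack[-1]
    for (v in t$adj[[u]]) {
      if (u < v) out[[length(out) + 1L]] <- c(u, v)
      if (!seen[v]) { seen[v] <- TRUE; stack <- c(stack, v) }
    }
  }
  do.call(rbind, out)
}

# all SPR neighbours of an unrooted binary tree, deduplicated by key;
# returns list of list(tree=, key=)
spr_neighbors <- function(t) {
  t <- as_utree(t)
  res <- new.env(parent = emptyenv())
  self_key <- canon_key(t)
  ed <- utree_edges(t)
  for (r in seq_len(nrow(ed))) {
    for (dir in 1:2) {
      u <- ed[r, dir]; v <- ed[r, 3 - dir]
      if (is.na(t$labels[u]) == FALSE) next  # u must be internal
      adj <- t$adj
      # prune v-side: detach edge u-v, suppress u
      adj[[u]] <- setdiff(adj[[u]], v)
      adj[[v]] <- setdiff(adj[[v]], u)
      rest <- adj[[u]]          # the two remaining neighbours of u
      if (length(rest) != 2) next
      x <- rest[1]; y <- rest[2]
      adj[[x]] <- c(setdiff(adj[[x]], u), y)
      adj[[y]] <- c(setdiff(adj[[y]], u), x)
      adj[[u]] <- integer(0)
      base <- utree(adj, t$labels)
      red <- utree_edges(base, from = x)
      for (q in seq_len(nrow(red))) {
        p1 <- red[q, 1]; p2 <- red[q, 2]
        a2 <- base$adj
        a2[[p1]] <- c(setdiff(a2[[p1]], p2), u)
        a2[[p2]] <- c(setdiff(a2[[p2]], p1), u)
        a2[[u]] <- c(p1, p2, v)
        a2[[v]] <- c(a2[[v]], u)
        cand <- utree(a2, t$labels)
        k <- canon_key(cand)
        if (k != self_key && is.null(res[[k]])) res[[k]] <- cand
      }
    }
  }
  ks <- ls(res)
  lapply(ks, function(k) list(tree = res[[k]], key = k))
}

# BFS ball around a tree: named integer vector key -> SPR distance, up to
# and including `depth` moves (depth = Inf explores the whole space).
spr_ball <- function(t, depth) {
  t <- as_utree(t)
  dist <- new.env(parent = emptyenv())
  k0 <- canon_key(t)
  assign(k0, 0L, envir = dist)
  frontier <- list(t)
  d <- 0L
  while (length(frontier) && d < depth) {
    d <- d + 1L
    nxt <- list()
    for (tr in frontier) {
      for (nb in spr_neighbors(tr)) {
        if (is.null(dist[[nb$key]])) {
          assign(nb$key, d, envir = dist)
          nxt[[length(nxt) + 1L]] <- nb$tree
        }
      }
    }
    frontier <- nxt
  }
  dist
}

#' SPR distance between two unrooted binary trees
#'
#' Exact minimum number of subtree prune-and-regraft moves, computed by
#' bidirectional breadth-first search over SPR neighbourhoods. Exact for the
#' leaf counts this package works at (the search space is the full set of
#' unrooted topologies, at most 10395 for 8 leaves); for larger trees the
#' search is truncated at `cap` moves and `cap + 1` is returned as a lower
#' bound with a warning.
#'
#' @param t1,t2 Trees on the same leaf set (`phylo`, Newick, or internal).
#' @param cap Give up beyond this many moves (default 8).
#' @return Integer SPR distance.
#' @export
spr_distance <- function(t1, t2, cap = 8L) {
  t1 <- as_utree(t1); t2 <- as_utree(t2)
  l1 <- sort(t1$labels[utree_leaves(t1)])
  l2 <- sort(t2$labels[utree_leaves(t2)])
  if (!identical(l1, l2)) stop("trees have different leaf sets")
  k1 <- canon_key(t1); k2 <- canon_key(t2)
  if (k1 == k2) return(0L)
  da <- new.env(parent = emptyenv()); assign(k1, 0L, envir = da)
  db <- new.env(parent = emptyenv()); assign(k2, 0L, envir = db)
  fa <- list(t1); fb <- list(t2)
  steps <- 0L
  while (length(fa) && length(fb)) {
    steps <- steps + 1L
    if (steps > cap) break
    # expand the smaller frontier
    if (length(fa) <= length(fb)) {
      cur <- fa; dcur <- da; dother <- db
    } else {
      cur <- fb; dcur <- db; dother <- da
    }
    nxt <- list()
    best <- NA_integer_
    d <- get(canon_key(cur[[1]]), envir = dcur) + 1L
    for (tr in cur) {
      for (nb in spr_neighbors(tr)) {
        if (!is.null(dother[[nb$key]])) {
          tot <- d + get(nb$key, envir = dother)
          if (is.na(best) || tot < best) best <- tot
        }
        if (is.null(dcur[[nb$key]])) {
          assign(nb$key, d, envir = dcur)
          nxt[[length(nxt) + 1L]] <- nb$tree
        }
      }
    }
    if (!is.na(best)) return(as.integer(best))
    if (length(fa) <= length(fb)) fa <- nxt else fb <- nxt
  }
  warning("SPR search truncated at cap = ", cap)
  as.integer(cap + 1L)
}

# enumerate all unrooted topologies on a leaf set (labels sorted first);
# (2n-5)!! trees, feasible for n <= 8
all_topologies <- function(labels) {
  labels <- sort(labels)
  n <- length(labels)
  stopifnot(n >= 2)
  if (n == 2) {
    return(list(utree(list(2L, 1L), labels)))
  }
  base <- utree(list(4L, 4L, 4L, c(1L, 2L, 3L)),
                c(labels[1:3], NA_character_))
  trees <- list(base)
  for (i in seq(4L, length.out = n - 3L)) {
    nxt <- list()
    for (tr in trees) {
      ed <- utree_edges(tr)
      for (r in seq_len(nrow(ed))) {
        p1 <- ed[r, 1]; p2 <- ed[r, 2]
        adj <- tr$adj
        leaf_id <- length(adj) + 1L
        mid_id <- length(adj) + 2L
        adj[[p1]] <- c(setdiff(adj[[p1]], p2), mid_id)
        adj[[p2]] <- c(setdiff(adj[[p2]], p1), mid_id)
        adj[[leaf_id]] <- mid_id
        adj[[mid_id]] <- c(p1, p2, leaf_id)
        nxt[[length(nxt) + 1L]] <-
          utree(adj, c(tr$labels, labels[i], NA_character_))
      }
    }
    trees <- nxt
  }
  trees
}

random_topology <- function(labels) {
  labels <- sort(labels)
  n <- length(labels)
  if (n == 2) return(all_topologies(labels)[[1]])
  tr <- utree(list(4L, 4L, 4L, c(1L, 2L, 3L)),
              c(labels[1:3], NA_character_))
  for (i in seq(4L, length.out = n - 3L)) {
    ed <- utree_edges(tr)
    r <- sample.int(nrow(ed), 1)
    p1 <- ed[r, 1]; p2 <- ed[r, 2]
    adj <- tr$adj
    leaf_id <- length(adj) + 1L
    mid_id <- length(adj) + 2L
    adj[[p1]] <- c(setdiff(adj[[p1]], p2), mid_id)
    adj[[p2]] <- c(setdiff(adj[[p2]], p1), mid_id)
    adj[[leaf_id]] <- mid_id
    adj[[mid_id]] <- c(p1, p2, leaf_id)
    tr <- utree(adj, c(tr$labels, labels[i], NA_character_))
  }
  tr
}

# drop leaves not in `keep`, suppressing degree-2 internal nodes
restrict_utree <- function(t, keep) {
  t <- as_utree(t)
  repeat {
    drop <- which(!is.na(t$labels) & !(t$labels %in% keep) &
                    lengths(t$adj) > 0)
    if (!length(drop)) break
    for (l in drop) {
      u <- t$adj[[l]]
      t$adj[[l]] <- integer(0)
      t$labels[l] <- NA_character_
      if (length(u)) t$adj[[u]] <- setdiff(t$adj[[u]], l)
    }
    # suppress internal nodes of degree 2 (and drop degree-1 internals)
    repeat {
      deg2 <- which(is.na(t$labels) & lengths(t$adj) == 2)
      deg1 <- which(is.na(t$labels) & lengths(t$adj) == 1)
      if (!length(deg2) && !length(deg1)) break
      for (u in deg2) {
        nb <- t$adj[[u]]
        if (length(nb) != 2) next
        t$adj[[nb[1]]] <- unique(c(setdiff(t$adj[[nb[1]]], u), nb[2]))
        t$adj[[nb[2]]] <- unique(c(setdiff(t$adj[[nb[2]]], u), nb[1]))
        t$adj[[u]] <- integer(0)
      }
      for (u in deg1) {
        nb <- t$adj[[u]]
        if (length(nb) != 1) next
        t$adj[[nb[1]]] <- setdiff(t$adj[[nb[1]]], u)
        t$adj[[u]] <- integer(0)
      }
    }
  }
  t
}

#' SPR supertree of a set of gene trees
#'
#' Finds the tree minimising the total SPR distance to the input trees (each
#' distance taken after restricting the candidate to that input's leaf set).
#' For 7 or fewer leaves the search is exhaustive over all unrooted
#' topologies; beyond that, hill-climbing over SPR neighbourhoods from the
#' input trees plus random restarts, scored against precomputed SPR-distance
#' balls of radius `cap - 1` around each input (distances beyond are
#' truncated at `cap` during the climb; the final tree and all candidate
#' starts are re-scored with exact distances, so the reported score is exact
#' and never exceeds that of any input evaluated as a candidate).
#'
#' @param trees List of input trees (`phylo` / Newick / internal) with
#'   overlapping leaf sets.
#' @param restarts Number of random restarts for the hill-climb.
#' @param seed Integer seed for the restarts.
#' @param cap Truncation radius for the hill-climb scoring.
#' @return List of class `spr_supertree`: `tree` ([ape::phylo]), `score`
#'   (total exact SPR distance), `per_input` (exact distances), `seed`.
#' @export
spr_supertree <- function(trees, restarts = 10L, seed = 1L, cap = 2L) {
  if (length(trees) < 2) stop("need at least 2 input trees")
  uts <- lapply(trees, as_utree)
  leafsets <- lapply(uts, function(t) sort(t$labels[utree_leaves(t)]))
  L <- sort(unique(unlist(leafsets)))
  if (any(vapply(leafsets, function(x) length(intersect(x, L)) == 0,
                 logical(1))))
    stop("input trees have disjoint leaf sets")
  exact_score <- function(cand, dist_cap = 6L) {
    ds <- vapply(seq_along(uts), function(i) {
      r <- restrict_utree(cand, leafsets[[i]])
      suppressWarnings(spr_distance(r, uts[[i]], cap = dist_cap))
    }, integer(1))
    ds
  }
  if (length(L) <= 7) {
    # exhaustive: full-space BFS ball around each input, then score all
    balls <- lapply(uts, function(t) spr_ball(t, Inf))
    topos <- all_topologies(L)
    best <- NULL; best_score <- Inf; best_key <- ""
    for (tp in topos) {
      sc <- 0L
      for (i in seq_along(uts)) {
        r <- restrict_utree(tp, leafsets[[i]])
        k <- canon_key(r)
        dv <- balls[[i]][[k]]
        if (is.null(dv)) dv <- spr_distance(r, uts[[i]])
        sc <- sc + dv
      }
      k0 <- canon_key(tp)
      if (sc < best_score || (sc == best_score && k0 < best_key)) {
        best <- tp; best_score <- sc; best_key <- k0
      }
    }
    per <- exact_score(best)
    return(structure(list(tree = as_phylo_tree(best),
                          score = sum(per), per_input = per, seed = seed),
                     class = "spr_supertree"))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  balls <- lapply(uts, function(t) spr_ball(t, max(cap - 1L, 1L)))
  truncated <- function(cand) {
    sum(vapply(seq_along(uts), function(i) {
      r <- restrict_utree(cand, leafsets[[i]])
      k <- canon_key(r)
      dv <- balls[[i]][[k]]
      if (is.null(dv)) cap else dv
    }, numeric(1)))
  }
  starts <- c(uts[vapply(uts, function(t)
    identical(sort(t$labels[utree_leaves(t)]), L), logical(1))],
    lapply(seq_len(restarts), function(i) random_topology(L)))
  finalists <- list()
  for (s in starts) {
    cur <- if (identical(sort(s$labels[utree_leaves(s)]), L)) s
           else random_topology(L)
    cur_sc <- truncated(cur)
    repeat {
      nbs <- spr_neighbors(cur)
      scs <- vapply(nbs, function(nb) truncated(nb$tree), numeric(1))
      if (!length(scs) || min(scs) >= cur_sc) break
      pick <- which(scs == min(scs))
      keys <- vapply(nbs[pick], `[[`, character(1), "key")
      cur <- nbs[[pick[order(keys)[1]]]]$tree
      cur_sc <- min(scs)
    }
    finalists[[length(finalists) + 1L]] <- cur
  }
  # shortlist by truncated score; exact-rescore the shortlist plus the input
  # trees themselves, which guarantees the returned score never exceeds the
  # score of any input evaluated as a candidate
  finalists <- c(finalists,
                 uts[vapply(uts, function(t)
                   identical(sort(t$labels[utree_leaves(t)]), L),
                   logical(1))])
  fkeys <- vapply(finalists, canon_key, character(1))
  finalists <- finalists[!duplicated(fkeys)]
  fkeys <- fkeys[!duplicated(fkeys)]
  tscores <- vapply(finalists, truncated, numeric(1))
  shortlist <- which(tscores <= min(tscores) + 1)
  shortlist <- shortlist[order(tscores[shortlist], fkeys[shortlist])]
  if (length(shortlist) > 8) shortlist <- shortlist[seq_len(8)]
  best <- NULL; best_per <- NULL; best_score <- Inf; best_key <- ""
  for (fi in shortlist) {
    per <- exact_score(finalists[[fi]])
    k0 <- fkeys[fi]
    if (sum(per) < best_score || (sum(per) == best_score && k0 < best_key)) {
      best <- finalists[[fi]]; best_per <- per
      best_score <- sum(per); best_key <- k0
    }
  }
  structure(list(tree = as_phylo_tree(best), score = best_score,
                 per_input = best_per, seed = seed),
            class = "spr_supertree")
}

#' @export
print.spr_supertree <- function(x, ...) {
  cat("spr_supertree: total SPR distance", x$score, "| per input:",
      paste(x$per_input, collapse = " "), "\n")
  invisible(x)
}
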