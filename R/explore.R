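## Ploidy-profile space operations: the split operation (un-zipping a
## reticulation), unzipping to a multiple-labelled tree, a distance upper
## bound between realizations, tree-based and tree-child analysis, and a
## bounded exhaustive enumerator of realizations.

## Is the arc (u, v) a cut-arc (its removal disconnects the underlying
## undirected graph)?
is_cut_arc <- function(N, u, v) {
  arcs <- N$arcs
  i <- which(arcs$tail == u & arcs$head == v)
  if (!length(i)) stop("no arc (", u, ",", v, ")")
  if (arcs$mult[i] > 1L) return(FALSE)
  arcs <- arcs[-i, , drop = FALSE]
  seen <- N$root; frontier <- N$root
  while (length(frontier)) {
    nxt <- unique(c(arcs$head[arcs$tail %in% frontier],
                    arcs$tail[arcs$head %in% frontier]))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  !(v %in% seen)
}

descendants_of <- function(N, v) {
  seen <- v; frontier <- v
  while (length(frontier)) {
    nxt <- setdiff(unique(N$arcs$head[N$arcs$tail %in% frontier]), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  seen
}

#' Split a reticulation vertex
#'
#' Removes a reticulation `h` whose child arc is a cut-arc and duplicates
#' the subgraph below its child, attaching one copy to each former parent of
#' `h` (for a bead, both copies to the bead's tree vertex). Label-summed
#' path counts are conserved; the result is in general multiple-labelled.
#'
#' @param N a valid [pnet()] (possibly multiple-labelled).
#' @param h a reticulation vertex identifier.
#' @return A multiple-labelled [pnet()].
#' @export
split_network <- function(N, h) {
  if (net_indeg(N, h) != 2L) stop(h, " is not a reticulation vertex")
  ch <- net_children(N, h)
  if (length(ch) != 1L) stop(h, " does not have a unique child")
  if (!is_cut_arc(N, h, ch)) stop("(", h, ",", ch, ") is not a cut-arc")
  par <- rep(N$arcs$tail[N$arcs$head == h], N$arcs$mult[N$arcs$head == h])
  below <- descendants_of(N, ch)
  vs <- net_vertices(N)
  k <- 1L
  repeat {
    suffix <- paste0("_cp", k)
    if (!any(paste0(below, suffix) %in% vs)) break
    k <- k + 1L
  }
  copy <- stats::setNames(paste0(below, suffix), below)
  sub <- N$arcs[N$arcs$tail %in% below, , drop = FALSE]
  sub$tail <- unname(copy[sub$tail]); sub$head <- unname(copy[sub$head])
  arcs <- N$arcs[!(N$arcs$head == h | N$arcs$tail == h), , drop = FALSE]
  arcs <- rbind(arcs, sub,
                data.frame(tail = c(par[2], par[1]), head = c(ch, unname(copy[ch])),
                           mult = 1L, stringsAsFactors = FALSE))
  labels <- N$labels
  dup <- names(labels)[names(labels) %in% below]
  labels <- c(labels, stats::setNames(unname(labels[dup]), unname(copy[dup])))
  pnet(arcs, root = N$root, labels = labels, mul = TRUE)
}

#' Unzip a network to a multiple-labelled tree
#'
#' Repeatedly applies [split_network()] (at the topologically first
#' reticulation whose child arc is a cut-arc) until no reticulations remain.
#'
#' @param N a valid [pnet()].
#' @return A list with `network` (a multiple-labelled tree) and `splits`
#'   (number of split operations used).
#' @export
unzip_to_multree <- function(N) {
  splits <- 0L
  repeat {
    inv <- reticulation_inventory(N)
    if (!nrow(inv)) break
    ord <- topo_order(N)
    rets <- ord[ord %in% inv$vertex]
    done <- FALSE
    for (h in rets) {
      ch <- net_children(N, h)
      if (length(ch) == 1L && is_cut_arc(N, h, ch)) {
        N <- split_network(N, h)
        splits <- splits + 1L
        done <- TRUE
        break
      }
    }
    if (!done) stop("no splittable reticulation found")     # cannot happen
  }
  list(network = N, splits = splits)
}

#' Upper bound on the ploidy-profile-space distance
#'
#' Unzips both realizations to multiple-labelled trees and adds the plugged
#' tree metric: `splits(N1) + splits(N2) + tree_distance(T1, T2)`. The exact
#' shortest-path distance is not computed.
#'
#' @param N1,N2 valid [pnet()] realizations of the same profile.
#' @param tree_distance a function of two multiple-labelled trees returning
#'   a non-negative number; the default returns 0 for isomorphic trees and
#'   refuses otherwise, forcing callers to supply a real MUL-tree metric.
#' @return Non-negative number.
#' @export
distance_upper_bound <- function(N1, N2, tree_distance = NULL) {
  c1 <- count_paths(N1); c2 <- count_paths(N2)
  if (!identical(c1[sort(names(c1))], c2[sort(names(c2))]))
    stop("networks do not realize the same ploidy profile")
  if (is.null(tree_distance))
    tree_distance <- function(t1, t2) {
      if (isomorphic_networks(t1, t2)) 0
      else stop("supply a MUL-tree edit distance for non-isomorphic unzipped trees")
    }
  u1 <- unzip_to_multree(N1); u2 <- unzip_to_multree(N2)
  u1$splits + u2$splits + tree_distance(u1$network, u2$network)
}

## Suppress all degree-(1,1) vertices and collapse an out-degree-one root.
normalize_subdivided <- function(N) {
  repeat {
    vs <- net_vertices(N)
    deg11 <- vs[vapply(vs, function(v) net_indeg(N, v) == 1L && net_outdeg(N, v) == 1L, TRUE)]
    if (length(deg11)) { N <- suppress_vertex(N, deg11[1L]); next }
    if (net_outdeg(N, N$root) == 1L && length(vs) > 1L) {
      ch <- net_children(N, N$root)
      N <- del_arc(N, N$root, ch)
      N$root <- ch
      next
    }
    break
  }
  N
}

#' Is the network tree-based?
#'
#' Searches over choices of one incoming arc to delete per reticulation
#' (for a bead, one of its two parallel arcs) such that the remaining
#' spanning digraph, after suppression, is a phylogenetic tree on the same
#' taxa: the *base tree*.
#'
#' @param N a valid [pnet()].
#' @return A list with `tree_based` (logical) and `base_tree` (a [pnet()]
#'   phylogenetic tree, or `NULL`).
#' @export
is_tree_based <- function(N) {
  if (is_single_vertex(N)) return(list(tree_based = TRUE, base_tree = N))
  inv <- reticulation_inventory(N)
  rets <- inv$vertex
  if (length(rets) > 24L) stop("refusing tree-based search beyond 24 reticulations")
  ord <- topo_order(N)
  rets <- ord[ord %in% rets]
  outdeg <- stats::setNames(vapply(ord, function(v) net_outdeg(N, v), 1L), ord)
  leaves <- names(N$labels)
  try_assign <- function(i, removed) {
    if (i > length(rets)) {
      M <- N
      for (r in seq_len(nrow(removed))) M <- del_arc(M, removed$tail[r], removed$head[r])
      M <- normalize_subdivided(M)
      rep <- validate_network(M)
      if (rep$ok && nrow(reticulation_inventory(M)) == 0L) return(M)
      return(NULL)
    }
    h <- rets[i]
    ins <- which(N$arcs$head == h)
    cands <- unique(N$arcs$tail[ins])
    for (u in cands) {
      if (outdeg[u] - 1L < 1L && !(u %in% leaves)) next   # would strand u
      outdeg[u] <<- outdeg[u] - 1L
      res <- try_assign(i + 1L, rbind(removed, data.frame(
        tail = u, head = h, stringsAsFactors = FALSE)))
      outdeg[u] <<- outdeg[u] + 1L
      if (!is.null(res)) return(res)
    }
    NULL
  }
  res <- try_assign(1L, data.frame(tail = character(0), head = character(0),
                                   stringsAsFactors = FALSE))
  list(tree_based = !is.null(res), base_tree = res)
}

#' Is the network tree-child (ignoring bead reticulations)?
#'
#' Every non-leaf vertex must reach some leaf by a directed path whose
#' vertices after the first are not reticulations outside beads.
#'
#' @param N a valid [pnet()].
#' @return Logical.
#' @export
is_tree_child <- function(N) {
  vs <- net_vertices(N)
  if (length(vs) == 1L) return(TRUE)
  beads <- bead_reticulations(N)
  ord <- rev(topo_order(N))
  ok <- stats::setNames(logical(length(ord)), ord)
  leaves <- names(N$labels)
  for (v in ord) {
    if (v %in% leaves) { ok[v] <- TRUE; next }
    kids <- net_children(N, v)
    good <- vapply(kids, function(c) {
      ok[c] && (!(net_indeg(N, c) == 2L) || c %in% beads)
    }, TRUE)
    ok[v] <- any(good)
  }
  all(ok)
}

#' Exhaustively enumerate realizations of a tiny profile
#'
#' Generates, up to isomorphism, every valid network on the profile's taxa
#' with at most `max_reticulations` reticulation vertices whose path counts
#' equal the profile. Degree accounting fixes the number of tree vertices,
#' so enumeration reduces to assigning arc endpoints under capacity,
#' acyclicity and bead constraints. Hard guards keep this desk-scale.
#'
#' @param p a [ploidy_profile()] with at most 2 taxa.
#' @param max_reticulations at most 3.
#' @return List of [pnet()] objects.
#' @export
enumerate_realizations <- function(p, max_reticulations) {
  p <- as_profile(p)
  n <- length(p$components)
  if (n > 2L) stop("enumeration guard: at most 2 taxa")
  if (max_reticulations > 3L) stop("enumeration guard: at most 3 reticulations")
  out <- list()
  if (n == 1L && p$components[1] == 1L)
    out[[1L]] <- single_vertex_net(p$labels[1])
  for (R in 0:max_reticulations) {
    Tn <- R + n - 2L
    if (Tn < 0L) next
    if (R == 0L && n == 1L) next              # needs the degenerate case above
    verts <- c("r", if (Tn) paste0("t", seq_len(Tn)), if (R) paste0("h", seq_len(R)),
               paste0("l", seq_len(n)))
    stubs <- c(rep("r", 2L),
               if (Tn) rep(paste0("t", seq_len(Tn)), each = 2L),
               if (R) paste0("h", seq_len(R)))
    cap <- stats::setNames(c(rep(1L, Tn), rep(2L, R), rep(1L, n)),
                           setdiff(verts, "r"))
    found <- list()
    assign_stub <- function(i, arcs, cap) {
      if (i > length(stubs)) {
        M <- pnet(arcs, root = "r",
                  labels = stats::setNames(p$labels, paste0("l", seq_len(n))))
        if (any(M$arcs$mult > 2L)) return()
        for (r in which(M$arcs$mult == 2L))
          if (!(M$arcs$head[r] %in% paste0("h", seq_len(R)))) return()
        if (is.null(topo_order(M))) return()
        if (!validate_network(M)$ok) return()
        if (!realizes(M, p)) return()
        if (!any(vapply(found, isomorphic_networks, TRUE, M)))
          found[[length(found) + 1L]] <<- M
        return()
      }
      src <- stubs[i]
      same_src_prev <- i > 1L && stubs[i - 1L] == src
      for (tg in names(cap)) {
        if (cap[tg] == 0L || tg == src) next
        if (same_src_prev && tg < arcs$head[nrow(arcs)]) next  # symmetry
        cap2 <- cap; cap2[tg] <- cap2[tg] - 1L
        assign_stub(i + 1L,
                    rbind(arcs, data.frame(tail = src, head = tg, mult = 1L,
                                           stringsAsFactors = FALSE)),
                    cap2)
      }
    }
    assign_stub(1L, data.frame(tail = character(0), head = character(0),
                               mult = integer(0), stringsAsFactors = FALSE), cap)
    out <- c(out, found)
  }
  out
}
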