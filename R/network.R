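## Rooted directed acyclic multigraph with beads: the network data model.
## Arcs are stored one row per ordered vertex pair with a multiplicity
## (capped at 2: a bead); vertex identifiers are opaque strings.

#' Construct a phylogenetic network object
#'
#' Networks here are rooted directed acyclic multigraphs in which parallel
#' arcs come in pairs at most (*beads*, modelling whole-genome duplication),
#' every non-root internal vertex is a tree vertex (in 1, out 2) or a
#' reticulation vertex (in 2, out 1), and leaves carry taxon labels. The
#' single labelled vertex with no arcs is the degenerate network on one
#' taxon. Constructors in this package produce valid networks; use
#' [validate_network()] to check hand-built ones.
#'
#' @param arcs data frame with columns `tail`, `head` and optionally `mult`
#'   (1 or 2); repeated `tail`/`head` rows are collapsed into multiplicities.
#' @param root root vertex identifier.
#' @param labels named character vector mapping leaf vertex ids to taxon
#'   labels.
#' @param mul logical; if `TRUE` the network is multiple-labelled (taxon
#'   labels may repeat across leaves).
#' @return An object of class `pnet`.
#' @export
pnet <- function(arcs, root, labels, mul = FALSE) {
  if (is.null(arcs) || nrow(arcs) == 0L) {
    arcs <- data.frame(tail = character(0), head = character(0), mult = integer(0),
                       stringsAsFactors = FALSE)
  } else {
    arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
    if (!"mult" %in% names(arcs)) arcs$mult <- 1L
    key <- paste(arcs$tail, arcs$head, sep = "\r")
    if (anyDuplicated(key)) {
      m <- tapply(as.integer(arcs$mult), key, sum)
      parts <- strsplit(names(m), "\r", fixed = TRUE)
      arcs <- data.frame(tail = vapply(parts, `[`, "", 1L),
                         head = vapply(parts, `[`, "", 2L),
                         mult = as.integer(m), stringsAsFactors = FALSE)
    }
    arcs$mult <- as.integer(arcs$mult)
  }
  structure(list(arcs = arcs, root = as.character(root),
                 labels = labels, mul = isTRUE(mul)),
            class = "pnet")
}

#' The degenerate single-vertex network on one taxon
#'
#' Realizes the profile `(1)` and is the endpoint of complete cherry
#' modification sequences.
#'
#' @param taxon the taxon label.
#' @param vid vertex identifier.
#' @return A [pnet()].
#' @export
single_vertex_net <- function(taxon, vid = "v1") {
  pnet(NULL, root = vid, labels = stats::setNames(taxon, vid))
}

net_vertices <- function(N) {
  unique(c(N$root, N$arcs$tail, N$arcs$head, names(N$labels)))
}

net_outdeg <- function(N, v) {
  i <- N$arcs$tail == v
  if (!any(i)) 0L else sum(N$arcs$mult[i])
}

net_indeg <- function(N, v) {
  i <- N$arcs$head == v
  if (!any(i)) 0L else sum(N$arcs$mult[i])
}

net_children <- function(N, v) sort(unique(N$arcs$head[N$arcs$tail == v]))
net_parents  <- function(N, v) sort(unique(N$arcs$tail[N$arcs$head == v]))

net_leaves <- function(N) {
  vs <- net_vertices(N)
  vs[!(vs %in% N$arcs$tail)]
}

#' @export
print.pnet <- function(x, ...) {
  vs <- net_vertices(x)
  cat(if (x$mul) "multiple-labelled network" else "phylogenetic network",
      ": ", length(vs), " vertices, ", sum(x$arcs$mult), " arcs, ",
      length(x$labels), " leaves {", paste(unname(x$labels), collapse = ","),
      "}\n", sep = "")
  invisible(x)
}

add_arc <- function(N, tail, head, mult = 1L) {
  i <- which(N$arcs$tail == tail & N$arcs$head == head)
  if (length(i)) N$arcs$mult[i] <- N$arcs$mult[i] + as.integer(mult)
  else N$arcs <- rbind(N$arcs, data.frame(tail = tail, head = head,
                                          mult = as.integer(mult),
                                          stringsAsFactors = FALSE))
  N
}

del_arc <- function(N, tail, head, mult = 1L) {
  i <- which(N$arcs$tail == tail & N$arcs$head == head)
  if (!length(i) || N$arcs$mult[i] < mult) stop("no arc (", tail, ",", head, ") to delete")
  N$arcs$mult[i] <- N$arcs$mult[i] - as.integer(mult)
  if (N$arcs$mult[i] == 0L) N$arcs <- N$arcs[-i, , drop = FALSE]
  N
}

fresh_vid <- function(N, prefix = "v") {
  vs <- net_vertices(N)
  k <- length(vs) + 1L
  repeat {
    id <- paste0(prefix, k)
    if (!(id %in% vs)) return(id)
    k <- k + 1L
  }
}

## Subdivide one copy of the arc (tail, head) by `new`.
subdivide_arc <- function(N, tail, head, new) {
  N <- del_arc(N, tail, head)
  N <- add_arc(N, tail, new)
  add_arc(N, new, head)
}

## Suppress a vertex of indegree 1 and outdegree 1 (merging its two arcs;
## the merge may create or extend a parallel pair).
suppress_vertex <- function(N, v) {
  if (net_indeg(N, v) != 1L || net_outdeg(N, v) != 1L)
    stop("cannot suppress ", v, ": not an indegree-1/outdegree-1 vertex")
  g <- N$arcs$tail[N$arcs$head == v]
  c <- N$arcs$head[N$arcs$tail == v]
  N <- del_arc(N, g, v)
  N <- del_arc(N, v, c)
  add_arc(N, g, c)
}

## Kahn's topological order with lexicographic tie-breaking.
topo_order <- function(N) {
  vs <- sort(net_vertices(N))
  indeg <- vapply(vs, function(v) net_indeg(N, v), 1L)
  out <- character(0)
  avail <- vs[indeg == 0L]
  arcs <- N$arcs
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    out <- c(out, v)
    hs <- arcs$head[arcs$tail == v]
    ms <- arcs$mult[arcs$tail == v]
    for (i in seq_along(hs)) {
      indeg[hs[i]] <- indeg[hs[i]] - ms[i]
      if (indeg[hs[i]] == 0L) avail <- sort(c(avail, hs[i]))
    }
  }
  if (length(out) != length(vs)) return(NULL)    # cycle
  out
}

#' Validate a network
#'
#' Checks the defining invariants: a unique root of indegree 0 and outdegree
#' 2, tree/reticulation degrees elsewhere, labelled leaves (injectively
#' unless multiple-labelled), acyclicity, and parallel arcs only as beads
#' (multiplicity 2, ending in a reticulation vertex). The single labelled
#' vertex is accepted as the degenerate network on one taxon.
#'
#' @param N a [pnet()].
#' @return A list with `ok` (logical) and `violations` (data frame with
#'   columns `rule` and `where`).
#' @export
validate_network <- function(N) {
  viol <- list()
  bad <- function(rule, where) viol[[length(viol) + 1L]] <<- data.frame(
    rule = rule, where = where, stringsAsFactors = FALSE)
  vs <- net_vertices(N)
  if (length(vs) == 1L && nrow(N$arcs) == 0L) {
    if (!identical(names(N$labels), vs)) bad("degenerate_unlabelled", vs)
    return(list(ok = length(viol) == 0L, violations = do.call(rbind, viol)))
  }
  indeg <- vapply(vs, function(v) net_indeg(N, v), 1L)
  outdeg <- vapply(vs, function(v) net_outdeg(N, v), 1L)
  roots <- vs[indeg == 0L]
  if (length(roots) != 1L) bad("single_root", paste(roots, collapse = ","))
  if (!(N$root %in% roots)) bad("declared_root", N$root)
  if (N$root %in% vs && indeg[N$root] == 0L && outdeg[N$root] != 2L)
    bad("root_outdegree", N$root)
  for (v in vs) {
    if (v %in% roots) next
    din <- indeg[v]; dout <- outdeg[v]
    if (dout == 0L) {
      if (din != 1L) bad("leaf_indegree", v)
      if (!(v %in% names(N$labels))) bad("leaf_unlabelled", v)
    } else if (!((din == 1L && dout == 2L) || (din == 2L && dout == 1L))) {
      bad("vertex_degree", v)
    }
  }
  lv <- vs[outdeg == 0L]
  if (length(setdiff(names(N$labels), lv))) bad("label_on_nonleaf",
    paste(setdiff(names(N$labels), lv), collapse = ","))
  if (!N$mul && anyDuplicated(unname(N$labels)))
    bad("label_not_injective", paste(unname(N$labels)[duplicated(unname(N$labels))], collapse = ","))
  if (any(N$arcs$mult > 2L))
    for (i in which(N$arcs$mult > 2L)) bad("triple_arc", paste0(N$arcs$tail[i], "->", N$arcs$head[i]))
  for (i in which(N$arcs$mult == 2L)) {
    h <- N$arcs$head[i]; t <- N$arcs$tail[i]
    if (!(indeg[h] == 2L && outdeg[h] == 1L)) bad("bead_head_not_reticulation", h)
    if (outdeg[t] != 2L) bad("bead_tail_degree", t)
  }
  if (is.null(topo_order(N))) bad("cycle", "")
  if (any(N$arcs$tail == N$arcs$head)) bad("loop", "")
  list(ok = length(viol) == 0L,
       violations = if (length(viol)) do.call(rbind, viol) else
         data.frame(rule = character(0), where = character(0)))
}

#' Count root-to-leaf paths per taxon
#'
#' Dynamic programming over a topological order; a parallel pair contributes
#' multiplicity 2. For multiple-labelled networks the count of a taxon is the
#' sum over all leaves carrying its label. This is the realization map: a
#' network realizes a ploidy profile when these counts equal the profile.
#'
#' @param N a valid [pnet()].
#' @return Named numeric vector, taxon label -> number of directed paths.
#' @examples
#' count_paths(build_B(ploidy_profile(c(5, 1, 1))))
#' @export
count_paths <- function(N) {
  vs <- net_vertices(N)
  if (length(vs) == 1L && nrow(N$arcs) == 0L)
    return(stats::setNames(1, unname(N$labels)))
  ord <- topo_order(N)
  if (is.null(ord)) stop("network contains a directed cycle")
  cnt <- stats::setNames(numeric(length(ord)), ord)
  cnt[N$root] <- 1
  for (v in ord) {
    i <- N$arcs$tail == v
    if (any(i)) {
      hs <- N$arcs$head[i]; ms <- N$arcs$mult[i]
      cnt[hs] <- cnt[hs] + cnt[v] * ms
    }
  }
  lv <- intersect(ord, names(N$labels))
  out <- tapply(cnt[lv], unname(N$labels[lv]), sum)
  stats::setNames(as.numeric(out), names(out))
}

## Does N realize profile p?
realizes <- function(N, p) {
  p <- as_profile(p)
  cp <- count_paths(N)
  want <- stats::setNames(as.numeric(p$components), p$labels)
  length(cp) == length(want) && all(sort(names(cp)) == sort(names(want))) &&
    all(cp[names(want)] == want)
}

#' Reticulation vertices and bead membership
#'
#' @param N a valid [pnet()].
#' @return Data frame with columns `vertex` and `in_bead` (`TRUE` when both
#'   incoming arcs share their tail, i.e. the vertex closes a bead).
#' @export
reticulation_inventory <- function(N) {
  vs <- net_vertices(N)
  rets <- vs[vapply(vs, function(v) net_indeg(N, v) == 2L, TRUE)]
  rets <- sort(rets)
  in_bead <- vapply(rets, function(v) {
    any(N$arcs$head == v & N$arcs$mult == 2L)
  }, TRUE)
  data.frame(vertex = rets, in_bead = unname(in_bead), stringsAsFactors = FALSE)
}

n_reticulations <- function(N) nrow(reticulation_inventory(N))

bead_reticulations <- function(N) {
  inv <- reticulation_inventory(N)
  inv$vertex[inv$in_bead]
}

## Convert to igraph (parallel pairs collapsed, multiplicity as attribute).
as_igraph_pnet <- function(N) {
  vs <- net_vertices(N)
  g <- igraph::graph_from_data_frame(N$arcs[, c("tail", "head")],
                                     directed = TRUE,
                                     vertices = data.frame(name = vs))
  igraph::E(g)$mult <- N$arcs$mult
  g
}

#' Test two networks for isomorphism
#'
#' Root-preserving, arc-multiplicity-preserving digraph isomorphism that
#' respects leaf labels (for multiple-labelled networks, the multiset of
#' labels). Backed by the VF2 algorithm on the multiplicity-collapsed graph
#' with labels encoded as vertex colours.
#'
#' @param N1,N2 valid [pnet()] objects.
#' @return Logical.
#' @export
isomorphic_networks <- function(N1, N2) {
  v1 <- net_vertices(N1); v2 <- net_vertices(N2)
  if (length(v1) != length(v2) || sum(N1$arcs$mult) != sum(N2$arcs$mult)) return(FALSE)
  if (length(v1) == 1L) return(identical(sort(unname(N1$labels)), sort(unname(N2$labels))))
  labs <- sort(unique(c(unname(N1$labels), unname(N2$labels))))
  colour <- function(N, vs) {
    cl <- integer(length(vs))
    i <- match(vs, names(N$labels))
    has <- !is.na(i)
    cl[has] <- match(unname(N$labels)[i[has]], labs)
    cl
  }
  g1 <- as_igraph_pnet(N1); g2 <- as_igraph_pnet(N2)
  igraph::is_isomorphic_to(g1, g2, method = "vf2",
                           vertex.color1 = colour(N1, igraph::V(g1)$name),
                           vertex.color2 = colour(N2, igraph::V(g2)$name),
                           edge.color1 = igraph::E(g1)$mult,
                           edge.color2 = igraph::E(g2)$mult)
}

## Rename vertex ids by adding a prefix (used when composing networks).
prefix_vertices <- function(N, prefix) {
  if (nrow(N$arcs)) {
    N$arcs$tail <- paste0(prefix, N$arcs$tail)
    N$arcs$head <- paste0(prefix, N$arcs$head)
  }
  N$root <- paste0(prefix, N$root)
  names(N$labels) <- paste0(prefix, names(N$labels))
  N
}

## Replace taxon labels according to a named map old -> new.
relabel_taxa <- function(N, map) {
  hit <- unname(N$labels) %in% names(map)
  N$labels[hit] <- unname(map[unname(N$labels)[hit]])
  N
}

## The leaf vertex carrying a taxon label (unique in non-MUL networks).
leaf_of <- function(N, taxon) {
  v <- names(N$labels)[unname(N$labels) == taxon]
  if (length(v) != 1L) stop("taxon ", taxon, " does not label a unique leaf")
  v
}
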