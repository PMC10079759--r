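## Core networks: realizations of simple ploidy profiles. Two constructions
## are provided: a naive path-based one, and the beaded network B(m) driven
## by the binary representation of the first component, whose structure
## supports (weak) HGT-consistent labellings.

#' Caterpillar tree on a set of taxa
#'
#' A phylogenetic tree with a single cherry on the last two taxa; the first
#' taxon hangs off the root, the second off the next internal vertex, and so
#' on.
#'
#' @param labels at least two taxon labels.
#' @return A [pnet()] phylogenetic tree.
#' @export
caterpillar <- function(labels) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 2L) stop("a caterpillar tree needs at least two taxa")
  leaf <- paste0("e", seq_len(n))
  if (n == 2L) {
    arcs <- data.frame(tail = c("c1", "c1"), head = leaf, stringsAsFactors = FALSE)
    return(pnet(arcs, root = "c1", labels = stats::setNames(labels, leaf)))
  }
  int <- paste0("c", seq_len(n - 1L))
  arcs <- data.frame(tail = character(0), head = character(0), stringsAsFactors = FALSE)
  for (r in seq_len(n - 2L))
    arcs <- rbind(arcs, data.frame(tail = int[r], head = c(leaf[r], int[r + 1L])))
  arcs <- rbind(arcs, data.frame(tail = int[n - 1L], head = c(leaf[n - 1L], leaf[n])))
  pnet(arcs, root = "c1", labels = stats::setNames(labels, leaf))
}

#' Chain of beads realizing a power of two
#'
#' `i1` beads in a chain with a pendant leaf below the last reticulation;
#' every bead doubles the path count, so the leaf receives `2^i1` paths.
#'
#' @param i1 number of beads (at least 1).
#' @param taxon taxon label for the pendant leaf.
#' @return A [pnet()].
#' @export
build_beaded_chain <- function(i1, taxon = "x1") {
  if (i1 < 1L) stop("i1 must be at least 1")
  b <- paste0("b", seq_len(i1)); h <- paste0("h", seq_len(i1))
  arcs <- data.frame(tail = b, head = h, mult = 2L, stringsAsFactors = FALSE)
  if (i1 >= 2L)
    arcs <- rbind(arcs, data.frame(tail = h[-i1], head = b[-1L], mult = 1L))
  arcs <- rbind(arcs, data.frame(tail = h[i1], head = "xlf", mult = 1L))
  pnet(arcs, root = b[1L], labels = stats::setNames(taxon, "xlf"))
}

#' Naive path-based core network for a simple profile
#'
#' A directed path of `n + 2(m1 - 1)` vertices with one pendant leaf per
#' unit-ploidy taxon and `m1 - 1` chords, each chord raising the path count
#' at the top taxon by one.
#'
#' @param p a simple [ploidy_profile()].
#' @return A [pnet()] realizing `p`.
#' @export
naive_core <- function(p) {
  p <- as_profile(p)
  if (!is_simple_profile(p)) stop("naive_core needs a simple ploidy profile")
  m1 <- p$components[1]; n <- length(p$components)
  v <- paste0("v", seq_len(m1 - 1L))
  w <- if (n >= 2L) paste0("w", 2:n) else character(0)
  vp <- paste0("vp", seq_len(m1 - 1L))
  path <- c(v, w, rev(vp), "xlf1")
  arcs <- data.frame(tail = path[-length(path)], head = path[-1L],
                     stringsAsFactors = FALSE)
  leaves <- "xlf1"
  if (n >= 2L) {
    xl <- paste0("xlf", 2:n)
    arcs <- rbind(arcs, data.frame(tail = w, head = xl))
    leaves <- c(leaves, xl)
  }
  arcs <- rbind(arcs, data.frame(tail = v, head = vp))
  pnet(arcs, root = path[1L], labels = stats::setNames(p$labels, leaves))
}

#' The beaded core network B(m)
#'
#' For a simple profile with first component `m1` and binary representation
#' `(i1, ..., ik)`: a chain of `i1` beads realizes `2^i1`; for `k >= 2` one
#' copy of the root arc is subdivided by `s_k`, the outgoing arc of the bead
#' reticulation with exactly `i_j` bead reticulations strictly below it is
#' subdivided by `s_j'`, and arcs `(s_j, s_j')` add the lower powers of two.
#' For a simple but not strictly simple profile, a vertex `w` (on a root arc
#' if `k = 1`, on the arc entering `s_k'` otherwise) carries a caterpillar
#' tree on the remaining unit-ploidy taxa.
#'
#' @param p a simple [ploidy_profile()].
#' @return A [pnet()] realizing `p`, carrying construction metadata used by
#'   [label_core()].
#' @examples
#' count_paths(build_B(ploidy_profile(c(77, 1, 1, 1))))
#' @export
build_B <- function(p) {
  p <- as_profile(p)
  if (!is_simple_profile(p)) stop("build_B needs a simple ploidy profile")
  m1 <- p$components[1]; n <- length(p$components)
  iv <- binary_representation(m1)
  k <- length(iv); i1 <- iv[1]
  b <- paste0("b", seq_len(i1)); h <- paste0("h", seq_len(i1))
  N <- build_beaded_chain(i1, taxon = p$labels[1])
  sk <- NULL; skp <- NULL; sjp <- character(0); sj <- character(0)
  if (k >= 2L) {
    sk <- paste0("s", k)
    N <- subdivide_arc(N, b[1L], h[1L], sk)          # breaks bead B1
    host_child <- function(N, hq) N$arcs$head[N$arcs$tail == hq]
    q <- i1 - iv[k]
    skp <- paste0("s", k, "p")
    N <- subdivide_arc(N, h[q], host_child(N, h[q]), skp)
    N <- add_arc(N, sk, skp)                         # arc a_k
    if (k >= 3L) {
      sj <- paste0("s", 2:(k - 1L))
      prev <- sk
      for (j in 2:(k - 1L)) {
        sjv <- paste0("s", j)
        N <- subdivide_arc(N, prev, skp, sjv)
        prev <- sjv
      }
      for (j in 2:(k - 1L)) {
        q <- i1 - iv[j]
        sp <- paste0("s", j, "p")
        N <- subdivide_arc(N, h[q], host_child(N, h[q]), sp)
        N <- add_arc(N, paste0("s", j), sp)          # arc a_j
        sjp[as.character(j)] <- sp
      }
    }
    sjp[as.character(k)] <- skp
  }
  w <- NULL; cat_net <- NULL
  if (n >= 2L) {
    w <- "w"
    if (k == 1L) {
      N <- subdivide_arc(N, b[1L], h[1L], w)         # breaks bead B1
    } else if (k == 2L) {
      N <- subdivide_arc(N, sk, skp, w)              # w on a_2
    } else {
      N <- subdivide_arc(N, paste0("s", k - 1L), skp, w)
    }
    if (n == 2L) {
      N <- add_arc(N, w, "e2")
      N$labels["e2"] <- p$labels[2]
    } else {
      cat_net <- prefix_vertices(caterpillar(p$labels[2:n]), "cat_")
      N$arcs <- rbind(N$arcs, cat_net$arcs)
      N$labels <- c(N$labels, cat_net$labels)
      N <- add_arc(N, w, cat_net$root)
    }
  }
  ## spine: the root-to-x1 path avoiding the s-chain, w and the caterpillar
  spine <- character(0)
  cur <- b[1L]
  avoid <- c(sk, sj, w, if (!is.null(cat_net)) net_vertices(cat_net), "e2")
  repeat {
    spine <- c(spine, cur)
    kids <- setdiff(net_children(N, cur), avoid)
    if (!length(kids)) break
    cur <- kids[1L]
  }
  attr(N, "binfo") <- list(profile = p, i = iv, k = k, i1 = i1, n = n,
                           b = b, h = h, sk = sk, skp = skp, sj = sj,
                           sjp = sjp, w = w, spine = spine,
                           cat_internal = if (!is.null(cat_net))
                             grep("^cat_c", net_vertices(cat_net), value = TRUE),
                           leaf1 = "xlf",
                           cat_leaves = if (n >= 3L) names(cat_net$labels)
                                        else if (n == 2L) "e2")
  N
}
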