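## Building N(m): traceback through the simplification sequence from a core
## network, plus bead prepending and the scaled composition that multiplies
## a realization by a power of two.

## Replace the leaf carrying `taxon` by a cherry on (new_taxon, taxon);
## the old leaf vertex becomes the cherry's parent.
replace_leaf_by_cherry <- function(N, taxon, new_taxon) {
  v <- leaf_of(N, taxon)
  a <- fresh_vid(N, "cl"); b <- fresh_vid(N, paste0("cl", "b"))
  N$labels <- N$labels[names(N$labels) != v]
  N <- add_arc(N, v, a)
  N <- add_arc(N, v, b)
  N$labels[a] <- new_taxon
  N$labels[b] <- taxon
  N
}

incoming_arc <- function(N, v) {
  i <- which(N$arcs$head == v)
  if (length(i) != 1L || N$arcs$mult[i] != 1L)
    stop("vertex ", v, " does not have a unique incoming arc")
  N$arcs$tail[i]
}

#' One traceback step
#'
#' Given a network realizing the successor profile of a simplification step,
#' rebuilds a realization of the predecessor profile: a removed duplicate
#' component grows back as a cherry; a subtracted difference grows back as a
#' reticulate cherry; a removed-and-reinserted component grows back as a
#' reticulate cherry fed from the inserted leaf's position, after which the
#' inserted leaf is deleted.
#'
#' @param N a [pnet()] realizing the successor profile.
#' @param step a step record from [simplify_step()].
#' @return A [pnet()] realizing the predecessor profile.
#' @export
traceback_step <- function(N, step) {
  if (step$case == "REMOVE_EQUAL") {
    N <- replace_leaf_by_cherry(N, step$succ1, step$deleted_label)
  } else if (step$case == "SUBTRACT") {
    l1 <- leaf_of(N, step$succ1); l2 <- leaf_of(N, step$succ2)
    u <- fresh_vid(N, "u"); v <- fresh_vid(N, "vv")
    N <- subdivide_arc(N, incoming_arc(N, l1), l1, u)
    N <- subdivide_arc(N, incoming_arc(N, l2), l2, v)
    N <- add_arc(N, v, u)
  } else if (step$case == "REMOVE_INSERT") {
    lj <- leaf_of(N, step$fresh_label)
    v <- fresh_vid(N, "vv")
    N <- subdivide_arc(N, incoming_arc(N, lj), lj, v)
    N <- replace_leaf_by_cherry(N, step$succ1, step$deleted_label)
    l1 <- leaf_of(N, step$deleted_label)
    u <- fresh_vid(N, "u")
    N <- subdivide_arc(N, incoming_arc(N, l1), l1, u)
    N <- add_arc(N, v, u)
    ## the paper deletes the inserted leaf "and its incoming arc"; after v
    ## subdivides that arc the parent is v, which is then suppressed
    N <- del_arc(N, v, lj)
    N$labels <- N$labels[names(N$labels) != lj]
    N <- suppress_vertex(N, v)
  } else stop("unknown simplification case: ", step$case)
  N
}

#' Realize a ploidy profile as a phylogenetic network
#'
#' Computes the simplification sequence of `p`, builds (or accepts) a core
#' network realizing its terminal element, and applies the traceback steps
#' to obtain a realization `N(m)` of `p`. The default core is [build_B()]
#' (the single labelled vertex for the degenerate terminal `(1)`).
#'
#' @param p a [ploidy_profile()] (or integer vector).
#' @param core optional core network realizing the terminal element.
#' @return A [pnet()] realizing `p`. Attribute `minimal_by_construction` is
#'   `TRUE` when the default beaded core was used and no subtraction step
#'   occurred, the situation in which the construction is known to use the
#'   minimum number of reticulation vertices.
#' @examples
#' N <- realize_profile(c(7, 6, 6, 5))
#' count_paths(N)
#' @export
realize_profile <- function(p, core = NULL) {
  p <- as_profile(p)
  s <- simplification_sequence(p)
  term <- s$terminal
  default_core <- is.null(core)
  if (default_core) {
    core <- if (length(term$components) == 1L && term$components[1] == 1L)
      single_vertex_net(term$labels[1]) else build_B(term)
  } else {
    ## the terminal's labels are internal renamings, so a user core matches
    ## by path-count multiset; its leaves are then relabelled accordingly
    cp <- count_paths(core)
    if (!identical(sort(unname(cp), decreasing = TRUE),
                   as.numeric(term$components)))
      stop("supplied core network does not realize the terminal element (",
           paste(term$components, collapse = ","), ")")
    ord <- order(-unname(cp))
    map <- stats::setNames(term$labels, names(cp)[ord])
    core <- relabel_taxa(core, map)
  }
  N <- core
  for (i in rev(seq_along(s$steps))) N <- traceback_step(N, s$steps[[i]])
  if (!realizes(N, p)) stop("internal error: traceback failed to realize the profile")
  attr(N, "binfo") <- NULL
  attr(N, "core") <- core
  attr(N, "sequence") <- s
  attr(N, "minimal_by_construction") <- default_core &&
    !any(vapply(s$steps, function(st) st$case == "SUBTRACT", TRUE))
  N
}

#' Prepend a bead above the root
#'
#' Models an autopolyploidization of the last common ancestor: a new root
#' with a bead feeding the old root. Every path count doubles.
#'
#' @param N a valid [pnet()].
#' @return A [pnet()].
#' @export
prepend_bead <- function(N) {
  nr <- fresh_vid(N, "rb"); nh <- fresh_vid(N, "rh")
  old <- N$root
  N <- add_arc(N, nr, nh, mult = 2L)
  N <- add_arc(N, nh, old)
  N$root <- nr
  N
}

#' Scaled composition of a realization
#'
#' Given `N` realizing `(m1, ..., mn)` and `i >= 1`, builds a realization of
#' `(2^i m1, ..., 2^i mn, 2^(i-1), ..., 2^0)`: a realization of the profile
#' of falling powers `(2^(i-1), ..., 1)` on fresh taxa is built, the
#' incoming arc of its largest-ploidy leaf is subdivided by `s` and `s'`,
#' and a new reticulation `s''` fed by both is placed above the root of `N`.
#'
#' @param N a valid [pnet()] realizing some profile.
#' @param i positive integer scaling exponent.
#' @param new_labels optional `i` fresh taxon labels for the appended
#'   powers-of-two taxa (defaults to `x<n+1>, ...`).
#' @return A [pnet()].
#' @examples
#' count_paths(compose_scaled(realize_profile(c(5, 3, 1)), 3))
#' @export
compose_scaled <- function(N, i, new_labels = NULL) {
  if (i < 1L) stop("i must be at least 1")
  old_taxa <- unname(N$labels)
  n <- length(old_taxa)
  if (is.null(new_labels)) {
    new_labels <- character(i)
    for (j in seq_len(i)) {
      cand <- paste0("x", n + j)
      while (cand %in% c(old_taxa, new_labels)) cand <- paste0("_", cand)
      new_labels[j] <- cand
    }
  }
  if (length(new_labels) != i) stop("need exactly i new labels")
  N <- prefix_vertices(N, "L_")
  if (i == 1L) {
    ## degenerate small profile (1): build the joint head directly
    x <- "R_e1"
    arcs <- data.frame(tail = c("R_s", "R_s", "R_sp", "R_sp"),
                       head = c("R_sp", "R_spp", x, "R_spp"),
                       stringsAsFactors = FALSE)
    out <- pnet(rbind(arcs, data.frame(tail = "R_spp", head = N$root)),
                root = "R_s",
                labels = c(stats::setNames(new_labels, x), N$labels))
    out$arcs <- rbind(out$arcs, N$arcs)
    out <- pnet(out$arcs, out$root, out$labels)
    return(out)
  }
  pw <- ploidy_profile(2^((i - 1L):0L), new_labels)
  N2 <- prefix_vertices(realize_profile(pw), "R_")
  top <- leaf_of(N2, new_labels[1])
  s <- "R_s"; sp <- "R_sp"; spp <- "R_spp"
  N2 <- subdivide_arc(N2, incoming_arc(N2, top), top, s)
  N2 <- subdivide_arc(N2, s, top, sp)
  N2 <- add_arc(N2, s, spp)
  N2 <- add_arc(N2, sp, spp)
  N2 <- add_arc(N2, spp, N$root)
  N2$arcs <- rbind(N2$arcs, N$arcs)
  N2$labels <- c(N2$labels, N$labels)
  pnet(N2$arcs, N2$root, N2$labels)
}
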