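## Time-stamp maps: verification of (weak) HGT-consistent labellings and
## their construction for B(m) and from cherry modification sequences.
## Stamps are dyadic rationals held in doubles (only midpoint insertions are
## ever performed), so equality tests are exact.

## is w below v (reachable from v, or equal)?
below_of <- function(N, v, w) {
  if (v == w) return(TRUE)
  seen <- v
  frontier <- v
  while (length(frontier)) {
    nxt <- unique(N$arcs$head[N$arcs$tail %in% frontier])
    nxt <- setdiff(nxt, seen)
    if (w %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

#' Verify a time-stamp map against the HGT-consistency properties
#'
#' (P1) time moves forward: along every arc the stamp does not decrease, and
#' increases strictly unless the head is a reticulation. (P2) every
#' non-leaf vertex has a child with a strictly later stamp. (P3) every
#' reticulation vertex *not in a bead* has exactly one parent with an equal
#' stamp (a horizontal arc). The weak variant (P3') exempts at most one
#' reticulation, which must have distinct, comparable parents.
#'
#' @param N a valid [pnet()].
#' @param stamps named numeric vector, vertex -> non-negative time.
#' @return A list: `p1_ok`, `p2_ok`, `p3_violations` (vertex names),
#'   `classification` one of `"HGT_CONSISTENT"`, `"WEAK_HGT_CONSISTENT"`,
#'   `"NEITHER"`.
#' @export
verify_labelling <- function(N, stamps) {
  vs <- net_vertices(N)
  if (!all(vs %in% names(stamps)))
    stop("missing stamp for vertex ", paste(setdiff(vs, names(stamps)), collapse = ","))
  if (any(stamps[vs] < 0)) stop("stamps must be non-negative")
  rets <- vs[vapply(vs, function(v) net_indeg(N, v) == 2L, TRUE)]
  beads <- bead_reticulations(N)
  p1 <- TRUE
  if (nrow(N$arcs)) for (r in seq_len(nrow(N$arcs))) {
    u <- N$arcs$tail[r]; v <- N$arcs$head[r]
    ok <- if (v %in% rets) stamps[u] <= stamps[v] else stamps[u] < stamps[v]
    if (!ok) { p1 <- FALSE; break }
  }
  p2 <- TRUE
  for (u in vs) {
    kids <- net_children(N, u)
    if (!length(kids)) next
    if (!any(stamps[kids] > stamps[u])) { p2 <- FALSE; break }
  }
  viol <- character(0)
  for (v in setdiff(rets, beads)) {
    par <- N$arcs$tail[N$arcs$head == v]
    if (sum(stamps[par] == stamps[v]) != 1L) viol <- c(viol, v)
  }
  cls <- "NEITHER"
  if (p1 && p2) {
    if (!length(viol)) cls <- "HGT_CONSISTENT"
    else if (length(viol) == 1L) {
      par <- N$arcs$tail[N$arcs$head == viol]
      eligible <- length(unique(par)) == 2L &&
        all(stamps[par] != stamps[viol]) &&
        (below_of(N, par[1], par[2]) || below_of(N, par[2], par[1]))
      if (eligible) cls <- "WEAK_HGT_CONSISTENT"
    }
  }
  list(p1_ok = p1, p2_ok = p2, p3_violations = viol, classification = cls)
}

#' Constructive labelling for a beaded core network
#'
#' Implements the spine labelling from the existence proof: unit time steps
#' along the root-to-x1 spine, with `t(s_k) = t(h_1)`, `t(s_j) = t(s_j')`,
#' `t(w) = t(s_k')` (or `t(w) = t(h_1)` when the binary representation has a
#' single exponent and `w` sits on a root arc), caterpillar vertices ticking
#' on from `w`, and all caterpillar leaves at a common late time. The result
#' is HGT-consistent exactly when the profile is practical, and weakly
#' HGT-consistent when it is arc-rich.
#'
#' @param B a network built by [build_B()].
#' @param p the simple profile `B` was built for (consistency check).
#' @return Named numeric stamp vector over the vertices of `B`.
#' @export
label_core <- function(B, p = NULL) {
  info <- attr(B, "binfo")
  if (is.null(info)) stop("label_core needs a network produced by build_B")
  if (!is.null(p)) {
    p <- as_profile(p)
    if (!identical(info$profile$components, p$components))
      stop("network was not built for this profile")
  }
  t <- stats::setNames(as.numeric(seq_along(info$spine) - 1L), info$spine)
  if (info$k >= 2L) {
    t[info$sk] <- t[info$h[1L]]
    for (j in names(info$sjp)) if (j != as.character(info$k))
      t[paste0("s", j)] <- t[info$sjp[[j]]]
  }
  if (!is.null(info$w)) {
    t[info$w] <- if (info$k == 1L) t[info$h[1L]] else t[info$skp]
  }
  if (info$n >= 2L) {
    if (info$n == 2L) {
      t["e2"] <- t[info$w] + 1
    } else {
      ints <- info$cat_internal
      ints <- ints[order(as.integer(sub("^cat_c", "", ints)))]
      for (r in seq_along(ints)) t[ints[r]] <- t[info$w] + r
      chi <- t[ints[length(ints)]] + 1
      for (lv in info$cat_leaves) t[lv] <- chi
    }
  }
  t
}

#' Horizontal arcs under a time-stamp map
#'
#' Arcs whose endpoints carry equal stamps; under an HGT-consistent
#' labelling every reticulation vertex outside a bead has exactly one
#' incoming horizontal arc, the signature of two ancestral species that
#' co-existed in time.
#'
#' @param N a valid [pnet()].
#' @param stamps a stamp map passing [verify_labelling()] (weakly at least).
#' @return Data frame with columns `tail`, `head`.
#' @export
horizontal_arcs <- function(N, stamps) {
  rep <- verify_labelling(N, stamps)
  if (rep$classification == "NEITHER")
    stop("stamps do not form a (weak) HGT-consistent labelling")
  if (!nrow(N$arcs)) return(data.frame(tail = character(0), head = character(0)))
  eq <- stamps[N$arcs$tail] == stamps[N$arcs$head]
  N$arcs[eq, c("tail", "head"), drop = FALSE]
}

#' Labelling replayed from a cherry modification sequence
#'
#' Replays a complete (weak) cherry modification sequence backwards,
#' rebuilding the network from the single vertex while assigning stamps:
#' cherries appear strictly later than their parent, reticulate cherries
#' re-add their reticulation arc with equal stamps at both ends (a
#' horizontal arc), bead restorations insert strictly increasing stamps, and
#' trim restorations insert a reticulation with no contemporaneous parent
#' (the exempt vertex of a weak labelling). For sequences with at most one
#' trim the result verifies at the corresponding strength.
#'
#' @param N a valid [pnet()].
#' @param ops a list of cherry operations (see [find_applicable()]) forming
#'   a complete sequence for `N`.
#' @return Named numeric stamp vector over the vertices of `N`.
#' @export
label_from_cherry_sequence <- function(N, ops) {
  vs <- net_vertices(N)
  if (length(vs) == 1L && !length(ops))
    return(stats::setNames(0, vs))
  cur <- N
  logs <- vector("list", length(ops))
  for (i in seq_along(ops)) {
    cur <- apply_operation(cur, ops[[i]])
    logs[[i]] <- attr(cur, "oplog")
  }
  if (length(net_vertices(cur)) != 1L)
    stop("sequence does not reduce the network to a single vertex")
  t <- stats::setNames(0, net_vertices(cur))
  mid <- function(a, b) (a + b) / 2
  for (i in rev(seq_along(logs))) {
    lg <- logs[[i]]
    if (lg$type == "reduce") {
      if (isTRUE(lg$collapsed)) {
        t[lg$p] <- t[lg$a] - 1
        t[lg$b] <- t[lg$a]
      } else {
        t[lg$p] <- mid(t[lg$g], t[lg$a])
        t[lg$b] <- t[lg$a]
      }
    } else if (lg$type == "cut") {
      lo <- max(t[lg$ga], t[lg$gb])
      hi <- min(t[lg$a], t[lg$b])
      if (!(lo < hi)) stop("cannot order stamps while reversing cut at step ", i)
      v <- mid(lo, hi)
      t[lg$pa] <- v; t[lg$pb] <- v
    } else if (lg$type == "simp") {
      if (isTRUE(lg$collapsed)) {
        t[lg$q] <- t[lg$a] - 2
        t[lg$h] <- t[lg$a] - 1
      } else {
        lo <- t[lg$g]; hi <- t[lg$a]
        t[lg$q] <- lo + (hi - lo) / 4
        t[lg$h] <- mid(lo, hi)
      }
    } else if (lg$type == "trim") {
      if (lg$case == "ii-b") {
        lo <- t[lg$q1]; hi <- t[lg$p]
        t[lg$q]  <- lo + (hi - lo) / 4
        t[lg$q2] <- mid(lo, hi)
      } else {
        ## cases i and ii-a: re-insert q1 on (g1, c1) and p on (qb, a);
        ## in case ii-a, c1 is the reticulation q2 fed by q1, whose (P3)
        ## property is restored by making the arc (q1, q2) horizontal
        t[lg$q1] <- if (lg$case == "ii-a") t[lg$c1]
                    else mid(t[lg$g1], t[lg$c1])
        lo <- max(t[lg$qb], t[lg$q1])
        if (!(lo < t[lg$a])) stop("cannot order stamps while reversing trim at step ", i)
        v <- mid(lo, t[lg$a])
        if (v == t[lg$q1] || v == t[lg$qb]) v <- mid(v, t[lg$a])
        t[lg$p] <- v
      }
    } else stop("unknown op log type")
  }
  t <- t[vs]
  t - min(t)
}
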