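## Cherry modification operations: reducing a cherry, cutting a reticulated
## cherry, simplifying a leaf under a bead, trimming a leaf under a
## reticulation with the prescribed local structure. Complete sequences of
## these certify that a network (and hence the ploidy profile it realizes)
## is an orchard (no trim used) or a weak orchard.

#' Construct a cherry modification operation
#'
#' @param kind one of `"REDUCE"`, `"CUT"` (ordered leaf pair, the second
#'   operand is deleted / is the reticulation leaf), `"SIMP"`, `"TRIM"`
#'   (single leaf).
#' @param a,b taxon labels (`b` only for `REDUCE`/`CUT`).
#' @param case for `TRIM`, the structural case tag (`"i"`, `"ii-a"`,
#'   `"ii-b"`); resolved automatically when applied.
#' @return A `cherry_op` object.
#' @export
cherry_op <- function(kind, a, b = NA_character_, case = NA_character_) {
  structure(list(kind = kind, a = a, b = b, case = case), class = "cherry_op")
}

#' @export
format.cherry_op <- function(x, ...) {
  body <- if (is.na(x$b)) x$a else paste0(x$a, ",", x$b)
  tag <- if (!is.na(x$case)) paste0("[", x$case, "]") else ""
  paste0(tolower(x$kind), "(", body, ")", tag)
}

#' @export
print.cherry_op <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

## Detect the trim structure above the reticulation parent p of a leaf.
detect_trim <- function(N, p) {
  par <- N$arcs$tail[N$arcs$head == p]
  par <- rep(par, N$arcs$mult[N$arcs$head == p])
  if (length(unique(par)) != 2L) return(NULL)
  beads <- bead_reticulations(N)
  inb <- par %in% beads
  if (sum(inb) == 1L)
    return(list(case = "i", q1 = par[!inb], qb = par[inb]))
  for (ord in list(par, rev(par))) {
    q1 <- ord[1]; q2 <- ord[2]
    if (any(N$arcs$tail == q1 & N$arcs$head == q2)) {
      q <- intersect(net_parents(N, q1), net_parents(N, q2))
      if (length(q)) return(list(case = "ii-a", q1 = q1, q2 = q2, q = q[1]))
    }
    cand <- N$arcs$head[N$arcs$tail == q1]
    for (q in cand) {
      if (any(N$arcs$tail == q & N$arcs$head == q2 & N$arcs$mult == 2L))
        return(list(case = "ii-b", q1 = q1, q2 = q2, q = q))
    }
  }
  NULL
}

#' Find all applicable cherry modification operations
#'
#' Cherries give `REDUCE` (both orientations), reticulated cherries give
#' `CUT` (second operand the reticulation leaf), a leaf under a bead
#' reticulation gives `SIMP`, and a leaf under a reticulation with one bead
#' parent or the two diamond-like parent configurations gives `TRIM` with
#' its structural case tag. Operations are returned in a deterministic
#' order: by kind (`CUT`, `REDUCE`, `SIMP`, `TRIM`), then by operand labels.
#'
#' @param N a valid [pnet()].
#' @return List of `cherry_op` objects.
#' @export
find_applicable <- function(N) {
  lv <- names(N$labels)
  lv <- lv[vapply(lv, function(v) net_outdeg(N, v) == 0L, TRUE)]
  beads <- bead_reticulations(N)
  ops <- list()
  addop <- function(...) ops[[length(ops) + 1L]] <<- cherry_op(...)
  for (la in lv) for (lb in lv) {
    if (la == lb) next
    pa <- net_parents(N, la); pb <- net_parents(N, lb)
    if (length(pa) != 1L || length(pb) != 1L) next
    A <- unname(N$labels[la]); B <- unname(N$labels[lb])
    if (pa == pb) addop("REDUCE", A, B)
    else if (net_indeg(N, pb) == 2L && !(pb %in% beads) &&
             any(N$arcs$tail == pa & N$arcs$head == pb))
      addop("CUT", A, B)
  }
  for (la in lv) {
    p <- net_parents(N, la)
    if (length(p) != 1L || net_indeg(N, p) != 2L) next
    A <- unname(N$labels[la])
    if (p %in% beads) addop("SIMP", A)
    else {
      d <- detect_trim(N, p)
      if (!is.null(d)) addop("TRIM", A, case = d$case)
    }
  }
  ord <- order(match(vapply(ops, `[[`, "", "kind"), c("CUT", "REDUCE", "SIMP", "TRIM")),
               vapply(ops, `[[`, "", "a"),
               vapply(ops, function(o) if (is.na(o$b)) "" else o$b, ""))
  ops[ord]
}

#' Apply a cherry modification operation
#'
#' The inverse of one growth step: `REDUCE` deletes the second leaf of a
#' cherry, `CUT` deletes the reticulation arc of a reticulated cherry,
#' `SIMP` deletes one arc of the bead above a leaf, `TRIM` deletes the
#' prescribed arc above a leaf's reticulation parent; degree-(1,1) vertices
#' are suppressed and a root left with a single outgoing arc is collapsed.
#' The reversal information needed by [label_from_cherry_sequence()] is
#' attached as attribute `oplog`.
#'
#' @param N a valid [pnet()].
#' @param op a `cherry_op` (from [find_applicable()]).
#' @return The modified [pnet()] (possibly the single-vertex network).
#' @export
apply_operation <- function(N, op) {
  beads <- bead_reticulations(N)
  if (op$kind == "REDUCE") {
    la <- leaf_of(N, op$a); lb <- leaf_of(N, op$b)
    p <- net_parents(N, lb)
    if (length(p) != 1L || !identical(net_parents(N, la), p))
      stop("reduce(", op$a, ",", op$b, ") not applicable: not a cherry")
    N <- del_arc(N, p, lb)
    N$labels <- N$labels[names(N$labels) != lb]
    if (p == N$root) {
      if (net_outdeg(N, p) != 1L) stop("root degree unexpected after reduce")
      N <- del_arc(N, p, la)
      N$root <- la
      lg <- list(type = "reduce", a = la, b = lb, p = p, collapsed = TRUE)
    } else {
      g <- net_parents(N, p)
      N <- suppress_vertex(N, p)
      lg <- list(type = "reduce", a = la, b = lb, p = p, g = g, collapsed = FALSE)
    }
  } else if (op$kind == "CUT") {
    la <- leaf_of(N, op$a); lb <- leaf_of(N, op$b)
    pa <- net_parents(N, la); pb <- net_parents(N, lb)
    ok <- length(pa) == 1L && length(pb) == 1L && pa != pb &&
      net_indeg(N, pb) == 2L && !(pb %in% beads) &&
      any(N$arcs$tail == pa & N$arcs$head == pb)
    if (!ok) stop("cut(", op$a, ",", op$b, ") not applicable: not a reticulated cherry")
    N <- del_arc(N, pa, pb)
    ga <- net_parents(N, pa)
    if (!length(ga)) stop("cut would leave an out-degree-one root")
    N <- suppress_vertex(N, pa)
    gb <- net_parents(N, pb)
    N <- suppress_vertex(N, pb)
    lg <- list(type = "cut", a = la, b = lb, pa = pa, ga = ga, pb = pb, gb = gb)
  } else if (op$kind == "SIMP") {
    la <- leaf_of(N, op$a)
    h <- net_parents(N, la)
    if (length(h) != 1L || !(h %in% beads))
      stop("simp(", op$a, ") not applicable: parent is not a bead reticulation")
    q <- net_parents(N, h)
    N <- del_arc(N, q, h)
    N <- suppress_vertex(N, h)
    if (q == N$root) {
      if (net_outdeg(N, q) != 1L || length(net_vertices(N)) != 2L)
        stop("simp root collapse in unexpected configuration")
      N <- del_arc(N, q, la)
      N$root <- la
      lg <- list(type = "simp", a = la, q = q, h = h, collapsed = TRUE)
    } else {
      g <- net_parents(N, q)
      N <- suppress_vertex(N, q)
      lg <- list(type = "simp", a = la, q = q, h = h, g = g, collapsed = FALSE)
    }
  } else if (op$kind == "TRIM") {
    la <- leaf_of(N, op$a)
    p <- net_parents(N, la)
    if (length(p) != 1L || net_indeg(N, p) != 2L || p %in% beads)
      stop("trim(", op$a, ") not applicable")
    d <- detect_trim(N, p)
    if (is.null(d)) stop("trim(", op$a, ") not applicable: no qualifying structure")
    if (d$case == "ii-b") {
      N <- del_arc(N, d$q, d$q2)
      N <- suppress_vertex(N, d$q)
      N <- suppress_vertex(N, d$q2)
      lg <- list(type = "trim", case = "ii-b", a = la, p = p,
                 q1 = d$q1, q = d$q, q2 = d$q2)
    } else {
      q1 <- d$q1
      qb <- if (d$case == "i") d$qb else d$q2
      N <- del_arc(N, q1, p)
      g1 <- net_parents(N, q1)
      c1 <- net_children(N, q1)
      if (!length(g1)) stop("trim would leave an out-degree-one root")
      N <- suppress_vertex(N, q1)
      N <- suppress_vertex(N, p)
      lg <- list(type = "trim", case = d$case, a = la, p = p,
                 q1 = q1, g1 = g1, c1 = c1, qb = qb)
    }
  } else stop("unknown cherry operation kind: ", op$kind)
  rep <- validate_network(N)
  if (!rep$ok) stop("cherry operation left an invalid network (",
                    paste(rep$violations$rule, collapse = ","), ")")
  attr(N, "oplog") <- lg
  N
}

is_single_vertex <- function(N) length(net_vertices(N)) == 1L && nrow(N$arcs) == 0L

## Backtracking search with an isomorphism-checked memo of failed states.
search_sequence <- function(N, allow_trim, memo) {
  if (is_single_vertex(N)) return(list())
  ops <- find_applicable(N)
  if (!allow_trim) ops <- Filter(function(o) o$kind != "TRIM", ops)
  for (op in ops) {
    N2 <- try(apply_operation(N, op), silent = TRUE)
    if (inherits(N2, "try-error")) next
    key <- paste(length(net_vertices(N2)), sum(N2$arcs$mult),
                 paste(sort(unname(N2$labels)), collapse = "|"))
    bucket <- memo$failed[[key]]
    if (!is.null(bucket) &&
        any(vapply(bucket, isomorphic_networks, TRUE, N2))) next
    res <- search_sequence(N2, allow_trim, memo)
    if (!is.null(res)) return(c(list(op), res))
    if (length(memo$failed) < 4000L)
      memo$failed[[key]] <- c(memo$failed[[key]], list(N2))
  }
  NULL
}

#' Decide orchard / weak-orchard status by backtracking search
#'
#' Searches for a complete cherry modification sequence reducing the network
#' to a single vertex. A sequence without `TRIM` certifies an orchard; if
#' none exists and `allow_trim` is `TRUE`, a sequence using `TRIM` certifies
#' a weak orchard.
#'
#' @param N a valid [pnet()].
#' @param allow_trim logical; permit the trimming operation.
#' @return A list with `status` (`"ORCHARD"`, `"WEAK_ORCHARD"` or
#'   `"NEITHER"`) and `sequence` (list of `cherry_op`, empty for
#'   `"NEITHER"`).
#' @export
orchard_status <- function(N, allow_trim = TRUE) {
  memo <- new.env(parent = emptyenv()); memo$failed <- list()
  seq1 <- search_sequence(N, allow_trim = FALSE, memo)
  if (!is.null(seq1)) return(list(status = "ORCHARD", sequence = seq1))
  if (allow_trim) {
    memo2 <- new.env(parent = emptyenv()); memo2$failed <- list()
    seq2 <- search_sequence(N, allow_trim = TRUE, memo2)
    if (!is.null(seq2)) return(list(status = "WEAK_ORCHARD", sequence = seq2))
  }
  list(status = "NEITHER", sequence = list())
}

## Deterministic greedy reduction used for core networks built by build_B:
## cut when possible, else reduce, else simp, else trim. For B(m) exactly
## one kind is applicable at every stage, so no search is needed.
greedy_core_sequence <- function(N) {
  ops <- list()
  guard <- 4L * length(net_vertices(N)) + 8L
  while (!is_single_vertex(N)) {
    avail <- find_applicable(N)
    if (!length(avail)) stop("greedy reduction stuck: no applicable operation")
    op <- avail[[1L]]
    N <- apply_operation(N, op)
    ops[[length(ops) + 1L]] <- op
    guard <- guard - 1L
    if (guard < 0L) stop("greedy reduction did not terminate")
  }
  ops
}

#' Cherry modification sequence derived from the simplification sequence
#'
#' No search: each simplification step maps to one cherry operation on the
#' realization (`REMOVE_EQUAL` to `REDUCE`, the two other cases to `CUT`),
#' and the remaining core network is reduced by a deterministic greedy pass.
#' The certificate contains no `TRIM` exactly when the terminal element is
#' practical (orchard); an arc-rich terminal forces trims (weak orchard).
#'
#' @param p a [ploidy_profile()] (or integer vector).
#' @return A list with `status`, `sequence`, and the realization `network`
#'   the certificate applies to (built by [realize_profile()] from the
#'   beaded core).
#' @examples
#' traceback_cherry_sequence(c(7, 6, 6, 5))$status
#' @export
traceback_cherry_sequence <- function(p) {
  p <- as_profile(p)
  N0 <- realize_profile(p)
  s <- attr(N0, "sequence")
  N <- N0
  cur <- p$labels
  ops <- list()
  push <- function(op) { ops[[length(ops) + 1L]] <<- op; N <<- apply_operation(N, op) }
  for (st in s$steps) {
    if (st$case == "REMOVE_EQUAL") {
      push(cherry_op("REDUCE", cur[2], cur[1]))
      cur <- cur[-1]
    } else if (st$case == "SUBTRACT") {
      push(cherry_op("CUT", cur[2], cur[1]))
    } else {
      push(cherry_op("CUT", cur[2], cur[1]))
      cur <- append(cur[-1], cur[1], after = st$inserted_index - 1L)
    }
  }
  ops <- c(ops, greedy_core_sequence(N))
  trims <- any(vapply(ops, function(o) o$kind == "TRIM", TRUE))
  list(status = if (trims) "WEAK_ORCHARD" else "ORCHARD",
       sequence = ops, network = N0)
}
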