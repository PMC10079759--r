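## Network serialization: extended Newick (read/write), a JSON graph format
## (read/write) and DOT (write). The eNewick dialect encodes a reticulation
## as a node carrying a #H tag; a bead appears as the same #H child listed
## twice under one parent. Children are ordered by their serialized subtree
## text so the writer is deterministic for a given object.

quote_label <- function(x) {
  if (grepl("[(),;:#'\\s]", x)) paste0("'", gsub("'", "''", x), "'") else x
}

#' Write a network as extended Newick
#'
#' @param N a valid [pnet()].
#' @return A single eNewick string (terminated by `;`).
#' @examples
#' to_enewick(build_beaded_chain(1))
#' @export
to_enewick <- function(N) {
  vs <- net_vertices(N)
  if (length(vs) == 1L && nrow(N$arcs) == 0L)
    return(paste0(quote_label(unname(N$labels)[1]), ";"))
  ord <- topo_order(N)
  rets <- ord[vapply(ord, function(v) net_indeg(N, v) == 2L, TRUE)]
  tag <- stats::setNames(paste0("#H", seq_along(rets)), rets)
  ## primary parent: the occurrence that expands the subtree below a
  ## reticulation; all other occurrences are bare tag references
  primary <- stats::setNames(vapply(rets, function(h) {
    sort(N$arcs$tail[N$arcs$head == h])[1]
  }, ""), rets)
  expand <- function(v) {
    lab <- if (v %in% names(N$labels)) quote_label(unname(N$labels[v])) else ""
    i <- which(N$arcs$tail == v)
    if (!length(i)) return(lab)
    kids <- character(0)
    for (r in i) {
      h <- N$arcs$head[r]; m <- N$arcs$mult[r]
      if (h %in% rets) {
        first <- if (primary[h] == v)
          paste0(expand(h), tag[h]) else tag[h]
        kids <- c(kids, first, if (m == 2L) tag[h])
      } else {
        kids <- c(kids, rep(expand(h), m))
      }
    }
    paste0("(", paste(sort(kids), collapse = ","), ")", lab)
  }
  paste0(expand(N$root), ";")
}

## --- eNewick parser ----------------------------------------------------

enewick_tokens <- function(txt) {
  txt <- sub(";\\s*$", "", trimws(txt))
  toks <- list(); i <- 1L; n <- nchar(txt)
  while (i <= n) {
    ch <- substr(txt, i, i)
    if (ch %in% c("(", ")", ",")) {
      toks[[length(toks) + 1L]] <- list(type = ch, pos = i); i <- i + 1L
    } else if (ch == "'") {
      j <- i + 1L; buf <- ""
      repeat {
        if (j > n) stop("eNewick parse error at position ", i, ": unterminated quote")
        cj <- substr(txt, j, j)
        if (cj == "'") {
          if (substr(txt, j + 1L, j + 1L) == "'") { buf <- paste0(buf, "'"); j <- j + 2L }
          else { j <- j + 1L; break }
        } else { buf <- paste0(buf, cj); j <- j + 1L }
      }
      toks[[length(toks) + 1L]] <- list(type = "name", text = buf, pos = i)
      i <- j
    } else if (grepl("\\s", ch)) {
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !grepl("[(),;\\s]", substr(txt, j, j))) j <- j + 1L
      toks[[length(toks) + 1L]] <- list(type = "name", text = substr(txt, i, j - 1L), pos = i)
      i <- j
    }
  }
  toks
}

#' Read a network from extended Newick
#'
#' Hybrid (reticulation) vertices are given by `#H` tags; occurrences of the
#' same tag are merged into one vertex, and the same tag listed twice under
#' one parent yields a bead. Branch lengths, if present, are ignored.
#'
#' @param txt eNewick text (one network, `;`-terminated).
#' @return A [pnet()].
#' @export
from_enewick <- function(txt) {
  toks <- enewick_tokens(txt)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_name <- function() {
    t <- peek()
    if (is.null(t) || t$type != "name") return(list(label = "", tag = NA_character_))
    take()
    raw <- sub(":.*$", "", t$text)          # discard any branch length
    hm <- regmatches(raw, regexpr("#[A-Za-z]*[0-9]+$", raw))
    if (length(hm) && nzchar(hm)) list(label = sub("#[A-Za-z]*[0-9]+$", "", raw), tag = hm)
    else list(label = raw, tag = NA_character_)
  }
  parse_subtree <- function() {
    t <- peek()
    if (is.null(t)) stop("eNewick parse error: unexpected end of input")
    if (t$type == "(") {
      take()
      kids <- list(parse_subtree())
      while (!is.null(peek()) && peek()$type == ",") { take(); kids[[length(kids) + 1L]] <- parse_subtree() }
      if (is.null(peek()) || peek()$type != ")")
        stop("eNewick parse error at position ", t$pos, ": expected ')'")
      take()
      nm <- parse_name()
      list(label = nm$label, tag = nm$tag, children = kids)
    } else if (t$type == "name") {
      nm <- parse_name()
      list(label = nm$label, tag = nm$tag, children = list())
    } else stop("eNewick parse error at position ", t$pos, ": unexpected '", t$type, "'")
  }
  tree <- parse_subtree()
  if (!is.null(peek())) stop("eNewick parse error: trailing input at position ", peek()$pos)

  ## flatten into arcs, merging hybrid tags
  counter <- 0L
  hyb_id <- list()
  arcs <- data.frame(tail = character(0), head = character(0), stringsAsFactors = FALSE)
  labels <- character(0)
  hyb_expanded <- list()
  hyb_count <- list()
  walk <- function(node) {
    if (!is.na(node$tag)) {
      hyb_count[[node$tag]] <<- (if (is.null(hyb_count[[node$tag]])) 0L else hyb_count[[node$tag]]) + 1L
      if (is.null(hyb_id[[node$tag]])) {
        counter <<- counter + 1L
        hyb_id[[node$tag]] <<- paste0("n", counter)
      }
      id <- hyb_id[[node$tag]]
      if (length(node$children)) {
        if (isTRUE(hyb_expanded[[node$tag]]))
          stop("eNewick error: hybrid ", node$tag, " expanded more than once")
        hyb_expanded[[node$tag]] <<- TRUE
      }
    } else {
      counter <<- counter + 1L
      id <- paste0("n", counter)
    }
    if (length(node$children)) {
      for (ch in node$children) {
        cid <- walk(ch)
        arcs[nrow(arcs) + 1L, ] <<- c(id, cid)
      }
    } else if (nzchar(node$label)) {
      labels[id] <<- node$label
    }
    id
  }
  root <- walk(tree)
  for (tg in names(hyb_count))
    if (hyb_count[[tg]] < 2L) stop("eNewick error: hybrid ", tg, " referenced once")
  mul <- anyDuplicated(unname(labels)) > 0L
  pnet(arcs, root = root, labels = labels, mul = mul)
}

## --- JSON graph format -------------------------------------------------

#' Write / read the bespoke JSON graph format
#'
#' `{"vertices": [...], "arcs": [[tail, head, mult], ...], "root": ...,
#' "labels": {...}, "mul": ...}`.
#'
#' @param N a [pnet()].
#' @param path optional file path.
#' @return `to_json_net`: JSON text; `from_json_net`: a [pnet()].
#' @export
to_json_net <- function(N, path = NULL) {
  obj <- list(vertices = net_vertices(N),
              arcs = unname(apply(N$arcs, 1L, function(r)
                list(r[["tail"]], r[["head"]], as.integer(r[["mult"]])))),
              root = N$root,
              labels = as.list(N$labels),
              mul = N$mul)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @param txt JSON text (used when `path` is missing).
#' @rdname to_json_net
#' @export
from_json_net <- function(txt = NULL, path = NULL) {
  if (!is.null(path)) txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  arcs <- if (length(obj$arcs)) data.frame(
    tail = vapply(obj$arcs, function(a) as.character(a[[1]]), ""),
    head = vapply(obj$arcs, function(a) as.character(a[[2]]), ""),
    mult = vapply(obj$arcs, function(a) if (length(a) > 2L) as.integer(a[[3]]) else 1L, 1L),
    stringsAsFactors = FALSE) else NULL
  pnet(arcs, root = obj$root,
       labels = stats::setNames(as.character(unlist(obj$labels)), names(obj$labels)),
       mul = isTRUE(obj$mul))
}

## --- DOT ---------------------------------------------------------------

#' Render a network as DOT
#'
#' Reticulation vertices are drawn as squares; if a verified time-stamp map
#' is supplied, vertices with equal stamps are constrained to the same rank
#' so that equal-stamp (horizontal) arcs render horizontally.
#'
#' @param N a valid [pnet()].
#' @param stamps optional named numeric time-stamp map (vertex -> time) that
#'   passes [verify_labelling()] at least weakly.
#' @return DOT text.
#' @export
to_dot <- function(N, stamps = NULL) {
  vs <- net_vertices(N)
  esc <- function(x) gsub("\"", "\\\\\"", x)
  lines <- c("digraph ploidynet {", "  rankdir=TB;")
  for (v in vs) {
    shape <- if (net_indeg(N, v) == 2L) "box" else "ellipse"
    lab <- if (v %in% names(N$labels)) unname(N$labels[v]) else ""
    lines <- c(lines, sprintf("  \"%s\" [shape=%s, label=\"%s\"];",
                              esc(v), shape, esc(lab)))
  }
  if (nrow(N$arcs)) for (i in seq_len(nrow(N$arcs))) {
    for (k in seq_len(N$arcs$mult[i])) {
      horiz <- !is.null(stamps) &&
        isTRUE(unname(stamps[N$arcs$tail[i]]) == unname(stamps[N$arcs$head[i]]))
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s;",
                                esc(N$arcs$tail[i]), esc(N$arcs$head[i]),
                                if (horiz) " [constraint=false, style=bold]" else ""))
    }
  }
  if (!is.null(stamps)) {
    for (s in unique(sort(stamps))) {
      grp <- intersect(names(stamps)[stamps == s], vs)
      if (length(grp) > 1L)
        lines <- c(lines, paste0("  { rank=same; ",
                                 paste(sprintf("\"%s\"", esc(grp)), collapse = "; "),
                                 "; }"))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
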