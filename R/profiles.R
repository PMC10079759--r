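#' Ploidy profiles
#'
#' A ploidy profile records, for each taxon, its ploidy level as a positive
#' integer. Profiles are kept in descending order with taxon labels permuted
#' alongside, the convention under which all constructions in this package
#' operate.
#'
#' @param components positive integers, one per taxon.
#' @param labels taxon identifiers, same length as `components`; defaults to
#'   `x1, x2, ...` in the order of the *sorted* components.
#' @return An object of class `ploidy_profile`: a list with elements
#'   `components` (descending integers) and `labels` (character).
#' @examples
#' ploidy_profile(c(5, 6, 7, 6), c("a", "b", "c", "d"))
#' @export
ploidy_profile <- function(components, labels = NULL) {
  if (length(components) < 1L) stop("a ploidy profile needs at least one component")
  if (any(is.na(components)) || any(components != round(components)) || any(components < 1))
    stop("ploidy levels must be positive integers")
  components <- as.integer(round(components))
  if (is.null(labels)) {
    components <- sort(components, decreasing = TRUE)
    labels <- paste0("x", seq_along(components))
  } else {
    labels <- as.character(labels)
    if (length(labels) != length(components)) stop("labels and components differ in length")
    if (anyDuplicated(labels)) stop("duplicate taxon labels")
    ord <- order(-components)            # stable: ties keep input label order
    components <- components[ord]
    labels <- labels[ord]
  }
  structure(list(components = components, labels = labels),
            class = "ploidy_profile")
}

#' @export
print.ploidy_profile <- function(x, ...) {
  cat("ploidy profile (", paste(x$components, collapse = ","), ") on {",
      paste(x$labels, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' @export
length.ploidy_profile <- function(x) length(x$components)

as_profile <- function(p) {
  if (inherits(p, "ploidy_profile")) p else ploidy_profile(p)
}

#' Classify a ploidy profile
#'
#' A profile is *simple* if its first component is at least 2 and all others
#' are 1; *strictly simple* if additionally it has a single component;
#' *practical* if it is simple but not strictly simple, or consists of a
#' single power of two at least 2; *arc-rich* if it is strictly simple and
#' the binary representation of its component has dimension at least 2.
#'
#' @param p a [ploidy_profile()].
#' @return A list of logical flags `simple`, `strictly_simple`, `practical`,
#'   `arc_rich`.
#' @examples
#' classify_profile(ploidy_profile(c(77, 1, 1, 1)))
#' classify_profile(ploidy_profile(77))
#' @export
classify_profile <- function(p) {
  p <- as_profile(p)
  m <- p$components
  n <- length(m)
  simple <- m[1] >= 2L && (n == 1L || all(m[-1] == 1L))
  strictly <- simple && n == 1L
  pow2 <- m[1] >= 2L && bitwAnd(m[1], m[1] - 1L) == 0L
  practical <- (simple && !strictly) || (n == 1L && pow2)
  arc_rich <- strictly && length(binary_representation(m[1])) >= 2L
  list(simple = simple, strictly_simple = strictly,
       practical = practical, arc_rich = arc_rich)
}

is_simple_profile <- function(p) classify_profile(p)$simple

# (1) is the degenerate terminal realized by the single-vertex network;
# every other terminal is simple in the strict sense.
is_terminal_profile <- function(p) {
  p <- as_profile(p)
  is_simple_profile(p) || (length(p$components) == 1L && p$components[1] == 1L)
}

#' Binary representation of a positive integer
#'
#' The strictly decreasing vector of exponents in the powers-of-two
#' decomposition, e.g. 77 = 2^6 + 2^3 + 2^2 + 2^0 gives (6, 3, 2, 0).
#'
#' @param m a positive integer.
#' @return Integer vector of exponents, strictly decreasing.
#' @examples
#' binary_representation(77)
#' @export
binary_representation <- function(m) {
  if (length(m) != 1L || is.na(m) || m != round(m) || m < 1) stop("m must be a positive integer")
  m <- as.numeric(m)
  e <- integer(0)
  k <- floor(log2(m) + 1e-9)
  while (m > 0) {
    while (2^k > m) k <- k - 1L
    e <- c(e, as.integer(k))
    m <- m - 2^k
  }
  e
}

fresh_label <- function(existing) {
  k <- 1L
  while (paste0("_s", k) %in% existing) k <- k + 1L
  paste0("_s", k)
}

#' One step of the simplification sequence
#'
#' For a non-terminal profile with components `m1 >= m2 >= ...`, puts
#' `alpha = m1 - m2` and applies one of three cases: `alpha == 0` removes the
#' first component (`REMOVE_EQUAL`); `alpha > m2` replaces the first
#' component by `alpha` (`SUBTRACT`); `0 < alpha <= m2` removes the first
#' component and inserts `alpha`, with a fresh taxon label, directly after
#' the last occurrence of the value `alpha` (`REMOVE_INSERT`).
#'
#' @param p a non-terminal [ploidy_profile()].
#' @return A list with the successor `profile` and the `step` record
#'   (`case`, `alpha`, `inserted_index`, `deleted_label`, `fresh_label`,
#'   `label_map`).
#' @examples
#' simplify_step(ploidy_profile(c(7, 6, 6, 5)))
#' @export
simplify_step <- function(p) {
  p <- as_profile(p)
  if (is_terminal_profile(p)) stop("profile is already simple; no simplification step applies")
  m <- p$components; lab <- p$labels
  alpha <- m[1] - m[2]
  if (alpha == 0L) {
    succ <- structure(list(components = m[-1], labels = lab[-1]), class = "ploidy_profile")
    step <- list(case = "REMOVE_EQUAL", alpha = 0L, inserted_index = NA_integer_,
                 deleted_label = lab[1], fresh_label = NA_character_,
                 label_map = stats::setNames(lab[-1], lab[-1]))
  } else if (alpha > m[2]) {
    comp <- m; comp[1] <- alpha
    succ <- structure(list(components = comp, labels = lab), class = "ploidy_profile")
    step <- list(case = "SUBTRACT", alpha = alpha, inserted_index = NA_integer_,
                 deleted_label = NA_character_, fresh_label = NA_character_,
                 label_map = stats::setNames(lab, lab))
  } else {
    a <- m[-1]; alab <- lab[-1]
    ge <- which(a >= alpha)
    j <- if (length(ge)) max(ge) + 1L else 1L
    fl <- fresh_label(lab)
    comp <- append(a, alpha, after = j - 1L)
    labs <- append(alab, fl, after = j - 1L)
    succ <- structure(list(components = comp, labels = labs), class = "ploidy_profile")
    lm <- stats::setNames(c(alab, lab[1]), c(alab, fl))
    step <- list(case = "REMOVE_INSERT", alpha = alpha, inserted_index = j,
                 deleted_label = lab[1], fresh_label = fl, label_map = lm)
  }
  ## successor's first two labels, used by the traceback
  step$succ1 <- succ$labels[1]
  step$succ2 <- if (length(succ$labels) >= 2L) succ$labels[2] else NA_character_
  list(profile = succ, step = step)
}

#' Simplification sequence of a ploidy profile
#'
#' Iterates [simplify_step()] until a simple profile (the *terminal element*)
#' is reached. A simple input yields a one-element sequence.
#'
#' @param p a [ploidy_profile()] (or bare integer vector).
#' @return An object of class `simplification_sequence`: list with `profiles`
#'   (list of profiles, first is the input), `steps` (one fewer step records)
#'   and `terminal`.
#' @examples
#' simplification_sequence(c(7, 6, 6, 5))$terminal
#' @export
simplification_sequence <- function(p) {
  p <- as_profile(p)
  profiles <- list(p)
  steps <- list()
  cur <- p
  while (!is_terminal_profile(cur)) {
    st <- simplify_step(cur)
    cur <- st$profile
    profiles[[length(profiles) + 1L]] <- cur
    steps[[length(steps) + 1L]] <- st$step
  }
  structure(list(profiles = profiles, steps = steps, terminal = cur),
            class = "simplification_sequence")
}

#' @export
print.simplification_sequence <- function(x, ...) {
  cat("simplification sequence, ", length(x$profiles), " profiles:\n", sep = "")
  for (pr in x$profiles)
    cat("  (", paste(pr$components, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Halve an all-even ploidy profile
#'
#' Removing a bead above the root of a realization halves every path count;
#' this is the corresponding operation on profiles.
#'
#' @param p a profile whose components are all even.
#' @return The profile with each component divided by two, labels preserved.
#' @examples
#' halve_profile(ploidy_profile(c(14, 12, 12, 10)))
#' @export
halve_profile <- function(p) {
  p <- as_profile(p)
  if (any(p$components %% 2L != 0L)) stop("all components must be even to halve")
  structure(list(components = p$components %/% 2L, labels = p$labels),
            class = "ploidy_profile")
}

#' Read a ploidy profile from a two-column file
#'
#' Plain text or CSV with columns taxon, ploidy level; a header line is
#' detected and skipped when the second field is not numeric.
#'
#' @param path file path.
#' @return A [ploidy_profile()].
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty profile file: ", path)
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else "[[:space:]]+"
  parts <- lapply(lines, function(l) trimws(strsplit(l, sep)[[1]]))
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("expected two columns (taxon, ploidy level) in ", path)
  if (suppressWarnings(is.na(as.numeric(parts[[1]][2])))) parts <- parts[-1]
  lab <- vapply(parts, `[`, "", 1L)
  val <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (any(is.na(val))) stop("non-numeric ploidy level in ", path)
  ploidy_profile(val, lab)
}

#' Export a simplification sequence as JSON
#'
#' @param s a [simplification_sequence()].
#' @param path optional file path; when missing the JSON string is returned.
#' @return JSON text (invisibly when written to a file).
#' @export
sequence_to_json <- function(s, path = NULL) {
  recs <- lapply(seq_along(s$profiles), function(i) {
    pr <- s$profiles[[i]]
    st <- if (i <= length(s$steps)) s$steps[[i]] else NULL
    c(list(components = pr$components, labels = pr$labels),
      if (!is.null(st)) list(case = st$case, alpha = st$alpha,
                             inserted_index = st$inserted_index))
  })
  txt <- jsonlite::toJSON(recs, auto_unbox = TRUE, null = "null", na = "null", pretty = TRUE)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Seeded random ploidy profile
#'
#' @param n number of taxa.
#' @param max_component upper bound for ploidy levels.
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @return A [ploidy_profile()] labelled `x1..xn`.
#' @export
random_profile <- function(n, max_component, seed) {
  if (n < 1L || max_component < 1L) stop("n and max_component must be at least 1")
  set.seed(seed)
  ploidy_profile(sort(sample.int(max_component, n, replace = TRUE), decreasing = TRUE))
}
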