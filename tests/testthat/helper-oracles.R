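# Independent oracles and corpus helpers shared across the test files.

# Brute-force path counting: enumerate every directed root-to-leaf path by
# depth-first expansion (a parallel pair is walked twice). Independent of
# the dynamic program in count_paths(); only used on small networks.
brute_count_paths <- function(N) {
  labs <- N$labels
  vs <- unique(c(N$root, N$arcs$tail, N$arcs$head, names(labs)))
  if (length(vs) == 1L && nrow(N$arcs) == 0L)
    return(stats::setNames(1, unname(labs)))
  acc <- new.env(parent = emptyenv())
  for (l in unique(unname(labs))) assign(l, 0, envir = acc)
  rec <- function(v) {
    rows <- which(N$arcs$tail == v)
    if (!length(rows)) {
      l <- unname(labs[v])
      assign(l, get(l, envir = acc) + 1, envir = acc)
      return(invisible())
    }
    for (r in rows) for (k in seq_len(N$arcs$mult[r])) rec(N$arcs$head[r])
  }
  rec(N$root)
  out <- vapply(sort(unique(unname(labs))), function(l) get(l, envir = acc), 1)
  out
}

n_vertices <- function(N) length(unique(c(N$root, N$arcs$tail, N$arcs$head,
                                          names(N$labels))))

# Seeded simple profile: first component in [2, max1], the rest (if any) 1.
random_simple_profile <- function(seed, max1 = 256L, max_n = 6L) {
  set.seed(seed)
  n <- sample.int(max_n, 1L)
  ploidy_profile(c(sample(2:max1, 1L), rep(1L, n - 1L)))
}

# Seeded profile whose simplification terminal is practical (rejection
# sampling over random_profile draws).
random_practical_terminal_profile <- function(seed, max_n = 6L, max_comp = 30L) {
  i <- 0L
  repeat {
    set.seed(seed * 1000L + i)
    p <- random_profile(sample(2:max_n, 1L), sample(2:max_comp, 1L),
                        seed = seed * 1000L + i)
    term <- simplification_sequence(p)$terminal
    if (classify_profile(term)$practical) return(p)
    i <- i + 1L
  }
}

replay_sequence <- function(N, ops) {
  for (op in ops) N <- apply_operation(N, op)
  N
}
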