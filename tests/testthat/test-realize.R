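test_that("single traceback steps rebuild the predecessor profile", {
  # REMOVE_INSERT: (6,5,1) -> (5,1,1); tracing back from B((5,1,1))
  st <- simplify_step(ploidy_profile(c(6, 5, 1), c("x1", "x2", "x3")))
  expect_equal(st$profile$components, c(5L, 1L, 1L))
  N <- build_B(st$profile)
  M <- traceback_step(N, st$step)
  expect_true(validate_network(M)$ok)
  expect_equal(unname(count_paths(M)[c("x1", "x2", "x3")]), c(6, 5, 1))

  # REMOVE_EQUAL: (6,6,5,1) -> (6,5,1)
  st2 <- simplify_step(ploidy_profile(c(6, 6, 5, 1)))
  M2 <- traceback_step(realize_profile(st2$profile), st2$step)
  expect_equal(unname(count_paths(M2)[st2$profile$labels[1]]), 6)
  expect_equal(sort(unname(count_paths(M2))), c(1, 5, 6, 6))

  # SUBTRACT: (10,2,2) -> (8,2,2); path count at the top leaf is 8 + 2
  st3 <- simplify_step(ploidy_profile(c(10, 2, 2)))
  M3 <- traceback_step(realize_profile(st3$profile), st3$step)
  expect_true(validate_network(M3)$ok)
  expect_equal(unname(count_paths(M3)["x1"]), 10)
})

test_that("realize_profile reproduces the worked examples", {
  N <- realize_profile(c(7, 6, 6, 5))
  expect_equal(count_paths(N), c(x1 = 7, x2 = 6, x3 = 6, x4 = 5))
  expect_equal(nrow(reticulation_inventory(N)), 5L)
  expect_true(attr(N, "minimal_by_construction"))

  # a simple profile is realized by its core unchanged
  expect_true(isomorphic_networks(realize_profile(c(5, 1, 1)),
                                  build_B(ploidy_profile(c(5, 1, 1)))))

  viola <- realize_profile(c(18, 14, 14, 10, 8, 8, 8, 4, 4, 2))
  cp <- count_paths(viola)
  expect_equal(unname(cp[paste0("x", 1:10)]),
               c(18, 14, 14, 10, 8, 8, 8, 4, 4, 2))
  inv <- reticulation_inventory(viola)
  expect_equal(sum(!inv$in_bead), 5L)
  expect_true(attr(viola, "minimal_by_construction"))
})

test_that("a supplied core must realize the terminal element", {
  expect_error(realize_profile(c(7, 6, 6, 5), core = build_beaded_chain(2)),
               "does not realize")
  N <- realize_profile(c(7, 6, 6, 5),
                       core = naive_core(ploidy_profile(c(5, 1, 1))))
  expect_equal(count_paths(N), c(x1 = 7, x2 = 6, x3 = 6, x4 = 5))
  expect_false(attr(N, "minimal_by_construction"))
})

test_that("prepending a bead doubles every path count", {
  N <- prepend_bead(realize_profile(c(7, 6, 6, 5)))
  expect_true(validate_network(N)$ok)
  expect_equal(count_paths(N), c(x1 = 14, x2 = 12, x3 = 12, x4 = 10))
  expect_equal(count_paths(prepend_bead(single_vertex_net("a"))), c(a = 2))
  twice <- prepend_bead(prepend_bead(single_vertex_net("x")))
  expect_equal(count_paths(twice), c(x = 4))
})

test_that("the doubling identity realizes all-even profiles", {
  for (pp in list(c(14, 12, 12, 10), c(8, 2), c(4, 4, 2, 2))) {
    p <- ploidy_profile(pp)
    N <- prepend_bead(realize_profile(halve_profile(p)))
    expect_equal(unname(count_paths(N)[p$labels]), as.numeric(pp))
  }
})

test_that("scaled composition realizes the stretched profile", {
  C <- compose_scaled(realize_profile(c(5, 3, 1)), 3)
  expect_true(validate_network(C)$ok)
  expect_equal(count_paths(C),
               c(x1 = 40, x2 = 24, x3 = 8, x4 = 4, x5 = 2, x6 = 1))
  C1 <- compose_scaled(realize_profile(ploidy_profile(1)), 1)
  expect_equal(sort(unname(count_paths(C1))), c(1, 2))
  C2 <- compose_scaled(realize_profile(c(2, 1, 1)), 2)
  expect_equal(sort(unname(count_paths(C2)), decreasing = TRUE), c(8, 4, 4, 2, 1))
  expect_error(compose_scaled(realize_profile(c(2, 1)), 0), "at least 1")
})

test_that("random profiles are realized correctly with consistent reticulation counts", {
  for (i in 1:500) {
    p <- random_profile(sample.int(8, 1), sample.int(200, 1), seed = 5000 + i)
    N <- realize_profile(p)
    cp <- count_paths(N)
    expect_equal(unname(cp[p$labels]), as.numeric(p$components))
    s <- attr(N, "sequence")
    core <- attr(N, "core")
    nonzero <- sum(vapply(s$steps, function(st) st$alpha != 0L, TRUE))
    expect_equal(nrow(reticulation_inventory(N)),
                 nrow(reticulation_inventory(core)) + nonzero)
    if (n_vertices(N) <= 14L)
      expect_equal(cp[sort(names(cp))], brute_count_paths(N))
  }
})
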