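test_that("normalization sorts components descending with stable label order", {
  p <- ploidy_profile(c(5, 6, 7, 6), c("a", "b", "c", "d"))
  expect_equal(p$components, c(7L, 6L, 6L, 5L))
  expect_equal(p$labels, c("c", "b", "d", "a"))
  q <- ploidy_profile(c(7, 6, 6, 5), paste0("x", 1:4))
  expect_equal(q$components, c(7L, 6L, 6L, 5L))
  expect_equal(q$labels, paste0("x", 1:4))
  expect_equal(ploidy_profile(1)$components, 1L)
  expect_error(ploidy_profile(c(3, 0)), "positive")
  expect_error(ploidy_profile(c(3, 2), c("a", "a")), "duplicate")
  expect_error(ploidy_profile(c(3, 2), "a"), "length")
})

test_that("classification flags match the simple/practical/arc-rich definitions", {
  f <- classify_profile(ploidy_profile(c(77, 1, 1, 1)))
  expect_true(f$simple && f$practical)
  expect_false(f$strictly_simple || f$arc_rich)
  g <- classify_profile(ploidy_profile(77))
  expect_true(g$strictly_simple && g$arc_rich)
  expect_false(g$practical)
  h <- classify_profile(ploidy_profile(8))
  expect_true(h$strictly_simple && h$practical)
  expect_false(h$arc_rich)
  expect_false(classify_profile(ploidy_profile(c(3, 2)))$simple)
})

test_that("binary representation lists strictly decreasing exponents", {
  expect_equal(binary_representation(77), c(6L, 3L, 2L, 0L))
  expect_equal(binary_representation(1), 0L)
  expect_equal(binary_representation(12), c(3L, 2L))
  expect_error(binary_representation(0))
  for (m in 1:5000) {
    e <- binary_representation(m)
    expect_true(all(diff(e) < 0) || length(e) == 1L)
    expect_equal(sum(2^e), m)
  }
  set.seed(7)
  for (m in sample.int(1e6, 300)) expect_equal(sum(2^binary_representation(m)), m)
})

test_that("simplification steps apply the three cases correctly", {
  st <- simplify_step(ploidy_profile(c(7, 6, 6, 5)))
  expect_equal(st$step$case, "REMOVE_INSERT")
  expect_equal(st$step$alpha, 1L)
  expect_equal(st$profile$components, c(6L, 6L, 5L, 1L))
  expect_equal(st$step$inserted_index, 4L)

  st2 <- simplify_step(st$profile)
  expect_equal(st2$step$case, "REMOVE_EQUAL")
  expect_equal(st2$profile$components, c(6L, 5L, 1L))

  st3 <- simplify_step(ploidy_profile(c(10, 2, 2)))
  expect_equal(st3$step$case, "SUBTRACT")
  expect_equal(st3$step$alpha, 8L)
  expect_equal(st3$profile$components, c(8L, 2L, 2L))

  expect_error(simplify_step(ploidy_profile(c(5, 1, 1))), "simple")
})

test_that("simplification sequences reach the documented terminals", {
  s <- simplification_sequence(c(7, 6, 6, 5))
  expect_length(s$profiles, 4L)
  expect_equal(s$terminal$components, c(5L, 1L, 1L))
  expect_length(simplification_sequence(c(5, 1, 1))$profiles, 1L)
  expect_equal(simplification_sequence(c(5, 3, 1))$terminal$components, c(2L, 1L, 1L))
  s63 <- simplification_sequence(c(6, 3))
  expect_equal(lapply(s63$profiles, `[[`, "components"),
               list(c(6L, 3L), c(3L, 3L), 3L))
})

test_that("simplification terminates, stays descending, and only the terminal is simple", {
  for (i in 1:500) {
    p <- random_profile(sample.int(8, 1), sample.int(150, 1), seed = i)
    s <- simplification_sequence(p)
    sums <- vapply(s$profiles, function(q) sum(q$components), 1)
    expect_true(all(diff(sums) < 0) || length(sums) == 1L)
    for (j in seq_along(s$profiles)) {
      q <- s$profiles[[j]]
      expect_true(all(diff(q$components) <= 0))
      expect_length(q$labels, length(q$components))
      simple_here <- classify_profile(q)$simple ||
        (length(q$components) == 1L && q$components[1] == 1L)
      expect_equal(simple_here, j == length(s$profiles) || length(s$profiles) == 1L)
    }
  }
})

test_that("removed-and-reinserted components land deterministically after the last equal value", {
  p <- ploidy_profile(c(9, 7, 5, 2, 2, 2))
  a <- simplify_step(p); b <- simplify_step(p)
  expect_identical(a$profile$components, b$profile$components)
  expect_equal(a$step$case, "REMOVE_INSERT")
  # alpha = 2 goes directly after the existing 2s
  expect_equal(a$profile$components, c(7L, 5L, 2L, 2L, 2L, 2L))
  expect_equal(a$step$inserted_index, 6L)
})

test_that("halving an all-even profile divides componentwise and keeps labels", {
  expect_equal(halve_profile(ploidy_profile(c(14, 12, 12, 10)))$components,
               c(7L, 6L, 6L, 5L))
  expect_equal(halve_profile(ploidy_profile(2))$components, 1L)
  expect_equal(halve_profile(ploidy_profile(c(18, 14, 14, 10, 8, 8, 8, 4, 4, 2)))$components,
               c(9L, 7L, 7L, 5L, 4L, 4L, 4L, 2L, 2L, 1L))
  expect_error(halve_profile(ploidy_profile(c(4, 3))), "even")
})

test_that("profile files round-trip through the two-column reader", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,ploidy", "a,7", "b,6", "c,6", "d,5"), f)
  p <- read_profile(f)
  expect_equal(p$components, c(7L, 6L, 6L, 5L))
  expect_equal(p$labels, c("a", "b", "c", "d"))
  f2 <- withr::local_tempfile()
  writeLines(c("a 3", "b 1"), f2)
  expect_equal(read_profile(f2)$components, c(3L, 1L))
})

test_that("random profiles are reproducible and valid", {
  a <- random_profile(4, 20, seed = 7)
  b <- random_profile(4, 20, seed = 7)
  expect_identical(a, b)
  expect_equal(random_profile(1, 1, seed = 0)$components, 1L)
  p <- random_profile(3, 200, seed = 1)
  expect_true(all(diff(p$components) <= 0))
})
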