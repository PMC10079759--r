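test_that("validation accepts constructed networks and the degenerate vertex", {
  expect_true(validate_network(build_beaded_chain(1))$ok)
  expect_true(validate_network(realize_profile(c(7, 6, 6, 5)))$ok)
  expect_true(validate_network(single_vertex_net("a"))$ok)
})

test_that("validation pinpoints single-invariant mutations", {
  N <- realize_profile(c(5, 1, 1))
  # in-2/out-2 vertex
  M <- N
  r <- reticulation_inventory(M)$vertex[1]
  ch <- M$arcs$head[M$arcs$tail == r][1]
  M$arcs <- rbind(M$arcs, data.frame(tail = r, head = setdiff(names(M$labels), ch)[1],
                                     mult = 1L))
  rep <- validate_network(M)
  expect_false(rep$ok)
  expect_true(any(rep$violations$rule == "vertex_degree" |
                  rep$violations$rule == "leaf_indegree"))
  # second root
  M2 <- N
  M2$arcs <- rbind(M2$arcs, data.frame(tail = "extra_root", head = names(N$labels)[1],
                                       mult = 1L))
  expect_false(validate_network(M2)$ok)
  # cycle
  M3 <- N
  lf <- names(N$labels)[1]
  M3$arcs <- rbind(M3$arcs, data.frame(tail = lf, head = N$root, mult = 1L))
  rep3 <- validate_network(M3)
  expect_false(rep3$ok)
  # triple arc
  M4 <- build_beaded_chain(2)
  i <- which(M4$arcs$mult == 2L)[1]
  M4$arcs$mult[i] <- 3L
  rep4 <- validate_network(M4)
  expect_false(rep4$ok)
  expect_true("triple_arc" %in% rep4$violations$rule)
})

test_that("path counting matches the worked examples", {
  expect_equal(count_paths(build_B(ploidy_profile(c(77, 1, 1, 1)))),
               c(x1 = 77, x2 = 1, x3 = 1, x4 = 1))
  expect_equal(count_paths(single_vertex_net("a")), c(a = 1))
  expect_equal(count_paths(realize_profile(c(7, 6, 6, 5))),
               c(x1 = 7, x2 = 6, x3 = 6, x4 = 5))
})

test_that("path counting agrees with brute-force enumeration on small networks", {
  nets <- list(
    build_beaded_chain(1), build_beaded_chain(3),
    build_B(ploidy_profile(3)), build_B(ploidy_profile(c(5, 1, 1))),
    build_B(ploidy_profile(c(2, 1, 1))), naive_core(ploidy_profile(c(3, 1))),
    realize_profile(c(3, 1)), realize_profile(c(6, 3)),
    realize_profile(c(2, 2)), caterpillar(letters[1:4])
  )
  for (N in nets) {
    if (n_vertices(N) > 14L) next
    expect_equal(count_paths(N)[sort(names(count_paths(N)))], brute_count_paths(N))
  }
})

test_that("reticulation inventory distinguishes bead membership", {
  inv1 <- reticulation_inventory(build_beaded_chain(1))
  expect_equal(nrow(inv1), 1L)
  expect_true(all(inv1$in_bead))
  # B((77)): 9 reticulations; the root subdivision s_k breaks the first bead
  inv <- reticulation_inventory(build_B(ploidy_profile(77)))
  expect_equal(nrow(inv), 9L)
  expect_equal(sum(inv$in_bead), 5L)
  invN <- reticulation_inventory(realize_profile(c(7, 6, 6, 5)))
  expect_equal(nrow(invN), 5L)
})

test_that("eNewick writing and parsing are inverse up to isomorphism", {
  bead <- build_beaded_chain(1)
  txt <- to_enewick(bead)
  expect_match(txt, "#H1")
  expect_true(isomorphic_networks(bead, from_enewick(txt)))
  for (i in 1:40) {
    p <- random_profile(sample.int(5, 1), sample.int(25, 1), seed = 100 + i)
    N <- realize_profile(p)
    M <- from_enewick(to_enewick(N))
    expect_true(validate_network(M)$ok)
    expect_true(isomorphic_networks(N, M))
  }
  expect_true(isomorphic_networks(single_vertex_net("a"),
                                  from_enewick(to_enewick(single_vertex_net("a")))))
})

test_that("malformed eNewick input is rejected with a reason", {
  expect_error(from_enewick("((x1)#H1,x2);"), "referenced once")
  expect_error(from_enewick("((x1,x2);"), "parse error")
  expect_error(from_enewick("(x1,'abc);"), "unterminated")
})

test_that("quoted labels survive an eNewick round trip", {
  N <- realize_profile(ploidy_profile(c(3, 1), c("V. palustris", "odd'name")))
  M <- from_enewick(to_enewick(N))
  expect_setequal(unname(M$labels), c("V. palustris", "odd'name"))
  expect_true(isomorphic_networks(N, M))
})

test_that("isomorphism respects structure, labels and multiplicities", {
  N <- realize_profile(c(5, 1, 1))
  M <- N
  vs <- unique(c(N$root, N$arcs$tail, N$arcs$head, names(N$labels)))
  perm <- stats::setNames(paste0("z", seq_along(vs)), vs)
  M$arcs$tail <- unname(perm[M$arcs$tail]); M$arcs$head <- unname(perm[M$arcs$head])
  M$root <- unname(perm[M$root]); names(M$labels) <- unname(perm[names(M$labels)])
  expect_true(isomorphic_networks(N, M))
  expect_false(isomorphic_networks(build_beaded_chain(2), build_beaded_chain(3)))
  # same shape, different leaf labels
  A <- realize_profile(ploidy_profile(c(3, 1), c("a", "b")))
  B <- realize_profile(ploidy_profile(c(3, 1), c("b", "a")))
  expect_false(isomorphic_networks(A, B))
  # alternative core for the same profile is a different network
  expect_false(isomorphic_networks(build_B(ploidy_profile(c(12, 1, 1))),
                                   naive_core(ploidy_profile(c(12, 1, 1)))))
})

test_that("JSON graph format round-trips", {
  N <- realize_profile(c(6, 3))
  M <- from_json_net(to_json_net(N))
  expect_true(isomorphic_networks(N, M))
  f <- withr::local_tempfile(fileext = ".json")
  to_json_net(N, path = f)
  expect_true(isomorphic_networks(N, from_json_net(path = f)))
})

test_that("DOT output marks reticulations and ranks equal stamps together", {
  B <- build_B(ploidy_profile(c(77, 1, 1, 1)))
  t <- label_core(B)
  txt <- to_dot(B, t)
  expect_match(txt, "digraph")
  expect_match(txt, "shape=box")
  expect_match(txt, "rank=same")
  # s_j and s_j' share a stamp, hence a rank group
  expect_match(txt, "\"s2\".*\"s2p\"|\"s2p\".*\"s2\"")
  expect_match(to_dot(single_vertex_net("a")), "digraph")
})
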