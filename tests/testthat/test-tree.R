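test_that("tree size follows the divergent-growth formula up to G4", {
  for (n in 0:4) {
    tr <- dendrimer(sprintf("DN-011-G%d", n))
    expect_equal(tr$unit_count, 3L * (2L^(n + 1L) - 1L))
    expect_equal(tr$leaf_count, 2L^(n + 1L))
    expect_equal(max(tr$depth), 2L * n + 1L)
  }
})

test_that("hand-expanded small trees match", {
  g0 <- dendrimer("DN-011-G0")
  expect_equal(g0$unit_count, 3L)
  expect_equal(g0$leaf_count, 2L)
  expect_equal(max(g0$depth), 1L)
  expect_equal(g0$bit, c(0L, 1L, 1L))

  g1 <- dendrimer("DN-011-G1")
  expect_equal(g1$unit_count, 9L)
  expect_equal(g1$leaf_count, 4L)
  expect_equal(max(g1$depth), 3L)
  # divergent growth: each growth-link unit carries one monomer focal
  links <- which(g1$role == "growth-link")
  expect_length(links, 2L)
  expect_true(all(lengths(g1$children[links]) == 1L))
  foc <- which(g1$role %in% c("focal", "monomer-focal"))
  expect_true(all(lengths(g1$children[foc]) == 2L))
})

test_that("bit multiset counts monomer bits across the schedule", {
  expect_equal(bit_multiset(dendrimer("DN-011-G1")),
               c(zeros = 3L, ones = 6L))
  expect_equal(bit_multiset(dendrimer("DN-111-000-G1")),
               c(zeros = 6L, ones = 3L))
  for (tr in small_trees()) {
    bm <- bit_multiset(tr)
    expect_equal(sum(bm), tr$unit_count)
  }
})

test_that("tree building is deterministic and child order follows the code", {
  a <- build_tree(parse_notation("DN-100-011-G1"))
  b <- build_tree(parse_notation("DN-100-011-G1"))
  expect_identical(a, b)
  # left child carries b1: code 1(01) puts 0 left, 1 right
  tr <- dendrimer("DN-101-G0")
  kids <- tr$children[[1]]
  expect_equal(tr$bit[kids], c(0L, 1L))
})
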