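tb <- composition_table()

test_that("calibrated precursors reproduce the tabulated DN values", {
  expect_equal(precursor_mz(dendrimer("DN-011-G1"), tb)$mz, 1892.60,
               tolerance = 1e-9)
  expect_equal(precursor_mz(dendrimer("DN-111-000-G1"), tb)$mz, 1808.51,
               tolerance = 0.01 / 1808.51)
  expect_equal(precursor_mz(dendrimer("DN-100-011-G1"), tb)$mz, 1864.57,
               tolerance = 0.01 / 1864.57)
  expect_equal(precursor_mz(dendrimer("DN-101-G1"), tb)$mz, 1892.60,
               tolerance = 1e-9)
  p2 <- precursor_mz(dendrimer("DN-011-G2"), tb)
  expect_equal(p2$mz, 4329.40, tolerance = 1e-9)
  expect_equal(p2$species, "[M+Na-8Fu]+")
  expect_equal(p2$n_furans, 8L)
})

test_that("composition mode agrees with calibrated mode for the DN family", {
  for (nm in c("DN-011-G1", "DN-111-000-G1", "DN-100-011-G1", "DN-011-G2")) {
    cal <- precursor_mz(dendrimer(nm), tb)$mz
    cmp <- precursor_mz(dendrimer(nm), tb, mode = "composition")$mz
    expect_equal(cmp, cal, tolerance = 0.01 / cal)
  }
})

test_that("structures without anchor or composition raise an error", {
  # DR has anchors at G1/G2 but no configured end group: G0 is unsupported
  expect_error(precursor_mz(dendrimer("DR-011-G0"), tb),
               "unsupported structure")
  # DN falls back to composition mode off-anchor
  expect_silent(precursor_mz(dendrimer("DN-011-G0"), tb))
  # two builds of one spec agree exactly
  expect_identical(precursor_mz(dendrimer("DN-101-G1"), tb)$mz,
                   precursor_mz(build_tree(parse_notation("DN-101-G1")),
                                tb)$mz)
})

test_that("bit-swap linearity: one 1->0 swap lowers the precursor by C2H4", {
  base <- precursor_mz(dendrimer("DN-011-G1"), tb)$mz
  # swap the focal monomer's b2: 011 -> 010
  swapped <- precursor_mz(dendrimer("DN-010-011-G1"), tb)$mz
  expect_equal(base - swapped, tb$bit_delta, tolerance = 1e-12)
  # composition mode, anywhere in the tree, any family topology
  for (pair in list(c("DN-111-G0", "DN-110-G0"),
                    c("DN-101-100-G1", "DN-100-100-G1"))) {
    hi <- precursor_mz(dendrimer(pair[[1]]), tb, mode = "composition")$mz
    lo <- precursor_mz(dendrimer(pair[[2]]), tb, mode = "composition")$mz
    expect_equal(hi - lo, tb$bit_delta, tolerance = 1e-12)
  }
})

test_that("DN-011-G1 has 16 primary fragments merging to 6 species", {
  raw <- enumerate_fragments(dendrimer("DN-011-G1"), tb, merge = FALSE)
  expect_equal(nrow(raw), 16L)       # 8 linkages x t/a
  merged <- enumerate_fragments(dendrimer("DN-011-G1"), tb)
  expect_equal(nrow(merged), 6L)
  expect_setequal(merged$label,
                  c("t2a", "t3a", "t4a", "a2a", "a3a", "a4a"))
  expect_equal(sum(merged$multiplicity), 16L)
  expect_equal(merged$retained_units[merged$label == "t4a"], 8L)
  expect_equal(merged$retained_units[merged$label == "a2a"], 4L)
})

test_that("every primary t/a pair satisfies the sodium complementarity", {
  for (nm in c("DN-011-G1", "DN-101-G1", "DN-100-011-G1", "DN-011-G2")) {
    tree <- dendrimer(nm)
    prec <- precursor_mz(tree, tb)$mz
    fr <- enumerate_fragments(tree, tb, merge = FALSE)
    # pair complements: ascending t masses meet descending a masses
    ts <- sort(fr$mz[fr$side == "t"])
    as_ <- sort(fr$mz[fr$side == "a"], decreasing = TRUE)
    expect_equal(ts + as_ - prec, rep(tb$sodium, length(ts)),
                 tolerance = 1e-9)
  }
})

test_that("fragment masses agree with the cut-every-edge oracle", {
  for (tr in small_trees()[c(1:8, seq(9, 72, by = 7))]) {
    fast <- enumerate_fragments(tr, tb, merge = FALSE)
    slow <- oracle_fragment_masses(tr, tb)
    expect_equal(sort(fast$mz[fast$side == "t"]),
                 sort(slow$mz[slow$side == "t"]), tolerance = 1e-9)
    expect_equal(sort(fast$mz[fast$side == "a"]),
                 sort(slow$mz[slow$side == "a"]), tolerance = 1e-9)
  }
})

test_that("secondary double-cleavage fragments are disjoint-branch only", {
  fr <- enumerate_fragments(dendrimer("DN-011-G0"), tb, secondary = TRUE)
  # 3-unit monomer: 2 edges, both children disjoint -> exactly 1 secondary
  expect_equal(sum(fr$secondary), 1L)
  prec <- precursor_mz(dendrimer("DN-011-G0"), tb,
                       mode = "calibrated")$mz
  sec <- fr$mz[fr$secondary]
  # root piece after removing both leaf units, one H per cleavage
  expected <- prec - 2 * (tb$bit1 + tb$hydrogen) + 2 * tb$hydrogen
  expect_equal(sec, expected, tolerance = 1e-9)
  # off by default
  expect_false(any(enumerate_fragments(dendrimer("DN-011-G1"), tb)$secondary))
})
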