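test_that("modules mirror the matrix bits", {
  dm <- encrypt_sort(extract_paths(dendrimer("DN-011-G1")))
  p <- matrix_to_pdmb(dm)
  expect_equal(dim(p), c(6L, 9L))
  expect_false(attr(p, "framed"))
  expect_equal(sum(p), 36L)           # 6 paths x 6 ones each
  expect_identical(unclass(p)[1, ],
                   strsplit(dm$rows[[1]], "")[[1]] == "1")

  all_white <- matrix_to_pdmb(encrypt_sort(c("00", "00")))
  expect_equal(sum(all_white), 0L)
})

test_that("framing adds the solid L and alternating timing ring", {
  p <- matrix_to_pdmb(encrypt_sort(extract_paths(dendrimer("DN-011-G1"))))
  f <- add_finder_patterns(p)
  expect_equal(dim(f), c(8L, 11L))
  expect_true(all(f[, 1]))            # solid left column
  expect_true(all(f[8, ]))            # solid bottom row
  expect_identical(unname(unclass(f)[1, ]),
                   rep(c(TRUE, FALSE), length.out = 11))   # top timing
  expect_identical(unname(unclass(f)[8:2, 11]),
                   rep(c(TRUE, FALSE), length.out = 7))    # right timing
  expect_true(f[1, 11])   # top-right corner: dark wins where edges meet
  # interior preserved
  expect_identical(unclass(f)[2:7, 2:10], unclass(p)[, ])
  expect_error(add_finder_patterns(f), "already framed")
})

test_that("bitmap rendering is deterministic and round-trips exactly", {
  p <- add_finder_patterns(
    matrix_to_pdmb(encrypt_sort(extract_paths(dendrimer("DN-011-G1")))))
  one <- render_pbm(p)
  expect_identical(one, render_pbm(p))
  expect_identical(read_pbm(one), unclass(p)[, ])

  scaled <- read_pbm(render_pbm(p, scale = 10))
  expect_equal(dim(scaled), c(80L, 110L))
  # quiet zone is white
  q <- read_pbm(render_pbm(p, scale = 2, quiet_zone = 1))
  expect_equal(dim(q), c(20L, 26L))
  expect_false(any(q[1:2, ]))
  expect_false(any(q[, 1:2]))
})

test_that("svg rendering counts one rect per dark module", {
  p <- matrix_to_pdmb(encrypt_sort(c("10", "01")))
  svg <- render_svg(p, scale = 5, quiet_zone = 0)
  expect_equal(lengths(regmatches(svg, gregexpr("<rect ", svg))) - 1L,
               sum(p))
  expect_error(render_pbm(p, scale = 0), "scale")
})
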