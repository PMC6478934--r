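test_that("the encryption comparator places right-to-left 1s upper", {
  expect_equal(encrypt_sort(c("10", "01"))$rows, c("01", "10"))
  # rightmost column equal -> decided further left
  expect_equal(encrypt_sort(c("001", "101"))$rows, c("101", "001"))
  # brute-force pairwise comparator agrees on the DN-011-G1 rows
  cmp_upper <- function(a, b) {  # TRUE if a belongs above b
    av <- rev(strsplit(a, "")[[1]]); bv <- rev(strsplit(b, "")[[1]])
    d <- which(av != bv)
    if (length(d) == 0L) return(NA)
    av[[d[[1]]]] == "1"
  }
  paths <- as.character(extract_paths(dendrimer("DN-011-G1")))
  rows <- encrypt_sort(paths)$rows
  for (i in seq_len(length(rows) - 1L))
    expect_true(cmp_upper(rows[[i]], rows[[i + 1L]]))
})

test_that("sorting is invariant to input order and idempotent", {
  paths <- as.character(extract_paths(dendrimer("DN-011-G1")))
  canon <- encrypt_sort(paths)
  set.seed(42)
  for (i in 1:50) {
    perm <- sample(paths)
    expect_identical(encrypt_sort(perm)$rows, canon$rows)
  }
  expect_identical(encrypt_sort(canon$rows)$rows, canon$rows)
})

test_that("ragged or non-binary rows are rejected", {
  expect_error(encrypt_sort(c("01", "011")), "ragged")
  expect_error(encrypt_sort(character(0)), "empty")
  expect_error(encrypt_sort(c("01", "0x")), "bit strings")
})

test_that("row-arrangement counts are exact factorials", {
  expect_identical(count_row_arrangements(rep("0", 1)), "1")
  expect_identical(count_row_arrangements(rep("0", 3)), "6")
  paths <- extract_paths(dendrimer("DN-011-G1"))
  expect_identical(count_row_arrangements(paths), "720")
  # 20! overflows no one: check against R's exact-in-double factorial
  expect_identical(count_row_arrangements(rep("1", 20)),
                   sprintf("%.0f", factorial(20)))
})

test_that("as.matrix gives the 0/1 integer grid", {
  m <- as.matrix(encrypt_sort(c("10", "01")))
  expect_identical(m, rbind(c(0L, 1L), c(1L, 0L)))
})
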