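tb <- composition_table()

test_that("exact theoretical peaks assign with zero mass error", {
  fr <- enumerate_fragments(dendrimer("DN-011-G1"), tb)
  asg <- match_peaks(fr$mz, fr, tolerance = 0.5)
  expect_true(all(asg$matched))
  expect_equal(asg$mass_error, rep(0, nrow(fr)))
  expect_setequal(asg$label, fr$label)
})

test_that("empty peak lists and out-of-tolerance peaks stay unassigned", {
  fr <- enumerate_fragments(dendrimer("DN-011-G1"), tb)
  expect_equal(nrow(match_peaks(numeric(0), fr)), 0L)
  far <- match_peaks(fr$mz + 3, fr, tolerance = 0.5)
  expect_false(any(far$matched))
  expect_error(match_peaks(fr$mz, fr, tolerance = 0), "positive")
  expect_error(match_peaks(-1, fr), "positive")
})

test_that("jittered theoretical peaks recover their generating assignment", {
  fr <- enumerate_fragments(dendrimer("DN-011-G1"), tb)
  set.seed(7)
  for (rep in 1:20) {
    jitter <- stats::runif(nrow(fr), -0.1, 0.1)
    asg <- match_peaks(fr$mz + jitter, fr, tolerance = 0.5)
    expect_true(all(asg$matched))
    expect_identical(asg$label, fr$label)
    expect_equal(asg$mass_error, jitter, tolerance = 1e-9)
  }
})

test_that("ties break toward the lower theoretical m/z", {
  fr <- data.frame(label = c("lo", "hi"), mz = c(100, 100.5))
  asg <- match_peaks(100.25, fr, tolerance = 0.5)
  expect_equal(asg$label, "lo")
})

test_that("self-identification ranks the generating dendrimer first", {
  fr <- enumerate_fragments(dendrimer("DN-011-G1"), tb)
  peaks <- data.frame(mz = fr$mz, intensity = fr$multiplicity * 10)
  res <- identify_dendrimer(peaks, c("DN-101-G1", "DN-011-G1"), tb)
  expect_equal(res$notation[[1]], "DN-011-G1")
  expect_equal(res$frac_matched[[1]], 1)
  # single candidate comes back scored
  one <- identify_dendrimer(peaks, "DN-011-G1", tb)
  expect_equal(nrow(one), 1L)
  expect_gt(one$score, 1.9)
})

test_that("uniform noise does not crown a confident winner", {
  set.seed(11)
  noise <- data.frame(mz = stats::runif(25, 150, 2000),
                      intensity = stats::runif(25, 1, 10))
  res <- identify_dendrimer(noise,
                            c("DN-011-G1", "DN-101-G1", "DN-111-000-G1"), tb)
  expect_true(all(res$frac_matched < 0.5))
})

test_that("identification ordering is deterministic", {
  fr <- enumerate_fragments(dendrimer("DN-011-G1"), tb)
  peaks <- data.frame(mz = fr$mz, intensity = rep(1, nrow(fr)))
  a <- identify_dendrimer(peaks, c("DN-011-G1", "DN-101-G1"), tb)
  b <- identify_dendrimer(peaks, c("DN-101-G1", "DN-011-G1"), tb)
  expect_identical(a, b)
})
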