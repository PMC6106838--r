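test_that("confusion matrix counts shared proteins", {
  ref <- complex_catalog(list(c("A", "B", "C")))
  pred <- complex_catalog(list(c("A", "B", "D")))
  expect_equal(confusion_matrix(ref, pred)[1, 1], 2L)
  expect_equal(confusion_matrix(ref, complex_catalog(list(c("X", "Y"))))[1, 1],
               0L)
  expect_equal(confusion_matrix(ref, ref)[1, 1], 3L)
})

test_that("Sn, PPV and ACC follow the clustering-wise definitions", {
  ref <- complex_catalog(list(c("a", "b", "c"), c("d", "e", "f")))
  expect_equal(complex_accuracy(ref, ref), c(sn = 1, ppv = 1, acc = 1))

  # one prediction covering both disjoint references: Sn 1, PPV 1/2
  ref2 <- complex_catalog(list(c("a", "b"), c("c", "d")))
  pred2 <- complex_catalog(list(c("a", "b", "c", "d")))
  a <- complex_accuracy(ref2, pred2)
  expect_equal(unname(a), c(1, 0.5, sqrt(0.5)))

  none <- complex_catalog(list(c("x", "y", "z")))
  expect_equal(complex_accuracy(ref, none), c(sn = 0, ppv = 0, acc = 0))
  expect_equal(complex_accuracy(ref, complex_catalog(list())),
               c(sn = 0, ppv = 0, acc = 0))
})

test_that("Fraction counts references matched at OS >= threshold", {
  ref <- complex_catalog(list(c("a", "b", "c", "d")))
  expect_equal(complex_fraction(ref, ref), 1)
  expect_equal(complex_fraction(ref, complex_catalog(list(c("a", "b")))), 1)
  expect_equal(complex_fraction(ref, complex_catalog(list(c("x", "y", "z")))),
               0)
  expect_error(complex_fraction(complex_catalog(list()), ref), "empty")
})

test_that("MMR matches simple hand computations", {
  ref <- complex_catalog(list(c("a", "b", "c"), c("d", "e", "f")))
  expect_equal(complex_mmr(ref, ref), 1)
  # one prediction matching one of two references at OS 0.5
  pred <- complex_catalog(list(c("a", "b")))
  expect_equal(overlap_score(pred[[1]], ref[[1]]), 2 / 3)
  pred2 <- complex_catalog(list(c("a", "b", "x", "y", "z", "w")))
  expect_equal(overlap_score(pred2[[1]], ref[[1]]), 4 / 18)
  half <- complex_catalog(list(c("a", "b", "c", "x", "y", "z")))
  expect_equal(complex_mmr(complex_catalog(list(c("a", "b", "c"),
                                                c("p", "q", "r"))), half),
               0.25)  # OS = 9/18 = 0.5, one edge, /2 references
})

test_that("MMR equals the exhaustive matching optimum on small instances", {
  set.seed(31)
  for (i in 1:40) {
    uni <- sprintf("p%02d", 1:14)
    ref <- random_catalog(sample(2:6, 1L), uni)
    pred <- random_catalog(sample(2:6, 1L), uni)
    expect_equal(complex_mmr(ref, pred), brute_mmr(ref, pred),
                 tolerance = 1e-9)
  }
})

test_that("self-evaluation of a disjoint catalog is perfect", {
  set.seed(5)
  for (i in 1:5) {
    uni <- split(sprintf("q%02d", 1:20), rep(1:5, each = 4))
    ref <- complex_catalog(uni[sample(5, sample(3:5, 1L))])
    rep <- evaluate_complexes(ref, ref)
    expect_equal(unlist(rep[c("sn", "ppv", "acc", "fraction", "mmr")]),
                 c(sn = 1, ppv = 1, acc = 1, fraction = 1, mmr = 1))
    expect_equal(rep$composite, 3)
  }
})

test_that("metrics are invariant under catalog permutation and ACC is the geometric mean", {
  set.seed(13)
  uni <- sprintf("p%02d", 1:15)
  ref <- random_catalog(4, uni)
  pred <- random_catalog(5, uni)
  r1 <- evaluate_complexes(ref, pred)
  perm_r <- complex_catalog(unclass(ref)[sample(4)])
  perm_p <- complex_catalog(unclass(pred)[sample(5)])
  r2 <- evaluate_complexes(perm_r, perm_p)
  expect_equal(unclass(r1)[1:6], unclass(r2)[1:6], tolerance = 1e-12)
  expect_equal(r1$acc, sqrt(r1$sn * r1$ppv))
  expect_true(all(unlist(r1[c("sn", "ppv", "acc", "fraction", "mmr")]) >= 0 &
                    unlist(r1[c("sn", "ppv", "acc", "fraction", "mmr")]) <= 1))
})

test_that("adding predictions never lowers Sn or Fraction but can lower PPV", {
  ref <- complex_catalog(list(c("a", "b", "c"), c("d", "e", "f")))
  p1 <- list(c("a", "b", "c"))
  p2 <- c(p1, list(c("a", "d", "x")))
  e1 <- evaluate_complexes(ref, complex_catalog(p1))
  e2 <- evaluate_complexes(ref, complex_catalog(p2))
  expect_gte(e2$sn, e1$sn)
  expect_gte(e2$fraction, e1$fraction)
  expect_lt(e2$ppv, e1$ppv)
})

test_that("catalog files round-trip and filter small complexes", {
  f <- withr::local_tempfile(lines = c("a b c", "d e", "f g h i"))
  cat3 <- read_complex_catalog(f, min_size = 3)
  expect_length(cat3, 2L)
  cat1 <- read_complex_catalog(f, min_size = 1)
  expect_length(cat1, 3L)
  f2 <- withr::local_tempfile()
  write_complex_catalog(cat3, f2)
  expect_identical(unclass(read_complex_catalog(f2, min_size = 1)),
                   unclass(cat3))
})
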