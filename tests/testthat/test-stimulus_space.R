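test_that("feature_space validates its input", {
  expect_s3_class(default_feature_space(), "feature_space")
  expect_error(
    feature_space(list(d = list(values = c("x", "x"), neutral = "x"))),
    "duplicate")
  expect_error(
    feature_space(list(d = list(values = c("a", "b"), neutral = "z"))),
    "neutral")
  expect_error(
    feature_space(list(d = list(values = character(0), neutral = "a"))),
    "no values")
  expect_error(feature_space(list()), "non-empty")
})

test_that("default space has the canonical cardinalities and neutrals", {
  fs <- default_feature_space()
  card <- vapply(fs$dimensions, function(d) length(d$values), integer(1))
  expect_equal(unname(card), c(9L, 8L, 11L, 9L))
  expect_equal(
    neutral_values(fs),
    c(body_shape = "spherical", color = "gray",
      arm_type = "straight_blunt", surface_pattern = "uniform"))
  expect_equal(n_objects(fs), 7128)
})

test_that("enumeration is exhaustive, unique and lexicographic", {
  # product rule + uniqueness on randomized small spaces (property test)
  set.seed(42)
  for (rep in 1:5) {
    dims <- lapply(seq_len(sample(2:4, 1)), function(i) {
      k <- sample(1:4, 1)
      vals <- paste0("v", seq_len(k))
      list(values = vals, neutral = vals[1])
    })
    names(dims) <- paste0("d", seq_along(dims))
    fs <- feature_space(dims)
    objs <- enumerate_objects(fs)
    expect_equal(nrow(objs), n_objects(fs))
    expect_equal(anyDuplicated(objs), 0L)
  }
  # declared order, last dimension fastest
  fs <- toy_space()
  objs <- enumerate_objects(fs)
  expect_equal(objs$arms[1:2], c("blunt", "spike"))
  expect_equal(objs$shape[1], "sph")
  expect_equal(nrow(objs), 12)
  # identity case: one value per dimension
  fs1 <- feature_space(list(a = list(values = "x", neutral = "x"),
                            b = list(values = "y", neutral = "y")))
  expect_equal(nrow(enumerate_objects(fs1)), 1)
})

test_that("exactly one fully neutral object exists (brute-force scan)", {
  fs <- default_feature_space()
  objs <- enumerate_objects(fs)
  flags <- vapply(seq_len(nrow(objs)), function(i) {
    neutral_dimension_count(objs[i, ], fs)$fully_neutral
  }, logical(1))
  expect_equal(sum(flags), 1L)
  nd <- neutral_dimension_count(neutral_object(fs), fs)
  expect_equal(nd$count, 4L)
  expect_true(nd$fully_neutral)
  # differ in color only -> count 3
  obj <- neutral_object(fs); obj[["color"]] <- "red"
  nd <- neutral_dimension_count(obj, fs)
  expect_equal(nd$count, 3L)
  expect_false(nd$fully_neutral)
  # membership violation
  obj[["color"]] <- "magenta"
  expect_error(neutral_dimension_count(obj, fs), "not in dimension")
})

test_that("color palette is equidistant at fixed lightness and chroma", {
  pal <- make_color_palette(8, L = 70, C = 40)
  expect_equal(nrow(pal), 8)
  expect_equal(pal$L, rep(70, 8))
  expect_equal(sqrt(pal$a^2 + pal$b^2), rep(40, 8), tolerance = 1e-12)
  d_adj <- sqrt(diff(c(pal$a, pal$a[1]))^2 + diff(c(pal$b, pal$b[1]))^2)
  expect_lt(max(d_adj) - min(d_adj), 1e-9)
  # diametric pair at n = 2 is 2C apart
  p2 <- make_color_palette(2, C = 40)
  expect_equal(sqrt(diff(p2$a)^2 + diff(p2$b)^2), 80, tolerance = 1e-9)
  # rotating the hue origin preserves pairwise distances
  palr <- make_color_palette(8, L = 70, C = 40, hue0 = 33)
  expect_equal(dist(cbind(palr$a, palr$b)), dist(cbind(pal$a, pal$b)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(make_color_palette(0), "n must be")
  expect_error(make_color_palette(8, C = 0), "chroma")
})

test_that("sample_target honors k_nonneutral and forced-neutral dims", {
  fs <- default_feature_space()
  set.seed(1)
  expect_equal(unname(sample_target(fs, 0)), unname(neutral_object(fs)))
  for (i in 1:20) {
    tg <- sample_target(fs, 3, forced_neutral_dims = "body_shape")
    expect_equal(tg[["body_shape"]], "spherical")
    expect_equal(neutral_dimension_count(tg, fs)$count, 1L)
  }
  expect_error(sample_target(fs, 4, forced_neutral_dims = "body_shape"),
               "infeasible")
  # k=1 picks dimensions uniformly (chi-square at alpha = 0.01)
  set.seed(7)
  hot <- replicate(10000, {
    tg <- sample_target(fs, 1)
    names(which(tg != neutral_values(fs)))
  })
  expect_gt(stats::chisq.test(table(hot))$p.value, 0.01)
})

test_that("search arrays meet the exact-shared-count contract", {
  fs <- default_feature_space()
  set.seed(5)
  for (ns in 1:3) {
    tg <- sample_target(fs, 3, "body_shape")
    arr <- sample_search_array(fs, tg, 12, n_shared = ns)
    expect_equal(nrow(arr), 12)
    expect_equal(anyDuplicated(arr), 0L)
    for (i in seq_len(nrow(arr))) {
      expect_equal(oracle_shared_count(arr[i, ], tg), ns)
      expect_false(neutral_dimension_count(arr[i, ], fs)$fully_neutral)
    }
  }
  expect_error(sample_search_array(fs, tg, 3, n_shared = 4), "n_shared")
  # pigeonhole: toy space admits few descriptors at n_shared = 2
  ts <- toy_space()
  tg2 <- c(shape = "cub", color = "red", arms = "spike")
  expect_error(sample_search_array(ts, tg2, 10000, n_shared = 2),
               "infeasible")
})

test_that("learning arrays carry exactly one rewarded object", {
  fs <- default_feature_space()
  set.seed(11)
  # 1-dimension variation: all other dims neutral, pairwise distinct values
  arr <- sample_learning_array(fs, "body_shape", "oblong", 3, "body_shape")
  expect_equal(anyDuplicated(arr$body_shape), 0L)
  expect_true(all(arr$color == "gray"))
  expect_true(all(arr$surface_pattern == "uniform"))
  expect_equal(sum(arr$body_shape == "oblong"), 1L)
  # distinctness across varied dims over many samples
  varied <- c("color", "arm_type", "surface_pattern")
  for (i in 1:200) {
    a <- sample_learning_array(fs, "color", "blue", 3, varied)
    for (d in varied) expect_equal(anyDuplicated(a[[d]]), 0L)
    expect_equal(sum(a$color == "blue"), 1L)
    expect_true(all(a$body_shape == "spherical"))
  }
  # rewarded position is not fixed
  set.seed(2)
  pos <- replicate(200, attr(
    sample_learning_array(fs, "color", "red", 3, "color"), "rewarded_index"))
  expect_setequal(unique(pos), 1:3)
  expect_error(sample_learning_array(fs, "color", "gray", 3, "color"),
               "non-neutral")
  expect_error(sample_learning_array(fs, "color", "red", 9, "color"),
               "too few")
  expect_error(sample_learning_array(fs, "color", "red", 3, "body_shape"),
               "varied_dims")
})

test_that("sampling is reproducible under a fixed seed", {
  fs <- default_feature_space()
  draw <- function() {
    set.seed(123)
    tg <- sample_target(fs, 3, "body_shape")
    list(tg, sample_search_array(fs, tg, 9, 2),
         sample_learning_array(fs, "arm_type", "spiral", 3,
                               c("arm_type", "color")))
  }
  expect_identical(draw(), draw())
})

test_that("feature-space files round-trip", {
  fs <- toy_space()
  path <- withr::local_tempfile(fileext = ".json")
  write_feature_space(fs, path)
  expect_identical(read_feature_space(path), fs)
})

test_that("palette CSV export writes the Lab and sRGB columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_palette_csv(make_color_palette(8), path)
  re <- utils::read.csv(path)
  expect_equal(nrow(re), 8)
  expect_true(all(c("label", "L", "a", "b", "hex") %in% names(re)))
})
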