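test_that("t thresholds reproduce the method constants at df = 60", {
  tt <- t_thresholds()
  expect_equal(tt$t_cut,
               c(1.671, 2.000, 2.390, 2.660, 2.915, 3.232, 3.460))
  expect_identical(t_thresholds(60, 0.5)$t_cut, 0)
  expect_true(all(diff(tt$t_cut) > 0))
  expect_error(t_thresholds(60, 0.7), class = "bowsvm_domain_error")
  expect_error(t_thresholds(0, 0.05), class = "bowsvm_domain_error")
})

test_that("the 14 signed ranges carry the printed boundary conventions", {
  rng <- make_ranges()
  expect_identical(nrow(rng), 14L)
  expect_identical(rng$lo[1], -Inf)
  expect_identical(rng$hi[14], Inf)
  hit <- function(v) which(vapply(seq_len(14), function(k)
    in_range(v, rng[k, ]), logical(1)))
  expect_identical(hit(2.000), 9L)    # [2.000, 2.390), not [1.671, 2.000)
  expect_identical(hit(-2.000), 6L)   # (-2.390, -2.000], not (-2.000, -1.671]
  expect_identical(hit(1.671), 8L)
  expect_identical(hit(10), 14L)
  expect_identical(hit(-10), 1L)
  expect_length(hit(1.5), 0)
  expect_error(make_ranges(t_thresholds(p = c(0.05, 0.01))),
               class = "bowsvm_config_error")
})

test_that("every suprathreshold value falls in exactly one range", {
  rng <- make_ranges()
  set.seed(1)
  v <- c(rnorm(500, 0, 3), 1.671, -1.671, 3.460, -3.460, 2, -2)
  counts <- rowSums(vapply(seq_len(14), function(k) in_range(v, rng[k, ]),
                           logical(length(v))))
  expect_true(all(counts[abs(v) >= 1.671] == 1))
  expect_true(all(counts[abs(v) < 1.671] == 0))
})

test_that("26-connectivity components match the definitional examples", {
  a <- array(FALSE, c(4, 4, 4))
  a[1:2, 1:2, 1:2] <- TRUE
  expect_length(connected_components(a), 1)
  expect_identical(nrow(connected_components(a)[[1]]), 8L)

  b <- array(FALSE, c(4, 4, 4))
  b[1, 1, 1] <- TRUE; b[2, 2, 2] <- TRUE  # corner adjacency counts
  expect_length(connected_components(b), 1)

  c3 <- array(FALSE, c(4, 4, 4))
  c3[1, 1, 1] <- TRUE; c3[3, 1, 1] <- TRUE
  expect_length(connected_components(c3), 2)

  expect_length(connected_components(array(FALSE, c(4, 4, 4))), 0)
})

test_that("component labeling agrees with a BFS flood-fill oracle", {
  set.seed(42)
  for (i in 1:25) {
    sel <- array(runif(16^3) < runif(1, 0.02, 0.2), c(16, 16, 16))
    mine <- lapply(bowsvm:::cc_linear(which(sel), dim(sel)), sort)
    oracle <- bfs_components(sel)
    expect_identical(mine, oracle)
  }
})

make_blob_map <- function(value = 2.5, id = "s1") {
  v <- array(0, c(10, 10, 10))
  v[4:6, 5, 5] <- value
  v[5, 6, 5] <- value
  v[5, 5, 6] <- value
  contrast_map(v, id)
}

test_that("dictionary building follows the harvesting rules", {
  zero <- contrast_map(array(0, c(8, 8, 8)), "z")
  expect_length(build_dictionary(list(zero))$words, 0)

  blob <- make_blob_map(2.5)
  d <- build_dictionary(list(blob))
  expect_length(d$words, 1)
  expect_identical(lengths(d$words), 5L)
  rng <- d$ranges[d$word_info$range_id, ]
  expect_identical(c(rng$lo, rng$hi), c(2.390, 2.660))

  # duplicated subjects contribute duplicated words
  d2 <- build_dictionary(list(make_blob_map(2.5, "a"), make_blob_map(2.5, "b")))
  expect_length(d2$words, 2)
  expect_identical(d2$words[[1]], d2$words[[2]])

  small <- build_dictionary(list(blob), min_region_voxels = 6L)
  expect_length(small$words, 0)

  other_grid <- contrast_map(array(0, c(9, 9, 9)), "g")
  expect_error(build_dictionary(list(blob, other_grid)),
               class = "bowsvm_dimension_error")
})

test_that("word sets partition the selected voxels within one subject-range", {
  set.seed(7)
  v <- array(rnorm(12^3, 0, 2), c(12, 12, 12))
  m <- contrast_map(v, "p")
  d <- build_dictionary(list(m))
  rng <- d$ranges
  for (k in unique(d$word_info$range_id)) {
    sel <- sort(which(in_range(v, rng[k, ])))
    words_k <- d$words[d$word_info$range_id == k]
    expect_identical(sort(unlist(words_k)), sel)
    expect_identical(sum(lengths(words_k)), length(sel))  # disjoint
  }
})

test_that("dictionaries are append-only in the builder cohort", {
  set.seed(8)
  maps <- lapply(1:3, function(i)
    contrast_map(array(rnorm(10^3, 0, 2), c(10, 10, 10)), paste0("s", i)))
  d2 <- build_dictionary(maps[1:2])
  d3 <- build_dictionary(maps)
  expect_identical(d3$words[seq_along(d2$words)], d2$words)
})

test_that("feature extraction is the mean over fixed template voxels", {
  blob <- make_blob_map(2.5)
  d <- build_dictionary(list(blob))
  probe <- contrast_map(array(0, c(10, 10, 10)), "probe")
  probe$values[d$words[[1]][1:2]] <- c(1, 3)
  f <- extract_features(d, probe)
  expect_equal(unname(f), mean(c(1, 3, 0, 0, 0)))

  expect_equal(unname(extract_features(d, contrast_map(array(0, c(10, 10, 10)),
                                                       "z"))), 0)
  # self-consistency: the builder's own value lies inside the source range
  own <- extract_features(d, blob)
  expect_true(own >= 2.390 && own < 2.660)
  # linearity in the map
  scaled <- blob; scaled$values <- 3 * blob$values
  expect_equal(extract_features(d, scaled), 3 * extract_features(d, blob))
  expect_error(extract_features(d, contrast_map(array(0, c(9, 9, 9)), "g")),
               class = "bowsvm_dimension_error")
})

test_that("VOX features enumerate the in-mask voxels in raster order", {
  co <- generate_cohort_maps(map_sim_config(
    n_controls = 2, n_effective = 0, n_ineffective = 0, n_unlabeled = 0,
    seed = 2))
  V <- vox_features(co)
  expect_identical(ncol(V), 13824L)
  expect_identical(nrow(V), 2L)
  expect_identical(unname(V[1, 1:5]), co$maps[[1]]$values[1:5])
  # identical maps give identical rows
  twin <- list(co$maps[[1]], co$maps[[1]])
  twin[[2]]$subject_id <- "copy"
  V2 <- vox_features(twin)
  expect_identical(unname(V2[1, ]), unname(V2[2, ]))
})

test_that("dictionary JSON export writes 0-based voxel indices", {
  d <- build_dictionary(list(make_blob_map(2.5)))
  path <- withr::local_tempfile(fileext = ".json")
  write_dictionary(d, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(sort(parsed$words$voxels[[1]]), sort(d$words[[1]] - 1L))
})
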