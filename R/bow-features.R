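#' Student-t threshold table
#'
#' Upper-tail t quantiles at a set of one-sided p-values, rounded to three
#' decimals. With the method's constants (`df = 60` and the seven default
#' p-values) this reproduces the thresholds 1.671, 2.000, 2.390, 2.660,
#' 2.915, 3.232 and 3.460 that define the contrast ranges.
#'
#' @param df Degrees of freedom (> 0).
#' @param p One-sided p-values in `(0, 0.5]`, ordered from largest to
#'   smallest.
#' @return A tibble with `one_sided_p` and the threshold `t_cut`.
#' @export
t_thresholds <- function(df = 60,
                         p = c(0.05, 0.025, 0.01, 0.005, 0.0025, 0.001, 0.0005)) {
  if (df <= 0) stop_bowsvm("`df` must be > 0", "bowsvm_domain_error")
  if (any(p <= 0 | p > 0.5)) {
    stop_bowsvm("one-sided p-values must lie in (0, 0.5]",
                "bowsvm_domain_error")
  }
  p <- sort(p, decreasing = TRUE)
  tibble::tibble(one_sided_p = p, t_cut = round(qt(1 - p, df), 3))
}

#' Build the 14 signed contrast ranges
#'
#' Seven half-open positive ranges `[t_i, t_{i+1})` (the last unbounded
#' above) and their mirrored negative ranges `(lo, hi]` (the first unbounded
#' below), ordered from the most negative to the most positive. The boundary
#' conventions follow the printed interval notation: a value of exactly
#' 2.000 falls in `[2.000, 2.390)`, and -2.000 falls in `(-2.390, -2.000]`.
#'
#' @param tt A threshold table from [t_thresholds()] with exactly 7 rows.
#' @return A 14-row tibble with `range_id`, `lo`, `hi`, `sign`, `inclusion`.
#' @export
make_ranges <- function(tt = t_thresholds()) {
  t_cut <- tt$t_cut
  if (length(t_cut) != 7L || any(diff(t_cut) <= 0)) {
    stop_bowsvm("need exactly 7 strictly increasing thresholds",
                "bowsvm_config_error")
  }
  pos <- tibble::tibble(lo = t_cut, hi = c(t_cut[-1], Inf),
                        sign = "positive", inclusion = "[lo,hi)")
  neg <- tibble::tibble(lo = c(-Inf, -rev(t_cut)[-7]), hi = -rev(t_cut),
                        sign = "negative", inclusion = "(lo,hi]")
  out <- dplyr::bind_rows(neg, pos)
  dplyr::mutate(out, range_id = dplyr::row_number(), .before = 1)
}

#' Which values fall in one signed contrast range
#'
#' @param values Numeric vector or array of contrast values.
#' @param range One row of the tibble from [make_ranges()].
#' @return Logical of the same shape as `values`.
#' @export
in_range <- function(values, range) {
  if (range$sign == "positive") {
    values >= range$lo & values < range$hi
  } else {
    values > range$lo & values <= range$hi
  }
}

# internal: 26-connected components as a list of sorted linear-index vectors
cc_linear <- function(idx, dims) {
  idx <- sort(as.integer(idx))
  if (length(idx) == 0) return(list())
  labels <- label_components_26(idx, as.integer(dims))
  unname(split(idx, labels))
}

#' 26-connected components of a selected voxel set
#'
#' Partitions the selected voxels of a 3-D logical array into maximal
#' 26-connected components (each interior voxel has 26 neighbors sharing a
#' face, edge or corner). Components are ordered by their smallest contained
#' voxel in raster (x-fastest) order.
#'
#' @param selected 3-D logical array.
#' @return A list of integer matrices, one per component, each row a 1-based
#'   voxel coordinate `(x, y, z)`, rows sorted in raster order.
#' @export
connected_components <- function(selected) {
  stopifnot(is.array(selected), length(dim(selected)) == 3L)
  comps <- cc_linear(which(selected), dim(selected))
  lapply(comps, index_to_coords, dims = dim(selected))
}

#' Convert linear voxel indices to (x, y, z) coordinates
#'
#' @param idx 1-based linear indices (column-major, x fastest).
#' @param dims Grid dimensions.
#' @return Integer matrix with columns `x`, `y`, `z` (1-based).
#' @export
index_to_coords <- function(idx, dims) {
  idx0 <- as.integer(idx) - 1L
  cbind(x = idx0 %% dims[1] + 1L,
        y = (idx0 %/% dims[1]) %% dims[2] + 1L,
        z = idx0 %/% (dims[1] * dims[2]) + 1L)
}

as_map_list <- function(maps) {
  if (inherits(maps, "cohort_maps")) maps$maps
  else if (inherits(maps, "contrast_map")) list(maps)
  else maps
}

#' Build a bag-of-words dictionary from a cohort of contrast maps
#'
#' For every builder subject and every signed contrast range, selects the
#' in-mask voxels whose value falls in the range, splits them into
#' 26-connected components, and appends each component of at least
#' `min_region_voxels` voxels to the dictionary as a word (a "characteristic
#' contrast region"). Words are kept in a deterministic order: builder
#' subject, then range, then smallest contained voxel. Identical regions
#' occurring in several subjects yield multiple copies — duplicates are
#' intentional and mirror the redundancy of the vocabulary.
#'
#' @param maps A `cohort_maps` object or list of [contrast_map()]s sharing
#'   one grid and affine.
#' @param ranges Contrast ranges from [make_ranges()].
#' @param min_region_voxels Minimum component size kept as a word.
#' @return A `bow_dictionary`: `words` (list of linear-index vectors),
#'   `word_info` (tibble with provenance), grid metadata and the builder
#'   cohort.
#' @export
build_dictionary <- function(maps, ranges = make_ranges(),
                             min_region_voxels = 1L) {
  maps <- as_map_list(maps)
  stopifnot(length(maps) > 0)
  dims <- dim(maps[[1]]$values)
  for (m in maps) {
    if (!same_grid(m, maps[[1]])) {
      stop_bowsvm("all maps entering one dictionary must share grid and affine",
                  "bowsvm_dimension_error")
    }
  }
  words <- list()
  info <- list()
  for (m in maps) {
    vals <- m$values
    masked <- which(m$mask)
    v <- vals[masked]
    for (k in seq_len(nrow(ranges))) {
      rng <- ranges[k, ]
      sel <- masked[in_range(v, rng)]
      comps <- cc_linear(sel, dims)
      comps <- comps[lengths(comps) >= min_region_voxels]
      if (length(comps) == 0) next
      words <- c(words, comps)
      info[[length(info) + 1L]] <- tibble::tibble(
        subject_id = m$subject_id, range_id = rng$range_id,
        n_voxels = lengths(comps),
        min_index = vapply(comps, `[`, integer(1), 1L))
    }
  }
  word_info <- if (length(info)) dplyr::bind_rows(info) else
    tibble::tibble(subject_id = character(), range_id = integer(),
                   n_voxels = integer(), min_index = integer())
  word_info <- dplyr::mutate(word_info, word_id = dplyr::row_number(),
                             .before = 1)
  structure(list(words = words, word_info = word_info, grid = dims,
                 affine = maps[[1]]$affine,
                 contrast_name = maps[[1]]$contrast_name,
                 builder_cohort = vapply(maps, `[[`, character(1), "subject_id"),
                 ranges = ranges),
            class = "bow_dictionary")
}

#' @export
print.bow_dictionary <- function(x, ...) {
  cat("<bow_dictionary>", length(x$words), "words from",
      length(x$builder_cohort), "builder subjects |", x$contrast_name,
      "| grid", paste(x$grid, collapse = "x"), "\n")
  invisible(x)
}

#' @export
length.bow_dictionary <- function(x) length(x$words)

#' Extract one subject's bag-of-words feature row
#'
#' Feature j is the arithmetic mean of this map's contrast values over word
#' j's fixed template-space voxel set — the word's own coordinates are used
#' regardless of where this map's values exceed any threshold, so the
#' extraction is linear in the map.
#'
#' @param dictionary A [build_dictionary()] result.
#' @param map A [contrast_map()] on the dictionary's grid.
#' @return Named numeric vector of length `length(dictionary)`.
#' @export
extract_features <- function(dictionary, map) {
  stopifnot(inherits(dictionary, "bow_dictionary"))
  if (!identical(dim(map$values), dictionary$grid)) {
    stop_bowsvm("map grid does not match dictionary grid",
                "bowsvm_dimension_error")
  }
  nw <- length(dictionary$words)
  if (nw == 0) return(setNames(numeric(0), character(0)))
  all_idx <- unlist(dictionary$words, use.names = FALSE)
  grp <- rep.int(seq_len(nw), lengths(dictionary$words))
  sums <- rowsum(map$values[all_idx], grp, reorder = TRUE)
  f <- as.numeric(sums) / lengths(dictionary$words)
  setNames(f, paste0("w", seq_len(nw)))
}

#' Bag-of-words feature matrix for a cohort
#'
#' @param dictionary A [build_dictionary()] result.
#' @param maps A `cohort_maps` object or list of maps to featurize (rows).
#' @return A `feature_matrix`: numeric matrix (subjects x words) with the
#'   dictionary in `attr(, "provenance")` and `attr(, "feature_type")`.
#' @export
featurize <- function(dictionary, maps) {
  maps <- as_map_list(maps)
  rows <- t(vapply(maps, function(m) extract_features(dictionary, m),
                   numeric(length(dictionary$words))))
  if (length(dictionary$words) == 0) {
    rows <- matrix(0, nrow = length(maps), ncol = 0)
  }
  rownames(rows) <- vapply(maps, `[[`, character(1), "subject_id")
  structure(rows, feature_type = "BoW", provenance = dictionary$word_info,
            class = c("feature_matrix", class(rows)))
}

#' Voxelwise (VOX) baseline feature matrix
#'
#' One row per subject, one column per in-mask voxel in fixed raster
#' (x-fastest) order; the mask is the intersection of all subjects' masks.
#'
#' @param maps A `cohort_maps` object or list of maps sharing one grid.
#' @return A `feature_matrix` with `feature_type = "VOX"`; column provenance
#'   (voxel linear indices) in `attr(, "provenance")`.
#' @export
vox_features <- function(maps) {
  maps <- as_map_list(maps)
  stopifnot(length(maps) > 0)
  dims <- dim(maps[[1]]$values)
  for (m in maps) {
    if (!same_grid(m, maps[[1]])) {
      stop_bowsvm("all maps must share grid and affine for VOX features",
                  "bowsvm_dimension_error")
    }
  }
  mask <- Reduce(`&`, lapply(maps, `[[`, "mask"))
  idx <- which(mask)
  rows <- t(vapply(maps, function(m) m$values[idx], numeric(length(idx))))
  rownames(rows) <- vapply(maps, `[[`, character(1), "subject_id")
  colnames(rows) <- paste0("v", idx)
  prov <- tibble::as_tibble(cbind(voxel_index = idx,
                                  index_to_coords(idx, dims)))
  structure(rows, feature_type = "VOX", provenance = prov,
            class = c("feature_matrix", class(rows)))
}

#' Write a dictionary to JSON
#'
#' Voxel indices are written 0-based for interoperability.
#'
#' @param dictionary A `bow_dictionary`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_dictionary <- function(dictionary, path) {
  obj <- list(
    contrast_name = dictionary$contrast_name,
    grid = dictionary$grid,
    builder_cohort = dictionary$builder_cohort,
    words = purrr::pmap(
      list(dictionary$word_info$word_id,
           dictionary$word_info$subject_id,
           dictionary$word_info$range_id,
           dictionary$words),
      function(id, subj, rng, vox) {
        list(word_id = id, source_subject = subj, range_id = rng,
             lo = dictionary$ranges$lo[rng], hi = dictionary$ranges$hi[rng],
             voxels = as.integer(vox) - 1L)
      })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
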