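#' Construct a multidimensional stimulus feature space
#'
#' A feature space is an ordered set of feature dimensions (e.g. body shape,
#' color, arm type, surface pattern), each carrying an ordered set of value
#' labels and exactly one *neutral* value. The neutral value is the
#' never-rewarded feature of that dimension; the single object that is neutral
#' on every dimension plays a special role in task logic (touching it aborts a
#' trial).
#'
#' @param dimensions Named list. Each element is a list with components
#'   `values` (character vector of unique value labels) and `neutral` (one
#'   element of `values`).
#' @return An object of class `feature_space`: a list with element
#'   `dimensions` (the validated input) plus convenience accessors via
#'   [dimension_names()], [dimension_values()], [neutral_values()].
#' @seealso [default_feature_space()] for the canonical Quaddle space.
#' @examples
#' fs <- feature_space(list(
#'   shape = list(values = c("sphere", "cube"), neutral = "sphere"),
#'   color = list(values = c("gray", "red"),   neutral = "gray")
#' ))
#' n_objects(fs)  # 4
#' @export
feature_space <- function(dimensions) {
  if (!is.list(dimensions) || length(dimensions) < 1L) {
    stop("`dimensions` must be a non-empty named list", call. = FALSE)
  }
  if (is.null(names(dimensions)) || anyNA(names(dimensions)) ||
      any(names(dimensions) == "") || anyDuplicated(names(dimensions))) {
    stop("every dimension must have a unique non-empty name", call. = FALSE)
  }
  for (nm in names(dimensions)) {
    d <- dimensions[[nm]]
    if (!is.list(d) || is.null(d$values) || is.null(d$neutral)) {
      stop(sprintf("dimension '%s' must have `values` and `neutral`", nm),
           call. = FALSE)
    }
    vals <- as.character(d$values)
    if (length(vals) < 1L) {
      stop(sprintf("dimension '%s' has no values", nm), call. = FALSE)
    }
    if (anyDuplicated(vals)) {
      stop(sprintf("duplicate value labels in dimension '%s'", nm),
           call. = FALSE)
    }
    neutral <- as.character(d$neutral)
    if (length(neutral) != 1L || !neutral %in% vals) {
      stop(sprintf("neutral value of dimension '%s' is not one of its values",
                   nm), call. = FALSE)
    }
    dimensions[[nm]] <- list(values = vals, neutral = neutral)
  }
  structure(list(dimensions = dimensions), class = "feature_space")
}

#' The canonical four-dimensional Quaddle feature space
#'
#' Nine body shapes, eight colors, eleven arm types, and nine surface
#' patterns, giving 9 x 8 x 11 x 9 = 7,128 unique objects. The neutral
#' (never-rewarded) features are the spherical body shape, gray color,
#' straight blunt arms, and uniform surface pattern. Value labels other than
#' the neutral ones are package-chosen mnemonics; the task machinery treats
#' them as opaque symbols.
#'
#' @return A `feature_space` with cardinalities (9, 8, 11, 9).
#' @export
default_feature_space <- function() {
  feature_space(list(
    body_shape = list(
      values = c("spherical", "oblong", "cubic", "pyramidal", "cylindrical",
                 "star", "ring", "peanut", "egg"),
      neutral = "spherical"),
    color = list(
      values = c("gray", "red", "orange", "yellow", "green", "cyan", "blue",
                 "purple"),
      neutral = "gray"),
    arm_type = list(
      values = c("straight_blunt", "straight_pointed", "curved_blunt",
                 "curved_pointed", "short_blunt", "short_pointed",
                 "long_blunt", "long_pointed", "spiral", "forked", "knobbed"),
      neutral = "straight_blunt"),
    surface_pattern = list(
      values = c("uniform", "stripes", "dots", "checker", "waves", "grid",
                 "swirl", "hexagons", "gradient"),
      neutral = "uniform")
  ))
}

#' @export
print.feature_space <- function(x, ...) {
  card <- vapply(x$dimensions, function(d) length(d$values), integer(1))
  cat("Feature space with", length(card), "dimensions,",
      format(prod(card), big.mark = ","), "objects\n")
  for (nm in names(x$dimensions)) {
    d <- x$dimensions[[nm]]
    cat(sprintf("  %-16s %2d values (neutral: %s)\n",
                nm, length(d$values), d$neutral))
  }
  invisible(x)
}

#' Feature-space accessors
#'
#' @param space A [feature_space()].
#' @param dim A dimension name (for `dimension_values`).
#' @return `dimension_names`: character vector of dimension names.
#'   `dimension_values`: value labels of one dimension.
#'   `neutral_values`: named character vector, one neutral label per
#'   dimension. `n_objects`: product of dimension cardinalities.
#' @export
dimension_names <- function(space) names(space$dimensions)

#' @rdname dimension_names
#' @export
dimension_values <- function(space, dim) {
  d <- space$dimensions[[dim]]
  if (is.null(d)) stop(sprintf("no dimension '%s' in space", dim), call. = FALSE)
  d$values
}

#' @rdname dimension_names
#' @export
neutral_values <- function(space) {
  vapply(space$dimensions, function(d) d$neutral, character(1))
}

#' @rdname dimension_names
#' @export
n_objects <- function(space) {
  prod(vapply(space$dimensions, function(d) length(d$values), integer(1)))
}

non_neutral_values <- function(space, dim) {
  d <- space$dimensions[[dim]]
  setdiff(d$values, d$neutral)
}

#' Enumerate every object in a feature space
#'
#' Objects ("Quaddle descriptors") are represented as one value label per
#' dimension. Enumeration is lexicographic: dimensions in declared order,
#' values in declared order, with the last dimension varying fastest.
#'
#' @param space A [feature_space()].
#' @return A data.frame with one column per dimension and one row per object;
#'   row count equals [n_objects()].
#' @examples
#' nrow(enumerate_objects(default_feature_space()))  # 7128
#' @export
enumerate_objects <- function(space) {
  validate_space(space)
  vals <- lapply(space$dimensions, function(d) d$values)
  # expand.grid varies the FIRST factor fastest; reverse to get
  # last-dimension-fastest lexicographic order.
  g <- expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(vals)), drop = FALSE]
  names(g) <- names(vals)
  rownames(g) <- NULL
  g
}

validate_space <- function(space) {
  if (!inherits(space, "feature_space")) {
    stop("expected a `feature_space` object", call. = FALSE)
  }
  invisible(space)
}

validate_descriptor <- function(obj, space) {
  validate_space(space)
  dims <- dimension_names(space)
  obj <- as_descriptor(obj, space)
  for (nm in dims) {
    if (!obj[[nm]] %in% space$dimensions[[nm]]$values) {
      stop(sprintf("value '%s' is not in dimension '%s'", obj[[nm]], nm),
           call. = FALSE)
    }
  }
  obj
}

# Accept a named character vector or a 1-row data.frame; return a named
# character vector ordered like the space's dimensions.
as_descriptor <- function(obj, space) {
  dims <- dimension_names(space)
  if (is.data.frame(obj)) {
    if (nrow(obj) != 1L) stop("descriptor must be a single object", call. = FALSE)
    v <- vapply(obj[1, , drop = FALSE], as.character, character(1))
  } else {
    v <- as.character(obj)
    names(v) <- names(obj)
  }
  if (!is.null(names(v)) && all(dims %in% names(v))) {
    v <- v[dims]
  } else if (length(v) == length(dims)) {
    names(v) <- dims
  } else {
    stop("descriptor does not match the space's dimensions", call. = FALSE)
  }
  v
}

#' The unique all-neutral object of a space
#'
#' @param space A [feature_space()].
#' @return Named character vector, one neutral value per dimension.
#' @export
neutral_object <- function(space) {
  validate_space(space)
  neutral_values(space)
}

#' Count neutral dimensions of an object
#'
#' An object with all dimensions neutral is the unique "blank" Quaddle;
#' touching it aborts a trial without reward.
#'
#' @param obj A descriptor: named character vector (one value per dimension)
#'   or 1-row data.frame.
#' @param space The object's [feature_space()].
#' @return List with `count` (integer, number of neutral dimensions) and
#'   `fully_neutral` (logical).
#' @export
neutral_dimension_count <- function(obj, space) {
  obj <- validate_descriptor(obj, space)
  cnt <- sum(obj == neutral_values(space))
  list(count = as.integer(cnt),
       fully_neutral = cnt == length(dimension_names(space)))
}

is_fully_neutral <- function(obj, space) {
  all(as_descriptor(obj, space) == neutral_values(space))
}

#' Sample a target object with a fixed number of non-neutral dimensions
#'
#' Draws a descriptor with exactly `k_nonneutral` non-neutral dimensions.
#' Dimensions listed in `forced_neutral_dims` are pinned to their neutral
#' value (e.g. targets keep the neutral spherical body shape in the
#' conjunction-search regime); the non-neutral dimensions are chosen uniformly
#' among the remaining dimensions and their values uniformly among that
#' dimension's non-neutral values. Uses R's global RNG; call `set.seed()`
#' for reproducibility.
#'
#' @param space A [feature_space()].
#' @param k_nonneutral Integer in `[0, n_dims - length(forced_neutral_dims)]`.
#' @param forced_neutral_dims Character vector of dimension names held neutral.
#' @return A descriptor (named character vector).
#' @export
sample_target <- function(space, k_nonneutral,
                          forced_neutral_dims = character(0)) {
  validate_space(space)
  dims <- dimension_names(space)
  if (!all(forced_neutral_dims %in% dims)) {
    stop("unknown dimension in `forced_neutral_dims`", call. = FALSE)
  }
  free <- setdiff(dims, forced_neutral_dims)
  k_nonneutral <- as.integer(k_nonneutral)
  if (k_nonneutral < 0L || k_nonneutral > length(free)) {
    stop(sprintf(
      "k_nonneutral = %d infeasible with %d free dimensions",
      k_nonneutral, length(free)), call. = FALSE)
  }
  obj <- neutral_values(space)
  hot <- if (k_nonneutral > 0L) sample(free, k_nonneutral) else character(0)
  for (nm in hot) {
    obj[[nm]] <- sample_one(non_neutral_values(space, nm))
  }
  obj
}

# sample() with length-1 x means sample.int(x); avoid that trap
sample_one <- function(x) x[sample.int(length(x), 1L)]

# Number of descriptors sharing exactly `n_shared` dimension values with
# `target`, excluding the target itself; optionally excluding the fully
# neutral object. Used for feasibility checks before rejection sampling.
count_sharing_exactly <- function(space, target, n_shared,
                                  exclude_neutral = TRUE) {
  dims <- dimension_names(space)
  card <- vapply(space$dimensions, function(d) length(d$values), integer(1))
  subs <- utils::combn(length(dims), n_shared, simplify = FALSE)
  total <- 0
  for (s in subs) {
    total <- total + prod(card[-s] - 1)
  }
  if (exclude_neutral) {
    neu <- neutral_values(space)
    if (sum(neu == target) == n_shared) total <- total - 1
  }
  total
}

#' Sample a visual-search distractor array
#'
#' Every distractor shares exactly `n_shared` feature values with the target
#' (value match within the same dimension), none equals the target, none is
#' the fully neutral object, and all are mutually distinct. Target-distractor
#' similarity (`n_shared` of 1--3 in the four-dimensional space) sets the
#' conjunction-search difficulty.
#'
#' @param space A [feature_space()].
#' @param target Target descriptor.
#' @param n_distractors Number of distractors to draw.
#' @param n_shared Exact number of shared feature values, in
#'   `[1, n_dims - 1]`.
#' @param max_tries Rejection-sampling attempt cap per distractor.
#' @return Data.frame of `n_distractors` descriptors (one row each).
#' @export
sample_search_array <- function(space, target, n_distractors, n_shared,
                                max_tries = 1000L) {
  target <- validate_descriptor(target, space)
  dims <- dimension_names(space)
  nd <- length(dims)
  n_shared <- as.integer(n_shared)
  if (n_shared < 1L || n_shared >= nd) {
    stop(sprintf("n_shared must be in [1, %d] (n_shared = n_dims would duplicate the target)",
                 nd - 1L), call. = FALSE)
  }
  avail <- count_sharing_exactly(space, target, n_shared)
  if (n_distractors > avail) {
    stop(sprintf(
      "infeasible: only %d distinct descriptors share exactly %d features with the target",
      avail, n_shared), call. = FALSE)
  }
  seen <- character(0)
  out <- vector("list", n_distractors)
  for (i in seq_len(n_distractors)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      shared <- sample(dims, n_shared)
      d <- target
      for (nm in setdiff(dims, shared)) {
        d[[nm]] <- sample_one(setdiff(space$dimensions[[nm]]$values,
                                      target[[nm]]))
      }
      key <- paste(d, collapse = "\r")
      if (!key %in% seen && !is_fully_neutral(d, space)) {
        seen <- c(seen, key)
        out[[i]] <- d
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("feasibility exhausted while sampling distinct distractors",
           call. = FALSE)
    }
  }
  descriptor_frame(out, space)
}

descriptor_frame <- function(desc_list, space) {
  dims <- dimension_names(space)
  df <- as.data.frame(
    do.call(rbind, lapply(desc_list, function(d) d[dims])),
    stringsAsFactors = FALSE)
  names(df) <- dims
  rownames(df) <- NULL
  df
}

#' Sample a feature-reward learning array
#'
#' Builds the object set for one trial of the flexible feature-reward
#' learning task: `n_objects` objects that are neutral in every non-varied
#' dimension and take pairwise-distinct non-neutral values within each varied
#' dimension. Exactly one object carries the block's rewarded feature value.
#'
#' @param space A [feature_space()].
#' @param rewarded_dim Dimension of the rewarded feature; must be in
#'   `varied_dims`.
#' @param rewarded_value Non-neutral value of `rewarded_dim`.
#' @param n_objects Number of objects on the display (default 3).
#' @param varied_dims Character vector of 1--3 dimensions that vary across
#'   objects; difficulty grows with its size.
#' @return Data.frame of descriptors; attribute `rewarded_index` gives the
#'   row carrying the rewarded value.
#' @export
sample_learning_array <- function(space, rewarded_dim, rewarded_value,
                                  n_objects = 3L,
                                  varied_dims = rewarded_dim) {
  validate_space(space)
  dims <- dimension_names(space)
  if (!all(varied_dims %in% dims)) stop("unknown varied dimension", call. = FALSE)
  if (!rewarded_dim %in% varied_dims) {
    stop("`rewarded_dim` must be one of `varied_dims`", call. = FALSE)
  }
  if (identical(rewarded_value, space$dimensions[[rewarded_dim]]$neutral)) {
    stop("rewarded value must be non-neutral", call. = FALSE)
  }
  if (!rewarded_value %in% non_neutral_values(space, rewarded_dim)) {
    stop("rewarded value not in rewarded dimension", call. = FALSE)
  }
  n_objects <- as.integer(n_objects)
  for (nm in varied_dims) {
    if (n_objects > length(non_neutral_values(space, nm))) {
      stop(sprintf("dimension '%s' has too few non-neutral values for %d objects",
                   nm, n_objects), call. = FALSE)
    }
  }
  cols <- list()
  for (nm in dims) {
    if (nm %in% varied_dims) {
      pool <- non_neutral_values(space, nm)
      if (nm == rewarded_dim) {
        others <- sample(setdiff(pool, rewarded_value), n_objects - 1L)
        v <- sample(c(rewarded_value, others))  # permute reward position
      } else {
        v <- sample(pool, n_objects)
      }
    } else {
      v <- rep(space$dimensions[[nm]]$neutral, n_objects)
    }
    cols[[nm]] <- v
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  attr(df, "rewarded_index") <- which(df[[rewarded_dim]] == rewarded_value)
  df
}

#' Equidistant CIELAB color palette
#'
#' `n` colors at equal hue increments (360/n degrees, starting at `hue0`) on
#' the circle of radius `C` (chroma) in the a*b* plane at lightness `L`. On a
#' fixed-chroma, fixed-lightness circle, equal hue steps give equal Euclidean
#' Lab distances between adjacent colors, realizing perceptual equidistance.
#'
#' @param n Number of colors (>= 1).
#' @param L CIELAB lightness in `[0, 100]` (default 70).
#' @param C Chroma radius, > 0 (default 40).
#' @param hue0 Hue origin in degrees (default 0).
#' @return Data.frame with columns `label`, `L`, `a`, `b`, and sRGB
#'   convenience columns `hex`, `R`, `G`, `B` (via [grDevices::convertColor]).
#' @examples
#' pal <- make_color_palette(8)
#' all(abs(sqrt(pal$a^2 + pal$b^2) - 40) < 1e-12)
#' @export
make_color_palette <- function(n, L = 70, C = 40, hue0 = 0) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (C <= 0) stop("chroma C must be > 0", call. = FALSE)
  if (L < 0 || L > 100) stop("lightness L must be in [0, 100]", call. = FALSE)
  hue <- (hue0 + 360 * (seq_len(n) - 1L) / n) * pi / 180
  lab <- cbind(L = rep(L, n), a = C * cos(hue), b = C * sin(hue))
  rgb01 <- grDevices::convertColor(lab, from = "Lab", to = "sRGB",
                                   clip = TRUE)
  data.frame(
    label = sprintf("c%02d", seq_len(n)),
    L = lab[, "L"], a = lab[, "a"], b = lab[, "b"],
    R = rgb01[, 1], G = rgb01[, 2], B = rgb01[, 3],
    hex = grDevices::rgb(rgb01[, 1], rgb01[, 2], rgb01[, 3]),
    stringsAsFactors = FALSE)
}

#' Export a palette to CSV
#'
#' @param palette Output of [make_color_palette()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_palette_csv <- function(palette, path) {
  utils::write.csv(palette, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a feature-space definition file
#'
#' The on-disk format is JSON: an object mapping dimension names to
#' `{"values": [...], "neutral": "..."}`. Round-trips losslessly.
#'
#' @param space A [feature_space()] (for writing).
#' @param path File path.
#' @return `read_feature_space` returns a validated [feature_space()];
#'   `write_feature_space` returns `path` invisibly.
#' @export
write_feature_space <- function(space, path) {
  validate_space(space)
  jsonlite::write_json(space$dimensions, path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_space
#' @export
read_feature_space <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  feature_space(lapply(raw, function(d) {
    list(values = as.character(d$values), neutral = as.character(d$neutral))
  }))
}
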