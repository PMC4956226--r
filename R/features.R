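#' Parametrize labelled segments into the 30-feature dataset
#'
#' Computes the feature vector of every segment row and returns the tidy
#' feature table that the classifier harnesses consume. By default the raw
#' features are passed through [transform_features()] (count normalization
#' plus the skew-reducing monotone maps).
#'
#' @param segments labelled segment tibble (typically
#'   `label_segments(...)` filtered to retained rows).
#' @param features which features to compute (default all 30); computing a
#'   subset only evaluates the transforms that subset needs.
#' @param transform apply [transform_features()] to the raw values.
#' @param fs sampling rate of the segment samples.
#' @return tibble with identifier columns (`patient_id`, `record_id`,
#'   `segment_id`, `duration`, `label` when present) and one column per
#'   feature.
#' @export
extract_features <- function(segments, features = feature_names(),
                             transform = TRUE, fs = 250) {
  stopifnot(all(features %in% feature_names()))
  funs <- feature_funs()[features]
  vals <- map(segments$samples, function(x) {
    ctx <- feature_context(x, fs)
    vapply(funs, function(f) f(ctx), numeric(1))
  })
  mat <- do.call(rbind, vals)
  meta <- segments |>
    select(dplyr::any_of(c(
      "patient_id", "record_id", "segment_id", "duration", "source_rhythm",
      "label"
    )))
  out <- bind_cols(meta, as_tibble(as.data.frame(mat)))
  if (transform) {
    ns <- lengths(segments$samples)
    out <- transform_features(out, window_samples = ns)
  }
  out
}

features_to_transform <- c("Kurt", "M", "A1", "x1", "x3", "x5", "Count3")
count_features <- c("Count1", "Count2", "Count3")

#' Normalize and variance-stabilise raw feature values
#'
#' `Count1`--`Count3` are divided by the number of samples in the window
#' (turning raw counts into fractions of the segment), then the seven
#' right-skewed nonnegative features `Kurt`, `M`, `A1`, `x1`, `x3`, `x5`
#' and `Count3` are passed through `log(1 + v)` -- a fixed, strictly
#' monotone map, so single-feature thresholds and rank-based analyses are
#' unaffected. Everything else is returned unchanged.
#'
#' @param raw a named numeric vector of raw features, or a feature tibble
#'   from [extract_features()].
#' @param duration segment duration in seconds (used with `fs` when
#'   `window_samples` is not given).
#' @param fs sampling rate in Hz.
#' @param window_samples number of samples per window (scalar or one per
#'   row); overrides `duration`.
#' @return object of the same shape with transformed values.
#' @export
transform_features <- function(raw, duration = NULL, fs = 250,
                               window_samples = NULL) {
  n <- window_samples %||% (duration * fs)
  if (is.null(n)) {
    abort("supply `duration` or `window_samples`", class = "shockable_error")
  }
  apply_one <- function(tab, col, f) {
    if (col %in% names(tab)) tab[[col]] <- f(tab[[col]])
    tab
  }
  if (is.numeric(raw) && !is.null(names(raw))) {
    tab <- as.list(raw)
    for (cn in intersect(count_features, names(tab))) {
      tab[[cn]] <- tab[[cn]] / n
    }
    for (cn in intersect(features_to_transform, names(tab))) {
      tab[[cn]] <- log1p(tab[[cn]])
    }
    return(unlist(tab))
  }
  tab <- raw
  for (cn in intersect(count_features, names(tab))) {
    tab[[cn]] <- tab[[cn]] / n
  }
  for (cn in intersect(features_to_transform, names(tab))) {
    tab[[cn]] <- log1p(tab[[cn]])
  }
  tab
}

#' Standardize features with training-set statistics
#'
#' Columns are centred and scaled to zero mean and unit variance using the
#' *training* rows only (population SD convention); the same statistics are
#' then applied to any other table. A zero-SD training column cannot be
#' scaled and is mapped to all zeros with a warning.
#'
#' @param train training feature tibble.
#' @param other optional tibble to transform with the training statistics.
#' @param cols feature columns to standardize (default: those of the 30
#'   present in `train`).
#' @return list with `train`, `other` (or `NULL`) and `stats` (tibble of
#'   per-feature mean and SD).
#' @export
standardize_features <- function(train, other = NULL,
                                 cols = intersect(feature_names(),
                                   names(train)
                                 )) {
  if (nrow(train) == 0) abort("empty training set", class = "shockable_error")
  mu <- vapply(train[cols], mean, numeric(1))
  n <- nrow(train)
  sdev <- vapply(train[cols], function(v) {
    sqrt(sum((v - mean(v))^2) / n) # population SD
  }, numeric(1))
  zero <- sdev == 0
  if (any(zero)) {
    warn(paste(
      "constant training column(s) mapped to zero:",
      paste(cols[zero], collapse = ", ")
    ))
  }
  scale_tab <- function(tab) {
    for (i in seq_along(cols)) {
      cn <- cols[i]
      tab[[cn]] <- if (zero[i]) {
        rep(0, nrow(tab))
      } else {
        (tab[[cn]] - mu[i]) / sdev[i]
      }
    }
    tab
  }
  list(
    train = scale_tab(train),
    other = if (!is.null(other)) scale_tab(other),
    stats = tibble(feature = cols, mean = mu, sd = sdev)
  )
}

# intermediate transforms each feature needs, with relative cost weights;
# used to demonstrate the computational economy of reduced subsets
feature_deps <- function() {
  list(
    bp = list(
      w = 2,
      f = c("Count1", "Count2", "Count3", "x1", "x2")
    ),
    spec = list(w = 2, f = c("M", "A1", "A2", "A3", "x3", "x4", "x5")),
    dwt = list(w = 3, f = c("bWT", "bW", "Li")),
    hilb = list(w = 2, f = "HILB"),
    sampen = list(w = 3, f = "SamEn")
  )
}

#' Relative cost of computing a feature subset
#'
#' A unit cost per feature plus the cost of each shared intermediate
#' transform (band-pass, spectrum, wavelet decomposition, analytic signal,
#' entropy search) that the subset requires. Dimensionless; used to show
#' that deployed subsets are cheaper than the full library.
#'
#' @param features character vector of feature names.
#' @param strict error on names outside the 30-feature library (default);
#'   otherwise unknown features cost one unit each.
#' @return a single numeric cost.
#' @export
feature_cost <- function(features = feature_names(), strict = TRUE) {
  if (strict) stopifnot(all(features %in% feature_names()))
  deps <- feature_deps()
  extra <- sum(vapply(deps, function(d) {
    if (any(d$f %in% features)) d$w else 0
  }, numeric(1)))
  length(features) + extra
}

#' Read and write the feature table
#'
#' Delimited table whose header names the 30 features exactly as reported
#' plus the identifier columns.
#'
#' @param features feature tibble from [extract_features()].
#' @param path CSV path.
#' @return `read_feature_table()` returns the tibble.
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
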