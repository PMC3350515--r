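#' Bootstrap confidence intervals for per-feature scores
#'
#' Percentile bootstrap for the Measure of Relevance: samples are resampled
#' with replacement within each group (matched pairs are resampled jointly
#' in the dependent design, preserving the pairing the dependent formulas
#' require), the full score is recomputed on every resample, and the
#' per-feature percentile interval is returned alongside the point
#' estimate.
#'
#' @param data A data frame, [feature_matrix()] or [simulate_features()]
#'   table.
#' @param group,pair,design As in [feature_matrix()] (ignored for a
#'   `feature_matrix` or `mor_sim` input).
#' @param features Optional character vector restricting the report to some
#'   features (all by default); the resampling itself always uses all
#'   samples.
#' @param times Number of bootstrap resamples (default 1000).
#' @param level Interval coverage (default 0.95).
#' @param seed Optional integer seed.
#' @param ... Passed on to [mor()] (e.g. `mode`, `gamma`, `weight`).
#' @return A tibble with `feature`, `estimate` (observed score), `lower`,
#'   `upper`, `times`, `level`.
#' @export
bootstrap_mor <- function(data, group = NULL, pair = NULL, design = NULL,
                          features = NULL, times = 1000, level = 0.95,
                          seed = NULL, ...) {
  stopifnot(times >= 1, level > 0, level < 1)
  fm <- if (inherits(data, "feature_matrix")) {
    data
  } else if (inherits(data, "mor_sim") && missing(group)) {
    fm_from_sim(data)
  } else {
    feature_matrix(data, group = {{ group }}, pair = {{ pair }},
                   design = design)
  }
  if (!is.null(seed)) set.seed(seed)

  obs <- mor(fm, ...)
  feats <- features %||% fm$feature_names
  missing_feats <- setdiff(feats, fm$feature_names)
  if (length(missing_feats)) {
    abort(paste0("Unknown feature(s): ",
                 paste(missing_feats, collapse = ", ")))
  }

  boot_stats <- matrix(NA_real_, times, length(feats),
                       dimnames = list(NULL, feats))
  for (b in seq_len(times)) {
    idx <- resample_indices(fm)
    fm_b <- fm
    fm_b$values <- fm$values[idx$rows, , drop = FALSE]
    fm_b$group <- fm$group[idx$rows]
    fm_b$pair_id <- idx$pair_id
    sc <- mor_engine(fm_b, ...)
    boot_stats[b, ] <- sc$mor[match(feats, sc$feature)]
  }
  lo <- (1 - level) / 2
  qs <- apply(boot_stats, 2L, quantile, probs = c(lo, 1 - lo), na.rm = TRUE,
              names = FALSE)
  tibble(
    feature = feats,
    estimate = obs$mor[match(feats, obs$feature)],
    lower = unname(qs[1L, ]),
    upper = unname(qs[2L, ]),
    times = times,
    level = level
  )
}

resample_indices <- function(fm) {
  if (fm$design == "independent") {
    g1 <- which(fm$group == levels(fm$group)[1L])
    g2 <- which(fm$group == levels(fm$group)[2L])
    rows <- c(sample(g1, length(g1), replace = TRUE),
              sample(g2, length(g2), replace = TRUE))
    list(rows = rows, pair_id = NULL)
  } else {
    lv <- levels(fm$group)
    i1 <- which(fm$group == lv[1L])
    i1 <- i1[order(fm$pair_id[i1])]
    i2 <- which(fm$group == lv[2L])
    i2 <- i2[order(fm$pair_id[i2])]
    pick <- sample(seq_along(i1), length(i1), replace = TRUE)
    rows <- c(i1[pick], i2[pick])
    # resampled pairs get fresh ids so duplicates stay distinct pairs
    list(rows = rows, pair_id = rep(seq_along(pick), 2L))
  }
}
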