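#' Biological difference of two groups on the U scale
#'
#' Difference of the two group means. On U-transformed data this is a
#' standardized location difference confined to `[-0.5, 0.5]`, attaining the
#' bounds exactly at complete separation of the groups.
#'
#' @param u1,u2 Values (usually U-transformed) of groups 1 and 2.
#' @return `mean(u1) - mean(u2)` (`NA` removed); `NA` if a group is empty.
#' @export
biological_difference <- function(u1, u2) {
  u1 <- u1[!is.na(u1)]
  u2 <- u2[!is.na(u2)]
  if (length(u1) == 0L || length(u2) == 0L) return(NA_real_)
  mean(u1) - mean(u2)
}

#' Dispersion factor of the Measure of Relevance
#'
#' Pooled dispersion of the two groups (independent design) or the standard
#' deviation of the paired differences (dependent design). Per-group
#' variances enter as empirical (1/n) variances -- the factor is not an
#' unbiased estimator of the pooled standard deviation, and is not meant to
#' be -- pooled with weights `n1 - 1` and `n2 - 1`.
#'
#' @param u1,u2 Group values; for the dependent design both must have the
#'   same length and be aligned by pair.
#' @param design `"independent"` or `"dependent"`.
#' @return Nonnegative dispersion; `NA` when not computable (fewer than two
#'   values in a group).
#' @export
dispersion_factor <- function(u1, u2, design = c("independent", "dependent")) {
  design <- match.arg(design)
  if (design == "dependent") {
    stopifnot(length(u1) == length(u2))
    d <- u1 - u2
    d <- d[!is.na(d)]
    if (length(d) < 2L) return(NA_real_)
    return(sqrt(mean(d^2) - mean(d)^2))
  }
  u1 <- u1[!is.na(u1)]
  u2 <- u2[!is.na(u2)]
  n1 <- length(u1)
  n2 <- length(u2)
  if (n1 < 2L || n2 < 2L) return(NA_real_)
  v1 <- mean((u1 - mean(u1))^2)
  v2 <- mean((u2 - mean(u2))^2)
  sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
}

#' Overlap factor for independent samples
#'
#' Two-proportion z-like statistic describing how the groups split around a
#' pooled quantile: `p_m` is the fraction of group `m` values strictly above
#' the empirical `gamma`-quantile of the pooled sample, and
#' `O = (p1 - p2) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2))` with the
#' size-weighted pooled proportion `pbar`. On untied U-transformed data
#' `pbar` equals `1 - gamma` up to the grid resolution `1/N`. Degenerate
#' splits (`pbar` 0 or 1) yield 0.
#'
#' @param u1,u2 Group values (usually U-transformed).
#' @param gamma Quantile level in (0, 1); the default 0.5 splits at the
#'   pooled median.
#' @return The overlap factor.
#' @export
overlap_independent <- function(u1, u2, gamma = 0.5) {
  stopifnot(gamma > 0, gamma < 1)
  u1 <- u1[!is.na(u1)]
  u2 <- u2[!is.na(u2)]
  n1 <- length(u1)
  n2 <- length(u2)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  q <- quantile(c(u1, u2), probs = gamma, type = 1, names = FALSE)
  p1 <- mean(u1 > q)
  p2 <- mean(u2 > q)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1) return(0)
  (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
}

#' Overlap factor for dependent (paired) samples
#'
#' Sign-balance statistic of the paired differences: among the `n'` pairs
#' with unequal values, `p1` and `p2` are the fractions of positive and
#' negative differences; tied pairs are not considered. Since `p1 + p2 = 1`
#' on the untied pairs, the pooled proportion is 0.5 and
#' `O = (p1 - p2) / sqrt(0.25 * 2 / n')`. All pairs tied yields 0.
#'
#' @param u1,u2 Paired vectors of equal length, aligned by pair.
#' @return The overlap factor.
#' @export
overlap_dependent <- function(u1, u2) {
  stopifnot(length(u1) == length(u2))
  d <- u1 - u2
  d <- d[!is.na(d)]
  n_pos <- sum(d > 0)
  n_neg <- sum(d < 0)
  np <- n_pos + n_neg
  if (np == 0L) return(0)
  (n_pos / np - n_neg / np) / sqrt(0.25 * 2 / np)
}

# Sentinel |MoR| for raw-mode features with zero dispersion but a nonzero
# location difference (constant-within-groups data).
MOR_SENTINEL <- 1e6

# Vectorized scoring over the columns of a feature_matrix.
# Returns a data.frame in input feature order.
mor_engine <- function(fm, gamma = 0.5, weight = 1, mode = "rank",
                       u_method = "midpoint") {
  values <- fm$values
  p <- ncol(values)
  um <- u_matrix(values, method = u_method)
  U <- um$u

  if (fm$design == "independent") {
    res <- score_independent(values, U, fm$group, gamma, mode)
  } else {
    res <- score_dependent(values, U, fm$group, fm$pair_id, gamma, mode,
                           u_method)
  }

  B <- res$B; S <- res$S; O <- res$O
  mor <- rep(0, p)
  degenerate <- !is.finite(B) | !is.finite(S) | !is.finite(O) | S <= 0 |
    res$n1 < 1 | res$n2 < 1
  ok <- !degenerate
  # direction from B, overlap magnitude from |O|: equals c*O*B/S whenever
  # the two factors agree in sign, but keeps the group direction readable
  # from sign(mor) in all cases
  mor[ok] <- weight * B[ok] * abs(O[ok]) / S[ok]
  if (mode == "raw") {
    sentinel <- degenerate & is.finite(B) & B != 0 & is.finite(S) & S == 0
    mor[sentinel] <- sign(B[sentinel]) * MOR_SENTINEL
  }
  data.frame(
    feature = fm$feature_names,
    n1 = res$n1, n2 = res$n2,
    B = B, S = S, O = O, mor = mor,
    degenerate = degenerate,
    stringsAsFactors = FALSE
  )
}

score_independent <- function(values, U, group, gamma, mode) {
  g1 <- group == levels(group)[1L]
  p <- ncol(U)
  U1 <- U[g1, , drop = FALSE]
  U2 <- U[!g1, , drop = FALSE]
  n1 <- colSums(!is.na(U1))
  n2 <- colSums(!is.na(U2))

  loc <- if (mode == "raw") {
    list(x1 = values[g1, , drop = FALSE], x2 = values[!g1, , drop = FALSE])
  } else {
    list(x1 = U1, x2 = U2)
  }
  m1 <- colMeans(loc$x1, na.rm = TRUE)
  m2 <- colMeans(loc$x2, na.rm = TRUE)
  B <- m1 - m2
  v1 <- colMeans(sweep(loc$x1, 2L, m1)^2, na.rm = TRUE)
  v2 <- colMeans(sweep(loc$x2, 2L, m2)^2, na.rm = TRUE)
  S <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))

  q <- apply(U, 2L, function(u) {
    u <- u[!is.na(u)]
    if (length(u) == 0L) return(NA_real_)
    quantile(u, probs = gamma, type = 1, names = FALSE)
  })
  qm1 <- matrix(q, nrow(U1), p, byrow = TRUE)
  qm2 <- matrix(q, nrow(U2), p, byrow = TRUE)
  p1 <- colMeans(U1 > qm1, na.rm = TRUE)
  p2 <- colMeans(U2 > qm2, na.rm = TRUE)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  O <- ifelse(is.na(pbar) | pbar <= 0 | pbar >= 1, 0,
              (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2)))
  list(B = B, S = S, O = O, n1 = n1, n2 = n2)
}

score_dependent <- function(values, U, group, pair_id, gamma, mode,
                            u_method) {
  lv <- levels(group)
  idx1 <- which(group == lv[1L])[order(pair_id[group == lv[1L]])]
  idx2 <- which(group == lv[2L])[order(pair_id[group == lv[2L]])]
  n <- length(idx1)
  p <- ncol(U)

  has_na <- colSums(is.na(values)) > 0L
  B <- S <- O <- numeric(p)
  n1 <- n2 <- integer(p)

  score_cols <- function(X1u, X2u, X1loc, X2loc) {
    # all inputs complete, pair-aligned
    m1 <- colMeans(X1loc); m2 <- colMeans(X2loc)
    Bj <- m1 - m2
    D <- X1loc - X2loc
    Sj <- sqrt(colMeans(D^2) - colMeans(D)^2)
    Du <- X1u - X2u
    pos <- colSums(Du > 0)
    neg <- colSums(Du < 0)
    np <- pos + neg
    Oj <- ifelse(np == 0L, 0, (pos / np - neg / np) / sqrt(0.25 * 2 / np))
    list(B = Bj, S = Sj, O = Oj)
  }

  if (any(!has_na)) {
    j <- which(!has_na)
    U1 <- U[idx1, j, drop = FALSE]
    U2 <- U[idx2, j, drop = FALSE]
    if (mode == "raw") {
      sc <- score_cols(U1, U2, values[idx1, j, drop = FALSE],
                       values[idx2, j, drop = FALSE])
    } else {
      sc <- score_cols(U1, U2, U1, U2)
    }
    B[j] <- sc$B; S[j] <- sc$S; O[j] <- sc$O
    n1[j] <- n; n2[j] <- n
  }
  for (j in which(has_na)) {
    # complete pairs only; re-rank within them so U stays a proper pooled
    # rank transform of the usable sample
    x1 <- values[idx1, j]
    x2 <- values[idx2, j]
    keep <- !is.na(x1) & !is.na(x2)
    nk <- sum(keep)
    n1[j] <- nk; n2[j] <- nk
    if (nk < 2L) {
      B[j] <- NA_real_; S[j] <- NA_real_; O[j] <- NA_real_
      next
    }
    x1 <- x1[keep]; x2 <- x2[keep]
    r <- rank_transform(c(x1, x2))
    u <- u_transform(r, method = u_method)
    u1 <- u[seq_len(nk)]; u2 <- u[nk + seq_len(nk)]
    if (mode == "raw") {
      B[j] <- biological_difference(x1, x2)
      S[j] <- dispersion_factor(x1, x2, design = "dependent")
    } else {
      B[j] <- biological_difference(u1, u2)
      S[j] <- dispersion_factor(u1, u2, design = "dependent")
    }
    O[j] <- overlap_dependent(u1, u2)
  }
  list(B = B, S = S, O = O, n1 = n1, n2 = n2)
}

#' Compute the Measure of Relevance for every feature
#'
#' Scores each feature of a two-sample table with `MoR = c * B * |O| / S`,
#' where `O` is the distribution-overlap factor ([overlap_independent()] /
#' [overlap_dependent()]), `B` the biological difference of the group means
#' and `S` the pooled dispersion ([dispersion_factor()]). The magnitude
#' `|MoR| = c |O| |B| / S` drives ranking and selection; the sign is that of
#' `B`, so it reads as the direction of the group difference (and agrees
#' with the sign of `O` except for noise-level features where the two
#' factors can disagree). In the default
#' rank mode all three factors are computed on the pooled-rank
#' U-transformation of the data, which makes the score distribution-free and
#' comparable across features of different scales and types. In raw mode
#' (recommended for very small samples with many continuous features, where
#' U-transformed differences are heavily tied) `B` and `S` come from the
#' original values while `O` -- which is invariant under strictly monotone
#' transforms -- is still computed on ranks.
#'
#' The result is the information chain: one row per feature, ordered by
#' decreasing `|MoR|` (ties keep input order), with `chain_rank` giving the
#' position. Degenerate features (empty group, fewer than two usable values,
#' zero dispersion on ranks) get `MoR = 0` and are flagged.
#'
#' @param data A data frame (samples as rows) or a [feature_matrix()].
#' @param group,pair,design Passed to [feature_matrix()]; ignored when
#'   `data` already is one.
#' @param mode `"rank"` (default) or `"raw"`.
#' @param gamma Pooled-quantile level for the independent-design overlap
#'   factor; default 0.5 (the pooled median).
#' @param weight Common weighting factor `c` applied to every feature;
#'   default 1.
#' @param u_method U-transformation variant, see [u_transform()].
#'
#' @return A tibble of class `mor_result` with columns `feature`,
#'   `chain_rank`, `n1`, `n2`, `B`, `S`, `O`, `mor`, `degenerate`, ordered by
#'   decreasing `|mor|`.
#'
#' @examples
#' d <- tibble::tibble(
#'   grp = rep(c("a", "b"), each = 10),
#'   sep = c(11:20, 1:10),    # complete separation
#'   noise = rnorm(20)
#' )
#' mor(d, group = grp)
#' @export
mor <- function(data, group = NULL, pair = NULL, design = NULL,
                mode = c("rank", "raw"), gamma = 0.5, weight = 1,
                u_method = c("midpoint", "ratio")) {
  mode <- match.arg(mode)
  u_method <- match.arg(u_method)
  stopifnot(gamma > 0, gamma < 1, is.numeric(weight), length(weight) == 1L)
  fm <- if (inherits(data, "feature_matrix")) {
    data
  } else if (inherits(data, "mor_sim") && missing(group)) {
    fm_from_sim(data)
  } else {
    feature_matrix(data, group = {{ group }}, pair = {{ pair }},
                   design = design)
  }
  scores <- as_tibble(mor_engine(fm, gamma = gamma, weight = weight,
                                 mode = mode, u_method = u_method))
  out <- build_chain(scores)
  new_mor_result(out, fm = fm,
                 params = list(mode = mode, gamma = gamma, weight = weight,
                               u_method = u_method, design = fm$design))
}

new_mor_result <- function(tbl, fm, params) {
  structure(
    tbl,
    fm = fm,
    params = params,
    class = c("mor_result", class(tibble())))
}

#' Sort scores into the information chain
#'
#' Orders per-feature relevance scores by decreasing `|MoR|`; ties keep
#' their input order (stable sort). The chain position is stored in
#' `chain_rank`.
#'
#' @param scores A data frame with at least a `mor` column (e.g. the output
#'   of [mor()] or [read_scores()]).
#' @return The same rows ordered by decreasing `|mor|` with a (re)computed
#'   `chain_rank` column.
#' @export
build_chain <- function(scores) {
  stopifnot("mor" %in% names(scores))
  out <- scores[order(-abs(scores$mor)), , drop = FALSE]
  out$chain_rank <- seq_len(nrow(out))
  out <- as_tibble(out)
  relocate(out, "chain_rank", .after = "feature")
}

mor_params <- function(x) attr(x, "params", exact = TRUE)
mor_fm <- function(x) attr(x, "fm", exact = TRUE)

#' @export
print.mor_result <- function(x, n = 10, ...) {
  p <- mor_params(x)
  cat("<mor_result> information chain of ", nrow(x), " features (",
      p$design, " design, ", p$mode, " mode, gamma = ", p$gamma,
      ", c = ", p$weight, ")\n", sep = "")
  NextMethod(n = n)
  invisible(x)
}

#' @rdname mor
#' @param x A `mor_result`.
#' @param ... Unused.
#' @export
tidy.mor_result <- function(x, ...) {
  as_tibble(unclass2(x))
}

#' @rdname mor
#' @export
glance.mor_result <- function(x, ...) {
  prm <- mor_params(x)
  tibble(
    p = nrow(x),
    n1 = max(x$n1), n2 = max(x$n2),
    design = prm$design, mode = prm$mode, gamma = prm$gamma,
    weight = prm$weight,
    u_method = prm$u_method,
    max_abs_mor = max(abs(x$mor)),
    n_degenerate = sum(x$degenerate)
  )
}

unclass2 <- function(x) {
  attr(x, "fm") <- NULL
  attr(x, "params") <- NULL
  class(x) <- class(tibble())
  x
}

#' Plot an information chain
#'
#' Chain position against `|MoR|`, optionally with the sample-related
#' cut-off `w * z0 / sqrt(n1 + n2)` as a horizontal reference line.
#'
#' @param object A `mor_result`.
#' @param cutoff Draw the sample-related cut-off line? (default `TRUE`).
#' @param w,z0 Cut-off parameters, see [select_sample_cutoff()].
#' @param top Show only the first `top` chain positions (default all).
#' @param log_y Log-scale the y axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mor_result <- function(object, cutoff = TRUE, w = 1, z0 = 3.28,
                                top = NULL, log_y = FALSE, ...) {
  df <- as_tibble(unclass2(object))
  if (!is.null(top)) df <- df[df$chain_rank <= top, , drop = FALSE]
  g <- ggplot(df, aes(x = .data$chain_rank, y = abs(.data$mor))) +
    geom_line(colour = "grey60") +
    geom_point(size = 0.8) +
    labs(x = "information chain position", y = "|MoR|") +
    theme_bw()
  if (cutoff) {
    thr <- w * z0 / sqrt(stats::median(df$n1 + df$n2))
    g <- g + geom_hline(yintercept = thr, colour = "red", linetype = 2)
  }
  if (log_y) g <- g + scale_y_log10()
  g
}

#' Write and re-read per-feature scores
#'
#' Round-trip delimited output of an information chain: tab-separated with
#' columns `feature`, `chain_rank`, `n1`, `n2`, `B`, `S`, `O`, `mor`,
#' `degenerate`.
#'
#' @param x A `mor_result` (or compatible tibble).
#' @param path Output file path (TSV).
#' @return `write_scores()` returns `x` invisibly; `read_scores()` a tibble
#'   in chain order.
#' @export
write_scores <- function(x, path) {
  readr::write_tsv(as_tibble(unclass2(x)), path)
  invisible(x)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
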