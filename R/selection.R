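new_mor_selection <- function(tbl, criterion, parameters, threshold = NA_real_,
                              status = "ok") {
  structure(
    tbl,
    criterion = criterion,
    parameters = parameters,
    threshold = threshold,
    status = status,
    class = c("mor_selection", class(tibble()))
  )
}

selection_base <- function(chain) {
  if (!"chain_rank" %in% names(chain)) chain <- build_chain(chain)
  keep <- intersect(c("feature", "chain_rank", "n1", "n2", "mor",
                      "degenerate"), names(chain))
  as_tibble(unclass2(chain))[, keep, drop = FALSE]
}

#' Selected feature names
#'
#' @param x A `mor_selection`.
#' @return Character vector of selected features, in chain order.
#' @export
selected_features <- function(x) {
  stopifnot(inherits(x, "mor_selection"))
  x$feature[x$selected]
}

#' @export
print.mor_selection <- function(x, n = 10, ...) {
  cat("<mor_selection> criterion: ", attr(x, "criterion"),
      " -- ", sum(x$selected), "/", nrow(x), " features selected",
      if (attr(x, "status") != "ok") paste0(" [", attr(x, "status"), "]"),
      "\n", sep = "")
  thr <- attr(x, "threshold")
  if (length(thr) == 1L && is.finite(thr)) {
    cat("  threshold on |MoR|: ", format(thr, digits = 6), "\n", sep = "")
  }
  NextMethod(n = n)
  invisible(x)
}

#' @rdname select_sample_cutoff
#' @param x A `mor_selection`.
#' @param ... Unused.
#' @export
tidy.mor_selection <- function(x, ...) {
  out <- x
  attr(out, "criterion") <- NULL
  attr(out, "parameters") <- NULL
  attr(out, "threshold") <- NULL
  attr(out, "status") <- NULL
  class(out) <- class(tibble())
  as_tibble(out)
}

#' @rdname select_sample_cutoff
#' @export
glance.mor_selection <- function(x, ...) {
  tibble(
    criterion = attr(x, "criterion"),
    n_features = nrow(x),
    n_selected = sum(x$selected),
    threshold = attr(x, "threshold")[1],
    status = attr(x, "status")
  )
}

#' @rdname select_sample_cutoff
#' @param object A `mor_selection`.
#' @export
autoplot.mor_selection <- function(object, log_y = FALSE, ...) {
  df <- tidy(object)
  g <- ggplot(df, aes(x = .data$chain_rank, y = abs(.data$mor),
                      colour = .data$selected)) +
    geom_point(size = 0.9) +
    labs(x = "information chain position", y = "|MoR|",
         colour = "selected") +
    theme_bw()
  thr <- attr(object, "threshold")
  if (length(thr) == 1L && is.finite(thr)) {
    g <- g + geom_hline(yintercept = thr, colour = "red", linetype = 2)
  }
  if (log_y) g <- g + scale_y_log10()
  g
}

#' Sample-related objective cut-off
#'
#' Declares a feature relevant when `|MoR| >= w * z0 / sqrt(n1 + n2)`, with
#' per-feature sample sizes. The anchor `z0 = 3.28` is the sum of the two
#' one-sided 5% standard-normal quantiles (2 x 1.645): for large samples the
#' overlap factor behaves like a Z statistic, so the threshold marks scores
#' outside the central null mass while shrinking as `1/sqrt(N)` -- larger
#' studies may call smaller standardized effects relevant. The weight `w`
#' brakes or relaxes the rule (larger `w` for small samples where only large
#' effects are credible).
#'
#' @param chain A [mor()] result (information chain).
#' @param w Effect-weighting factor (> 0), default 1.
#' @param z0 Normal-quantile anchor, default 3.28.
#' @return A `mor_selection`: the chain plus a per-feature `threshold` and
#'   logical `selected` column; `tidy()` and `glance()` methods summarise it.
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b"), each = 10),
#'                     f1 = c(11:20, 1:10), f2 = rnorm(20))
#' mor(d, g) |> select_sample_cutoff()
#' @export
select_sample_cutoff <- function(chain, w = 1, z0 = 3.28) {
  stopifnot(w > 0, z0 > 0)
  out <- selection_base(chain)
  out$threshold <- w * z0 / sqrt(out$n1 + out$n2)
  out$selected <- is.finite(out$threshold) & abs(out$mor) >= out$threshold
  new_mor_selection(out, "sample_cutoff",
                    parameters = list(w = w, z0 = z0),
                    threshold = w * z0 / sqrt(max(out$n1 + out$n2)))
}

#' Entropy-based stopping rule
#'
#' Walks down the information chain and stops when adding the next feature
#' no longer changes the entropy of the selected set appreciably. For a
#' prefix of size `k` the features get weights
#' `q_i = |MoR_(i)| / sum_(j<=k) |MoR_(j)|` and Shannon entropy
#' `H_k = -sum q_i log q_i`. The adjusted change when extending the prefix is
#' `D_k = (H_(k+1) - H_k) / H_k` (`change = "relative"`, the default) or the
#' plain increment `H_(k+1) - H_k` (`change = "absolute"`). The first
#' `k >= 2` with `D_k < delta` stops the walk and the first `k` features are
#' selected; if the condition never holds, all features with nonzero `|MoR|`
#' are selected. An all-zero chain selects nothing.
#'
#' For a chain of (near-)equal scores `H_k = log k`, so `D_k` decreases
#' monotonically with small decrements and the rule walks far down; a chain
#' dominated by one large score plateaus immediately.
#'
#' @param chain A [mor()] result.
#' @param delta Stopping tolerance (> 0), default 0.01.
#' @param change `"relative"` or `"absolute"` adjusted entropy change.
#' @return A `mor_selection` (selected set is a chain prefix).
#' @export
select_entropy <- function(chain, delta = 0.01,
                           change = c("relative", "absolute")) {
  stopifnot(delta > 0)
  change <- match.arg(change)
  out <- selection_base(chain)
  am <- abs(out$mor)
  p <- length(am)
  k_star <- 0L
  if (p > 0L && am[1L] > 0) {
    cs <- cumsum(am)
    xlx <- ifelse(am > 0, am * log(am), 0)
    cl <- cumsum(xlx)
    H <- ifelse(cs > 0, log(cs) - cl / cs, 0)
    n_pos <- sum(am > 0)
    if (p == 1L || n_pos == 1L) {
      k_star <- 1L
    } else {
      k_star <- n_pos # default: never negligible -> all informative features
      for (k in 2:(p - 1L)) {
        dH <- H[k + 1L] - H[k]
        Dk <- if (change == "relative") {
          if (H[k] > 0) dH / H[k] else Inf
        } else {
          dH
        }
        if (is.finite(Dk) && Dk < delta) {
          k_star <- k
          break
        }
      }
      k_star <- min(k_star, n_pos)
    }
  }
  out$selected <- out$chain_rank <= k_star
  new_mor_selection(out, "entropy",
                    parameters = list(delta = delta, change = change,
                                      k = k_star),
                    threshold = if (k_star > 0L) am[k_star] else NA_real_,
                    status = if (k_star == 0L) "empty_chain" else "ok")
}

#' Cumulative-information fraction cut-off
#'
#' Selects the smallest chain prefix whose cumulative `|MoR|` reaches at
#' least a fraction `d` of the total `|MoR|` over all features.
#'
#' @param chain A [mor()] result.
#' @param d Target fraction in (0, 1].
#' @return A `mor_selection` (selected set is a chain prefix).
#' @export
select_fraction <- function(chain, d) {
  stopifnot(d > 0, d <= 1)
  out <- selection_base(chain)
  am <- abs(out$mor)
  total <- sum(am)
  if (total == 0) {
    out$selected <- FALSE
    return(new_mor_selection(out, "fraction", list(d = d),
                             status = "empty_chain"))
  }
  out$cum_share <- cumsum(am) / total
  k <- which(out$cum_share >= d - 1e-12)[1L]
  out$selected <- out$chain_rank <= k
  new_mor_selection(out, "fraction", parameters = list(d = d, k = k),
                    threshold = am[k])
}

#' Top-proportion cut-off
#'
#' Selects the `ceiling(epsilon * p)` features with the largest `|MoR|`
#' (a fixed proportion of the total number of features).
#'
#' @param chain A [mor()] result.
#' @param epsilon Proportion in \[0, 1\].
#' @return A `mor_selection` (selected set is a chain prefix).
#' @export
select_top_proportion <- function(chain, epsilon) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  out <- selection_base(chain)
  k <- ceiling(epsilon * nrow(out))
  out$selected <- out$chain_rank <= k
  new_mor_selection(out, "top_proportion",
                    parameters = list(epsilon = epsilon, k = k),
                    threshold = if (k >= 1L) abs(out$mor[k]) else NA_real_)
}

#' Permutation-null selection criterion
#'
#' Re-scores every feature under random regroupings of the samples and
#' declares a feature relevant when its observed `|MoR|` lies among the
#' `alpha * K` greatest permuted values (equivalently, permutation
#' `p <= alpha`). For the independent design the group labels are permuted
#' with the original group sizes kept fixed; for the dependent design the
#' within-pair assignment is flipped at random. When the requested number of
#' permutations reaches the number of distinct regroupings
#' (`choose(N, n1)` or `2^n`), all of them are enumerated exhaustively
#' instead.
#'
#' The chain is not needed for the decision itself, but restricting the test
#' to its first `top_m` positions (`top_m` argument) avoids wasting
#' permutation effort on clearly uninformative features.
#'
#' @param chain A [mor()] result (must still carry its data, i.e. come
#'   straight from [mor()]).
#' @param alpha Selection level; a raw or user-corrected value.
#' @param n_perm Number of permutations `K`; `K >= 1/alpha` is needed for
#'   the rule to be able to select at all.
#' @param top_m Optional restriction to the first `top_m` chain features;
#'   features beyond it are reported unselected with `perm_p = NA`.
#' @param seed Optional integer seed for the permutation draw.
#' @return A `mor_selection` with a `perm_p` column.
#' @export
select_permutation <- function(chain, alpha = 0.05, n_perm = 1000,
                               top_m = NULL, seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 1)
  fm <- mor_fm(chain)
  prm <- mor_params(chain)
  if (is.null(fm)) {
    abort("`chain` no longer carries its data; pass the result of `mor()`.")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  out <- selection_base(chain)
  test_idx <- if (is.null(top_m)) {
    seq_len(nrow(out))
  } else {
    which(out$chain_rank <= top_m)
  }
  feat <- out$feature[test_idx]
  col_idx <- match(feat, fm$feature_names)

  perm_abs <- if (fm$design == "independent") {
    perm_stats_independent(fm, col_idx, n_perm, prm)
  } else {
    perm_stats_dependent(fm, col_idx, n_perm, prm)
  }
  K <- nrow(perm_abs)
  m <- max(1L, ceiling(alpha * K))
  obs <- abs(out$mor[test_idx])
  thr <- apply(perm_abs, 2L, function(v) sort(v, decreasing = TRUE)[m])
  pvals <- colMeans(perm_abs >= matrix(obs, K, length(obs), byrow = TRUE))

  out$perm_p <- NA_real_
  out$perm_p[test_idx] <- pvals
  out$selected <- FALSE
  out$selected[test_idx] <- obs >= thr & obs > 0
  new_mor_selection(out, "permutation",
                    parameters = list(alpha = alpha, n_perm = K,
                                      exhaustive = attr(perm_abs, "exhaustive"),
                                      top_m = top_m))
}

# |MoR| under permuted group labels; rows = permutations, cols = features.
perm_stats_independent <- function(fm, col_idx, n_perm, prm) {
  values <- fm$values[, col_idx, drop = FALSE]
  um <- u_matrix(values, method = prm$u_method)
  U <- um$u
  N <- nrow(U)
  n1 <- sum(fm$group == levels(fm$group)[1L])
  total <- choose(N, n1)
  exhaustive <- is.finite(total) && n_perm >= total
  masks <- if (exhaustive) {
    combn(N, n1, simplify = FALSE)
  } else {
    replicate(n_perm, sample.int(N, n1), simplify = FALSE)
  }
  loc <- if (prm$mode == "raw") values else U
  stat <- vapply(masks, function(idx) {
    g1 <- logical(N)
    g1[idx] <- TRUE
    grp <- factor(ifelse(g1, "g1", "g2"), levels = c("g1", "g2"))
    sc <- score_independent(loc, U, grp, prm$gamma, prm$mode)
    m <- ifelse(is.finite(sc$S) & sc$S > 0 & is.finite(sc$O) &
                  is.finite(sc$B),
                prm$weight * sc$O * sc$B / sc$S, 0)
    abs(m)
  }, numeric(ncol(U)))
  res <- t(matrix(stat, ncol = length(masks)))
  attr(res, "exhaustive") <- exhaustive
  res
}

perm_stats_dependent <- function(fm, col_idx, n_perm, prm) {
  values <- fm$values[, col_idx, drop = FALSE]
  lv <- levels(fm$group)
  i1 <- which(fm$group == lv[1L])
  i2 <- which(fm$group == lv[2L])
  i1 <- i1[order(fm$pair_id[i1])]
  i2 <- i2[order(fm$pair_id[i2])]
  n <- length(i1)
  um <- u_matrix(values, method = prm$u_method)
  DU <- um$u[i1, , drop = FALSE] - um$u[i2, , drop = FALSE]
  DL <- if (prm$mode == "raw") {
    values[i1, , drop = FALSE] - values[i2, , drop = FALSE]
  } else {
    DU
  }
  total <- 2^n
  exhaustive <- n <= 30 && n_perm >= total
  signs <- if (exhaustive) {
    sgn <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    matrix(sample(c(1, -1), n * n_perm, replace = TRUE), ncol = n)
  }
  stat <- apply(signs, 1L, function(s) {
    du <- DU * s
    dl <- DL * s
    B <- colMeans(dl, na.rm = TRUE)
    S <- sqrt(pmax(colMeans(dl^2, na.rm = TRUE) -
                     colMeans(dl, na.rm = TRUE)^2, 0))
    pos <- colSums(du > 0, na.rm = TRUE)
    neg <- colSums(du < 0, na.rm = TRUE)
    np <- pos + neg
    O <- ifelse(np == 0L, 0, (pos / np - neg / np) / sqrt(0.25 * 2 / np))
    ifelse(is.finite(S) & S > 0, abs(prm$weight * O * B / S), 0)
  })
  res <- t(matrix(stat, ncol = nrow(signs)))
  attr(res, "exhaustive") <- exhaustive
  res
}

#' Composite screening workflow
#'
#' The recommended two-stage use of the selection criteria: first the
#' objective sample-related cut-off decides whether the chain contains any
#' informative feature at all (if the chain maximum stays below the
#' threshold the result status is `"none_informative"` and nothing is
#' selected); when it does, an optional subjective criterion prunes the
#' cut-off survivors to a workable number (the final set is the intersection
#' of the two rules).
#'
#' @param chain A [mor()] result.
#' @param w,z0 Cut-off parameters, see [select_sample_cutoff()].
#' @param refine `"none"`, `"entropy"`, `"fraction"` or `"top_proportion"`.
#' @param delta,d,epsilon Parameters of the refining criterion.
#' @return A `mor_selection` with status `"ok"` or `"none_informative"`.
#' @export
screen_features <- function(chain, w = 1, z0 = 3.28,
                            refine = c("none", "entropy", "fraction",
                                       "top_proportion"),
                            delta = 0.01, d = 0.8, epsilon = 0.01) {
  refine <- match.arg(refine)
  cut <- select_sample_cutoff(chain, w = w, z0 = z0)
  if (!any(cut$selected)) {
    attr(cut, "criterion") <- "screen"
    attr(cut, "status") <- "none_informative"
    return(cut)
  }
  if (refine == "none") {
    attr(cut, "criterion") <- "screen"
    return(cut)
  }
  ref <- switch(refine,
    entropy = select_entropy(chain, delta = delta),
    fraction = select_fraction(chain, d = d),
    top_proportion = select_top_proportion(chain, epsilon = epsilon)
  )
  out <- tidy(cut)
  out$selected <- out$selected & out$feature %in% selected_features(ref)
  new_mor_selection(out, "screen",
                    parameters = c(list(w = w, z0 = z0, refine = refine),
                                   attr(ref, "parameters")),
                    threshold = attr(cut, "threshold"))
}

#' Write a selection report
#'
#' Writes a `mor_selection` either as tab-separated per-feature decisions or
#' (for a `.json` path) as a JSON report with the criterion, its parameters,
#' the threshold, the status and the selected features in chain order.
#'
#' @param x A `mor_selection`.
#' @param path Output path; extension picks the format.
#' @return `x`, invisibly.
#' @export
write_selection <- function(x, path) {
  stopifnot(inherits(x, "mor_selection"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    report <- list(
      criterion = attr(x, "criterion"),
      parameters = attr(x, "parameters"),
      threshold = attr(x, "threshold"),
      status = attr(x, "status"),
      n_selected = sum(x$selected),
      selected = selected_features(x)
    )
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    readr::write_tsv(tidy(x), path)
  }
  invisible(x)
}
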