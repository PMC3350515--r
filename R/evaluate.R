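#' Sensitivity and specificity of a selection
#'
#' Compares a selected feature set against the known truly informative set:
#' sensitivity is the fraction of truly informative features that were
#' selected, specificity the fraction of truly non-informative features that
#' were not. A metric with an empty truth class is reported as `NA`, not 0.
#'
#' @param selection A `mor_selection`, a `baseline_tests()`/
#'   `baseline_forest()` result, or a character vector of selected features.
#' @param truth Character vector of truly informative feature names (e.g.
#'   [informative_features()]).
#' @param features All feature names in the study; taken from `selection`
#'   when it is a per-feature table.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_selection <- function(selection, truth, features = NULL) {
  if (is.data.frame(selection)) {
    features <- features %||% selection$feature
    selected <- selection$feature[selection$selected]
  } else {
    selected <- as.character(selection)
    if (is.null(features)) {
      abort("`features` is required when `selection` is a character vector.")
    }
  }
  truth <- intersect(features, truth)
  nulls <- setdiff(features, truth)
  tp <- sum(truth %in% selected)
  fn <- length(truth) - tp
  fp <- sum(nulls %in% selected)
  tn <- length(nulls) - fp
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = if (length(truth)) tp / (tp + fn) else NA_real_,
    specificity = if (length(nulls)) tn / (tn + fp) else NA_real_
  )
}

#' Per-feature two-sample baseline tests
#'
#' Classical multiple-testing baselines for the simulation studies: a
#' two-sided test per feature at level `alpha` (Bonferroni variants use
#' `alpha / p`). Independent design: pooled-variance t test or Wilcoxon
#' rank-sum test; dependent design: paired t test or Wilcoxon signed-rank
#' test. The selected set is the rejected set.
#'
#' @param data A data frame or [feature_matrix()].
#' @param group,pair,design As in [feature_matrix()].
#' @param method One of `"t_test"`, `"t_test_bonferroni"`, `"rank_test"`,
#'   `"rank_test_bonferroni"`.
#' @param alpha Nominal level before any adjustment (default 0.05).
#' @return A tibble with `feature`, `p_value`, `selected`; the per-feature
#'   level actually applied is in `attr(, "alpha_applied")`.
#' @export
baseline_tests <- function(data, group = NULL, pair = NULL, design = NULL,
                           method = c("t_test", "t_test_bonferroni",
                                      "rank_test", "rank_test_bonferroni"),
                           alpha = 0.05) {
  method <- match.arg(method)
  fm <- if (inherits(data, "feature_matrix")) {
    data
  } else if (inherits(data, "mor_sim") && missing(group)) {
    fm_from_sim(data)
  } else {
    feature_matrix(data, group = {{ group }}, pair = {{ pair }},
                   design = design)
  }
  p <- ncol(fm$values)
  alpha_applied <- if (grepl("bonferroni", method)) alpha / p else alpha
  rank_based <- grepl("rank", method)

  if (fm$design == "independent") {
    g1 <- fm$group == levels(fm$group)[1L]
    pv <- vapply(seq_len(p), function(j) {
      x1 <- fm$values[g1, j]
      x2 <- fm$values[!g1, j]
      x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
      if (length(x1) < 2L || length(x2) < 2L) return(NA_real_)
      if (rank_based) {
        suppressWarnings(wilcox.test(x1, x2, exact = FALSE)$p.value)
      } else {
        t.test(x1, x2, var.equal = TRUE)$p.value
      }
    }, numeric(1))
  } else {
    lv <- levels(fm$group)
    i1 <- which(fm$group == lv[1L])
    i2 <- which(fm$group == lv[2L])
    i1 <- i1[order(fm$pair_id[i1])]
    i2 <- i2[order(fm$pair_id[i2])]
    pv <- vapply(seq_len(p), function(j) {
      x1 <- fm$values[i1, j]
      x2 <- fm$values[i2, j]
      keep <- !is.na(x1) & !is.na(x2)
      if (sum(keep) < 2L) return(NA_real_)
      d <- x1[keep] - x2[keep]
      if (all(d == 0)) return(1)
      if (rank_based) {
        suppressWarnings(wilcox.test(x1[keep], x2[keep], paired = TRUE,
                                     exact = FALSE)$p.value)
      } else {
        if (sd(d) == 0) return(0)
        t.test(x1[keep], x2[keep], paired = TRUE)$p.value
      }
    }, numeric(1))
  }
  out <- tibble(
    feature = fm$feature_names,
    p_value = pv,
    selected = !is.na(pv) & pv <= alpha_applied
  )
  attr(out, "alpha_applied") <- alpha_applied
  out
}

#' Random-forest baseline (illustrative)
#'
#' Thin wrapper around a randomized-tree ensemble: features are selected
#' when their permutation importance (mean decrease in accuracy) is positive
#' and reaches a high quantile of the importance distribution. The selection
#' rule is a pragmatic convention -- ensemble importances come with no
#' canonical threshold -- so this baseline is qualitative, not part of the
#' numeric calibration.
#'
#' @param data A data frame or [feature_matrix()] (independent design).
#' @param group As in [feature_matrix()].
#' @param n_trees Number of trees (default 500).
#' @param importance_quantile Importance quantile a feature must reach
#'   (default 0.95).
#' @param seed Optional integer seed.
#' @return A tibble with `feature`, `importance`, `selected`.
#' @export
baseline_forest <- function(data, group = NULL, n_trees = 500,
                            importance_quantile = 0.95, seed = NULL) {
  if (!requireNamespace("randomForest", quietly = TRUE)) {
    abort("baseline_forest() needs the randomForest package.")
  }
  fm <- if (inherits(data, "feature_matrix")) {
    data
  } else {
    feature_matrix(data, group = {{ group }})
  }
  if (!is.null(seed)) set.seed(seed)
  X <- as.data.frame(fm$values)
  rf <- randomForest::randomForest(x = X, y = fm$group, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1)[, 1L]
  thr <- max(0, quantile(imp, importance_quantile, names = FALSE))
  tibble(
    feature = fm$feature_names,
    importance = unname(imp),
    selected = imp > thr
  )
}

score_sim <- function(sim, ...) {
  mor(fm_from_sim(sim), ...)
}

test_sim <- function(sim, method, alpha = 0.05) {
  baseline_tests(fm_from_sim(sim), method = method, alpha = alpha)
}

#' Run a calibration study
#'
#' Loops generate -> score -> select -> evaluate over a grid of simulation
#' conditions and averages sensitivity and specificity over runs:
#'
#' * `objectivity`: normal features, independent (n = 12/10, 15/15, 30/30)
#'   and dependent (11, 15, 30 pairs) designs, information classes high
#'   (`nbd = 2`), semi (`nbd = 1`) and none (`nbd = 0`); the screening score
#'   with the sample-related cut-off, plus nonparametric-test detection
#'   rates (Wilcoxon, Bonferroni-adjusted and unadjusted).
#' * `reliability`: same evaluation with uniform and bimodal features,
#'   independent design (n = 12/10, 14/16, 30/30), classes high and semi.
#' * `validity`: normal features, both designs, comparing the screening
#'   procedure with per-feature t tests (unadjusted and Bonferroni) and
#'   optionally a random forest.
#' * `boxplot`: returns the raw per-feature score distributions at a fixed
#'   sample size (15 per group) across data types (metric, median-split
#'   binary), designs and classes, for judging comparability of the score
#'   scale (plot with [plot_mor_boxplots()]).
#'
#' @param study One of `"objectivity"`, `"reliability"`, `"validity"`,
#'   `"boxplot"`.
#' @param runs Simulation runs per condition (default 100).
#' @param seed Integer seed for the whole study.
#' @param p,n_informative Feature counts per dataset.
#' @param nbd_levels Named numeric vector of class effect sizes.
#' @param w,z0 Sample-related cut-off parameters.
#' @param alpha Level for the baseline tests.
#' @param include_forest Add the random-forest baseline to the validity
#'   study (slow; default `FALSE`).
#' @return A tibble of per-condition metrics (or per-feature scores for
#'   `study = "boxplot"`).
#' @export
run_study <- function(study = c("objectivity", "reliability", "validity",
                                "boxplot"),
                      runs = 100, seed = 1, p = 1000, n_informative = 10,
                      nbd_levels = c(high = 2, semi = 1, none = 0),
                      w = 1, z0 = 3.28, alpha = 0.05,
                      include_forest = FALSE) {
  study <- match.arg(study)
  set.seed(seed)
  switch(study,
    objectivity = study_metrics(
      grid_objectivity(nbd_levels), runs, p, n_informative, w, z0, alpha,
      methods = c("mor", "rank_test", "rank_test_bonferroni"), study = study
    ),
    reliability = study_metrics(
      grid_reliability(nbd_levels), runs, p, n_informative, w, z0, alpha,
      methods = c("mor", "rank_test", "rank_test_bonferroni"), study = study
    ),
    validity = study_metrics(
      grid_validity(nbd_levels), runs, p, n_informative, w, z0, alpha,
      methods = c("mor", "t_test", "t_test_bonferroni",
                  if (include_forest) "random_forest"), study = study
    ),
    boxplot = study_boxplot(runs, p, nbd_levels, seed)
  )
}

grid_objectivity <- function(nbd_levels) {
  indep <- tibble(design = "independent", distribution = "normal",
                  n1 = c(12, 15, 30), n2 = c(10, 15, 30))
  dep <- tibble(design = "dependent", distribution = "normal",
                n1 = c(11, 15, 30), n2 = c(11, 15, 30))
  tidyr::crossing(bind_rows(indep, dep),
                  tibble(class = names(nbd_levels),
                         nbd = unname(nbd_levels)))
}

grid_reliability <- function(nbd_levels) {
  nbd_levels <- nbd_levels[names(nbd_levels) != "none"]
  base <- tidyr::crossing(
    tibble(distribution = c("uniform", "bimodal")),
    tibble(n1 = c(12, 14, 30), n2 = c(10, 16, 30))
  )
  base$design <- "independent"
  tidyr::crossing(base, tibble(class = names(nbd_levels),
                               nbd = unname(nbd_levels)))
}

grid_validity <- function(nbd_levels) {
  indep <- tibble(design = "independent", distribution = "normal",
                  n1 = c(12, 14, 30), n2 = c(10, 16, 30))
  dep <- tibble(design = "dependent", distribution = "normal",
                n1 = c(11, 15, 30), n2 = c(11, 15, 30))
  tidyr::crossing(bind_rows(indep, dep),
                  tibble(class = names(nbd_levels),
                         nbd = unname(nbd_levels)))
}

study_metrics <- function(grid, runs, p, n_informative, w, z0, alpha,
                          methods, study) {
  res <- pmap(grid, function(design, distribution, n1, n2, class, nbd) {
    acc <- matrix(0, length(methods), 2,
                  dimnames = list(methods, c("sensitivity", "specificity")))
    truth_first <- sprintf("f%04d", seq_len(n_informative))
    for (r in seq_len(runs)) {
      sim <- simulate_features(p = p, n_informative = n_informative,
                               nbd = nbd, distribution = distribution,
                               design = design, n1 = n1, n2 = n2,
                               n_pairs = n1)
      for (m in methods) {
        sel <- switch(m,
          mor = screen_features(score_sim(sim), w = w, z0 = z0),
          random_forest = {
            d <- as_tibble(sim)
            baseline_forest(d[, setdiff(names(d), c("sample", "pair"))],
                            group = group)
          },
          test_sim(sim, method = m, alpha = alpha)
        )
        ev <- evaluate_selection(sel, truth_first)
        acc[m, ] <- acc[m, ] + c(ev$sensitivity %||% NA_real_,
                                 ev$specificity %||% NA_real_)
      }
    }
    acc <- acc / runs
    tibble(study = study, design = design, distribution = distribution,
           class = class, nbd = nbd, n1 = n1, n2 = n2,
           method = methods, runs = runs,
           sensitivity = acc[, "sensitivity"],
           specificity = acc[, "specificity"])
  })
  list_rbind(res)
}

study_boxplot <- function(runs, p, nbd_levels, seed) {
  grid <- tidyr::crossing(
    tibble(design = c("independent", "dependent")),
    tibble(data_type = c("metric", "binary")),
    tibble(class = names(nbd_levels), nbd = unname(nbd_levels))
  )
  res <- pmap(grid, function(design, data_type, class, nbd) {
    out <- vector("list", runs)
    for (r in seq_len(runs)) {
      # information content assigned to every feature
      sim <- simulate_features(p = p, n_informative = p, nbd = nbd,
                               distribution = "normal", design = design,
                               n1 = 15, n2 = 15, n_pairs = 15)
      if (data_type == "binary") sim <- dichotomize_at_median(sim)
      sc <- score_sim(sim)
      out[[r]] <- tibble(run = r, feature = sc$feature, mor = sc$mor)
    }
    mutate(list_rbind(out), design = design, data_type = data_type,
           class = class, nbd = nbd)
  })
  list_rbind(res)
}

#' Plot study metrics
#'
#' Sensitivity and specificity per condition and method from a
#' [run_study()] metrics table.
#'
#' @param metrics A metrics tibble from [run_study()].
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(metrics, c("sensitivity", "specificity"),
                              names_to = "metric", values_to = "value")
  long$n_label <- paste0(long$n1, "/", long$n2)
  ggplot(long, aes(x = .data$n_label, y = .data$value,
                   fill = .data$method)) +
    geom_col(position = "dodge") +
    facet_grid(metric ~ class) +
    labs(x = "sample sizes", y = NULL) +
    theme_bw()
}

#' Boxplots of the score distributions across designs and data types
#'
#' @param scores Output of `run_study("boxplot", ...)`.
#' @return A ggplot object.
#' @export
plot_mor_boxplots <- function(scores) {
  scores$condition <- paste(scores$design, scores$data_type)
  ggplot(scores, aes(x = .data$condition, y = .data$mor)) +
    geom_boxplot(outlier.size = 0.4) +
    facet_wrap(~class, scales = "free_y") +
    labs(x = NULL, y = "MoR") +
    theme_bw()
}
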