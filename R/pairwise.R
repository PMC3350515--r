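#' Pairwise screening for group factors with more than two levels
#'
#' A factor with `k` levels defines `k (k - 1) / 2` two-sample problems.
#' Each level pair is screened exactly like a plain two-sample study
#' ([mor()] followed by [screen_features()]), and the union of the per-pair
#' selections is reported as the overall biomarker-candidate set for the
#' factor. With two levels this degenerates to the single two-sample
#' analysis.
#'
#' @param data A data frame with feature columns and a group column.
#' @param group Column (tidy-eval) holding the k-level group factor.
#' @param ... Passed on to [mor()] (e.g. `mode`, `gamma`).
#' @param w,z0 Sample-related cut-off parameters for the per-pair screening.
#' @return An object of class `mor_pairwise`: a list with `pairs` (a tibble
#'   with one row per level pair, holding the chain and selection as list
#'   columns) and `candidates` (the union of selected features).
#' @examples
#' d <- tibble::tibble(
#'   grp = rep(c("a", "b", "c"), each = 8),
#'   f1 = c(rnorm(8), rnorm(8, 3), rnorm(8)),
#'   f2 = rnorm(24)
#' )
#' pw <- pairwise_mor(d, grp)
#' pw$candidates
#' @export
pairwise_mor <- function(data, group, ..., w = 1, z0 = 3.28) {
  stopifnot(is.data.frame(data))
  group_q <- enquo(group)
  grp <- eval_tidy(group_q, data)
  if (is.null(grp)) abort("`group` column not found in `data`.")
  grp <- droplevels(as.factor(grp))
  if (nlevels(grp) < 2L) abort("`group` needs at least two levels.")
  lv <- levels(grp)
  combos <- combn(lv, 2L, simplify = FALSE)

  rows <- map(combos, function(pr) {
    sub <- data[grp %in% pr, , drop = FALSE]
    chain <- mor(sub, group = {{ group }}, ...)
    sel <- screen_features(chain, w = w, z0 = z0)
    tibble(level_1 = pr[1L], level_2 = pr[2L],
           n_selected = sum(sel$selected),
           chain = list(chain), selection = list(sel))
  })
  pairs <- list_rbind(rows)
  candidates <- unique(unlist(map(pairs$selection, selected_features)))
  structure(list(pairs = pairs, candidates = candidates),
            class = "mor_pairwise")
}

#' @export
print.mor_pairwise <- function(x, ...) {
  cat("<mor_pairwise> ", nrow(x$pairs), " level pair(s), ",
      length(x$candidates), " overall candidate feature(s)\n", sep = "")
  print(select(x$pairs, "level_1", "level_2", "n_selected"))
  invisible(x)
}

#' @rdname pairwise_mor
#' @param x A `mor_pairwise`.
#' @export
tidy.mor_pairwise <- function(x, ...) {
  rows <- map2(seq_len(nrow(x$pairs)), x$pairs$selection, function(i, sel) {
    mutate(tidy(sel), level_1 = x$pairs$level_1[i],
           level_2 = x$pairs$level_2[i])
  })
  relocate(list_rbind(rows), "level_1", "level_2")
}
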