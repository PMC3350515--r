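#' Build a two-sample feature matrix
#'
#' Assembles a samples-by-features table plus a two-level group label (and,
#' for matched designs, a pair identifier) into the container all scoring
#' functions work on. Every column other than the group/pair columns is
#' treated as a feature. Feature kinds are inferred from the data: columns
#' with at most two distinct non-missing values are `binary`, ordered factors
#' are `ordinal`, numeric columns are `metric`. Unordered factors or character
#' columns with more than two categories are nominal; nominal features carry
#' no defensible one-dimensional ordering, so they are dropped from scoring
#' with a warning.
#'
#' @param data A data frame with one row per sample: feature columns plus the
#'   group column and, for `design = "dependent"`, a pair column.
#' @param group Column (tidy-eval) holding the two-level group label.
#' @param pair Optional column (tidy-eval) identifying the matched pair or
#'   subject; required for the dependent design, where every pair id must
#'   occur exactly once in each group.
#' @param design `"independent"` or `"dependent"`. Defaults to dependent when
#'   a pair column is supplied, independent otherwise.
#' @param feature_kind Optional named character vector overriding the
#'   inferred kind (`"metric"`, `"ordinal"`, `"binary"`, `"nominal"`) for
#'   specific features.
#'
#' @return An object of class `feature_matrix`: a list with the numeric
#'   `values` matrix (n samples x p features), `group` (two-level factor),
#'   `design`, `pair_id`, `feature_names` and `feature_kind`.
#'
#' @examples
#' d <- tibble::tibble(
#'   grp = rep(c("control", "case"), each = 5),
#'   f1 = c(rnorm(5), rnorm(5, 2)),
#'   f2 = rnorm(10)
#' )
#' fm <- feature_matrix(d, group = grp)
#' fm
#' @export
feature_matrix <- function(data, group, pair = NULL, design = NULL,
                           feature_kind = NULL) {
  stopifnot(is.data.frame(data))
  group_q <- enquo(group)
  pair_q <- enquo(pair)
  grp <- eval_tidy(group_q, data)
  if (is.null(grp)) abort("`group` column not found in `data`.")
  group_name <- rlang::as_name(group_q)

  pair_id <- NULL
  pair_name <- NULL
  if (!quo_is_null(pair_q)) {
    pair_id <- eval_tidy(pair_q, data)
    pair_name <- rlang::as_name(pair_q)
  }
  if (is.null(design)) {
    design <- if (is.null(pair_id)) "independent" else "dependent"
  }
  design <- match.arg(design, c("independent", "dependent"))

  grp <- droplevels(as.factor(grp))
  if (nlevels(grp) != 2L) {
    abort(paste0(
      "`group` must have exactly two levels (found ", nlevels(grp), "). ",
      "For factors with more than two levels use `pairwise_mor()`."
    ))
  }
  if (design == "dependent") {
    if (is.null(pair_id)) {
      abort("The dependent design requires a `pair` column.")
    }
    tab <- table(pair_id, grp)
    if (!all(tab == 1L)) {
      abort("Every pair id must occur exactly once in each group.")
    }
  }

  feat_cols <- setdiff(names(data), c(group_name, pair_name))
  if (length(feat_cols) == 0L) abort("No feature columns found.")

  kinds <- vapply(feat_cols, function(nm) infer_kind(data[[nm]]), character(1))
  if (!is.null(feature_kind)) {
    bad <- setdiff(names(feature_kind), feat_cols)
    if (length(bad)) {
      abort(paste0("Unknown features in `feature_kind`: ",
                   paste(bad, collapse = ", ")))
    }
    kinds[names(feature_kind)] <- unname(feature_kind)
  }
  nominal <- feat_cols[kinds == "nominal"]
  if (length(nominal)) {
    warn(paste0(
      "Dropping ", length(nominal),
      " nominal feature(s) with more than two categories from scoring: ",
      paste(head(nominal, 5L), collapse = ", "),
      if (length(nominal) > 5L) ", ..." else ""
    ))
    feat_cols <- setdiff(feat_cols, nominal)
    kinds <- kinds[feat_cols]
    if (length(feat_cols) == 0L) abort("No scorable features left.")
  }

  values <- vapply(feat_cols, function(nm) as_feature_numeric(data[[nm]]),
                   numeric(nrow(data)))
  values <- matrix(values, nrow = nrow(data),
                   dimnames = list(NULL, feat_cols))

  binary_declared <- feat_cols[kinds == "binary"]
  for (nm in binary_declared) {
    v <- values[, nm]
    if (!all(v[!is.na(v)] %in% c(0, 1))) {
      abort(paste0("Binary feature `", nm, "` must take values in {0, 1}."))
    }
  }

  structure(
    list(
      values = values,
      group = grp,
      design = design,
      pair_id = pair_id,
      feature_names = feat_cols,
      feature_kind = kinds
    ),
    class = "feature_matrix"
  )
}

infer_kind <- function(x) {
  if (is.ordered(x)) return("ordinal")
  vals <- unique(x[!is.na(x)])
  if (is.numeric(x)) {
    if (length(vals) > 2L) return("metric")
    # two-valued numeric: binary only on a 0/1 coding, else a 2-level scale
    return(if (all(vals %in% c(0, 1))) "binary" else "ordinal")
  }
  if (length(vals) <= 2L) return("binary")
  "nominal"
}

as_feature_numeric <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.logical(x)) return(as.numeric(x))
  if (is.ordered(x)) return(as.numeric(x))
  # two-category factor/character: code as 0/1 in level order
  f <- as.factor(x)
  if (nlevels(f) > 2L) return(as.numeric(f)) # nominal, dropped upstream
  as.numeric(f) - 1
}

#' @export
print.feature_matrix <- function(x, ...) {
  n <- table(x$group)
  cat("<feature_matrix> ", nrow(x$values), " samples x ",
      ncol(x$values), " features (", x$design, " design)\n", sep = "")
  cat("  groups: ", paste0(names(n), " (n=", n, ")", collapse = ", "), "\n",
      sep = "")
  cat("  kinds:  ", paste(names(table(x$feature_kind)),
                          table(x$feature_kind), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Read a delimited feature table
#'
#' Reads a CSV/TSV file with samples as rows into a [feature_matrix()].
#' The delimiter is taken from the file extension (`.csv` -> comma,
#' anything else -> tab). Feature kinds are inferred as in
#' [feature_matrix()]; a sidecar key-value text file (`feature=kind`, one
#' per line) can override the inference.
#'
#' @param path Path to the delimited file.
#' @param group Name of the group column (string).
#' @param pair Optional name of the pair column (string).
#' @param design As in [feature_matrix()].
#' @param kinds_file Optional path to a `feature=kind` sidecar file.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path, group, pair = NULL, design = NULL,
                                kinds_file = NULL) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  kinds <- NULL
  if (!is.null(kinds_file)) {
    lines <- readr::read_lines(kinds_file)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    if (any(lengths(kv) != 2L)) {
      abort("Each line of `kinds_file` must be `feature=kind`.")
    }
    kinds <- setNames(trimws(vapply(kv, `[[`, "", 2L)),
                      trimws(vapply(kv, `[[`, "", 1L)))
  }
  if (is.null(pair)) {
    feature_matrix(data, group = !!rlang::sym(group), design = design,
                   feature_kind = kinds)
  } else {
    feature_matrix(data, group = !!rlang::sym(group),
                   pair = !!rlang::sym(pair), design = design,
                   feature_kind = kinds)
  }
}

#' Pooled-rank transformation
#'
#' Ranks a feature over the whole pooled sample (both groups jointly).
#' Ties receive midranks; missing values stay missing and do not count
#' towards the pooled sample size.
#'
#' @param x Numeric vector with possible `NA`s.
#' @return Numeric vector of midranks, `NA` where `x` is `NA`.
#' @examples
#' rank_transform(c(5, 5, 7))     # 1.5 1.5 3
#' rank_transform(c(3, NA, 1, 2)) # 3 NA 1 2
#' @export
rank_transform <- function(x) {
  rank(x, na.last = "keep", ties.method = "average")
}

#' U-transformation of midranks into the unit interval
#'
#' Maps pooled midranks onto (0, 1) so that features of different scales and
#' types become comparable. The default mapping `U = (R - 0.5) / N` centres a
#' full untied rank set at exactly 0.5 and makes the pooled median of the
#' transformed values 0.5; the alternative `U = R / (N + 1)` is available via
#' `method = "ratio"`.
#'
#' @param ranks Midranks on `1..N` (`NA` allowed).
#' @param N Number of non-missing values the ranks were computed over.
#'   Defaults to the count of non-missing ranks.
#' @param method `"midpoint"` for `(R - 0.5)/N` (default) or `"ratio"` for
#'   `R/(N + 1)`.
#' @return Values in (0, 1), `NA` preserved; `numeric(0)` when `N = 0`.
#' @examples
#' u_transform(1:4)             # 0.125 0.375 0.625 0.875
#' u_transform(c(1.5, 1.5, 3))  # 0.333... 0.333... 0.833...
#' @export
u_transform <- function(ranks, N = sum(!is.na(ranks)),
                        method = c("midpoint", "ratio")) {
  method <- match.arg(method)
  if (N == 0L) return(numeric(0))
  if (method == "midpoint") (ranks - 0.5) / N else ranks / (N + 1)
}

# U-transform every column of a values matrix; returns list(u, ranks, N).
u_matrix <- function(values, method = "midpoint") {
  ranks <- apply(values, 2L, rank, na.last = "keep", ties.method = "average")
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = nrow(values))
  N <- colSums(!is.na(values))
  Nm <- matrix(N, nrow(values), ncol(values), byrow = TRUE)
  u <- if (method == "midpoint") (ranks - 0.5) / Nm else ranks / (Nm + 1)
  dimnames(u) <- dimnames(values)
  list(u = u, ranks = ranks, N = N)
}
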