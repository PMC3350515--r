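#' Simulate a two-sample feature table with known informative features
#'
#' Generates the synthetic study designs used to calibrate and evaluate the
#' screening procedure: `p` features, of which the first `n_informative`
#' carry a standardized group difference (normalized biological difference,
#' NBD) of `nbd` pooled standard deviations and the rest none. All features
#' share the same marginal distribution family; informative ones differ only
#' in their location parameter. The conventional information classes are
#' `nbd = 2` (very informative), `nbd = 1` (semi-informative) and `nbd = 0`
#' (non-informative).
#'
#' Distributions (all unit variance so the location offset *is* the NBD):
#' * `normal`: standard normal, informative group-1 mean shifted by `nbd`.
#' * `uniform`: width `sqrt(12)` uniform; the informative group-1 interval
#'   is shifted by `nbd` (same width).
#' * `bimodal`: equal mixture of two unit-sd normals at `+/- bimodal_sep`,
#'   rescaled to unit variance, then shifted.
#' * `bernoulli`: success probabilities symmetric about 0.5 solving
#'   `|p1 - p2| / sqrt(pbar (1 - pbar)) = nbd`, i.e. `0.5 +/- nbd/4`
#'   (requires `nbd <= 2`); non-informative features use 0.5 in both groups.
#'
#' The dependent design draws matched pairs with within-pair correlation
#' `rho` (shared standard-normal component; Bernoulli pairs via a latent
#' correlated normal thresholded at the target success probabilities). The
#' informative shift is then `nbd` standard deviations *of the pair
#' difference*, i.e. `nbd * sqrt(2 (1 - rho))`, so the standardized paired
#' effect equals `nbd`. Matched designs with uniform or bimodal marginals
#' are not provided.
#'
#' @param p Number of features (default 1000).
#' @param n_informative Number of informative features (default 10); they
#'   occupy the first columns and are named in the `informative` attribute.
#' @param nbd Standardized effect size of the informative features.
#' @param distribution `"normal"`, `"uniform"`, `"bimodal"` or
#'   `"bernoulli"`.
#' @param design `"independent"` or `"dependent"`.
#' @param n1,n2 Group sizes (independent design).
#' @param n_pairs Number of matched pairs (dependent design).
#' @param rho Within-pair correlation in `[0, 1)` (dependent design),
#'   default 0.5.
#' @param bimodal_sep Pre-scaling separation of the bimodal mixture modes,
#'   default 2.
#' @param seed Optional integer seed; a fixed seed reproduces the matrix
#'   bitwise.
#'
#' @return A tibble of class `mor_sim` with columns `sample`, `group`
#'   (levels `g1`, `g2`), `pair` (dependent design only) and features
#'   `f0001`, ...; the truly informative feature names are in
#'   `attr(, "informative")` (see [informative_features()]).
#' @examples
#' sim <- simulate_features(p = 50, n_informative = 5, nbd = 2,
#'                          n1 = 10, n2 = 10, seed = 1)
#' informative_features(sim)
#' @export
simulate_features <- function(p = 1000, n_informative = 10, nbd = 2,
                              distribution = c("normal", "uniform",
                                               "bimodal", "bernoulli"),
                              design = c("independent", "dependent"),
                              n1 = 15, n2 = 15, n_pairs = 15, rho = 0.5,
                              bimodal_sep = 2, seed = NULL) {
  distribution <- match.arg(distribution)
  design <- match.arg(design)
  stopifnot(n_informative <= p, nbd >= 0, rho >= 0, rho < 1)
  if (distribution == "bernoulli" && nbd > 2) {
    abort("Bernoulli features cannot attain nbd > 2 (probabilities leave [0, 1]).")
  }
  if (design == "dependent" && distribution %in% c("uniform", "bimodal")) {
    abort(paste0("The dependent design is provided for normal and bernoulli ",
                 "features only."))
  }
  if (!is.null(seed)) set.seed(seed)

  shift <- c(rep(nbd, n_informative), rep(0, p - n_informative))
  feat_names <- sprintf("f%04d", seq_len(p))

  if (design == "independent") {
    draw <- function(n, delta) {
      switch(distribution,
        normal = matrix(rnorm(n * p), n, p) +
          matrix(delta, n, p, byrow = TRUE),
        uniform = matrix(runif(n * p, -sqrt(12) / 2, sqrt(12) / 2), n, p) +
          matrix(delta, n, p, byrow = TRUE),
        bimodal = {
          modes <- matrix(sample(c(-1, 1), n * p, replace = TRUE), n, p)
          z <- (modes * bimodal_sep + matrix(rnorm(n * p), n, p)) /
            sqrt(1 + bimodal_sep^2)
          z + matrix(delta, n, p, byrow = TRUE)
        },
        bernoulli = {
          pr <- 0.5 + delta / 4 # delta is +nbd in group 1, -nbd in group 2
          matrix(rbinom(n * p, 1L, rep(pr, each = n)), n, p)
        }
      )
    }
    if (distribution == "bernoulli") {
      X1 <- draw(n1, shift)
      X2 <- draw(n2, -shift)
    } else {
      X1 <- draw(n1, shift)
      X2 <- draw(n2, rep(0, p))
    }
    X <- rbind(X1, X2)
    out <- tibble(
      sample = sprintf("s%03d", seq_len(n1 + n2)),
      group = factor(rep(c("g1", "g2"), c(n1, n2)))
    )
  } else {
    n <- n_pairs
    if (distribution == "normal") {
      Z0 <- matrix(rnorm(n * p), n, p)
      X1 <- sqrt(rho) * Z0 + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
      X2 <- sqrt(rho) * Z0 + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
      sd_diff <- sqrt(2 * (1 - rho))
      X1 <- X1 + matrix(shift * sd_diff, n, p, byrow = TRUE)
    } else { # bernoulli via correlated latent normals
      Z0 <- matrix(rnorm(n * p), n, p)
      L1 <- sqrt(rho) * Z0 + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
      L2 <- sqrt(rho) * Z0 + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
      pr1 <- 0.5 + shift / 4
      pr2 <- 0.5 - shift / 4
      X1 <- 0 + (L1 < matrix(qnorm(pr1), n, p, byrow = TRUE))
      X2 <- 0 + (L2 < matrix(qnorm(pr2), n, p, byrow = TRUE))
    }
    X <- rbind(X1, X2)
    out <- tibble(
      sample = sprintf("s%03d", seq_len(2 * n)),
      group = factor(rep(c("g1", "g2"), each = n)),
      pair = rep(sprintf("p%03d", seq_len(n)), 2)
    )
  }

  colnames(X) <- feat_names
  out <- dplyr::bind_cols(out, as_tibble(X))
  structure(out,
            informative = feat_names[seq_len(n_informative)],
            sim_config = list(p = p, n_informative = n_informative,
                              nbd = nbd, distribution = distribution,
                              design = design, n1 = n1, n2 = n2,
                              n_pairs = n_pairs, rho = rho,
                              bimodal_sep = bimodal_sep),
            class = c("mor_sim", class(out)))
}

#' @rdname simulate_features
#' @param x A `mor_sim` table.
#' @export
informative_features <- function(x) {
  attr(x, "informative", exact = TRUE) %||% character(0)
}

# feature_matrix from a simulated table: the sample-id column is metadata,
# group/pair columns are fixed by construction.
fm_from_sim <- function(sim) {
  d <- as_tibble(sim)
  d <- d[, setdiff(names(d), "sample"), drop = FALSE]
  if ("pair" %in% names(d)) {
    feature_matrix(d, group = group, pair = pair)
  } else {
    feature_matrix(d, group = group)
  }
}

#' Dichotomize features at the pooled median
#'
#' Converts every feature to binary: 1 where the value exceeds the
#' whole-pooled-sample median of that feature, 0 otherwise (so a constant
#' feature becomes all 0). This is the reference construction for comparing
#' scores across data types, since the binary version of a table carries
#' roughly the same group information as the metric original.
#'
#' @param data A data frame with feature columns (e.g. a
#'   [simulate_features()] table); `sample`, `group` and `pair` columns are
#'   passed through untouched.
#' @return The table with all feature columns replaced by 0/1 values;
#'   attributes (informative set) are preserved.
#' @export
dichotomize_at_median <- function(data) {
  stopifnot(is.data.frame(data))
  meta <- intersect(c("sample", "group", "pair"), names(data))
  feats <- setdiff(names(data), meta)
  out <- data
  for (nm in feats) {
    v <- out[[nm]]
    out[[nm]] <- as.numeric(v > median(v, na.rm = TRUE))
  }
  out
}
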