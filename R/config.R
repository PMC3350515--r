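#' Run configuration for a scoring workflow
#'
#' Bundles every knob of a screening run -- input table, design, score
#' parameters, selection criterion and outputs -- into a plain list that
#' serializes losslessly to JSON, so a full run can be driven headless from
#' one config file (see the `mor.R` command-line script in
#' `system.file("cli", package = "morscreen")`).
#'
#' @param input Path to the delimited input table (see
#'   [read_feature_matrix()]).
#' @param group,pair,design Column names / design passed to
#'   [read_feature_matrix()].
#' @param mode,gamma,weight,u_method Score parameters, see [mor()].
#' @param criterion One of `"sample_cutoff"`, `"entropy"`, `"permutation"`,
#'   `"fraction"`, `"top_proportion"`, `"screen"`.
#' @param w,z0,delta,alpha,n_perm,top_m,d,epsilon Criterion parameters.
#' @param seed Integer seed for any randomness (permutation criterion).
#' @param scores_out,selection_out Optional output paths.
#' @return A list of class `mor_config`.
#' @export
mor_config <- function(input, group, pair = NULL, design = NULL,
                       mode = "rank", gamma = 0.5, weight = 1,
                       u_method = "midpoint", criterion = "sample_cutoff",
                       w = 1, z0 = 3.28, delta = 0.01, alpha = 0.05,
                       n_perm = 1000, top_m = NULL, d = 0.8, epsilon = 0.01,
                       seed = NULL, scores_out = NULL, selection_out = NULL) {
  cfg <- list(
    input = input, group = group, pair = pair, design = design,
    mode = mode, gamma = gamma, weight = weight, u_method = u_method,
    criterion = criterion, w = w, z0 = z0, delta = delta, alpha = alpha,
    n_perm = n_perm, top_m = top_m, d = d, epsilon = epsilon, seed = seed,
    scores_out = scores_out, selection_out = selection_out
  )
  structure(cfg, class = "mor_config")
}

#' @rdname mor_config
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(config)
}

#' @rdname mor_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(mor_config, raw[!vapply(raw, is.null, logical(1))])
}

#' @rdname mor_config
#' @param config A `mor_config`.
#' @param quiet Suppress progress messages.
#' @return `run_mor_config()` returns a list with the information `chain`
#'   and the `selection`, invisibly writing any configured output files.
#' @export
run_mor_config <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "mor_config"))
  say <- function(...) if (!quiet) message(...)
  say("reading ", config$input)
  fm <- read_feature_matrix(config$input, group = config$group,
                            pair = config$pair, design = config$design)
  say("scoring ", ncol(fm$values), " features (", fm$design, " design, ",
      config$mode, " mode)")
  chain <- mor(fm, mode = config$mode, gamma = config$gamma,
               weight = config$weight, u_method = config$u_method)
  sel <- switch(config$criterion,
    sample_cutoff = select_sample_cutoff(chain, w = config$w,
                                         z0 = config$z0),
    entropy = select_entropy(chain, delta = config$delta),
    permutation = select_permutation(chain, alpha = config$alpha,
                                     n_perm = config$n_perm,
                                     top_m = config$top_m,
                                     seed = config$seed),
    fraction = select_fraction(chain, d = config$d),
    top_proportion = select_top_proportion(chain,
                                           epsilon = config$epsilon),
    screen = screen_features(chain, w = config$w, z0 = config$z0),
    abort(paste0("Unknown criterion: ", config$criterion))
  )
  say("criterion ", attr(sel, "criterion"), ": ", sum(sel$selected), "/",
      nrow(sel), " features selected",
      if (attr(sel, "status") != "ok") paste0(" [", attr(sel, "status"), "]"))
  if (!is.null(config$scores_out)) write_scores(chain, config$scores_out)
  if (!is.null(config$selection_out)) {
    write_selection(sel, config$selection_out)
  }
  invisible(list(chain = chain, selection = sel))
}
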