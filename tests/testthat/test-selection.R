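chain_of <- function(mors) {
  build_chain(tibble::tibble(
    feature = paste0("f", seq_along(mors)),
    n1 = 10, n2 = 10,
    mor = mors,
    degenerate = FALSE
  ))
}

test_that("entropy of an equal-score chain is ln(k) with decreasing relative change", {
  ch <- chain_of(rep(10, 60))
  sel <- select_entropy(ch, delta = 1e-9) # never triggers -> select all
  expect_equal(sum(sel$selected), 60)
  # H_k = ln k means D_k = (ln(k+1) - ln k)/ln k, monotone decreasing
  Dk <- vapply(2:59, function(k) (log(k + 1) - log(k)) / log(k), numeric(1))
  expect_true(all(diff(Dk) < 0))
  # with delta = 0.01 the walk stops where the closed form drops below it
  k_expected <- 1 + which(Dk < 0.01)[1]
  sel2 <- select_entropy(ch, delta = 0.01)
  expect_equal(sum(sel2$selected), k_expected)
})

test_that("a dominant-mass chain plateaus immediately (absolute change)", {
  ch <- chain_of(c(100, rep(0.001, 20)))
  sel <- select_entropy(ch, delta = 0.01, change = "absolute")
  expect_lte(sum(sel$selected), 2)
  expect_gte(sum(sel$selected), 1)
})

test_that("entropy selection handles empty and trivial chains", {
  expect_equal(sum(select_entropy(chain_of(rep(0, 5)))$selected), 0)
  expect_equal(attr(select_entropy(chain_of(rep(0, 5))), "status"),
               "empty_chain")
  expect_equal(sum(select_entropy(chain_of(3))$selected), 1)
})

test_that("entropy selection size is non-increasing in delta", {
  set.seed(81)
  for (i in 1:5) {
    ch <- chain_of(sort(abs(rnorm(40, sd = 3)), decreasing = TRUE))
    sizes <- vapply(c(0.001, 0.005, 0.01, 0.05, 0.2),
                    function(dl) sum(select_entropy(ch, delta = dl)$selected),
                    numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("fraction cut-off picks the smallest prefix reaching the share", {
  expect_equal(sum(select_fraction(chain_of(c(5, 3, 2)), d = 0.8)$selected), 2)
  expect_equal(sum(select_fraction(chain_of(c(4, 0, 0)), d = 0.5)$selected), 1)
  expect_equal(sum(select_fraction(chain_of(c(5, 3, 2, 0)), d = 1)$selected), 3)
})

test_that("top-proportion cut-off takes the ceiling of epsilon * p", {
  expect_equal(sum(select_top_proportion(chain_of(rnorm(1000)),
                                         epsilon = 0.01)$selected), 10)
  expect_equal(sum(select_top_proportion(chain_of(rnorm(7)),
                                         epsilon = 0.5)$selected), 4)
  expect_equal(sum(select_top_proportion(chain_of(rnorm(7)),
                                         epsilon = 0)$selected), 0)
})

test_that("sample-related cut-off scales as w * z0 / sqrt(N)", {
  ch <- chain_of(c(2, 0.5, 0))
  sel <- select_sample_cutoff(ch)
  expect_equal(unique(sel$threshold), 3.28 / sqrt(20), tolerance = 1e-12)
  expect_equal(selected_features(sel), "f1")
  # linear in w
  sel2 <- select_sample_cutoff(ch, w = 2)
  expect_equal(unique(sel2$threshold), 2 * 3.28 / sqrt(20))
  # strictly decreasing in N
  thr <- vapply(c(10, 20, 50, 200), function(N) {
    ch_n <- build_chain(tibble::tibble(feature = "f", n1 = N / 2, n2 = N / 2,
                                       mor = 1, degenerate = FALSE))
    select_sample_cutoff(ch_n)$threshold
  }, numeric(1))
  expect_true(all(diff(thr) < 0))
  # zero scores never pass
  expect_false(select_sample_cutoff(chain_of(0), w = 1e-6)$selected)
  # the complete-separation worked example passes for any w in (0, 4]
  d <- separated_tbl(n = 10, p_noise = 0)
  res <- mor(d, g)
  for (w in c(0.1, 1, 4)) {
    expect_true(select_sample_cutoff(res, w = w)$selected[1])
  }
})

test_that("chain-prefix criteria always return prefixes", {
  set.seed(91)
  for (i in 1:5) {
    ch <- chain_of(rnorm(30, sd = 2))
    for (sel in list(select_entropy(ch, delta = 0.02),
                     select_fraction(ch, d = runif(1, 0.2, 0.95)),
                     select_top_proportion(ch, epsilon = runif(1)))) {
      k <- sum(sel$selected)
      expect_equal(sel$selected, sel$chain_rank <= k)
    }
  }
})

test_that("permutation criterion enumerates all assignments for tiny samples", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 3),
                      f1 = c(4, 5, 6, 1, 2, 3), f2 = c(2, 9, 4, 7, 1, 8))
  sel <- select_permutation(mor(d, g), alpha = 0.05, n_perm = 1000)
  prm <- attr(sel, "parameters")
  expect_true(prm$exhaustive)
  expect_equal(prm$n_perm, choose(6, 3))
  # the separated feature attains the maximum over all 20 assignments
  expect_true(sel$selected[sel$feature == "f1"])
  expect_false(sel$selected[sel$feature == "f2"])
})

test_that("dependent permutations flip within-pair assignments", {
  set.seed(103)
  n <- 8
  x2 <- rnorm(n)
  x1 <- x2 + runif(n, 0.5, 3) # all differences positive, varying size
  d <- tibble::tibble(
    g = rep(c("t1", "t2"), each = n), id = rep(1:n, 2),
    f1 = c(x1, x2), f2 = rnorm(2 * n)
  )
  sel <- select_permutation(mor(d, g, pair = id), alpha = 0.05,
                            n_perm = 2^n)
  expect_true(attr(sel, "parameters")$exhaustive)
  expect_equal(attr(sel, "parameters")$n_perm, 2^n)
  expect_true(sel$selected[sel$feature == "f1"])
})

test_that("permutation null selection rate stays near alpha", {
  set.seed(101)
  alpha <- 0.05
  reps <- 300
  hits <- 0
  for (r in seq_len(reps)) {
    d <- tibble::tibble(g = rep(c("a", "b"), each = 4), f = rnorm(8))
    sel <- select_permutation(mor(d, g), alpha = alpha, n_perm = 100)
    hits <- hits + sel$selected[1]
  }
  K <- choose(8, 4) # 70, enumerated
  granularity <- ceiling(alpha * K) / K
  se <- sqrt(granularity * (1 - granularity) / reps)
  expect_lte(hits / reps, granularity + 3 * se)
})

test_that("top_m restriction only tests the head of the chain", {
  set.seed(105)
  d <- separated_tbl(n = 5, p_noise = 6)
  sel <- select_permutation(mor(d, g), alpha = 0.1, n_perm = 60, top_m = 2,
                            seed = 1)
  expect_equal(sum(!is.na(sel$perm_p)), 2)
  expect_true(all(!sel$selected[sel$chain_rank > 2]))
})

test_that("screening reports no informative features on a null table", {
  set.seed(111)
  d <- tibble::tibble(g = rep(c("a", "b"), each = 4))
  for (j in 1:5) d[[paste0("f", j)]] <- rnorm(8)
  sel <- screen_features(mor(d, g), w = 4) # very strict for tiny n
  expect_equal(attr(sel, "status"), "none_informative")
  expect_equal(sum(sel$selected), 0)

  d$sep <- rep(c(10, 0), each = 4) + rnorm(8, sd = 0.01)
  res <- mor(d, g)
  sel2 <- screen_features(res)
  expect_equal(res$feature[1], "sep")
  expect_true("sep" %in% selected_features(sel2))
})

test_that("screen refinement intersects the cut-off with the subjective rule", {
  set.seed(112)
  sim <- simulate_features(p = 200, n_informative = 20, nbd = 2,
                           n1 = 15, n2 = 15)
  res <- mor(sim)
  cut <- select_sample_cutoff(res)
  ref <- screen_features(res, refine = "top_proportion", epsilon = 0.025)
  expect_lte(sum(ref$selected), min(sum(cut$selected), 5))
  expect_true(all(selected_features(ref) %in% selected_features(cut)))
})

test_that("selection reports serialize to TSV and JSON", {
  d <- separated_tbl(n = 8, p_noise = 2)
  sel <- screen_features(mor(d, g))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, tsv)
  write_selection(sel, json)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$feature, sel$feature)
  expect_equal(back$selected, sel$selected)
  rep <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(rep$criterion, "screen")
  expect_equal(rep$selected, selected_features(sel))
  expect_equal(rep$n_selected, sum(sel$selected))
})
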