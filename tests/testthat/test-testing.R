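test_that("decision rule, provenance and reproducibility of dhsic_test", {
  d <- sim_ar_pairwise_coupled(T = 120, lambda = 1, seed = 5)
  r1 <- dhsic_test(d, resamples = 60, seed = 9)
  r2 <- dhsic_test(d, resamples = 60, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$rejected, r1$alpha > r1$p_value)
  expect_identical(r1$scheme, "shift")
  expect_length(r1$sigmas, 3L)
  expect_length(r1$null, 60L)
  # auto scheme picks permutation for multi-realization input
  dm <- iid_multireal(n = 20, T = 2, d = 2, seed = 2)
  expect_identical(dhsic_test(dm, resamples = 20, seed = 1)$scheme, "permute")
  expect_error(dhsic_test(dm, scheme = "shift"), "stationary")
  expect_error(dhsic_test(d, scheme = "permute"), "multireal")
})

test_that("a single resample can never reject at alpha = 0.05", {
  d <- sim_ar_pairwise_coupled(T = 100, lambda = 2, seed = 3)
  r <- dhsic_test(d, resamples = 1, seed = 1)
  expect_true(r$p_value %in% c(0.5, 1))
  expect_false(r$rejected)
})

test_that("scan recovers the coupled-pair structure of the additive system", {
  d <- sim_ar_pairwise_coupled(T = 400, lambda = 1.5, seed = 21)
  sc <- dhsic_scan(d, resamples = 200, seed = 21)
  tab <- sc$table
  get <- function(v) tab[tab$variables == v, ]
  expect_true(get("X,Z")$rejected)
  expect_true(get("Y,Z")$rejected)
  expect_false(get("X,Y")$rejected)
  expect_true(get("X,Y,Z")$rejected)
  expect_false(get("X,Y,Z")$emergent)  # explained by the rejected pairs
})

test_that("emergent flags require rejection and no rejected sub-subset", {
  flags <- dhsicts:::emergent_flags
  keys <- c("a,b", "a,c", "b,c", "a,b,c")
  expect_identical(flags(keys, c(FALSE, FALSE, FALSE, TRUE)),
                   c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(flags(keys, c(TRUE, FALSE, FALSE, TRUE)),
                   c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(flags(keys, c(FALSE, FALSE, FALSE, FALSE)),
                   rep(FALSE, 4))
  # brute-force cross-check on random reports over 4 variables
  vars <- letters[1:4]
  subsets <- unlist(lapply(2:4, function(k)
    combn(vars, k, paste, collapse = ",")), use.names = FALSE)
  members <- strsplit(subsets, ",")
  withr::with_seed(31, {
    for (rep in 1:20) {
      rej <- runif(length(subsets)) < 0.4
      got <- flags(subsets, rej)
      want <- vapply(seq_along(subsets), function(i) {
        rej[i] && !any(vapply(seq_along(subsets), function(j)
          length(members[[j]]) < length(members[[i]]) &&
            all(members[[j]] %in% members[[i]]) && rej[j], logical(1)))
      }, logical(1))
      expect_identical(got, want)
    }
  })
})

test_that("scan seeds derive from subset identity, not iteration order", {
  d <- sim_ar_pairwise_coupled(T = 150, lambda = 1, seed = 4)
  full <- dhsic_scan(d, resamples = 50, seed = 7)
  pairs_only <- dhsic_scan(d, resamples = 50, seed = 7, d_max = 2)
  for (k in pairs_only$table$variables) {
    expect_identical(full$results[[k]]$p_value,
                     pairs_only$results[[k]]$p_value)
  }
})

test_that("per-order multiplicity adjustment is monotone and optional", {
  d <- sim_ar_pairwise_coupled(T = 150, lambda = 1, seed = 6)
  raw <- dhsic_scan(d, resamples = 50, seed = 2)
  holm <- dhsic_scan(d, resamples = 50, seed = 2, multiplicity = "holm")
  expect_identical(raw$table$p_value, holm$table$p_value)
  expect_true(all(holm$table$p_adjusted >= raw$table$p_value - 1e-15))
  expect_true(all(holm$table$rejected <= raw$table$rejected |
                    holm$table$rejected == raw$table$rejected))
})

test_that("the parity gate is an emergent four-way dependency on short records", {
  x <- sim_xor_gate(n = 200, T = 2, seed = 5, invert_prob = 0)
  sc <- dhsic_scan(x, resamples = 200, seed = 5)
  tab <- sc$table
  expect_identical(sum(tab$rejected[tab$order <= 3]), 0L)
  four <- tab[tab$order == 4, ]
  expect_true(four$rejected)
  expect_true(four$emergent)
})

test_that("hypergraphs carry rejected or emergent subsets only", {
  d <- sim_ar_pairwise_coupled(T = 400, lambda = 1.5, seed = 21)
  sc <- dhsic_scan(d, resamples = 200, seed = 21)
  hg_all <- as_hypergraph(sc)
  hg_em <- as_hypergraph(sc, "emergent_only")
  expect_identical(length(hg_all$hyperedges), sum(sc$table$rejected))
  expect_identical(length(hg_em$hyperedges), sum(sc$table$emergent))
  # emergent edges are a subset of all rejections
  key <- function(e) paste(sort(e$members), collapse = ",")
  expect_true(all(vapply(hg_em$hyperedges, key, character(1)) %in%
                    vapply(hg_all$hyperedges, key, character(1))))
  # a report with no rejections yields nodes only
  d0 <- white_noise_dataset(80, d = 3, seed = 44)
  sc0 <- dhsic_scan(d0, resamples = 30, alpha = 0.001, seed = 1)
  hg0 <- as_hypergraph(sc0)
  expect_identical(hg0$nodes, d0$variable_names)
  expect_length(hg0$hyperedges, 0L)
})

test_that("scan reports and hypergraphs serialize to valid JSON and text", {
  d <- sim_ar_pairwise_coupled(T = 150, lambda = 1.5, seed = 12)
  sc <- dhsic_scan(d, resamples = 50, seed = 12)
  jf <- withr::local_tempfile(fileext = ".json")
  write_scan_json(sc, jf)
  rec <- jsonlite::read_json(jf)
  expect_length(rec, nrow(sc$table))
  expect_setequal(names(rec[[1]]),
                  c("variables", "statistic", "p_value", "p_adjusted",
                    "alpha", "rejected", "emergent", "scheme", "resamples",
                    "seed", "sigmas_used", "h"))
  hg <- as_hypergraph(sc)
  tf <- withr::local_tempfile(fileext = ".txt")
  write_hyperedges(hg, tf)
  expect_length(readLines(tf), length(hg$hyperedges))
  hf <- withr::local_tempfile(fileext = ".json")
  write_hypergraph_json(hg, hf)
  parsed <- jsonlite::read_json(hf)
  expect_identical(unlist(parsed$nodes), d$variable_names)
})
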