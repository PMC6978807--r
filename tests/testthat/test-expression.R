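test_that("detection filter applies the CPM >= 1 in >= 6 samples rule", {
  lib <- rep(1e6, 12)
  m <- rbind(
    at_boundary = c(rep(1, 6), rep(0, 6)),    # CPM exactly 1 in exactly 6
    below = c(rep(1, 5), rep(0, 7)),          # only 5 samples
    zero = rep(0, 12),
    high = rep(50, 12))
  colnames(m) <- paste0("s", 1:12)
  kept <- detection_filter(m, lib_sizes = setNames(lib, colnames(m)))
  expect_identical(rownames(kept), c("at_boundary", "high"))
  # idempotent, never gains rows
  kept2 <- detection_filter(kept, lib_sizes = attr(kept, "lib_sizes"))
  expect_identical(rownames(kept2), rownames(kept))
  expect_error(detection_filter(m, min_samples = 13,
                                lib_sizes = setNames(lib, colnames(m))),
               "min_samples")
})

test_that("TMM factors are exactly 1 for duplicated and scaled samples", {
  set.seed(1)
  x <- rpois(40, 50) + 1
  m <- cbind(a = x, b = x)
  expect_equal(unname(tmm_factors(m)), c(1, 1))
  m2 <- cbind(a = x, b = 2 * x)   # pure depth change, same composition
  expect_equal(unname(tmm_factors(m2)), c(1, 1))
})

test_that("TMM factors match edgeR::calcNormFactors on toy matrices", {
  library(edgeR)
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(rpois(20 * 4, 60) + 1, 20, 4,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
    m[1:2, 2] <- m[1:2, 2] * 40L   # two high-count genes spiked in sample 2
    f_pkg <- tmm_factors(m)
    f_edg <- edgeR::calcNormFactors(m, method = "TMM")
    expect_equal(unname(f_pkg), unname(f_edg), tolerance = 1e-6)
    expect_lt(abs(exp(mean(log(f_pkg))) - 1), 1e-9)
  }
})

test_that("log-CPM matches its closed form and is scale invariant", {
  m <- matrix(c(0, 100), 2, 1, dimnames = list(c("a", "b"), "s1"))
  lc <- log_cpm(m, lib_sizes = c(s1 = 1e6))
  expect_equal(lc$log_cpm["a", 1], log2(0.5 / (1e6 + 1) * 1e6))
  # CPM of 1 with zero prior has log-CPM zero
  m1 <- matrix(1, 1, 1, dimnames = list("a", "s1"))
  lc0 <- log_cpm(m1, prior_count = 0, lib_sizes = c(s1 = 1e6))
  expect_equal(unname(lc0$log_cpm[1, 1]), 0)
  # doubling counts and library size leaves log-CPM almost unchanged
  lc1 <- log_cpm(m, prior_count = 0.5, lib_sizes = c(s1 = 100))
  lc2 <- log_cpm(2 * m, prior_count = 1, lib_sizes = c(s1 = 200))
  expect_equal(lc2$log_cpm, lc1$log_cpm + 0)
})

test_that("PCA separates duplicated sample groups and matches eigen oracle", {
  set.seed(7)
  base1 <- rnorm(30); base2 <- rnorm(30)
  lc <- cbind(a1 = base1, a2 = base1, b1 = base2, b2 = base2)
  p <- pca_samples(lc, n_components = 3)
  pc1 <- p$coordinates$PC1
  expect_lt(abs(pc1[1] - pc1[2]), 1e-8)
  expect_lt(abs(pc1[3] - pc1[4]), 1e-8)
  expect_gt(abs(pc1[1] - pc1[3]), 1)
  # variance fractions of a non-degenerate matrix sum to 1
  lc2 <- matrix(rnorm(40 * 5), 40, 5,
                dimnames = list(NULL, paste0("s", 1:5)))
  p2 <- pca_samples(lc2, n_components = 5)
  expect_equal(sum(p2$sdev^2 / sum(p2$sdev^2)), 1)
  # oracle: eigendecomposition of the sample covariance of centered data
  cen <- lc2 - rowMeans(lc2)
  ev <- eigen(crossprod(cen))
  for (k in 1:2) {
    a <- p2$coordinates[[paste0("PC", k)]]
    b <- ev$vectors[, k] * sqrt(ev$values[k])
    expect_true(max(abs(a - b)) < 1e-8 || max(abs(a + b)) < 1e-8)
  }
  # constant matrix: zero coordinates and variance
  pc <- pca_samples(matrix(3, 5, 4, dimnames = list(NULL, paste0("s", 1:4))))
  expect_true(all(pc$coordinates$PC1 == 0))
  expect_true(all(pc$variance_explained == 0))
})

test_that("differential expression handles identical and degenerate groups", {
  d <- toy_design(2, methods = "UC")
  d <- d[d$timepoint == "24h", ]
  lc <- rbind(flat = rep(5, 4), shift = c(5, 5, 7, 7))
  colnames(lc) <- d$sample_id
  de <- differential_expression(lc, d, timepoint = "24h")
  expect_equal(de$p_value[de$mature_id == "flat"], 1)
  expect_equal(de$log2fc[de$mature_id == "flat"], 0)
  # constant but unequal: smallest representable p, flagged
  expect_equal(de$p_value[de$mature_id == "shift"], .Machine$double.xmin)
  expect_true(de$zero_variance[de$mature_id == "shift"])
  expect_error(differential_expression(lc, d[-1, ], timepoint = "24h"),
               "two samples")
})

test_that("Welch DE controls type-I error near nominal on null data", {
  ref <- generate_reference(400, seed = 55)
  d <- toy_design(3, methods = c("UC", "kit"))   # methods pooled: 6 vs 6
  d <- d[d$timepoint == "24h", ]
  fps <- vapply(1:3, function(s) {
    cfg <- simulation_config(d, seed = 100 + s, library_size_mean = 2e5)
    sim <- simulate_counts(cfg, ref)
    norm <- log_cpm(sim$counts, lib_sizes = sim$lib_sizes)
    de <- differential_expression(norm, d, timepoint = "24h")
    mean(de$p_value < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fps) - 0.05), 0.02)
})

test_that("a planted 4-fold change is recovered with high power", {
  ref <- generate_reference(100, seed = 77)
  target <- ref$mature_id[11]
  d <- toy_design(3, methods = "UC")
  d <- d[d$timepoint == "24h", ]
  hits <- vapply(1:25, function(s) {
    cfg <- simulation_config(d, seed = 500 + s, library_size_mean = 1e6,
                             planted_de = tibble::tibble(
                               mature_id = target, log2fc = 2,
                               timepoint = "24h"))
    sim <- simulate_counts(cfg, ref)
    norm <- log_cpm(sim$counts, tmm_factors(sim$counts),
                    lib_sizes = sim$lib_sizes)
    de <- differential_expression(norm, d, timepoint = "24h")
    de$differential[de$mature_id == target]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("abundance ranking orders by mean log-CPM and flags common miRNAs", {
  set.seed(3)
  lc <- matrix(rnorm(30 * 4, 5), 30, 4,
               dimnames = list(paste0("m", 1:30), paste0("s", 1:4)))
  counts <- matrix(100L, 30, 4, dimnames = dimnames(lc))
  rk <- abundance_ranking(lc, counts, top_n = 10)
  expect_identical(rk$mature_id, rownames(lc)[order(-rowMeans(lc))])
  expect_identical(sum(rk$common), 10L)   # identical detection everywhere
  # zeroing a top miRNA in one sample drops it from the common subset
  drop_id <- rk$mature_id[1]
  counts2 <- counts; counts2[drop_id, 2] <- 0L
  rk2 <- abundance_ranking(lc, counts2, top_n = 10)
  expect_false(rk2$common[rk2$mature_id == drop_id])
  expect_warning(abundance_ranking(lc, counts, top_n = 50), "top_n")
})

test_that("set overlap partitions exactly, including the study's set sizes", {
  expect_equal(set_overlap(letters[1:3], letters[4:7])[1:3],
               list(only_a = 3L, common = 0L, only_b = 4L))
  expect_equal(set_overlap(letters, letters)[1:3],
               list(only_a = 0L, common = 26L, only_b = 0L))
  # 420 and 520 detected with 397 shared -> 23 and 123 unique
  a <- c(sprintf("c%03d", 1:397), sprintf("a%02d", 1:23))
  b <- c(sprintf("c%03d", 1:397), sprintf("b%03d", 1:123))
  ov <- set_overlap(a, b)
  expect_equal(ov[1:3], list(only_a = 23L, common = 397L, only_b = 123L))
  expect_equal(ov$only_a + ov$common, length(a))
  expect_equal(ov$only_b + ov$common, length(b))
})

test_that("cell-type attribution separates exclusive, ambiguous, unassigned", {
  lists <- list(neuron = c("m1", "m2", "m3"), astro = c("m3", "m4"),
                microglia = "m5")
  res <- attribute_cell_types(c("m1", "m3", "m4", "m6"), lists)
  expect_equal(unname(res$summary[c("neuron", "astro", "microglia",
                                    "ambiguous", "unassigned")]),
               c(1L, 1L, 0L, 1L, 1L))
  expect_identical(res$assignments$label[res$assignments$mature_id == "m3"],
                   "ambiguous")
  # empty lists leave everything unassigned
  res0 <- attribute_cell_types(c("x", "y"), list(neuron = character()))
  expect_equal(unname(res0$summary["unassigned"]), 2L)
  # brute-force membership oracle on a random toy case
  set.seed(9)
  mir <- paste0("m", 1:10)
  rl <- list(A = sample(mir, 4), B = sample(mir, 5), C = sample(mir, 3))
  res2 <- attribute_cell_types(mir, rl)
  oracle <- vapply(mir, function(m)
    sum(vapply(rl, function(s) m %in% s, logical(1))), integer(1))
  expect_equal(res2$assignments$n_lists, unname(oracle))
})
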