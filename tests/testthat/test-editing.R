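test_that("binomial upper tail matches closed forms and direct summation", {
  expect_equal(binomial_tail(0, 50, 0.01), 1)
  expect_equal(binomial_tail(1, 100, 0.01), 1 - 0.99^100)
  expect_equal(binomial_tail(4, 6, 1 / 3), 73 / 729)
  expect_error(binomial_tail(5, 4, 0.01), "k <= n")
  expect_error(binomial_tail(1, 4, 0), "p_err")
  # exhaustive small-instance oracle: direct summation of the pmf
  for (n in c(1:60, 100, 250, 500)) {
    k <- 0:n
    direct <- rev(cumsum(rev(choose(n, k) * 0.01^k * 0.99^(n - k))))
    expect_lt(max(abs(binomial_tail(k, n, 0.01) - direct)), 1e-12)
  }
  # survival formulation stays finite and monotone at large n
  big <- binomial_tail(c(0, 1e4, 1e5, 1e7), 1e7, 0.01)
  expect_true(all(diff(big) <= 0) && all(is.finite(big)))
})

test_that("Phred 20 converts to the 0.01 null miscall rate", {
  expect_equal(phred_to_error(20), 0.01)
  expect_equal(phred_to_error(c(10, 30)), c(0.1, 0.001))
})

make_mod_table <- function(...) {
  tibble::tibble(...)
}

test_that("modification tests respect the count filter and BH scope", {
  counts <- matrix(c(9L, 1000L), 2, 2,
                   dimnames = list(c("low", "high"), c("s1", "s2")))
  mods <- make_mod_table(
    sample_id = c("s1", "s1", "s2"),
    mature_id = c("low", "high", "high"),
    position = c(5L, 7L, 7L),
    ref_nt = "A", obs_nt = "G",
    count = c(8L, 500L, 3L))
  tst <- call_sample_modifications(mods, counts, min_count = 10)
  # the n = 9 miRNA is never tested, however obvious the edit
  expect_false(any(tst$mature_id == "low"))
  expect_true(tst$significant[tst$sample_id == "s1"])
  expect_equal(tst$p_value[tst$sample_id == "s1"],
               binomial_tail(500, 1000, 0.01))
  # empty modification table: no tests
  expect_identical(nrow(call_sample_modifications(mods[0, ], counts)), 0L)
  # inconsistent input is a hard error
  bad <- make_mod_table(sample_id = "s9", mature_id = "high",
                        position = 1L, ref_nt = "A", obs_nt = "G",
                        count = 1L)
  expect_error(call_sample_modifications(bad, counts), "matching count")
  over <- make_mod_table(sample_id = "s2", mature_id = "high",
                         position = 1L, ref_nt = "A", obs_nt = "G",
                         count = 2000L)
  expect_error(call_sample_modifications(over, counts), "exceeds")
})

test_that("replication filter keeps sites flagged in >= 2 samples of a cell", {
  d <- simulate_design(3)
  tpl <- function(samples) make_mod_table(
    sample_id = samples, mature_id = "m1", position = 5L,
    ref_nt = "A", obs_nt = "G", count = 300L)
  counts <- matrix(1000L, 1, nrow(d), dimnames = list("m1", d$sample_id))
  one <- call_sample_modifications(tpl("control_24h_UC_r1"), counts)
  expect_identical(nrow(replication_filter(one, d)), 0L)
  two <- call_sample_modifications(
    tpl(c("control_24h_UC_r1", "control_24h_UC_r2")), counts)
  kept <- replication_filter(two, d)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$substitution, "A>G")
  # two significant samples split across different cells do not replicate
  split <- call_sample_modifications(
    tpl(c("control_24h_UC_r1", "KA_24h_UC_r1")), counts)
  expect_identical(nrow(replication_filter(split, d)), 0L)
  # ...unless the lenient threshold is met within a cell of either method
  expect_identical(nrow(replication_filter(split, d, min_samples = 1L)), 1L)
  # design must cover the flagged samples
  expect_error(replication_filter(two, d[-1, ]), "absent from design")
})

test_that("editing levels are k/n with missing levels under the count floor", {
  counts <- matrix(c(100L, 5L, 200L), 1, 3,
                   dimnames = list("m1", c("s1", "s2", "s3")))
  mods <- make_mod_table(sample_id = c("s1", "s3"), mature_id = "m1",
                         position = 4L, ref_nt = "A", obs_nt = "G",
                         count = c(50L, 0L))
  sites <- tibble::tibble(mature_id = "m1", position = 4L,
                          substitution = "A>G")
  lv <- editing_levels(sites, mods, counts)
  expect_equal(lv$level[lv$sample_id == "s1"], 0.5)
  expect_equal(lv$level[lv$sample_id == "s3"], 0)
  expect_true(is.na(lv$level[lv$sample_id == "s2"]))
})

test_that("differential editing: identical level vectors give p = 1", {
  d <- simulate_design(3)
  sites <- tibble::tibble(mature_id = "m1", position = 4L,
                          substitution = "A>G")
  lv <- tidyr::crossing(sites, sample_id = d$sample_id)
  lv$k <- 30L; lv$n <- 100L; lv$level <- 0.3
  de <- differential_editing(lv, d)
  expect_true(all(de$diff_p == 1))
  expect_false(any(de$significant))
})

test_that("planted differential editing is detected; equal levels are not", {
  ref <- generate_reference(6, seed = 31)
  mat <- mature_seq(ref)
  pos <- vapply(mat, function(s)
    as.integer(regexpr("A", substr(s, 2, nchar(s) - 1))) + 1L, integer(1))
  hosts <- names(pos)[pos >= 2]
  d <- toy_design(3)[toy_design(3)$timepoint == "24h" &
                       toy_design(3)$method == "UC", ]
  run_once <- function(s, lv_control, lv_ka) {
    edits <- dplyr::bind_rows(lapply(hosts, function(h)
      planted_edit(d, h, pos[[h]],
                   level = c(control = lv_control, KA = lv_ka))))
    cfg <- flat_config(d, seed = s, lib = 5000 * length(mat),
                       planted_edits = edits)
    sim <- simulate_counts(cfg, ref)
    rr <- emit_reads(sim, cfg, ref)
    q <- quantify_samples(rr$reads, ref)
    sites <- tibble::tibble(mature_id = hosts, position = pos[hosts],
                            substitution = "A>G")
    lv <- editing_levels(sites, q$modifications, q)
    differential_editing(lv, d)
  }
  alt <- vapply(1:12, function(s) all(run_once(s, 0.05, 0.5)$significant),
                logical(1))
  expect_gte(mean(alt), 0.95)
  null <- vapply(13:32, function(s) any(run_once(s, 0.3, 0.3)$significant),
                 logical(1))
  expect_lte(mean(null), 0.10)
})

test_that("planted editing levels are recovered with small bias", {
  ref <- generate_reference(4, seed = 31)
  mat <- mature_seq(ref)
  pos <- vapply(mat, function(s)
    as.integer(regexpr("A", substr(s, 2, nchar(s) - 1))) + 1L, integer(1))
  hosts <- names(pos)[pos >= 2][1:2]
  d <- toy_design(1)[1:2, ]
  for (level in c(0.05, 0.3)) {
    est <- vapply(1:8, function(s) {
      edits <- dplyr::bind_rows(lapply(hosts, function(h)
        planted_edit(d, h, pos[[h]], level = level)))
      cfg <- flat_config(d, seed = 300 + s, lib = 4 * 2500,
                         planted_edits = edits)
      sim <- simulate_counts(cfg, ref)
      rr <- emit_reads(sim, cfg, ref)
      q <- quantify_samples(rr$reads, ref)
      sites <- tibble::tibble(mature_id = hosts, position = pos[hosts],
                              substitution = "A>G")
      lv <- editing_levels(sites, q$modifications, q)
      mean(lv$level, na.rm = TRUE)
    }, numeric(1))
    expect_lt(abs(mean(est) - level), 0.02)
  }
})

test_that("seed enrichment is the exact upper-tail binomial", {
  expect_equal(seed_enrichment(6, 0), 1)
  expect_equal(seed_enrichment(6, 4, 1), 1)
  expect_equal(seed_enrichment(6, 4, 1 / 3), 73 / 729)
  expect_error(seed_enrichment(6, 7), "n_in_seed")
})

test_that("motif context reads flanks off the mature sequence", {
  ref <- mirna_reference("g1", "UUAGGGAAACCCUUUGGAC", "m1", 1, 19)
  sites <- tibble::tibble(mature_id = "m1", position = 3L,
                          substitution = "A>G")
  mc <- motif_context(sites, ref)
  expect_equal(mc$contexts$preceding, "U")
  expect_equal(mc$contexts$edited, "A")
  expect_equal(mc$contexts$following, "G")
  # boundary: position 1 has no preceding flank
  ref2 <- mirna_reference("g2", "AUAGGGAAACCCUUUGGAC", "m2", 1, 19)
  mc2 <- motif_context(tibble::tibble(mature_id = "m2", position = 1L,
                                      substitution = "A>U"), ref2)
  expect_true(is.na(mc2$contexts$preceding))
  # reference / substitution inconsistency is an error
  expect_error(motif_context(tibble::tibble(mature_id = "m1", position = 3L,
                                            substitution = "G>A"), ref),
               "disagrees")
  expect_equal(sum(mc$pfm["preceding", ]), 1)
})

test_that("site restriction filters substitution class and whitelist", {
  sites <- tibble::tibble(
    mature_id = c("m1", "m2", "m3", "m4"),
    position = 1:4,
    substitution = c("A>G", "C>U", "A>G", "A>G"))
  expect_identical(restrict_sites(sites)$mature_id, c("m1", "m3", "m4"))
  expect_identical(restrict_sites(sites, "C>U")$mature_id, "m2")
  wl <- c("m3", "m2")
  expect_identical(restrict_sites(sites, whitelist = wl)$mature_id, "m3")
  expect_warning(none <- restrict_sites(sites, whitelist = character()),
                 "empty whitelist")
  expect_identical(nrow(none), 0L)
  # oracle: plain logical filter
  oracle <- sites[sites$substitution == "A>G" & sites$mature_id %in% wl, ]
  expect_equal(restrict_sites(sites, whitelist = wl), oracle)
})

test_that("the bundled catalog classifies 4 of 6 sites as seed-edited", {
  cat6 <- edited_site_catalog()
  expect_identical(nrow(cat6$sites), 6L)
  ann <- annotate_seed(cat6$sites, cat6$reference)
  expect_identical(sum(ann$in_seed), 4L)
  expect_true(all(ann$in_seed[ann$position <= 8]))
  mc <- motif_context(cat6$sites, cat6$reference)
  expect_equal(unname(mc$pfm["preceding", "U"]), 4)
  expect_equal(unname(mc$pfm["preceding", "G"]), 0)
  expect_equal(unname(mc$pfm["following", "G"]), 5)
  expect_true(all(mc$contexts$edited == "A"))
})
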