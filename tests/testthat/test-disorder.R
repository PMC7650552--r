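test_that("disorder mask thresholds at >= cutoff, strict mode at >", {
  expect_equal(call_disorder_mask(c(0.6, 0.4, 0.5)), c(TRUE, FALSE, TRUE))
  expect_equal(call_disorder_mask(c(0.6, 0.4, 0.5), strict = TRUE),
               c(TRUE, FALSE, FALSE))
  expect_false(any(call_disorder_mask(rep(0, 10))))
  expect_true(all(call_disorder_mask(rep(1, 10))))
  expect_error(call_disorder_mask(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(call_disorder_mask(numeric(0)), "empty")
})

test_that("IDR calling respects the 30-residue minimum-length boundary", {
  f30 <- rep(c(FALSE, TRUE, FALSE), c(10, 30, 60))
  got <- call_idrs(f30, min_len = 30)
  expect_equal(got, data.frame(start = 11L, end = 40L, length = 30L))

  f29 <- rep(c(FALSE, TRUE, FALSE), c(10, 29, 61))
  expect_equal(nrow(call_idrs(f29, min_len = 30)), 0L)

  two <- rep(c(TRUE, FALSE, TRUE), c(40, 1, 40))
  got2 <- call_idrs(two, min_len = 30)
  expect_equal(got2$start, c(1L, 42L))
  expect_equal(got2$length, c(40L, 40L))
})

test_that("IDR caller matches the run-enumeration oracle on random masks", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(1:200, 1)
    flags <- runif(n) < runif(1, 0.2, 0.8)
    min_len <- sample(c(1L, 5L, 30L), 1)
    expect_equal(call_idrs(flags, min_len), oracle_idrs(flags, min_len))
  }
})

test_that("an IDP is a protein with at least one IDR", {
  none <- call_idrs(rep(FALSE, 50))
  one <- call_idrs(rep(TRUE, 50))
  expect_false(is_idp(none))
  expect_true(is_idp(one))
  three <- call_idrs(rep(c(TRUE, FALSE, TRUE, FALSE, TRUE),
                         c(30, 5, 30, 5, 30)))
  expect_equal(nrow(three), 3L)
  expect_true(is_idp(three))
})

test_that("proteome summaries compute both disorder fractions", {
  mk <- function(id, n, idr_len, at = 1L) {
    sc <- rep(0.1, n)
    if (idr_len > 0) sc[at:(at + idr_len - 1)] <- 0.9
    disorder_mask(sc, id)
  }
  masks <- c(lapply(1:4, function(i) mk(paste0("d", i), 100, 30)),
             lapply(1:6, function(i) mk(paste0("o", i), 100, 0)))
  names(masks) <- vapply(masks, `[[`, character(1), "protein_id")
  s <- summarize_proteome(masks, "sp1")
  expect_equal(s$idp_fraction, 0.4)
  expect_equal(s$n_idps, 4L)
  expect_equal(s$n_residues, 1000L)
  expect_equal(s$idr_fraction, 120 / 1000)

  one <- list(p1 = mk("p1", 100, 30))
  expect_equal(summarize_proteome(one, "x")$idr_fraction, 0.30)

  ordered <- list(p1 = mk("p1", 100, 0), p2 = mk("p2", 80, 0))
  s0 <- summarize_proteome(ordered, "x")
  expect_equal(s0$idp_fraction, 0)
  expect_equal(s0$idr_fraction, 0)
  expect_error(summarize_proteome(list(), "x"), "empty")
})

test_that("flag counting upper-bounds IDR counting and cutoffs are monotone", {
  set.seed(31)
  for (i in 1:20) {
    sc <- runif(sample(50:300, 1))
    m_idr <- disorder_mask(sc, "p", min_len = 10)
    masks <- list(p = m_idr)
    s_idr <- summarize_proteome(masks, "s", residue_counting = "idr")
    s_flag <- summarize_proteome(masks, "s", residue_counting = "flag")
    expect_lte(s_idr$n_disordered_residues, s_flag$n_disordered_residues)
    # lowering the cutoff never decreases disordered residues
    lo <- sum(call_disorder_mask(sc, cutoff = 0.3))
    hi <- sum(call_disorder_mask(sc, cutoff = 0.7))
    expect_gte(lo, hi)
    # lowering min_len never decreases the number of IDRs
    expect_gte(nrow(call_idrs(m_idr$flags, 5)), nrow(call_idrs(m_idr$flags, 20)))
  }
})

test_that("proteome filter keeps species at the 300-protein boundary", {
  s <- data.frame(species_id = c("a", "b", "c"),
                  n_proteins = c(299L, 300L, 301L))
  expect_message(kept <- filter_proteomes(s, 300), "removed 1")
  expect_equal(kept$species_id, c("b", "c"))
  expect_equal(nrow(filter_proteomes(s[0, ], 300)), 0L)
})

test_that("pearson_r matches hand-computed covariance arithmetic", {
  # x=(1,2,3,4), y=(2,1,4,3): cov = 3/3, var_x = var_y = 5/3, r = 3/5
  got <- pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(got$r, 0.6, tolerance = 1e-12)
  expect_equal(pearson_r(1:5, 1:5 * 2)$r, 1.0)
  expect_equal(pearson_r(1:5, -(1:5))$r, -1.0)
  expect_error(pearson_r(1:4, 1:3), "length mismatch")
  expect_error(pearson_r(rep(1, 4), 1:4), "zero variance")
  expect_error(pearson_r(1:2, 2:1), "at least 3")
})

test_that("disorder-vs-cell-types correlation recovers a planted relation", {
  set.seed(53)
  n <- 12
  cts <- round(seq(20, 220, length.out = n))
  summaries <- data.frame(
    species_id = sprintf("sp%02d", 1:n),
    idp_fraction = 0.1 + 0.002 * cts,            # exact linear
    idr_fraction = 0.05 + 0.001 * cts + rnorm(n, 0, 0.005))
  tab <- data.frame(species_id = summaries$species_id,
                    taxon_label = "vert", n_proteins = 500L,
                    n_cell_types = cts)
  got <- correlate_disorder_with_celltypes(summaries, tab)
  expect_equal(got$r_idp, 1.0, tolerance = 1e-9)
  expect_gt(got$r_idr, 0.9)
  expect_lt(got$p_idr, 0.01)

  const <- summaries
  const$idp_fraction <- 0.5
  expect_error(correlate_disorder_with_celltypes(const, tab), "zero variance")
  expect_error(correlate_disorder_with_celltypes(summaries[1:2, ], tab),
               "at least 3")
})

test_that("taxon quartiles reproduce the 1.5-IQR whisker rule", {
  s <- data.frame(species_id = sprintf("s%02d", 1:11),
                  idp_fraction = c(seq(0.1, 0.5, length.out = 10), 0.95),
                  idr_fraction = 0.1)
  tab <- data.frame(species_id = s$species_id, taxon_label = "tx",
                    n_proteins = 400L)
  q <- taxon_quartiles(s, tab, "idp_fraction")
  expect_equal(q$n, 11L)
  expect_equal(q$median, median(s$idp_fraction))
  expect_equal(q$q1, unname(quantile(s$idp_fraction, 0.25)))
  # 0.95 is an outlier beyond q3 + 1.5 IQR, so the whisker stops below it
  expect_lt(q$whisker_high, 0.95)
  expect_equal(q$max, 0.95)
})
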