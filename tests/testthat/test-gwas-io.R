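test_that("reading a well-formed TSV loads every record and a round trip preserves it", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
    "rs1\t1\t1000\tA\tG\t0.25\t0.02\t0.005\t6.3e-5\t100000",
    "rs2\t2\t2000\tc\tt\t0.40\t-0.01\t0.004\t0.012\t100000",
    "rs3\t3\t3000\tG\tA\t0.10\t0.03\t0.006\t5.7e-7\t100000"
  ), path)
  ss <- read_summary_stats(path, trait_name = "demo")
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss), 3L)
  # lowercase alleles are normalised, not rejected
  expect_equal(ss$effect_allele[ss$variant_id == "rs2"], "C")
  expect_equal(attr(ss, "load_report")[["n_rejected"]], 0L)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, out)
  back <- read_summary_stats(out, trait_name = "demo")
  expect_equal(as.data.frame(back)[names(back) != "chrom"],
               as.data.frame(ss)[names(ss) != "chrom"])
})

test_that("rows violating record invariants are dropped and counted", {
  rec <- data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    chrom = "1", pos = c(100, 200, 300, 400, 500),
    effect_allele = c("A", "A", "A", "A", "A"),
    other_allele = c("G", "G", "A", "G", "G"),
    eaf = c(0.3, 0.3, 0.3, 1.2, 0.3),
    beta = 0.01, se = c(0.005, 0, 0.005, 0.005, 0.005),
    pvalue = c(0.04, 0.04, 0.04, 0.04, 1.7), n = 1e5
  )
  ss <- summary_stats(rec, trait_name = "qc")
  expect_equal(nrow(ss), 1L)
  rep <- attr(ss, "load_report")
  expect_equal(rep[["n_rejected"]], 4L)
  expect_equal(rep[["bad_se"]], 1L)
  expect_equal(rep[["bad_allele"]], 1L)
  expect_equal(rep[["bad_eaf"]], 1L)
  expect_equal(rep[["bad_pvalue"]], 1L)
})

test_that("read errors name the missing column and reject empty files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tPOS\tEA\tOA\tEAF\tSE\tP\tN",
               "rs1\t1\t100\tA\tG\t0.3\t0.005\t0.04\t1e5"), path)
  expect_error(read_summary_stats(path), "BETA")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN", empty)
  expect_error(read_summary_stats(empty), "empty")
})

test_that("instrument selection applies the significance threshold", {
  ss <- make_ss(paste0("rs", 1:5), beta = rep(0.01, 5), se = rep(0.005, 5),
                pvalue = c(1e-6, 1e-7, 5e-8, 2e-3, 0.5))
  expect_equal(nrow(select_instruments(ss)), 0L)
  ss2 <- make_ss(paste0("rs", 1:5), beta = rep(0.01, 5), se = rep(0.005, 5),
                 pvalue = c(1e-9, 1e-7, 4.9e-8, 2e-3, 0.5))
  expect_setequal(select_instruments(ss2)$variant_id, c("rs1", "rs3"))
})

test_that("greedy LD clumping keeps the best of a correlated trio and respects the window", {
  ss <- make_ss(c("rsA", "rsB", "rsC"), beta = c(0.05, 0.05, 0.05),
                se = 0.005, pvalue = c(1e-9, 1e-10, 1e-8),
                pos = c(1000, 2000, 3000))
  r2 <- matrix(0.5, 3, 3); diag(r2) <- 1
  ld <- ld_matrix(c("rsA", "rsB", "rsC"), r2)
  kept <- select_instruments(ss, ld = ld)
  expect_equal(kept$variant_id, "rsB")

  # distance-only fallback: two hits 20,000 kb apart both survive
  far <- make_ss(c("rs1", "rs2"), beta = 0.05, se = 0.005,
                 pvalue = c(1e-9, 1e-9), pos = c(1e6, 1e6 + 2e7))
  expect_equal(nrow(select_instruments(far)), 2L)
  # ...but at exactly the window boundary (inclusive) only one survives
  near <- make_ss(c("rs1", "rs2"), beta = 0.05, se = 0.005,
                  pvalue = c(1e-9, 1e-8), pos = c(1e6, 1e6 + 1e7))
  expect_equal(select_instruments(near)$variant_id, "rs1")
})

test_that("an LD matrix missing a significant variant is an error naming it", {
  ss <- make_ss(c("rsA", "rsB"), beta = 0.05, se = 0.005,
                pvalue = c(1e-9, 1e-9), pos = c(1000, 2000))
  ld <- ld_matrix("rsA", matrix(1, 1, 1))
  expect_error(select_instruments(ss, ld = ld), "rsB")
})

test_that("clumping output is independent of input row order and satisfies the r2 rule", {
  set.seed(11)
  n <- 40
  ids <- sprintf("rs%02d", 1:n)
  pos <- sort(sample.int(5e7, n))
  p <- 10^runif(n, -12, -5)
  z <- matrix(rnorm(n * 3), n)
  r <- cor(t(z))
  ld <- ld_matrix(ids, r^2)
  ss <- make_ss(ids, beta = 0.05, se = 0.005, pvalue = p, pos = pos)
  kept <- select_instruments(ss, r2_max = 0.2, window_kb = 10000, ld = ld)

  perm <- sample.int(n)
  ss_perm <- make_ss(ids[perm], beta = 0.05, se = 0.005, pvalue = p[perm],
                     pos = pos[perm])
  kept_perm <- select_instruments(ss_perm, r2_max = 0.2, window_kb = 10000,
                                  ld = ld)
  expect_equal(kept$variant_id, kept_perm$variant_id)

  # exhaustive scan: retained pairs within the window have r2 < threshold
  k <- kept$variant_id
  for (i in seq_along(k)) for (j in seq_along(k)) {
    if (i >= j) next
    if (abs(kept$pos[i] - kept$pos[j]) <= 1e7) {
      expect_lt(ld[k[i], k[j]], 0.2)
    }
  }
  # every dropped significant variant conflicts with some retained one
  dropped <- setdiff(ids[p < 5e-8], k)
  for (d in dropped) {
    dpos <- pos[match(d, ids)]
    conflict <- any(vapply(seq_along(k), function(i) {
      abs(kept$pos[i] - dpos) <= 1e7 && ld[d, k[i]] >= 0.2
    }, logical(1)))
    expect_true(conflict)
  }
})

test_that("harmonisation aligns swapped alleles, flips signs, and is idempotent", {
  exp <- make_ss(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.1, 0.1), se = 0.01,
                 effect_allele = c("A", "A", "A"),
                 other_allele = c("G", "G", "G"), eaf = 0.3)
  out_rec <- data.frame(
    variant_id = c("rs1", "rs2"), chrom = "1", pos = c(3e7, 6e7),
    effect_allele = c("A", "G"), other_allele = c("G", "A"),
    eaf = c(0.3, 0.7), beta = c(0.2, 0.2), se = 0.02,
    pvalue = 0.001, n = 1e5
  )
  out <- summary_stats(out_rec, trait_name = "outcome")
  h <- harmonise(exp, out)
  expect_equal(h$variant_id, c("rs1", "rs2"))
  expect_equal(h$flag, c("unchanged", "allele_flipped"))
  expect_equal(h$beta_out, c(0.2, -0.2))
  prov <- attr(h, "provenance")
  expect_equal(prov$flag[prov$variant_id == "rs3"], "dropped_missing")

  # idempotence: re-harmonising the aligned pair changes nothing
  out2 <- summary_stats(data.frame(
    variant_id = h$variant_id, chrom = h$chrom, pos = h$pos,
    effect_allele = h$effect_allele, other_allele = h$other_allele,
    eaf = h$eaf, beta = h$beta_out, se = h$se_out, pvalue = 0.001, n = 1e5
  ), trait_name = "outcome")
  h2 <- harmonise(exp, out2)
  expect_equal(h2$beta_out, h$beta_out)
  expect_true(all(h2$flag == "unchanged"))
})

test_that("double allele swap is the identity", {
  swap <- function(rec) {
    tmp <- rec$effect_allele; rec$effect_allele <- rec$other_allele
    rec$other_allele <- tmp
    rec$beta <- -rec$beta; rec$eaf <- 1 - rec$eaf
    rec
  }
  rec <- data.frame(variant_id = "rs1", chrom = "1", pos = 100,
                    effect_allele = "A", other_allele = "G", eaf = 0.2,
                    beta = 0.05, se = 0.01, pvalue = 1e-4, n = 1e5)
  expect_equal(swap(swap(rec)), rec)
})

test_that("palindromic variants are aligned by frequency or dropped in the ambiguous band", {
  exp <- make_ss(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.01,
                 effect_allele = "A", other_allele = "T",
                 eaf = c(0.2, 0.50, 0.2))
  out <- summary_stats(data.frame(
    variant_id = c("rs1", "rs2", "rs3"), chrom = "1",
    pos = c(3e7, 6e7, 9e7),
    effect_allele = "A", other_allele = "T",
    eaf = c(0.2, 0.5, 0.8), beta = 0.2, se = 0.02, pvalue = 0.001, n = 1e5
  ), trait_name = "outcome")
  h <- harmonise(exp, out)
  prov <- attr(h, "provenance")
  # rs1: both eafs 0.2, same side -> kept unchanged
  expect_equal(h$beta_out[h$variant_id == "rs1"], 0.2)
  # rs2: eaf 0.50 inside (0.40, 0.60) -> dropped
  expect_equal(prov$flag[prov$variant_id == "rs2"], "dropped_palindromic")
  expect_false("rs2" %in% h$variant_id)
  # rs3: opposite sides -> strand flip, sign reversed
  expect_equal(h$beta_out[h$variant_id == "rs3"], -0.2)
  expect_equal(h$flag[h$variant_id == "rs3"], "allele_flipped")
})

test_that("palindromic variants with missing frequency and irreconcilable alleles are dropped", {
  exp <- make_ss(c("rs1", "rs2"), beta = 0.1, se = 0.01,
                 effect_allele = c("A", "A"), other_allele = c("T", "G"),
                 eaf = c(NA, 0.3))
  out <- summary_stats(data.frame(
    variant_id = c("rs1", "rs2"), chrom = "1", pos = c(3e7, 6e7),
    effect_allele = c("A", "A"), other_allele = c("T", "C"),
    eaf = c(0.2, 0.3), beta = 0.2, se = 0.02, pvalue = 0.001, n = 1e5
  ), trait_name = "outcome")
  expect_warning(h <- harmonise(exp, out), "irreconcilable")
  prov <- attr(h, "provenance")
  expect_equal(prov$flag[prov$variant_id == "rs1"], "dropped_palindromic")
  expect_equal(prov$flag[prov$variant_id == "rs2"], "dropped_mismatch")
  expect_equal(nrow(h), 0L)
})

test_that("strand-complemented non-palindromic records are recognised", {
  exp <- make_ss("rs1", beta = 0.1, se = 0.01,
                 effect_allele = "A", other_allele = "G", eaf = 0.3)
  out <- summary_stats(data.frame(
    variant_id = "rs1", chrom = "1", pos = 3e7,
    effect_allele = "T", other_allele = "C", eaf = 0.3,
    beta = 0.2, se = 0.02, pvalue = 0.001, n = 1e5
  ), trait_name = "outcome")
  h <- harmonise(exp, out)
  expect_equal(h$flag, "unchanged")
  expect_equal(h$beta_out, 0.2)
})

test_that("instrument strength computes per-variant and mean F with a strict weak boundary", {
  h <- make_hset(beta_exp = c(0.02), se_exp = c(0.005),
                 beta_out = 0.01, se_out = 0.01)
  st <- instrument_strength(h)
  expect_equal(unname(st$f), 16)
  expect_false(st$weak)

  h2 <- make_hset(0.01, 0.01, 0.01, 0.01)
  expect_true(instrument_strength(h2)$weak)

  # mean F exactly 10 is NOT "exceeding 10": flagged weak
  h3 <- make_hset(c(0.02, 0.01), c(0.005, 0.005), c(0.01, 0.01), 0.01)
  st3 <- instrument_strength(h3)
  expect_equal(st3$mean_f, 10)
  expect_true(st3$weak)

  expect_error(instrument_strength(h3[0, ]), "empty")
})
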