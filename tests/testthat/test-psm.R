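test_that("filter_psms enforces length and the inclusive E-value boundary", {
  tab <- psm_table(peptide = c("SHORT", "LONGPEPTIDE", "ATBOUNDARYK",
                               "JUSTABOVEK"),
                   protein_ids = c("p1", "p2", "p3", "p4"),
                   e_value = c(1e-12, 1e-12, 10^-8.3, 10^-8.29),
                   source_organism = "S", target_genome = "S")
  out <- filter_psms(tab, filter_config())
  # 5-residue peptide removed despite confident E-value; -8.30 kept, -8.29 not
  expect_setequal(out$peptide, c("LONGPEPTIDE", "ATBOUNDARYK"))
})

test_that("duplicate peptides collapse to the best E-value", {
  tab <- psm_table(peptide = c("PEPTIDEK", "PEPTIDEK", "OTHERPEPK"),
                   protein_ids = c("p1", "p1", "p2"),
                   e_value = c(1e-9, 1e-12, 1e-10),
                   source_organism = "S", target_genome = "S")
  out <- filter_psms(tab, filter_config())
  expect_identical(nrow(out), 2L)
  expect_equal(out$e_value[out$peptide == "PEPTIDEK"], 1e-12)
})

test_that("filtering matches the naive predicate oracle and is idempotent", {
  tab <- with_seed_helper(23, random_psm_table(5000))
  out <- filter_psms(tab, filter_config())
  keep <- nchar(tab$peptide) >= 6 & log10(tab$e_value) <= -8.3
  want <- tab[keep, ]
  want <- want[order(want$e_value), ]
  want <- want[!duplicated(want$peptide), ]
  expect_setequal(out$peptide, want$peptide)
  expect_equal(sort(out$e_value), sort(want$e_value))
  expect_identical(as.data.frame(filter_psms(out, filter_config())),
                   as.data.frame(out))
})

test_that("fully tryptic verification against an index and genome guard", {
  prot <- proteome("G", "p1", "MKTAYIAKQR")
  idx <- build_peptide_index(prot, digest_params(6, 0))
  tab <- psm_table(peptide = c("TAYIAK", "NOTTRYPTIC"),
                   protein_ids = c("p1", "p1"), e_value = c(1e-12, 1e-12),
                   source_organism = "G", target_genome = "G")
  out <- filter_psms(tab, filter_config(), idx)
  expect_identical(out$peptide, "TAYIAK")
  expect_identical(attr(out, "digest_params"), idx$params)
  wrong <- psm_table("TAYIAK", "p1", 1e-12, "G", "H")
  expect_error(filter_psms(wrong, filter_config(), idx), "targets H")
})

test_that("top-fraction mode recomputes the E-value cut from the data", {
  tab <- with_seed_helper(5, random_psm_table(2000))
  out <- filter_psms(tab, filter_config(min_length = 1,
                                        top_fraction = 0.10))
  # roughly the top 10% most confident records survive (before peptide
  # dedup the count is bounded by the quantile definition)
  expect_lte(nrow(out), ceiling(0.11 * nrow(tab)))
  expect_gte(nrow(out), floor(0.09 * nrow(tab)) - 1)
  expect_true(all(out$e_value <= sort(tab$e_value)[ceiling(0.11 * nrow(tab))]))
})

test_that("the printed E-value and log cutoffs denote the same filter", {
  expect_equal(log10(5.01e-9), -8.3, tolerance = 1e-4)
  expect_equal(signif(10^-8.3, 3), 5.01e-9)
})

test_that("percentile interval boundaries match an independent oracle", {
  # degenerate distribution: all boundaries equal the constant
  b <- evalue_percentile_intervals(rep(-5, 40))
  expect_true(all(unclass(b) == -5))
  x <- -10:-1
  b <- evalue_percentile_intervals(x)
  want <- vapply(c(0.10, 0.25, 0.50, 0.75, 0.90), oracle_percentile,
                 numeric(1), x = x)
  expect_equal(unname(unclass(b)), want)
  # rank-count property at the 10th percentile
  set.seed(8)
  for (i in 1:10) {
    v <- runif(sample(5:200, 1), -14, -1)
    b <- evalue_percentile_intervals(v)
    expect_gte(sum(v <= b[["p10"]]), ceiling(0.10 * length(v)) - 1)
  }
  expect_error(evalue_percentile_intervals(numeric(0)), "nonempty")
})

test_that("interval assignment partitions values as A-E", {
  v <- with_seed_helper(2, runif(500, -14, -1))
  b <- evalue_percentile_intervals(v)
  a <- assign_interval(v, b)
  expect_false(anyNA(a))
  expect_identical(levels(a), c("A", "B", "C", "D", "E"))
  expect_true(all(v[a == "A"] <= b[["p10"]]))
  expect_true(all(v[a == "E"] > b[["p75"]]))
})

test_that("infer_proteins applies the two-unique-peptide rule per locus", {
  tab <- psm_table(peptide = c("AAAAAAK", "CCCCCCK", "DDDDDDK", "EEEEEEK"),
                   protein_ids = c("p1,p2", "p1", "p2", "p3"),
                   e_value = rep(1e-12, 4),
                   source_organism = "S", target_genome = "S")
  obs <- infer_proteins(tab, 2)
  # the shared peptide supports both loci; p3 has a single peptide
  expect_setequal(names(obs), c("p1", "p2"))
  expect_setequal(obs$p1, c("AAAAAAK", "CCCCCCK"))
  expect_identical(names(infer_proteins(tab, 1)),
                   sort(c("p1", "p2", "p3")))
})

test_that("infer_proteins equals a group-by oracle and is monotone", {
  tab <- with_seed_helper(77, random_psm_table(800))
  prev <- Inf
  for (k in 1:4) {
    obs <- infer_proteins(tab, k)
    # oracle: explode rows, count distinct peptides per protein
    ids <- strsplit(tab$protein_ids, ",")
    df <- data.frame(prot = unlist(ids),
                     pep = rep(tab$peptide, lengths(ids)))
    cnt <- tapply(df$pep, df$prot, function(p) length(unique(p)))
    expect_setequal(names(obs), names(cnt)[cnt >= k])
    expect_lte(length(obs), prev)
    prev <- length(obs)
  }
})

test_that("PSM TSV dialect round-trips and rejects bad rows", {
  tab <- with_seed_helper(4, random_psm_table(50))
  path <- tempfile(fileext = ".tsv")
  write_psm_table(tab, path)
  back <- read_psm_table(path)
  expect_identical(back$peptide, tab$peptide)
  expect_equal(back$e_value, tab$e_value)
  expect_identical(attr(back, "target_genome"), "S")
  bad <- tab
  bad$e_value[1] <- -1
  write.table(as.data.frame(bad), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_psm_table(path), "e_value")
})
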