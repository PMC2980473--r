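test_that("normalized_ratio reproduces the worked example and guards zero", {
  expect_equal(round(normalized_ratio(3067, 4594), 2), 0.67)
  expect_identical(normalized_ratio(250, 250), 1)
  expect_identical(normalized_ratio(0, 10), 0)
  expect_error(normalized_ratio(5, 0), "n_self")
  expect_error(normalized_ratio(-1, 10), "n_neighbor")
})

make_pair <- function(kd = 0.1, seed = 50, n = 25) {
  cl <- simulate_clade(synthetic_config(
    n_proteins = n, protein_length_mean = 150,
    target_16s_distances = c(0, kd / 5), kappa = 5, seed = seed))
  idx <- lapply(cl$taxa, build_peptide_index, params = digest_params())
  tab <- simulate_observation(cl$taxa$T1, digest_params(),
                              detection_config(1, seed = seed))
  flt <- filter_psms(tab, filter_config(min_length = 6, max_log_e = 0),
                     idx$T1)
  list(cl = cl, idx = idx, flt = flt)
}

test_that("trans_search keeps exactly the peptides present in the neighbor index", {
  pr <- make_pair()
  # identity neighbor: everything is retained
  self_hit <- trans_search(pr$flt, pr$idx$T1)
  expect_setequal(self_hit$peptide, pr$flt$peptide)
  # divergent neighbor: retained set equals brute-force membership in the
  # neighbor's enumerated digest
  hit <- trans_search(pr$flt, pr$idx$T2)
  nb_set <- unique(unlist(lapply(pr$cl$taxa$T2$records$sequence,
                                 oracle_digest)))
  expect_setequal(hit$peptide, intersect(pr$flt$peptide, nb_set))
  expect_identical(attr(hit, "target_genome"), "T2")
  # output is a subset of the input
  expect_true(all(hit$peptide %in% pr$flt$peptide))
  # protein ids are rewritten to neighbor loci
  expect_true(all(unlist(strsplit(hit$protein_ids, ",")) %in%
                    pr$cl$taxa$T2$records$id))
  # no shared sequence: empty result
  alien <- proteome("Z", "z1", "WWWWWWWWWWKWWWWWWWWWWK")
  expect_identical(nrow(trans_search(pr$flt,
                                     build_peptide_index(alien))), 0L)
})

test_that("trans_search rejects mismatched digestion parameters", {
  pr <- make_pair()
  other <- build_peptide_index(pr$cl$taxa$T2, digest_params(7, 1))
  expect_error(trans_search(pr$flt, other), "digestion parameters")
})

test_that("conservation profiles decay with distance at both levels", {
  cl <- simulate_clade(synthetic_config(
    n_proteins = 40, protein_length_mean = 200,
    target_16s_distances = c(0, 0.01, 0.03, 0.05, 0.08, 0.1),
    kappa = 5, seed = 13))
  idx <- lapply(cl$taxa, build_peptide_index, params = digest_params())
  dm <- distance_matrix(cl$markers)
  tab <- simulate_observation(cl$taxa$T1, digest_params(),
                              detection_config(0.9, seed = 13))
  flt <- filter_psms(tab, filter_config(), idx$T1)
  pep <- conservation_profile("T1", names(idx), flt, idx, dm,
                              level = "peptide")
  prot <- conservation_profile("T1", names(idx), flt, idx, dm,
                               level = "protein")
  # self search is the (0, 1) point and every ratio is at most 1
  expect_equal(pep$ratio[pep$neighbor == "T1"], 1)
  expect_equal(prot$ratio[prot$neighbor == "T1"], 1)
  expect_true(all(pep$ratio <= 1 & pep$ratio >= 0))
  expect_true(all(diff(pep$distance) >= 0))
  # ratios decrease with distance at both levels
  expect_lt(cor(pep$distance, pep$ratio, method = "spearman"), 0)
  expect_lt(cor(prot$distance, prot$ratio, method = "spearman"), 0)
  expect_error(conservation_profile("T1", "nope", flt, idx, dm),
               "absent from")
})

test_that("category conservation matches the group-by oracle in both modes", {
  map <- data.frame(query_locus = sprintf("q%02d", 1:10),
                    neighbor_locus = sprintf("n%02d", 1:10),
                    category = rep(c("energy", "synthesis"), each = 5),
                    stringsAsFactors = FALSE)
  self_obs <- sprintf("q%02d", 1:8)
  nb_obs <- sprintf("n%02d", c(1:3, 6))
  got <- category_conservation(self_obs, nb_obs, map, mode = "methods")
  expect_equal(unname(got[["energy"]]), 3 / 5)
  expect_equal(unname(got[["synthesis"]]), 1 / 3)
  expect_equal(unname(got[["overall"]]), 4 / 8)
  # identical sets give 1.0 everywhere
  same <- category_conservation(self_obs, self_obs, map, mode = "methods")
  expect_true(all(same[c("energy", "synthesis", "overall")] == 1))
  # composition mode sums to one within each observed set
  fig <- category_conservation(self_obs, nb_obs, map, mode = "figure2")
  expect_equal(unname(rowSums(fig)), c(1, 1))
  expect_equal(unname(fig["neighbor", "energy"]), 3 / 4)
  expect_error(category_conservation(character(0), nb_obs, map), "empty")
  # unmapped loci are skipped and counted
  expect_message(
    out <- category_conservation(c(self_obs, "stray"), nb_obs, map),
    "skipped")
  expect_identical(attr(out, "n_unmapped"), 1L)
})

test_that("coverage gaps report maximal unobserved runs", {
  genes <- data.frame(id = sprintf("g%02d", 1:30),
                      start = as.integer(seq(1, by = 1000, length.out = 30)),
                      end = as.integer(seq(900, by = 1000, length.out = 30)))
  # everything observed: no gaps
  all_seen <- list(i1 = genes$id, i2 = genes$id)
  expect_identical(nrow(detect_coverage_gaps(genes, all_seen, 5)), 0L)
  # nothing observed anywhere: one gap spanning the whole table
  none <- detect_coverage_gaps(genes, list(i1 = character(0)), 5)
  expect_identical(nrow(none), 1L)
  expect_identical(none$start_gene, 1L)
  expect_identical(none$end_gene, 30L)
  expect_identical(none$start_bp, 1L)
  expect_identical(none$end_bp, 29900L)
  # a run shorter than min_genes is not reported
  part <- detect_coverage_gaps(genes,
                               list(i1 = genes$id[-(10:13)]), 5)
  expect_identical(nrow(part), 0L)
  expect_identical(
    detect_coverage_gaps(genes, list(i1 = genes$id[-(10:15)]), 5)$n_genes,
    6L)
  expect_error(detect_coverage_gaps(genes[c(2, 1, 3:30), ],
                                    list(i1 = genes$id)), "sorted")
  genes_na <- genes
  genes_na$start[3] <- NA
  expect_error(detect_coverage_gaps(genes_na, list(i1 = genes$id)),
               "coordinates")
})

test_that("scope=all gaps are contained in per-isolate scope=any gaps", {
  set.seed(61)
  genes <- data.frame(id = sprintf("g%02d", 1:40),
                      start = seq(1, by = 500, length.out = 40),
                      end = seq(400, by = 500, length.out = 40))
  obs <- list(i1 = sample(genes$id, 20), i2 = sample(genes$id, 20))
  g_all <- detect_coverage_gaps(genes, obs, 2, scope = "all")
  g_any <- detect_coverage_gaps(genes, obs, 2, scope = "any")
  if (nrow(g_all)) {
    for (r in seq_len(nrow(g_all))) {
      for (iso in names(obs)) {
        hit <- g_any$absent_in == iso &
          g_any$start_gene <= g_all$start_gene[r] &
          g_any$end_gene >= g_all$end_gene[r]
        expect_true(any(hit))
      }
    }
  }
  # BED output is 0-based half-open
  bed <- tempfile(fileext = ".bed")
  write_gaps_bed(detect_coverage_gaps(genes, list(i1 = character(0)), 2),
                 bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_identical(as.integer(fields[2]), 0L)
  expect_equal(as.numeric(fields[3]), max(genes$end))
})
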