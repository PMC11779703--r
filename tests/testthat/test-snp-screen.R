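test_that("the default panel screen flags exactly the five diagnostic sites", {
  aln <- make_species_panel(seed = 0)
  prof <- diversity_profile(aln, "Rh_crenulata")
  reg <- candidate_regions(prof)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$member_sites[[1]], c(162L, 166L, 167L, 172L, 177L))
  expect_equal(reg$start, 162L)
  expect_equal(reg$end, 177L)
})

test_that("no site above the divergence threshold gives an empty region list", {
  aln <- species_alignment(c("a1", "a2", "b1", "b2"),
                           c("A", "A", "B", "B"), rep("ACGTACGT", 4))
  reg <- candidate_regions(diversity_profile(aln, "A"))
  expect_equal(nrow(reg), 0L)
  expect_error(candidate_regions(diversity_profile(aln, "A"), inter_min = 1.5),
               class = "lampdx_error_parameter")
})

test_that("sites merge at distance merge_gap and split at merge_gap + 1", {
  make_two_site_panel <- function(gap) {
    len <- 40L
    p1 <- 5L; p2 <- p1 + gap
    a <- rep("A", len); b <- rep("A", len)
    a[c(p1, p2)] <- "C"; b[c(p1, p2)] <- "T"
    species_alignment(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"),
                      c(paste(a, collapse = ""), paste(a, collapse = ""),
                        paste(b, collapse = ""), paste(b, collapse = "")))
  }
  gap <- 10L
  reg_merge <- candidate_regions(
    diversity_profile(make_two_site_panel(gap), "A"), merge_gap = gap)
  expect_equal(nrow(reg_merge), 1L)
  reg_split <- candidate_regions(
    diversity_profile(make_two_site_panel(gap + 1L), "A"), merge_gap = gap)
  expect_equal(nrow(reg_split), 2L)
  expect_equal(reg_split$n_sites, c(1L, 1L))
})

test_that("region calls are invariant under record and group permutation", {
  aln <- make_species_panel(seed = 3)
  perm <- withr::with_seed(9, sample(nrow(aln)))
  shuffled <- species_alignment(aln$seq_id[perm], aln$species[perm],
                                aln$residues[perm])
  r1 <- candidate_regions(diversity_profile(aln, "Rh_crenulata"))
  r2 <- candidate_regions(diversity_profile(shuffled, "Rh_crenulata"))
  expect_equal(r1$member_sites, r2$member_sites)
})

test_that("base preference frequencies sum to one and carry information", {
  aln <- make_species_panel(seed = 0)
  pref <- base_preference(aln, 162, 177)
  sums <- rowSums(pref[, c("A", "C", "G", "T")])
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(pref$information <= 2 + 1e-9))
  # target group is fixed C at 166: zero entropy, 2 bits
  row <- pref[pref$species == "Rh_crenulata" & pref$position == 166, ]
  expect_equal(row$C, 1)
  expect_equal(row$information, 2)
  # target modal base at 172 is A
  row <- pref[pref$species == "Rh_crenulata" & pref$position == 172, ]
  expect_equal(names(which.max(row[, c("A", "C", "G", "T")])), "A")
  expect_error(base_preference(aln, 0, 10), class = "lampdx_error_parameter")
})

test_that("a 50/50 column carries exactly one bit", {
  aln <- species_alignment(c("a1", "a2", "a3", "a4"), rep("A", 4),
                           c("C", "C", "T", "T"))
  pref <- base_preference(aln, 1, 1)
  expect_equal(pref$information, 1)
})

test_that("diagnostic SNP calls respect the fixation threshold", {
  aln <- make_species_panel(seed = 0)
  snps <- diagnostic_snps(aln, "Rh_crenulata", c(162, 166, 167, 172, 177))
  expect_true(all(snps$fixed))
  expect_equal(snps$target_allele, c("C", "C", "C", "A", "T"))
  expect_equal(snps$comparator_allele, c("T", "T", "T", "G", "A"))
  expect_equal(snps$inter_pi, rep(1, 5))

  # both groups modal C: not a diagnostic difference
  same <- species_alignment(c("a1", "a2", "b1", "b2"),
                            c("A", "A", "B", "B"), rep("C", 4))
  expect_false(diagnostic_snps(same, "A", 1)$fixed)

  # 90% target C / 10% T stays below a 0.95 threshold
  mixed <- species_alignment(sprintf("s%02d", 1:12),
                             rep(c("A", "B"), c(10, 2)),
                             c(rep("C", 9), "T", "T", "T"))
  call <- diagnostic_snps(mixed, "A", 1, fixation_threshold = 0.95)
  expect_false(call$fixed)
  expect_equal(call$target_freq, 0.9)
  expect_true(diagnostic_snps(mixed, "A", 1, fixation_threshold = 0.9)$fixed)
  expect_error(diagnostic_snps(mixed, "A", 99),
               class = "lampdx_error_parameter")
})

test_that("threshold 1 admits only zero within-group variation", {
  aln <- make_species_panel(panel_config(noise_rate = 0.05), seed = 5)
  snps <- diagnostic_snps(aln, "Rh_crenulata", seq_len(alignment_columns(aln)),
                          fixation_threshold = 1)
  mat <- do.call(rbind, strsplit(aln$residues, ""))
  for (p in snps$position[snps$fixed]) {
    expect_equal(length(unique(mat[aln$species == "Rh_crenulata", p])), 1L)
  }
  # and every diagnostic site is still among them (noise spares those sites)
  expect_true(all(c(162, 166, 167, 172, 177) %in% snps$position[snps$fixed]))
})

test_that("tied modal alleles are never called fixed", {
  aln <- species_alignment(c("a1", "a2", "b1", "b2"),
                           c("A", "A", "B", "B"), c("C", "T", "G", "G"))
  call <- diagnostic_snps(aln, "A", 1, fixation_threshold = 0.4)
  expect_false(call$fixed)
  expect_equal(call$target_allele, "C")  # A<C<G<T tie order
})

test_that("ambiguity scan separates hybrid-consistent from inconsistent codes", {
  snps <- tibble::tibble(position = c(162L, 166L),
                         target_allele = c("C", "C"),
                         comparator_allele = c("T", "T"))
  seqv <- strsplit(strrep("A", 200), "")[[1]]
  seqv[162] <- "C"; seqv[166] <- "Y"
  hits <- ambiguity_scan(paste(seqv, collapse = ""), snps)
  expect_equal(hits$position, 166L)
  expect_equal(hits$status, "hybrid_consistent")

  seqv[166] <- "R"  # {A,G} covers neither C nor T fully
  hits <- ambiguity_scan(paste(seqv, collapse = ""), snps)
  expect_equal(hits$status, "inconsistent")

  seqv[166] <- "C"
  expect_equal(nrow(ambiguity_scan(paste(seqv, collapse = ""), snps)), 0L)
})

test_that("panel hybrids carry hybrid-consistent codes at every SNP site", {
  aln <- make_species_panel(panel_config(n_hybrids = 2L), seed = 4)
  snps <- diagnostic_snps(
    species_alignment(aln$seq_id[aln$species != "hybrid"],
                      aln$species[aln$species != "hybrid"],
                      aln$residues[aln$species != "hybrid"]),
    "Rh_crenulata", c(162, 166, 167, 172, 177))
  hyb <- aln$residues[aln$species == "hybrid"][1]
  flags <- ambiguity_scan(hyb, snps)
  expect_equal(flags$position, snps$position)
  expect_true(all(flags$status == "hybrid_consistent"))
})
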