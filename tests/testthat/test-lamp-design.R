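fixture_alleles <- function(seed = 0) {
  fix <- make_lamp_fixture(seed = seed)
  list(alleles = c(target = fix$target, comparator = fix$comparator),
       dpos = fix$diagnostic_positions, window = fix$loop_window)
}

test_that("candidates perfectly match their own allele and cover SNPs", {
  fx <- fixture_alleles()
  cands <- enumerate_loop_candidates(fx$alleles, fx$dpos, fx$window)
  expect_gt(nrow(cands), 0)
  for (i in seq_len(nrow(cands))) {
    own <- fx$alleles[[cands$allele[i]]]
    window_seq <- substr(own, cands$start[i], cands$end[i])
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(window_seq)))
    expect_identical(cands$sequence[i], rc)
    expect_true(all(cands$covered_snps[[i]] >= cands$start[i] &
                      cands$covered_snps[[i]] <= cands$end[i]))
  }
  # every placement emits one candidate per allele
  expect_equal(sum(cands$allele == "target"),
               sum(cands$allele == "comparator"))
})

test_that("17-nt candidates can cover at least four diagnostic sites", {
  fx <- fixture_alleles()
  cands <- enumerate_loop_candidates(fx$alleles, fx$dpos, fx$window,
                                     lengths = 17)
  expect_gte(max(cands$n_covered), 4)
})

test_that("11-nt candidates report 5'/center/3' mismatch classes", {
  fx <- fixture_alleles()
  cands <- enumerate_loop_candidates(fx$alleles, fx$dpos, fx$window,
                                     lengths = 11)
  classes <- unique(unlist(purrr::map(cands$mismatches,
                                      ~ .x$position_class)))
  expect_true(all(c("five_prime_terminal", "center",
                    "three_prime_terminal") %in% classes))
})

test_that("no diagnostic positions means no candidates", {
  fx <- fixture_alleles()
  out <- enumerate_loop_candidates(fx$alleles, integer(), fx$window)
  expect_equal(nrow(out), 0L)
  expect_error(enumerate_loop_candidates(fx$alleles, fx$dpos, NULL),
               class = "lampdx_error_design")
  expect_warning(
    enumerate_loop_candidates(fx$alleles, fx$dpos, fx$window,
                              lengths = c(17, 500)),
    "exceeds the loop window")
})

test_that("discrimination scoring follows the weight-table arithmetic", {
  w <- mismatch_weights()
  expect_equal(score_discrimination(
    tibble::tibble(position_class = character(), pair = character(),
                   change = character()), w), 0)
  # one center mismatch breaking a C-G pair: 2.0 * 1.5
  center_cg <- tibble::tibble(position_class = "center", pair = "C-G",
                              change = "C>T")
  expect_equal(score_discrimination(center_cg, w), 3.0)
  # strictly above a single 3'-terminal A-T mismatch
  term_at <- tibble::tibble(position_class = "three_prime_terminal",
                            pair = "A-T", change = "A>G")
  expect_gt(score_discrimination(center_cg, w),
            score_discrimination(term_at, w))
  # the center T>A multiplier applies
  center_ta <- tibble::tibble(position_class = "center", pair = "A-T",
                              change = "T>A")
  expect_equal(score_discrimination(center_ta, w), 2.0 * 1.0 * 1.25)
})

test_that("scores are monotone in added and upgraded mismatches", {
  w <- mismatch_weights()
  base <- tibble::tibble(position_class = "internal", pair = "A-T",
                         change = "A>C")
  more <- dplyr::bind_rows(base,
                           tibble::tibble(position_class = "five_prime_terminal",
                                          pair = "A-T", change = "T>G"))
  expect_gte(score_discrimination(more, w), score_discrimination(base, w))
  # terminal -> center upgrade of the same broken pair never decreases
  term <- tibble::tibble(position_class = "three_prime_terminal",
                         pair = "C-G", change = "C>A")
  cent <- tibble::tibble(position_class = "center", pair = "C-G",
                         change = "C>A")
  expect_gte(score_discrimination(cent, w), score_discrimination(term, w))
})

test_that("weight tables violating the ordering rules are rejected", {
  expect_error(mismatch_weights(position = c(five_prime_terminal = 2,
                                             internal = 1.5, center = 1,
                                             three_prime_terminal = 2)),
               class = "lampdx_error_configuration")
  expect_error(mismatch_weights(pair = c("C-G" = 1, "A-T" = 1.5)),
               class = "lampdx_error_configuration")
})

test_that("the designed pair is allele-specific with a total-order ranking", {
  fx <- fixture_alleles()
  des <- design_allele_pair(fx$alleles, fx$dpos, fx$window)
  expect_equal(sort(des$best$allele), c("comparator", "target"))
  expect_true(all(des$best$n_mismatches >= 1))
  # scaled weights leave the ranking unchanged (positively homogeneous)
  w2 <- mismatch_weights(
    position = c(five_prime_terminal = 3, internal = 4.5, center = 6,
                 three_prime_terminal = 3),
    pair = c("C-G" = 4.5, "A-T" = 3))
  des2 <- design_allele_pair(fx$alleles, fx$dpos, fx$window, weights = w2)
  expect_equal(des2$candidates$sequence, des$candidates$sequence)
  # ranking is invariant under enumeration order: re-rank a shuffled copy
  shuffled <- withr::with_seed(5, dplyr::slice_sample(des$candidates,
                                                      prop = 1))
  rr <- dplyr::arrange(shuffled, dplyr::desc(score), dplyr::desc(n_covered),
                       dplyr::desc(length), start, sequence)
  expect_equal(rr$sequence, des$candidates$sequence)
  # no candidate covering a site -> design failure
  expect_error(design_allele_pair(fx$alleles, max(fx$window) + 100L,
                                  fx$window),
               class = "lampdx_error_design")
})
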