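ecori <- enzyme_def("EcoRI", "GAATTC", 1, 5)
bgli <- builtin_enzymes()[builtin_enzymes()$name == "BglI", ]

test_that("site scanning finds direct and degenerate matches", {
  hits <- find_sites("AAAAGAATTCAAAA", ecori)
  expect_equal(hits$start, 5L)
  expect_equal(hits$cut_after, 5L)  # G^AATTC

  # degenerate single-N site matches everywhere
  n1 <- enzyme_def("AnyBase", "N", 1)
  expect_equal(find_sites("ACGTACGT", n1)$start, 1:8)

  # site longer than the sequence: no hits
  expect_equal(nrow(find_sites("ACG", ecori)), 0L)

  expect_error(find_sites("ACGTN", ecori),
               class = "lampdx_error_digest_input")
})

test_that("degenerate hits agree with the position-by-position oracle", {
  withr::local_seed(7)
  enzymes <- builtin_enzymes()
  for (rep in 1:20) {
    s <- random_dna(sample(50:400, 1))
    e <- enzymes[sample(nrow(enzymes), 1), ]
    expect_equal(find_sites(s, e)$start[find_sites(s, e)$strand == "+"],
                 oracle_find_sites(s, e$site))
  }
})

test_that("hits also agree with Biostrings degenerate matching", {
  withr::local_seed(11)
  for (rep in 1:10) {
    s <- random_dna(300)
    m <- Biostrings::matchPattern(Biostrings::DNAString(bgli$site),
                                  Biostrings::DNAString(s),
                                  fixed = "subject")
    mine <- find_sites(s, bgli)
    expect_equal(mine$start, BiocGenerics::start(m))
  }
})

test_that("palindromic sites are reported once with mirror-consistent hits", {
  pair <- make_amplicon_pair(seed = 2)
  hits_fwd <- find_sites(pair$target, bgli)
  expect_equal(nrow(hits_fwd), 1L)
  expect_true(all(hits_fwd$strand == "+"))
  # the site survives on the reverse complement at the mirrored position
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pair$target)))
  hits_rev <- find_sites(rc, bgli)
  expect_equal(hits_rev$start,
               nchar(pair$target) - (hits_fwd$start + nchar(bgli$site) - 1L) + 1L)
})

test_that("digestion fragment arithmetic is exact", {
  # 20-bp molecule, one cut after position 5
  s <- paste0("AAAA", "GAATTC", "AAAAAAAAAA")
  d <- digest(s, ecori)
  expect_equal(d$fragments[[1]], c(15, 5))
  expect_equal(sum(d$fragments[[1]]), nchar(s))

  # no site: one full-length fragment
  d0 <- digest("ACGTACGTACGT", ecori)
  expect_equal(d0$fragments[[1]], 12)
  expect_equal(d0$n_hits, 0L)
})

test_that("fragment lengths always sum to the sequence length", {
  withr::local_seed(13)
  enzymes <- builtin_enzymes()
  for (rep in 1:25) {
    s <- random_dna(sample(30:500, 1))
    e <- enzymes[sample(nrow(enzymes), 1), ]
    d <- digest(s, e)
    expect_equal(sum(d$fragments[[1]]), nchar(s))
    expect_equal(length(d$fragments[[1]]),
                 length(d$cut_after[[1]]) + 1L)
  }
})

test_that("digesting a concatenation merges only the junction fragments", {
  withr::local_seed(17)
  x <- random_dna(120); y <- random_dna(150)
  no_span <- function(a, b) {
    # discard draws where a site spans the junction
    joint <- digest(paste0(a, b), ecori)
    da <- digest(a, ecori); db <- digest(b, ecori)
    expect_equal(sort(joint$cut_after[[1]]),
                 sort(c(da$cut_after[[1]], db$cut_after[[1]] + nchar(a))))
  }
  no_span(x, y)
  no_span(paste0(x, "GAATTC"), y)
})

test_that("the amplicon pair digests into the expected diagnostic bands", {
  pair <- make_amplicon_pair(seed = 0)
  expect_equal(digest(pair$target, bgli)$fragments[[1]], c(462, 232))
  expect_equal(digest(pair$comparator, bgli)$fragments[[1]], 694)
  expect_equal(hybrid_pattern(pair$target, pair$comparator, bgli),
               c(694, 462, 232))
})

test_that("differential digestion flags discriminating enzymes", {
  pair <- make_amplicon_pair(seed = 0)
  dd <- differential_digest(pair$target, pair$comparator, builtin_enzymes())
  bgli_row <- dd[dd$enzyme == "BglI", ]
  expect_true(bgli_row$diagnostic)
  expect_equal(bgli_row$hybrid_bands[[1]], c(694, 462, 232))
  # diagnostic rows sort first
  expect_true(all(diff(as.integer(dd$diagnostic)) <= 0))

  # identical alleles can never be discriminated
  same <- differential_digest(pair$target, pair$target, builtin_enzymes())
  expect_false(any(same$diagnostic))

  # an enzyme absent from both alleles: full-length fragments, not diagnostic
  s1 <- strrep("A", 60); s2 <- strrep("C", 60)
  dd2 <- differential_digest(s1, s2, ecori)
  expect_false(dd2$diagnostic)
  expect_equal(dd2$fragments_a[[1]], 60)
  expect_equal(dd2$fragments_b[[1]], 60)

  expect_error(differential_digest(s1, s2, tibble::tibble()),
               class = "lampdx_error_parameter")
})

test_that("hybrid bands are the distinct union of both alleles' fragments", {
  # allele A cuts into {100, 50}; allele B carries no site
  a <- paste0(strrep("A", 49), "GAATTC", strrep("A", 95))
  b <- strrep("A", 150)
  expect_equal(digest(a, ecori)$fragments[[1]], c(100, 50))
  expect_equal(hybrid_pattern(a, b, ecori), c(150, 100, 50))
  # identical alleles without a site: a single shared band
  expect_equal(hybrid_pattern(b, b, ecori), 150)
})
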