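# Per-site nucleotide diversity and the interspecific SNP screen.
#
# Diversity at a site is the fraction of sequence pairs whose residues
# differ there. Gaps and fully undetermined residues are dropped from that
# site's denominator (pairwise deletion); partial IUPAC ambiguity codes
# count as a difference only when their base sets are disjoint, which keeps
# heterozygous/hybrid residues from inflating divergence.

# 15x15 logical matrix: TRUE where two informative codes have disjoint sets
.disjoint_matrix <- local({
  codes <- names(IUPAC_SETS)
  m <- matrix(FALSE, length(codes), length(codes), dimnames = list(codes, codes))
  for (a in codes) for (b in codes) {
    m[a, b] <- length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) == 0L
  }
  m
})

# counts of informative residue codes in a character vector
.code_counts <- function(res) {
  res <- res[is_informative(res)]
  table(factor(res, levels = names(IUPAC_SETS)))
}

# fraction of differing pairs within one group's residues at a site;
# NA when fewer than 2 usable residues
.pi_within <- function(counts) {
  n <- sum(counts)
  if (n < 2L) return(NA_real_)
  idx <- which(counts > 0L)
  diff_pairs <- 0
  for (i in idx) for (j in idx) {
    if (j > i && .disjoint_matrix[i, j]) diff_pairs <- diff_pairs + counts[i] * counts[j]
  }
  unname(diff_pairs / (n * (n - 1) / 2))
}

# fraction of differing cross pairs between two residue-count vectors
.pi_between <- function(ca, cb) {
  na <- sum(ca); nb <- sum(cb)
  if (na < 1L || nb < 1L) return(NA_real_)
  ia <- which(ca > 0L); ib <- which(cb > 0L)
  diff_pairs <- 0
  for (i in ia) for (j in ib) {
    if (.disjoint_matrix[i, j]) diff_pairs <- diff_pairs + ca[i] * cb[j]
  }
  unname(diff_pairs / (na * nb))
}

#' Per-site intra- and inter-specific nucleotide diversity
#'
#' Computes, at every alignment position (or sliding window), the
#' within-group diversity of each species and the divergence between a
#' target group and the pooled remaining sequences. Divergence is the
#' average cross-group pairwise difference (Dxy-style) by default; set
#' `inter_mode = "pooled"` to use the nucleotide diversity of the pooled
#' target + comparator sample instead.
#'
#' @param aln a [species_alignment()].
#' @param target_group species label whose diagnostic alleles are sought;
#'   all other groups form the comparator pool.
#' @param window_width,step sliding-window size and step in positions
#'   (defaults 1/1, i.e. per-site values). Windows are anchored at their
#'   start position and average the per-site values they cover.
#' @param inter_mode `"dxy"` (between-group average pairwise difference) or
#'   `"pooled"` (diversity of the pooled sample).
#' @return a tibble of class `diversity_profile` with columns `position`
#'   (window start), `inter_pi`, `n_cross_pairs`, and per species
#'   `intra_<species>` and `n_pairs_<species>`. Sites where a group has
#'   fewer than two usable sequences carry `NA` intra values.
#' @export
diversity_profile <- function(aln, target_group, window_width = 1L, step = 1L,
                              inter_mode = c("dxy", "pooled")) {
  inter_mode <- match.arg(inter_mode)
  stopifnot(inherits(aln, "species_alignment"))
  groups <- unique(aln$species)
  if (!target_group %in% groups) {
    abort(sprintf("target group '%s' not present", target_group),
          class = "lampdx_error_group")
  }
  if (length(groups) < 2L) {
    abort("need at least 2 species groups", class = "lampdx_error_group")
  }
  ncol_aln <- alignment_columns(aln)
  check_number(window_width, "window_width", 1)
  check_number(step, "step", 1)
  if (window_width > ncol_aln) {
    abort("window wider than the alignment", class = "lampdx_error_parameter")
  }
  small <- groups[table(aln$species)[groups] < 2L]
  if (length(small)) {
    warn(sprintf("group(s) with <2 sequences, intra diversity missing: %s",
                 paste(small, collapse = ", ")))
  }

  mat <- residue_matrix(aln)
  in_target <- aln$species == target_group
  per_group_rows <- lapply(groups, function(g) which(aln$species == g))
  names(per_group_rows) <- groups

  site <- lapply(seq_len(ncol_aln), function(p) {
    col <- mat[, p]
    counts_by_group <- lapply(per_group_rows, function(r) .code_counts(col[r]))
    ct <- .code_counts(col[in_target])
    cc <- .code_counts(col[!in_target])
    inter <- if (inter_mode == "dxy") {
      .pi_between(ct, cc)
    } else {
      .pi_within(ct + cc)
    }
    c(inter_pi = inter,
      n_cross_pairs = sum(ct) * sum(cc),
      unlist(lapply(counts_by_group, function(k) {
        c(intra = .pi_within(k), n_pairs = sum(k) * (sum(k) - 1) / 2)
      })))
  })
  per_site <- as_tibble(do.call(rbind, site))
  names(per_site) <- c("inter_pi", "n_cross_pairs",
                       as.vector(rbind(paste0("intra_", groups),
                                       paste0("n_pairs_", groups))))
  per_site$position <- seq_len(ncol_aln)

  if (window_width > 1L || step > 1L) {
    starts <- seq(1L, ncol_aln - window_width + 1L, by = step)
    value_cols <- c("inter_pi", paste0("intra_", groups))
    count_cols <- c("n_cross_pairs", paste0("n_pairs_", groups))
    win <- lapply(starts, function(s) {
      rows <- per_site[s:(s + window_width - 1L), ]
      vals <- vapply(value_cols, function(cn) mean(rows[[cn]], na.rm = FALSE),
                     numeric(1))
      cnts <- vapply(count_cols, function(cn) sum(rows[[cn]]), numeric(1))
      c(position = s, vals, cnts)
    })
    per_site <- as_tibble(do.call(rbind, win))
  }

  out <- dplyr::relocate(per_site, "position")
  structure(out,
            target_group = target_group, groups = groups,
            window_width = as.integer(window_width), step = as.integer(step),
            inter_mode = inter_mode,
            class = c("diversity_profile", class(out)))
}

#' Candidate diagnostic-SNP regions from a diversity profile
#'
#' Flags positions whose between-group divergence exceeds `inter_min` while
#' every species' within-group diversity stays below `intra_max`, then
#' merges flagged sites separated by at most `merge_gap` positions into
#' regions. Groups whose intra value is missing at a site (fewer than two
#' usable sequences) do not veto that site.
#'
#' @param profile a [diversity_profile()].
#' @param inter_min,intra_max screen thresholds in `[0, 1]` (defaults 0.37
#'   and 0.19).
#' @param merge_gap sites at distance `<= merge_gap` join one region
#'   (default 10).
#' @return tibble with one row per region: `region`, `start`, `end`,
#'   `length`, `n_sites` and list-column `member_sites`; sorted by `start`.
#' @export
candidate_regions <- function(profile, inter_min = 0.37, intra_max = 0.19,
                              merge_gap = 10L) {
  check_number(inter_min, "inter_min", 0, 1)
  check_number(intra_max, "intra_max", 0, 1)
  check_number(merge_gap, "merge_gap", 0)
  groups <- attr(profile, "groups")
  intra_cols <- paste0("intra_", groups)
  intra <- as.matrix(profile[, intra_cols, drop = FALSE])
  intra_ok <- apply(intra, 1L, function(r) all(r[!is.na(r)] < intra_max))
  hit <- !is.na(profile$inter_pi) & profile$inter_pi > inter_min & intra_ok
  sites <- profile$position[hit]
  empty <- tibble(region = integer(), start = integer(), end = integer(),
                  length = integer(), n_sites = integer(),
                  member_sites = list())
  if (!length(sites)) return(empty)
  sites <- sort(sites)
  grp <- cumsum(c(1L, diff(sites) > merge_gap))
  purrr::map_dfr(split(sites, grp), function(s) {
    tibble(start = min(s), end = max(s), length = max(s) - min(s) + 1L,
           n_sites = length(s), member_sites = list(unname(s)))
  }) |>
    arrange(.data$start) |>
    mutate(region = row_number(), .before = 1L)
}

#' Per-group base-preference matrix over a region
#'
#' Relative A/C/G/T frequencies per group per position (IUPAC ambiguity
#' codes are split fractionally over their base sets; gaps and N are
#' ignored), plus the information content `2 - H` in bits used by sequence
#' logos.
#'
#' @param aln a [species_alignment()].
#' @param start,end 1-based inclusive region bounds; alternatively pass a
#'   one-row region tibble from [candidate_regions()] as `start`.
#' @return tibble with columns `species`, `position`, `A`, `C`, `G`, `T`,
#'   `n_observed`, `information`.
#' @export
base_preference <- function(aln, start, end = NULL) {
  if (is.data.frame(start)) {
    end <- start$end[1]; start <- start$start[1]
  }
  ncol_aln <- alignment_columns(aln)
  if (start < 1L || end > ncol_aln || start > end) {
    abort("region outside alignment bounds", class = "lampdx_error_parameter")
  }
  mat <- residue_matrix(aln)
  groups <- unique(aln$species)
  purrr::map_dfr(groups, function(g) {
    sub <- mat[aln$species == g, , drop = FALSE]
    purrr::map_dfr(start:end, function(p) {
      res <- sub[, p]
      res <- res[is_informative(res)]
      w <- c(A = 0, C = 0, G = 0, T = 0)
      for (r in res) {
        s <- iupac_set(r)
        w[s] <- w[s] + 1 / length(s)
      }
      tot <- sum(w)
      freq <- if (tot > 0) w / tot else w * NA_real_
      h <- if (tot > 0) {
        pz <- freq[freq > 0]
        -sum(pz * log2(pz))
      } else {
        NA_real_
      }
      tibble(species = g, position = p,
             A = freq[["A"]], C = freq[["C"]], G = freq[["G"]], T = freq[["T"]],
             n_observed = length(res), information = 2 - h)
    })
  })
}

#' Call fixed diagnostic SNPs at candidate sites
#'
#' For each site the modal allele of the target group and of the pooled
#' comparator is determined (fractional IUPAC weighting, ties broken
#' A<C<G<T and never called fixed). A site is a fixed diagnostic SNP when
#' both modal-allele frequencies reach `fixation_threshold` and the modal
#' alleles differ.
#'
#' @param aln a [species_alignment()].
#' @param target_group species whose private alleles are sought.
#' @param sites integer vector of 1-based candidate positions (e.g. the
#'   `member_sites` of a [candidate_regions()] row).
#' @param fixation_threshold minimum modal-allele frequency on both sides
#'   (default 0.95).
#' @return tibble with one row per site: `position`, `target_allele`,
#'   `comparator_allele`, `target_freq`, `comparator_freq`, `fixed`,
#'   `inter_pi`, `max_intra_pi`.
#' @export
diagnostic_snps <- function(aln, target_group, sites,
                            fixation_threshold = 0.95) {
  check_number(fixation_threshold, "fixation_threshold", 0, 1)
  ncol_aln <- alignment_columns(aln)
  if (any(sites < 1L | sites > ncol_aln)) {
    abort("site outside alignment bounds", class = "lampdx_error_parameter")
  }
  mat <- residue_matrix(aln)
  in_target <- aln$species == target_group
  if (!any(in_target)) {
    abort(sprintf("target group '%s' not present", target_group),
          class = "lampdx_error_group")
  }
  groups <- unique(aln$species)

  modal <- function(res) {
    res <- res[is_informative(res)]
    w <- c(A = 0, C = 0, G = 0, T = 0)
    for (r in res) {
      s <- iupac_set(r)
      w[s] <- w[s] + 1 / length(s)
    }
    tot <- sum(w)
    if (tot == 0) return(list(base = NA_character_, freq = NA_real_, tie = TRUE))
    top <- names(w)[w == max(w)]  # names in A<C<G<T order already
    list(base = top[1], freq = max(w) / tot, tie = length(top) > 1L)
  }

  purrr::map_dfr(as.integer(sites), function(p) {
    col <- mat[, p]
    mt <- modal(col[in_target])
    mc <- modal(col[!in_target])
    intra <- vapply(groups, function(g) {
      .pi_within(.code_counts(col[aln$species == g]))
    }, numeric(1))
    tibble(
      position = p,
      target_allele = mt$base, comparator_allele = mc$base,
      target_freq = mt$freq, comparator_freq = mc$freq,
      fixed = !mt$tie && !mc$tie &&
        !is.na(mt$freq) && !is.na(mc$freq) &&
        mt$freq >= fixation_threshold && mc$freq >= fixation_threshold &&
        mt$base != mc$base,
      inter_pi = .pi_between(.code_counts(col[in_target]),
                             .code_counts(col[!in_target])),
      max_intra_pi = if (all(is.na(intra))) NA_real_ else max(intra, na.rm = TRUE)
    )
  })
}

#' Scan a sequence for hybrid-consistent ambiguity codes at SNP sites
#'
#' A heterozygous individual carrying both species' alleles shows double
#' sequencing peaks, i.e. an IUPAC ambiguity code covering both diagnostic
#' alleles. Codes covering both alleles are flagged `hybrid_consistent`;
#' other ambiguity codes at those sites are flagged `inconsistent`.
#'
#' @param sequence residue string aligned to panel coordinates.
#' @param snps tibble with columns `position`, `target_allele`,
#'   `comparator_allele` (e.g. from [diagnostic_snps()]).
#' @return tibble `position`, `residue`, `status`; zero rows for a clean
#'   unambiguous sequence.
#' @export
ambiguity_scan <- function(sequence, snps) {
  ch <- seq_chars(sequence)
  purrr::map_dfr(seq_len(nrow(snps)), function(i) {
    p <- snps$position[i]
    r <- ch[p]
    if (r %in% c("A", "C", "G", "T") || r %in% UNDETERMINED) return(NULL)
    covers <- all(c(snps$target_allele[i], snps$comparator_allele[i]) %in%
                    iupac_set(r))
    tibble(position = p, residue = r,
           status = if (covers) "hybrid_consistent" else "inconsistent")
  })
}
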