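# Seeded synthetic fixtures: species alignment panels carrying the five
# fixed diagnostic alleles, allele amplicon pairs with an embedded
# diagnostic BglI site, geometry-legal LAMP primer sets, and a real-time
# LAMP kinetics simulator with mismatch penalties. These generators are the
# test substrate for every other module; identical seeds and configs give
# byte-identical output.

#' Default diagnostic-site table of the synthetic panel
#'
#' Five fixed interspecific SNPs in alignment coordinates: the target
#' species carries C162, C166, C167, A172 and T177 while the comparator
#' species carry T, T, T, G and A. C166 + C167 create the diagnostic BglI
#' site.
#'
#' @return tibble `position`, `target`, `comparator`.
#' @export
default_diagnostic_sites <- function() {
  tibble(position = c(162L, 166L, 167L, 172L, 177L),
         target = c("C", "C", "C", "A", "T"),
         comparator = c("T", "T", "T", "G", "A"))
}

#' Synthetic species-panel configuration
#'
#' Defaults emulate the study panel: three species totalling 149 barcode
#' sequences over a 260-position alignment (a typical ITS2 barcode), the
#' five fixed diagnostic alleles of [default_diagnostic_sites()], and a
#' 0.5% per-site intraspecific substitution rate at non-diagnostic sites.
#'
#' @param length alignment width in positions.
#' @param n_target,target_species size and label of the target group.
#' @param n_comparators,comparator_species sizes and labels of the
#'   comparator groups.
#' @param diagnostic_sites tibble as in [default_diagnostic_sites()].
#' @param noise_rate per-site per-sequence substitution probability at
#'   non-diagnostic sites, in `[0, 1)`.
#' @param n_hybrids sequences (species label `"hybrid"`) carrying the
#'   IUPAC code covering both alleles at every diagnostic site.
#' @param gc_bias background G+C fraction (0.5 = uniform composition).
#' @return list of class `panel_config`.
#' @export
panel_config <- function(length = 260L,
                         n_target = 60L, target_species = "Rh_crenulata",
                         n_comparators = c(50L, 39L),
                         comparator_species = c("Rh_fastigiata",
                                                "Rh_kirilowii"),
                         diagnostic_sites = default_diagnostic_sites(),
                         noise_rate = 0.005, n_hybrids = 0L,
                         gc_bias = 0.5) {
  if (any(diagnostic_sites$position > length)) {
    abort("diagnostic position outside the alignment",
          class = "lampdx_error_parameter")
  }
  if (any(diagnostic_sites$target == diagnostic_sites$comparator)) {
    abort("diagnostic alleles must differ", class = "lampdx_error_parameter")
  }
  check_number(noise_rate, "noise_rate", 0, 1 - 1e-9)
  check_number(gc_bias, "gc_bias", 0, 1)
  structure(list(length = as.integer(length),
                 n_target = as.integer(n_target),
                 target_species = target_species,
                 n_comparators = as.integer(n_comparators),
                 comparator_species = comparator_species,
                 diagnostic_sites = diagnostic_sites,
                 noise_rate = noise_rate,
                 n_hybrids = as.integer(n_hybrids),
                 gc_bias = gc_bias),
            class = "panel_config")
}

.sample_background <- function(n, gc_bias) {
  probs <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2,
             G = gc_bias / 2, T = (1 - gc_bias) / 2)
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a seeded synthetic species alignment panel
#'
#' All sequences share one random background; every non-hybrid sequence
#' carries its species' diagnostic alleles; intraspecific noise substitutes
#' non-diagnostic sites at the configured rate; hybrids carry the IUPAC
#' ambiguity code covering both alleles at each diagnostic site.
#'
#' @param config a [panel_config()].
#' @param seed integer RNG seed; identical seeds give identical panels.
#' @return a [species_alignment()] with attribute `diagnostic_sites`.
#' @export
make_species_panel <- function(config = panel_config(), seed = 0L) {
  stopifnot(inherits(config, "panel_config"))
  withr::with_seed(seed, {
    bg <- .sample_background(config$length, config$gc_bias)
    sites <- config$diagnostic_sites
    hybrid_codes <- vapply(seq_len(nrow(sites)), function(i) {
      iupac_code_for(c(sites$target[i], sites$comparator[i]))
    }, character(1))

    one_seq <- function(alleles) {
      s <- bg
      if (config$noise_rate > 0) {
        free <- setdiff(seq_len(config$length), sites$position)
        hit <- free[stats::runif(length(free)) < config$noise_rate]
        for (p in hit) {
          s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
        }
      }
      s[sites$position] <- alleles
      paste(s, collapse = "")
    }

    specs <- c(
      rep(config$target_species, config$n_target),
      rep(config$comparator_species, config$n_comparators),
      rep("hybrid", config$n_hybrids)
    )
    residues <- vapply(specs, function(sp) {
      one_seq(switch(
        sp,
        hybrid = hybrid_codes,
        if (sp == config$target_species) sites$target else sites$comparator
      ))
    }, character(1))
    ids <- sprintf("%s_%03d", specs, stats::ave(seq_along(specs), specs,
                                                FUN = seq_along))
    aln <- species_alignment(ids, specs, unname(residues))
    attr(aln, "diagnostic_sites") <- sites
    aln
  })
}

#' Generate an allele amplicon pair with an embedded diagnostic BglI site
#'
#' Builds a random amplicon in which only the target allele carries exactly
#' one BglI site (`GCCNNNNNGGC`), placed so that the top-strand cut falls
#' after position `cut_at`; the comparator allele replaces the two
#' allele-specific Cs of the site with Ts, destroying it. With
#' `extra_snps = TRUE` the remaining three diagnostic substitutions are
#' embedded as well (needed by the loop-primer design fixtures). A
#' coordinate map records which amplicon positions play the roles of the
#' alignment's diagnostic sites.
#'
#' @param length amplicon length in bp (default 694).
#' @param cut_at top-strand cut position of the target allele (default
#'   232, giving fragments of 232 and `length - 232` bp).
#' @param seed integer RNG seed.
#' @param extra_snps also embed the three diagnostic SNPs outside the
#'   restriction site (default FALSE: the pair differs only at the two
#'   site-destroying bases).
#' @return list with `target`, `comparator` (sequences), `site_start`,
#'   `cut_at`, and `map` (tibble `alignment_position`,
#'   `amplicon_position`, `target_allele`, `comparator_allele`).
#' @export
make_amplicon_pair <- function(length = 694L, cut_at = 232L, seed = 0L,
                               extra_snps = FALSE) {
  length <- as.integer(length)
  cut_at <- as.integer(cut_at)
  enz <- builtin_enzymes()[1, ]  # BglI
  site_start <- cut_at - enz$cut_top + 1L
  site_len <- nchar(enz$site)
  if (site_start < 1L || site_start + site_len - 1L > length ||
        cut_at >= length) {
    abort("restriction site placement infeasible for this length/cut",
          class = "lampdx_error_parameter")
  }
  sites <- default_diagnostic_sites()
  offset <- (site_start + 1L) - 166L  # alignment 166 -> first site C
  map <- mutate(sites,
                alignment_position = .data$position,
                amplicon_position = .data$position + offset,
                .keep = "unused") |>
    dplyr::rename(target_allele = "target", comparator_allele = "comparator") |>
    select("alignment_position", "amplicon_position",
           "target_allele", "comparator_allele")
  if (!extra_snps) map <- filter(map, .data$alignment_position %in% c(166L, 167L))
  if (any(map$amplicon_position < 1L | map$amplicon_position > length)) {
    abort("diagnostic sites fall outside the amplicon",
          class = "lampdx_error_parameter")
  }

  withr::with_seed(seed, {
    for (try in 1:200) {
      s <- .sample_background(length, 0.5)
      # implant the interrupted palindrome; inner N positions stay random
      site_ch <- seq_chars(enz$site)
      fixed <- site_ch != "N"
      s[(site_start:(site_start + site_len - 1L))[fixed]] <- site_ch[fixed]
      s[map$amplicon_position] <- map$target_allele
      target <- paste(s, collapse = "")
      s[map$amplicon_position] <- map$comparator_allele
      comparator <- paste(s, collapse = "")
      dt <- digest(target, enz)
      dc <- digest(comparator, enz)
      if (dt$n_hits == 1L && identical(dt$cut_after[[1]], cut_at) &&
            dc$n_hits == 0L) {
        return(list(target = target, comparator = comparator,
                    site_start = site_start, cut_at = cut_at, map = map))
      }
    }
  })
  abort("could not place a unique restriction site; relax length/cut",
        class = "lampdx_error_parameter")
}

#' Generate a geometry-legal LAMP fixture: amplicon pair plus primer set
#'
#' Builds an amplicon pair with all five diagnostic SNPs embedded
#' ([make_amplicon_pair()] with `extra_snps = TRUE`), chooses element
#' intervals obeying the F3 < F2 < F1 < B1 < B2 < B3 geometry with the
#' diagnostic cluster inside the backward loop domain, and resamples each
#' primer region's free bases until every [validate_primer_set()] rule
#' passes (a constructed-to-pass fixture, not a thermodynamic search).
#'
#' @param seed integer RNG seed.
#' @param length amplicon length (default 694).
#' @return list with the [make_amplicon_pair()] fields plus `primer_set`
#'   (a [lamp_primer_set()] for the target allele), `loop_window`
#'   (backward loop domain) and `diagnostic_positions` (amplicon
#'   coordinates of the five SNPs).
#' @export
make_lamp_fixture <- function(seed = 0L, length = 694L) {
  pair <- make_amplicon_pair(length = length, seed = seed, extra_snps = TRUE)
  dpos <- pair$map$amplicon_position
  elements <- tibble(
    role  = c("F3", "F2", "F1c", "B1c", "LB", "B2", "B3"),
    start = c(10L, 38L, 70L, 175L, 245L, 280L, 310L),
    end   = c(31L, 59L, 91L, 196L, 266L, 301L, 331L)
  )
  enz <- builtin_enzymes()[1, ]
  protected <- c(pair$site_start:(pair$site_start + nchar(enz$site) - 1L),
                 dpos)

  withr::with_seed(child_seed(seed, "primers"), {
    tgt <- seq_chars(pair$target)
    cmp <- seq_chars(pair$comparator)
    for (i in seq_len(nrow(elements))) {
      region <- elements$start[i]:elements$end[i]
      free <- setdiff(region, protected)
      role <- elements$role[i]
      tmin <- if (role %in% c("LF", "LB")) 50 else 55
      ok <- FALSE
      for (try in 1:500) {
        tgt[free] <- .sample_background(base::length(free), 0.55)
        sq <- paste(tgt[region], collapse = "")
        tm <- melting_temp(sq)
        gc <- gc_fraction(sq)
        if (tm >= tmin + 0.5 && tm <= 64.5 && gc >= 0.41 && gc <= 0.64) {
          ok <- TRUE
          break
        }
      }
      if (!ok) abort("could not satisfy primer constraints",
                     class = "lampdx_error_design")
      cmp[free] <- tgt[free]
    }
    target <- paste(tgt, collapse = "")
    comparator <- paste(cmp, collapse = "")
    # primer regions must not have created a second restriction site
    if (digest(target, enz)$n_hits != 1L ||
          digest(comparator, enz)$n_hits != 0L) {
      return(make_lamp_fixture(child_seed(seed, "retry"), length))
    }
    set <- lamp_primer_set(target, elements)
    loop_window <- c(elements$end[elements$role == "B1c"] + 1L,
                     elements$start[elements$role == "B2"] - 1L)
    c(pair[c("site_start", "cut_at", "map")],
      list(target = target, comparator = comparator, primer_set = set,
           loop_window = loop_window, diagnostic_positions = dpos))
  })
}

#' LAMP kinetics parameters for the Cq simulator
#'
#' Detection time is modelled as an affine function of log10 template
#' copies with a quadratic temperature penalty around the 62 degrees C
#' optimum, a penalty proportional to the primer-template discrimination
#' score, and Gaussian replicate noise. Defaults are loose calibrations
#' chosen so a matched 1e4-copy reaction is positive within the 35-min
#' visual window and matched-vs-mismatched gaps exceed 40 min; none are
#' fitted values.
#'
#' @param intercept minutes at 1 copy (default 47).
#' @param slope minutes per log10 copies (default 3.5, > 0).
#' @param t_opt optimal reaction temperature in degrees C (default 62).
#' @param temp_coef quadratic penalty in min per squared degree (default
#'   0.5).
#' @param penalty_scale minutes per unit discrimination score (default 15).
#' @param noise_sd replicate noise SD in minutes (default 0.5).
#' @param detection_floor minimum amplifiable copy number (default 100).
#' @param run_limit run length in minutes (default 90).
#' @return list of class `kinetics_params`.
#' @export
kinetics_params <- function(intercept = 47, slope = 3.5, t_opt = 62,
                            temp_coef = 0.5, penalty_scale = 15,
                            noise_sd = 0.5, detection_floor = 100,
                            run_limit = 90) {
  check_number(slope, "slope", min = 1e-9)
  check_number(noise_sd, "noise_sd", 0)
  check_number(run_limit, "run_limit", min = 1e-9)
  structure(list(intercept = intercept, slope = slope, t_opt = t_opt,
                 temp_coef = temp_coef, penalty_scale = penalty_scale,
                 noise_sd = noise_sd, detection_floor = detection_floor,
                 run_limit = run_limit),
            class = "kinetics_params")
}

#' Simulate real-time LAMP detection times
#'
#' `Cq = intercept - slope * log10(copies) + temp_coef * (T - t_opt)^2 +
#' penalty_scale * score + N(0, noise_sd)`, censored (NA Cq) when the copy
#' load is below the detection floor or the draw exceeds the run limit.
#'
#' @param copies template copies per reaction (vectorised, >= 0).
#' @param score primer-template discrimination score (0 = perfect match).
#' @param temperature reaction temperature in degrees C.
#' @param params a [kinetics_params()].
#' @param seed integer RNG seed.
#' @return tibble `copies`, `score`, `temperature`, `cq` (minutes, NA =
#'   censored), `censored`, `run_limit`.
#' @export
simulate_cq <- function(copies, score = 0, temperature = 62,
                        params = kinetics_params(), seed = 0L) {
  if (any(copies < 0)) {
    abort("copies must be >= 0", class = "lampdx_error_parameter")
  }
  withr::with_seed(seed, {
    n <- base::length(copies)
    cq <- params$intercept - params$slope * log10(pmax(copies, 1)) +
      params$temp_coef * (temperature - params$t_opt)^2 +
      params$penalty_scale * score +
      rnorm(n, 0, params$noise_sd)
    censored <- copies < params$detection_floor | cq > params$run_limit
    tibble(copies = copies, score = score, temperature = temperature,
           cq = ifelse(censored, NA_real_, cq), censored = censored,
           run_limit = params$run_limit)
  })
}

#' Simulate the dual allele-specific assay and call the species
#'
#' Runs the matched-loop-primer and mismatched-loop-primer reactions for a
#' template class and applies [call_species()]: target and comparator
#' ("other") templates amplify at matched kinetics with their own primer
#' and penalised kinetics with the other; hybrid templates carry both
#' alleles and amplify at matched kinetics in both reactions; blanks are
#' censored in both.
#'
#' @param template one of `"target"`, `"other"`, `"hybrid"`, `"blank"`.
#' @param params a [kinetics_params()].
#' @param cutoff positive threshold in minutes (default 35).
#' @param copies template copies per reaction (default 1e4).
#' @param mismatch_score discrimination score of the mismatched
#'   primer-template duplex (default 4).
#' @param temperature reaction temperature in degrees C.
#' @param seed integer RNG seed.
#' @return one-row tibble: `template`, `rc_cq`, `rh_cq` plus the
#'   [call_species()] columns.
#' @export
simulate_dual_assay <- function(template, params = kinetics_params(),
                                cutoff = 35, copies = 1e4,
                                mismatch_score = 4, temperature = 62,
                                seed = 0L) {
  if (!template %in% c("target", "other", "hybrid", "blank")) {
    abort(sprintf("unknown template label '%s'", template),
          class = "lampdx_error_parameter")
  }
  scores <- switch(template,
    target = c(rc = 0, rh = mismatch_score),
    other  = c(rc = mismatch_score, rh = 0),
    hybrid = c(rc = 0, rh = 0),
    blank  = c(rc = 0, rh = 0)
  )
  load <- if (template == "blank") 0 else copies
  rc <- simulate_cq(load, scores[["rc"]], temperature, params,
                    seed = child_seed(seed, "rc"))
  rh <- simulate_cq(load, scores[["rh"]], temperature, params,
                    seed = child_seed(seed, "rh"))
  bind_rows(tibble(template = template, rc_cq = rc$cq, rh_cq = rh$cq)) |>
    mutate(call_species(.data$rc_cq, .data$rh_cq, cutoff = cutoff))
}
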