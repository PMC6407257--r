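# Seeded generator of structured multi-population genotype matrices under
# the Balding-Nichols model: per-variant population allele frequencies are
# beta-distributed around an ancestral frequency with variance
# F_ST * p * (1 - p), and genotypes are binomial(2, q) allele counts.
# Admixed populations draw genotypes from a fixed mixture of source
# frequencies (global proportions; no local-ancestry tracts).

#' Describe one simulated population
#'
#' Exactly one of `fst` and `admixture` must be given: a differentiated
#' population drifts away from its ancestral frequencies with fixation
#' index `fst`, while an admixed population mixes the allele frequencies of
#' previously defined source populations with fixed global proportions.
#'
#' @param name Population name (used as the label).
#' @param n_individuals Number of individuals to simulate.
#' @param fst Fixation index in (0, 1) relative to the parent frequencies.
#' @param admixture Named numeric vector of admixture proportions (names
#'   are source population names; must sum to 1).
#' @param parent Name of the population (or frequency-only group defined
#'   with `n_individuals = 0`) whose frequencies act as the ancestral
#'   frequencies; default is the shared ancestral pool.
#' @param superpopulation Higher-level grouping label; defaults to `parent`
#'   when set, else `name`.
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, n_individuals, fst = NULL, admixture = NULL,
                            parent = NULL, superpopulation = NULL) {
  check_number(n_individuals, "n_individuals", min = 0, integerish = TRUE)
  if (is.null(fst) == is.null(admixture)) {
    stop_gtmap("Exactly one of `fst` and `admixture` must be supplied.",
               "gtmap_parameter_error")
  }
  if (!is.null(fst) && (fst <= 0 || fst >= 1)) {
    stop_gtmap("`fst` must lie strictly between 0 and 1.",
               "gtmap_parameter_error")
  }
  if (!is.null(admixture)) {
    if (is.null(names(admixture)) || any(names(admixture) == "")) {
      stop_gtmap("`admixture` must be a named vector of proportions.",
                 "gtmap_parameter_error")
    }
    if (abs(sum(admixture) - 1) > 1e-12) {
      stop_gtmap("Admixture proportions must sum to 1.",
                 "gtmap_parameter_error")
    }
  }
  structure(list(name = name, n_individuals = as.integer(n_individuals),
                 fst = fst, admixture = admixture, parent = parent,
                 superpopulation = superpopulation %||% parent %||% name),
            class = "population_spec")
}

#' Describe a simulated dataset
#'
#' @param populations List of [population_spec()]s; admixture sources and
#'   parents must be defined before use, and at least one population must
#'   be non-admixed.
#' @param n_variants Number of variants D.
#' @param maf_range Ancestral allele-frequency range `(low, high)` with
#'   `0 < low < high <= 0.5`.
#' @param seed Integer seed making the whole dataset reproducible.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(populations, n_variants,
                            maf_range = c(0.05, 0.5), seed = 1) {
  if (!length(populations) || !all(purrr::map_lgl(populations, inherits,
                                                  "population_spec"))) {
    stop_gtmap("`populations` must be a list of population_spec objects.",
               "gtmap_parameter_error")
  }
  check_number(n_variants, "n_variants", min = 1, integerish = TRUE)
  if (length(maf_range) != 2L || maf_range[1L] <= 0 ||
      maf_range[2L] <= maf_range[1L] || maf_range[2L] > 0.5) {
    stop_gtmap("`maf_range` must satisfy 0 < low < high <= 0.5.",
               "gtmap_parameter_error")
  }
  names <- purrr::map_chr(populations, "name")
  if (anyDuplicated(names)) {
    stop_gtmap("Population names must be unique.", "gtmap_uniqueness_error")
  }
  if (all(purrr::map_lgl(populations, ~ !is.null(.x$admixture)))) {
    stop_gtmap("At least one population must be non-admixed.",
               "gtmap_parameter_error")
  }
  seen <- character(0)
  for (p in populations) {
    refs <- c(p$parent, names(p$admixture))
    bad <- setdiff(refs, seen)
    if (length(bad)) {
      stop_gtmap(sprintf("Population '%s' references '%s' before it is defined.",
                         p$name, bad[1L]),
                 "gtmap_parameter_error")
    }
    seen <- c(seen, p$name)
  }
  structure(list(populations = populations,
                 n_variants = as.integer(n_variants),
                 maf_range = as.numeric(maf_range),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Draw ancestral allele frequencies
#'
#' @param spec A [simulation_spec()] (its `n_variants`, `maf_range` and
#'   `seed` are used).
#' @return Numeric vector of D ancestral frequencies, uniform on
#'   `maf_range`.
#' @export
sample_ancestral_freqs <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, runif(spec$n_variants, spec$maf_range[1L],
                             spec$maf_range[2L]))
}

#' Balding-Nichols population frequencies
#'
#' Draws per-variant population frequencies
#' `q_d ~ Beta(p_d (1-F)/F, (1-p_d)(1-F)/F)`, which have mean `p_d` and
#' variance `F p_d (1 - p_d)`.
#'
#' @param p Ancestral frequency vector.
#' @param fst Fixation index in (0, 1).
#' @param seed Integer seed.
#' @return Frequency vector of the same length as `p`.
#' @export
population_freqs <- function(p, fst, seed = 1) {
  if (!is.numeric(fst) || length(fst) != 1L || fst <= 0 || fst >= 1) {
    stop_gtmap("`fst` must lie strictly between 0 and 1.",
               "gtmap_parameter_error")
  }
  with_seed(seed, bn_draw(p, fst))
}

bn_draw <- function(p, fst) {
  scale <- (1 - fst) / fst
  rbeta(length(p), p * scale, (1 - p) * scale)
}

#' Simulate unadmixed genotypes
#'
#' @param q Population allele-frequency vector (length D, values in
#'   `[0, 1]`).
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return n x D integer matrix of allele counts, each entry
#'   `Binomial(2, q_d)`.
#' @export
simulate_genotypes <- function(q, n, seed = 1) {
  if (any(q < 0 | q > 1)) {
    stop_gtmap("Frequencies must lie in [0, 1].", "gtmap_parameter_error")
  }
  check_number(n, "n", min = 1, integerish = TRUE)
  with_seed(seed, binom_genotypes(q, n))
}

binom_genotypes <- function(q, n) {
  matrix(rbinom(n * length(q), 2L, rep(q, each = n)), nrow = n)
}

#' Simulate admixed genotypes
#'
#' Each individual draws every genotype from
#' `Binomial(2, sum_s alpha_s q_sd)`: global admixture proportions applied
#' at the allele-frequency level.
#'
#' @param sources List of source frequency vectors (equal lengths).
#' @param proportions Admixture proportions summing to 1, one per source.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return n x D integer matrix of allele counts.
#' @export
simulate_admixed <- function(sources, proportions, n, seed = 1) {
  if (length(sources) != length(proportions)) {
    stop_gtmap("One proportion per source is required.",
               "gtmap_parameter_error")
  }
  if (abs(sum(proportions) - 1) > 1e-12) {
    stop_gtmap("Admixture proportions must sum to 1.", "gtmap_parameter_error")
  }
  q_eff <- Reduce(`+`, purrr::map2(sources, proportions, ~ .x * .y))
  simulate_genotypes(q_eff, n, seed = seed)
}

#' Simulate a full structured dataset
#'
#' Draws ancestral frequencies, per-population Balding-Nichols
#' frequencies (hierarchically, when populations name a `parent`),
#' genotypes for every population in order, and assembles a labelled
#' [genotype_matrix()]. Fully deterministic given `spec$seed`; generated
#' matrices contain no missing cells (use [corrupt_missing()] to add
#' missingness for I/O testing).
#'
#' @param spec A [simulation_spec()], e.g. from [preset_superpopulations()]
#'   or [preset_fine_structure()].
#' @return List with `genotypes` (labelled [genotype_matrix()]),
#'   `admixture` (tibble population/source/proportion of true global
#'   ancestry), `ancestral_freqs`, and `population_freqs` (D x populations
#'   matrix, admixed populations at their effective mixture frequencies).
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  pops <- spec$populations
  with_seed(spec$seed, {
    p_anc <- runif(spec$n_variants, spec$maf_range[1L], spec$maf_range[2L])
    freqs <- list()
    for (pop in pops) {
      if (is.null(pop$admixture)) {
        base <- if (is.null(pop$parent)) p_anc else freqs[[pop$parent]]
        freqs[[pop$name]] <- bn_draw(base, pop$fst)
      } else {
        freqs[[pop$name]] <- Reduce(`+`, purrr::map2(
          freqs[pop$admixture |> names()], pop$admixture, ~ .x * .y))
      }
    }
    blocks <- list()
    labels <- list()
    for (pop in pops) {
      if (pop$n_individuals == 0L) next
      blocks[[pop$name]] <- binom_genotypes(freqs[[pop$name]],
                                            pop$n_individuals)
      labels[[pop$name]] <- tibble::tibble(
        population = pop$name, superpopulation = pop$superpopulation,
        n = pop$n_individuals)
    }
    values <- do.call(rbind, blocks)
    lab <- dplyr::bind_rows(labels)
    sample_ids <- unlist(purrr::map2(lab$population, lab$n,
                                     ~ sprintf("%s_%03d", .x, seq_len(.y))))
    label_tab <- tibble::tibble(
      sample_id = sample_ids,
      population = rep(lab$population, lab$n),
      superpopulation = rep(lab$superpopulation, lab$n))
    g <- genotype_matrix(values, sample_ids,
                         sprintf("v%05d", seq_len(spec$n_variants)),
                         labels = label_tab)
    adx <- dplyr::bind_rows(purrr::map(pops, function(pop) {
      if (pop$n_individuals == 0L) return(NULL)
      if (is.null(pop$admixture)) {
        tibble::tibble(population = pop$name, source = pop$name,
                       proportion = 1)
      } else {
        tibble::tibble(population = pop$name,
                       source = names(pop$admixture),
                       proportion = as.numeric(pop$admixture))
      }
    }))
    list(genotypes = g, admixture = adx, ancestral_freqs = p_anc,
         population_freqs = do.call(cbind, freqs[names(blocks)]))
  })
}

#' Preset A: five well-differentiated populations
#'
#' Emulates continental-scale structure: 5 populations, each of 100
#' individuals, drifted from a common ancestral pool at F_ST = 0.1, with
#' 1000 variants of ancestral frequency in (0.05, 0.5).
#'
#' @param seed Integer seed.
#' @return A [simulation_spec()].
#' @export
preset_superpopulations <- function(seed = 1) {
  pops <- purrr::map(paste0("POP", 1:5), population_spec,
                     n_individuals = 100, fst = 0.1)
  simulation_spec(pops, n_variants = 1000, seed = seed)
}

#' Preset B: fine structure within broad groups
#'
#' Emulates within-continent structure: 4 groups drifted from the
#' ancestral pool at F_ST = 0.1, each containing 3 populations of 50
#' individuals drifted from their group at F_ST = 0.01, over 2000
#' variants. Group membership is carried in the `superpopulation` label.
#'
#' @param seed Integer seed.
#' @return A [simulation_spec()].
#' @export
preset_fine_structure <- function(seed = 1) {
  pops <- list()
  for (g in 1:4) {
    grp <- sprintf("GRP%d", g)
    pops <- c(pops, list(population_spec(grp, n_individuals = 0, fst = 0.1)))
    for (s in 1:3) {
      pops <- c(pops, list(population_spec(
        sprintf("%s_P%d", grp, s), n_individuals = 50, fst = 0.01,
        parent = grp)))
    }
  }
  simulation_spec(pops, n_variants = 2000, seed = seed)
}

#' Introduce missingness for I/O testing
#'
#' Masks a fraction of cells uniformly at random (setting them `NA`), so
#' readers and imputation can be exercised on otherwise complete simulated
#' matrices.
#'
#' @param g A [genotype_matrix()].
#' @param rate Fraction of cells to mask, in `[0, 1)`.
#' @param seed Integer seed.
#' @return The corrupted [genotype_matrix()].
#' @export
corrupt_missing <- function(g, rate, seed = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (rate < 0 || rate >= 1) {
    stop_gtmap("`rate` must lie in [0, 1).", "gtmap_parameter_error")
  }
  vals <- g$values
  with_seed(seed, {
    n_mask <- round(rate * length(vals))
    vals[sample(length(vals), n_mask)] <- NA_integer_
  })
  genotype_matrix(vals, g$sample_ids, g$variant_ids, labels = g$labels)
}
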