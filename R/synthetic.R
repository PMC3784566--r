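#' Synthetic filter-mating observations
#'
#' Emulates an end-point mating count table: given a true conjugation rate
#' parameter, transconjugant densities are drawn as
#' `T ~ Poisson(true_gamma * D * R)`, the single-plate cfu counting noise
#' model. Donor and recipient densities are taken as given (they are
#' measured from heavy plate counts whose relative error is negligible at
#' this scale).
#'
#' @param true_gamma true end-point rate parameter (ml/cfu, >= 0).
#' @param D,R donor and recipient densities (cfu/ml, > 0); recycled to the
#'   length of the longest argument.
#' @param n number of matings per parameter combination (default 1).
#' @param immune logical flag copied into the output (default `FALSE`).
#' @param seed optional integer seed.
#' @return tibble with columns `donor_plasmid`, `recipient_strain`, `D`,
#'   `R`, `T`, `immune`, ready for [compute_gamma()].
#' @export
make_mating_counts <- function(true_gamma, D, R, n = 1, immune = FALSE,
                               seed = NULL) {
  if (any(true_gamma < 0)) abort("`true_gamma` must be >= 0")
  if (any(D <= 0) || any(R <= 0)) abort("`D` and `R` must be > 0")
  len <- max(length(true_gamma), length(D), length(R)) * n
  with_seed_if(seed, {
    tab <- tibble(
      donor_plasmid = "synthetic",
      recipient_strain = "synthetic",
      D = rep_len(D, len),
      R = rep_len(R, len),
      true_gamma = rep_len(true_gamma, len),
      immune = rep_len(immune, len)
    )
    tab |>
      mutate(T = rpois(len, .data$true_gamma * .data$D * .data$R)) |>
      select("donor_plasmid", "recipient_strain", "D", "R", "T", "immune")
  })
}

#' Synthetic serial-transfer competition trajectory
#'
#' Emulates the data collection of a pairwise competition experiment: the
#' deterministic frequency path from [predict_frequency()] is observed at
#' each transfer by scoring `colonies_per_plate` colonies, so the observed
#' frequency is `Binomial(colonies, q) / colonies`.
#'
#' @inheritParams predict_frequency
#' @param colonies_per_plate colonies scored per transfer (>= 1).
#' @param seed optional integer seed.
#' @return tibble with columns `transfer`, `total` (colonies scored),
#'   `plasmid_bearing` and the observed frequency `q`, accepted by
#'   [estimate_s()].
#' @export
make_competition_trajectory <- function(q0, s, n_transfers,
                                        colonies_per_plate = 200,
                                        gens_per_transfer = log2(100),
                                        seed = NULL) {
  if (q0 <= 0 || q0 >= 1) abort("`q0` must be strictly inside (0, 1)")
  if (colonies_per_plate < 1) abort("`colonies_per_plate` must be >= 1")
  path <- predict_frequency(q0, s, n_transfers, gens_per_transfer)
  with_seed_if(seed, {
    hits <- rbinom(nrow(path), size = colonies_per_plate, prob = path$q)
    tibble(
      transfer = path$transfer,
      total = colonies_per_plate,
      plasmid_bearing = hits,
      q = hits / colonies_per_plate
    )
  })
}

synth_genotype_one <- function(category) {
  switch(category,
    spacer_deletion = paste0(
      "Δspc", paste(seq_len(sample(3, 1)), collapse = ",")
    ),
    spacer_point = "spc1(ΔA1)",
    is_insertion = sprintf(
      "%s(%d)::IS256-%s",
      sample(c("csm5", "csm6", "cas6"), 1), sample(1500, 1),
      sample(c("d", "i"), 1)
    ),
    frameshift = sprintf(
      "%s(ΔA%d). Frameshift",
      sample(c("cas10", "csm2", "csm4", "csm6", "cas6"), 1), sample(1500, 1)
    ),
    nonsense = {
      pos <- sample(1500, 1)
      sprintf(
        "%s(C%dT; Q%dStop)",
        sample(c("cas10", "cas6"), 1), pos, ceiling(pos / 3)
      )
    },
    missense = {
      pos <- sample(1500, 1)
      sprintf("csm4(G%dT; G%dV)", pos, ceiling(pos / 3))
    },
    locus_deletion = {
      start <- sample(2250000:2500000, 1)
      sprintf(
        "Δ%d–%d (%s)", start, start + sample(60000:300000, 1),
        sample(c("IS431", "IS256", "Tn554"), 1)
      )
    },
    abort(paste0("unknown mutation category '", category, "'"))
  )
}

#' Synthetic escape-genotype table
#'
#' Draws isolate categories from a multinomial over the seven mutation
#' categories and synthesizes a valid genotype string for each from
#' per-category template grammars; every output is parseable by
#' [parse_genotype()].
#'
#' @param proportions named numeric vector of category proportions (names
#'   from the seven categories of [parse_genotype()]; must sum to 1).
#' @param n number of isolates.
#' @param seed optional integer seed.
#' @return tibble with columns `isolate_id`, `genotype_string`, `batch`
#'   (all `"S"` for synthetic), matching the packaged genotype fixture
#'   schema.
#' @export
make_genotype_table <- function(proportions, n, seed = NULL) {
  if (is.null(names(proportions)) ||
        !all(names(proportions) %in% mutation_categories)) {
    abort(paste0(
      "`proportions` must be named with categories among: ",
      paste(mutation_categories, collapse = ", ")
    ))
  }
  if (abs(sum(proportions) - 1) > 1e-8) abort("`proportions` must sum to 1")
  if (n == 0) {
    return(tibble(
      isolate_id = character(), genotype_string = character(),
      batch = character()
    ))
  }
  with_seed_if(seed, {
    cats <- sample(names(proportions), n, replace = TRUE, prob = proportions)
    tibble(
      isolate_id = paste0("S", seq_len(n)),
      genotype_string = vapply(cats, synth_genotype_one, character(1)),
      batch = "S"
    )
  })
}
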