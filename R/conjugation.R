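#' End-point conjugation rate parameter and transfer frequency
#'
#' Computes, for each filter mating, the end-point rate parameter
#' \eqn{\Gamma = T / (D \times R)} (ml cfu^-1) and the transfer frequency
#' \eqn{T / R}, where `D`, `R` and `T` are the donor, recipient and
#' transconjugant densities (cfu/ml) recovered after mating. \eqn{\Gamma}
#' normalises the transconjugant yield by the mass-action collision term
#' \eqn{D \times R}, so matings run at different cell densities become
#' comparable; it is an end-point summary, not the per-hour rate constant of
#' a dynamic transfer model.
#'
#' @param matings data frame with numeric columns `D`, `R`, `T` (cfu/ml).
#'   Any other columns (strain labels, an `immune` flag) are carried through.
#' @return the input as a tibble with columns `gamma` and `frequency`
#'   appended. Values are exact quotients; round with [report_signif()] for
#'   presentation.
#' @examples
#' matings <- tibble::tibble(D = 4.8e9, R = 1.3e9, T = 8.0e4)
#' compute_gamma(matings)
#' @export
compute_gamma <- function(matings) {
  assert_columns(matings, c("D", "R", "T"))
  if (any(!is.finite(matings$D) | matings$D <= 0)) {
    abort("donor densities `D` must all be finite and > 0")
  }
  if (any(!is.finite(matings$R) | matings$R <= 0)) {
    abort("recipient densities `R` must all be finite and > 0")
  }
  if (any(!is.finite(matings$T) | matings$T < 0)) {
    abort("transconjugant densities `T` must all be finite and >= 0")
  }
  as_tibble(matings) |>
    mutate(gamma = .data$T / (.data$D * .data$R), frequency = .data$T / .data$R)
}

group_mean <- function(x, type = c("arithmetic", "geometric")) {
  type <- arg_match(type)
  if (type == "arithmetic") return(mean(x))
  if (any(x <= 0)) return(0) # geometric mean degenerates with zero rates
  exp(mean(log(x)))
}

split_immunity <- function(matings, call = caller_env()) {
  assert_columns(matings, c("D", "R", "T", "immune"), call = call)
  est <- compute_gamma(matings)
  imm <- filter(est, .data$immune)
  per <- filter(est, !.data$immune)
  if (nrow(imm) == 0 || nrow(per) == 0) {
    abort("`matings` must contain both immune and permissive rows", call = call)
  }
  list(immune = imm, permissive = per)
}

#' Fold reduction of plasmid transfer imposed by CRISPR immunity
#'
#' Ratio of the group-mean \eqn{\Gamma} for permissive matings (recipient not
#' immune to the donor plasmid) over immune matings. A CRISPR-Cas locus
#' targeting the incoming plasmid typically depresses \eqn{\Gamma} by three
#' to four orders of magnitude, so this ratio lands in the 10^3--10^4 range.
#'
#' @param matings data frame with columns `D`, `R`, `T` and a logical
#'   `immune` flag marking matings where the recipient's CRISPR-Cas system
#'   targets the donor plasmid.
#' @param mean_type `"arithmetic"` (default) or `"geometric"` group mean.
#' @return one-row tibble with columns `gamma_immune`, `gamma_permissive`
#'   and `fold_reduction`. When every immune mating yielded zero
#'   transconjugants the reduction is reported as `Inf`.
#' @export
fold_reduction <- function(matings, mean_type = c("arithmetic", "geometric")) {
  mean_type <- arg_match(mean_type)
  grp <- split_immunity(matings)
  gi <- group_mean(grp$immune$gamma, mean_type)
  gp <- group_mean(grp$permissive$gamma, mean_type)
  tibble(
    gamma_immune = gi,
    gamma_permissive = gp,
    fold_reduction = if (gi == 0) Inf else gp / gi
  )
}

#' Pre-existing CRISPR-escape fraction of a recipient population
#'
#' The reciprocal of [fold_reduction()]: mean \eqn{\Gamma} into immune
#' recipients over mean \eqn{\Gamma} into permissive recipients. Because
#' plasmid evasion of CRISPR immunity occurs at the level of the host -- via
#' recipients that have already lost or inactivated the targeting locus --
#' this ratio estimates the standing fraction of CRISPR-defective cells in
#' the recipient population (of order 10^-4 to 10^-3 in *S. epidermidis*).
#'
#' @inheritParams fold_reduction
#' @return one-row tibble with columns `gamma_immune`, `gamma_permissive` and
#'   `escape_fraction` (dimensionless; time-normalisation to a per-generation
#'   or per-hour rate is left to the caller).
#' @export
estimate_escape_fraction <- function(matings,
                                     mean_type = c("arithmetic", "geometric")) {
  mean_type <- arg_match(mean_type)
  grp <- split_immunity(matings)
  gi <- group_mean(grp$immune$gamma, mean_type)
  gp <- group_mean(grp$permissive$gamma, mean_type)
  if (gp == 0) abort("permissive mean gamma is zero; escape fraction undefined")
  tibble(
    gamma_immune = gi,
    gamma_permissive = gp,
    escape_fraction = gi / gp
  )
}
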