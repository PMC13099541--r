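# Linked-structure generator: plants (a) a regression of multifunctionality
# on network stability and (b) a 4-block latent causal chain
# density -> environment -> network -> multifunctionality, and returns the
# ground truth so downstream estimators can be tested for recovery.

#' Scenario for the linked stability / multifunctionality generator
#'
#' @param slope,intercept Planted regression of multifunctionality on the
#'   network-stability score.
#' @param noise_sd Residual sd (>= 0) used both in the regression and at
#'   each stage of the latent chain.
#' @param path_coefficients Numeric length 3 in `[-1, 1]`: raw slopes of the
#'   chain density -> environment -> network -> multifunctionality.
#' @return An object of class `"linkage_scenario"`.
#' @export
linkage_scenario <- function(slope = 0.5, intercept = 0.4, noise_sd = 0.1,
                             path_coefficients = c(0.6, -0.9, -0.2)) {
  if (!(noise_sd >= 0)) stop("noise_sd must be >= 0")
  if (length(path_coefficients) != 3 || any(abs(path_coefficients) > 1)) {
    stop("path_coefficients must be 3 values in [-1, 1]")
  }
  structure(list(slope = slope, intercept = intercept, noise_sd = noise_sd,
                 path_coefficients = as.numeric(path_coefficients)),
            class = "linkage_scenario")
}

#' Generate a linked stability/multifunctionality dataset with known truth
#'
#' Two linked pieces are generated for `n` plots:
#' \describe{
#'   \item{regression}{`multifun = intercept + slope * stability + noise`,
#'     with stability scores drawn standard-normal.}
#'   \item{latent chain}{density (standardized trees-per-hectare of the
#'     design, recycled over plots) feeding environment, network and
#'     multifunctionality blocks, each stage `next = beta * scale(prev) +
#'     noise`.}
#' }
#' Because each stage's input is standardized before the planted raw slope
#' `beta` is applied, the population path coefficient on standardized scales
#' is `beta / sqrt(beta^2 + noise_sd^2)`; the truth record carries both
#' (`path_coefficients` raw, `std_path_coefficients` standardized), so raw
#' per-stage OLS is checked against the former and standardized estimators
#' (such as [fit_plspm()]) against the latter.
#'
#' @param design A [study_design()] (supplies the density gradient values).
#' @param scenario A [linkage_scenario()].
#' @param n Number of plots; defaults to the design's sample count.
#' @param seed Integer seed.
#' @return List with `stability` (data.frame plot, stability, multifun),
#'   `chain` (data.frame density, environment, network, multifun), and
#'   `truth` (scenario parameters plus implied standardized coefficients).
#' @export
generate_linked_dataset <- function(design, scenario, n = NULL, seed = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(scenario, "linkage_scenario"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- design$n_samples
  s <- scenario$noise_sd

  stability <- rnorm(n)
  multifun <- scenario$intercept + scenario$slope * stability +
    (if (s > 0) rnorm(n, 0, s) else 0)
  reg <- data.frame(plot = sprintf("plot%03d", seq_len(n)),
                    stability = stability, multifun = multifun)

  dens_vals <- if (is.null(design$density_trees_ha)) {
    seq_along(design$density_levels)
  } else design$density_trees_ha
  density <- rep_len(dens_vals, n)
  b <- scenario$path_coefficients
  # each stage input is standardized by its *population* moments (the
  # density design vector is deterministic, so its empirical moments are
  # population constants; later stages have mean 0, sd sqrt(b^2 + s^2)),
  # keeping the samples iid — sample-based scaling would couple them
  zd <- as.numeric(scale(density))
  environment <- b[1] * zd + (if (s > 0) rnorm(n, 0, s) else 0)
  network <- b[2] * environment / sqrt(b[1]^2 + s^2) +
    (if (s > 0) rnorm(n, 0, s) else 0)
  mf <- b[3] * network / sqrt(b[2]^2 + s^2) +
    (if (s > 0) rnorm(n, 0, s) else 0)
  chain <- data.frame(density = density, environment = environment,
                      network = network, multifun = mf)

  std <- b / sqrt(b^2 + s^2)
  list(stability = reg, chain = chain,
       truth = list(slope = scenario$slope, intercept = scenario$intercept,
                    noise_sd = s, path_coefficients = b,
                    std_path_coefficients = std))
}
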