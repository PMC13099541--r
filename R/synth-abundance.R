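# Compositional count simulator: softmax(base + effects + logistic-normal
# noise) -> multinomial draw at a sample-specific sequencing depth.

#' Compositional model for synthetic ASV counts
#'
#' Expected per-sample taxon proportions are the softmax of a base
#' log-abundance profile plus additive per-density and per-depth log-fold
#' effects plus a logistic-normal perturbation (iid normal noise on the log
#' scale with standard deviation `dispersion`). Counts are then a single
#' multinomial draw at a sample-specific sequencing depth drawn from a
#' normal distribution (rounded, floored at 1).
#'
#' @param n_taxa Integer >= 2.
#' @param base_log_abundance Numeric length `n_taxa`; defaults to a smooth
#'   decreasing profile spanning ~5 natural-log units (a few dominant taxa,
#'   a long tail of rare ones).
#' @param density_effects Matrix (densities x taxa) of per-taxon log-fold
#'   shifts, rownames = density labels; defaults to all-zero for the default
#'   four-density design.
#' @param depth_effect Numeric length `n_taxa`, the log-fold shift applied to
#'   the second (sub-surface) depth layer; default zero.
#' @param dispersion Positive sd of the logistic-normal noise.
#' @param depth_mean,depth_sd Mean and sd of the sequencing depth per sample.
#' @param density_levels Density labels the effect matrix rows refer to.
#' @return An object of class `"composition_model"`.
#' @export
composition_model <- function(n_taxa = 300L,
                              base_log_abundance = NULL,
                              density_effects = NULL,
                              depth_effect = NULL,
                              dispersion = 0.3,
                              depth_mean = 30000,
                              depth_sd = 2000,
                              density_levels = c("VHD", "HD", "MD", "LD")) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  if (is.null(base_log_abundance)) {
    base_log_abundance <- -5 * (seq_len(n_taxa) - 1) / (n_taxa - 1)
  }
  if (length(base_log_abundance) != n_taxa) stop("base profile length != n_taxa")
  if (is.null(density_effects)) {
    density_effects <- matrix(0, length(density_levels), n_taxa,
                              dimnames = list(density_levels, NULL))
  }
  density_effects <- as.matrix(density_effects)
  if (ncol(density_effects) != n_taxa) stop("effect vectors must have length n_taxa")
  if (is.null(rownames(density_effects))) rownames(density_effects) <- density_levels
  if (is.null(depth_effect)) depth_effect <- rep(0, n_taxa)
  if (length(depth_effect) != n_taxa) stop("depth effect must have length n_taxa")
  if (!(dispersion >= 0)) stop("dispersion must be >= 0")
  if (depth_mean <= 0) stop("sequencing depth must be positive")
  structure(
    list(n_taxa = n_taxa, base_log_abundance = as.numeric(base_log_abundance),
         density_effects = density_effects,
         depth_effect = as.numeric(depth_effect),
         dispersion = dispersion, depth_mean = depth_mean, depth_sd = depth_sd),
    class = "composition_model"
  )
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Expected taxon proportions for one design cell (no noise)
#'
#' @param model A [composition_model()].
#' @param density Density label (a row of the model's effect matrix).
#' @param depth_index 1 for the surface layer, 2 for the sub-surface layer.
#' @return Numeric vector of proportions summing to 1.
#' @export
expected_proportions <- function(model, density, depth_index = 1L) {
  stopifnot(inherits(model, "composition_model"))
  eta <- model$base_log_abundance + model$density_effects[density, ]
  if (depth_index > 1L) eta <- eta + model$depth_effect
  softmax(eta)
}

#' Generate a synthetic abundance table
#'
#' @param design A [study_design()]; its density labels must appear in the
#'   model's effect matrix.
#' @param model A [composition_model()].
#' @param seed Integer seed.
#' @param taxon_prefix Prefix for generated taxon ids.
#' @return An [abundance_table()] whose metadata is [design_metadata()] of
#'   the design. Each sample's counts sum to its drawn sequencing depth.
#' @export
#' @examples
#' tab <- generate_abundance_table(study_design(replicates = 2),
#'                                 composition_model(n_taxa = 50), seed = 1)
#' rowSums(tab$counts)[1:3]
generate_abundance_table <- function(design, model, seed = NULL,
                                     taxon_prefix = "ASV") {
  stopifnot(inherits(design, "study_design"), inherits(model, "composition_model"))
  if (!all(design$density_levels %in% rownames(model$density_effects))) {
    stop("model density effects do not cover the design's density levels")
  }
  if (!is.null(seed)) set.seed(seed)
  md <- design_metadata(design)
  n <- nrow(md)
  counts <- matrix(0, n, model$n_taxa,
                   dimnames = list(md$sample_id,
                                   sprintf("%s%04d", taxon_prefix,
                                           seq_len(model$n_taxa))))
  for (i in seq_len(n)) {
    eta <- model$base_log_abundance +
      model$density_effects[md$density[i], ]
    if (match(md$depth[i], design$depth_levels) > 1L) {
      eta <- eta + model$depth_effect
    }
    if (model$dispersion > 0) {
      eta <- eta + rnorm(model$n_taxa, 0, model$dispersion)
    }
    p <- softmax(eta)
    size <- max(1L, as.integer(round(rnorm(1, model$depth_mean, model$depth_sd))))
    counts[i, ] <- rmultinom(1, size, p)[, 1]
  }
  abundance_table(counts, md)
}

#' Preset: density-stable ("bacteria-like") composition model
#'
#' Random but reproducible base profile, no density effects, a mild depth
#' effect — emulating a community whose composition is insensitive to the
#' density gradient.
#'
#' @param n_taxa,dispersion,seed See [composition_model()].
#' @return A [composition_model()].
#' @export
bacterial_composition_model <- function(n_taxa = 300L, dispersion = 0.3,
                                        seed = 101L) {
  r <- local_rng(seed)
  base <- sort(r$norm(n_taxa, 0, 1.5), decreasing = TRUE)
  composition_model(n_taxa, base, depth_effect = r$norm(n_taxa, 0, 0.15),
                    dispersion = dispersion)
}

#' Preset: density-sensitive ("fungi-like") composition model
#'
#' As [bacterial_composition_model()] but with a graded per-density log-fold
#' effect on a quarter of the taxa, so composition shifts along the density
#' gradient (strongest contrast between the very-high- and low-density ends).
#'
#' @param n_taxa,dispersion,seed See [composition_model()].
#' @param effect_size Log-fold magnitude of the planted density response.
#' @return A [composition_model()].
#' @export
fungal_composition_model <- function(n_taxa = 120L, dispersion = 0.45,
                                     effect_size = 1.2, seed = 202L) {
  r <- local_rng(seed)
  base <- sort(r$norm(n_taxa, 0, 1.8), decreasing = TRUE)
  levels <- c("VHD", "HD", "MD", "LD")
  responders <- seq_len(max(2L, n_taxa %/% 4L))
  direction <- sign(r$norm(length(responders), 0, 1))
  grad <- seq(-1, 1, length.out = length(levels)) # VHD -> LD
  eff <- matrix(0, length(levels), n_taxa, dimnames = list(levels, NULL))
  for (k in seq_along(levels)) {
    eff[k, responders] <- grad[k] * direction * effect_size
  }
  composition_model(n_taxa, base, density_effects = eff,
                    depth_effect = r$norm(n_taxa, 0, 0.2),
                    dispersion = dispersion)
}

# self-contained RNG stream that does not disturb the global .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(norm = function(n, mean = 0, sd = 1) draw(rnorm, n, mean, sd),
       unif = function(n, min = 0, max = 1) draw(runif, n, min, max))
}
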