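# Soil-property generator: truncated-normal draws around per-cell means/SDs.

#' The twelve soil chemistry / enzyme variables used throughout the package
#'
#' pH; soil organic carbon (SOC, g kg-1); easily oxidizable organic carbon
#' (EOC, also called OSOC); total nitrogen (TN); total phosphorus (TP); total
#' potassium (TK, g kg-1); ammonium nitrogen (AN, NH4+-N) and nitrate
#' nitrogen (NN, NO3--N, mg kg-1); polyphenol oxidase (PPO), urease (URE),
#' acid phosphatase (PHO) and nitrate reductase (NR) activities.
#' @export
SOIL_VARIABLES <- c("pH", "SOC", "EOC", "TN", "TP", "TK",
                    "AN", "NN", "PPO", "URE", "PHO", "NR")

#' Per-cell soil generator parameters
#'
#' A long-format parameter table with one row per density-by-depth cell and
#' per variable, carrying the mean and standard deviation of a truncated
#' normal draw. [default_soil_params()] populates it with the published
#' field means and SDs of the emulated study system, e.g. surface soil under
#' very high density has pH 6.50 +/- 0.04 and SOC 6.69 +/- 0.26 g kg-1.
#'
#' @param params A data.frame with columns `density`, `depth`, `variable`,
#'   `mean`, `sd`.
#' @return The validated parameter table, classed `"soil_params"`.
#' @export
soil_params <- function(params) {
  need <- c("density", "depth", "variable", "mean", "sd")
  if (!all(need %in% names(params))) {
    stop("soil params need columns: ", paste(need, collapse = ", "))
  }
  if (any(params$sd < 0)) stop("all SDs must be >= 0")
  class(params) <- c("soil_params", "data.frame")
  params
}

#' Default soil generator parameters (field-observed cell means and SDs)
#'
#' @return A [soil_params()] table covering the default 4 density x 2 depth
#'   design for all twelve variables in [SOIL_VARIABLES].
#' @export
default_soil_params <- function() {
  # rows: VHD,HD,MD,LD within depth 0-20 then 20-40; cols follow SOIL_VARIABLES
  m <- rbind(
    c(6.50,  6.69, 24.37, 0.83, 0.59, 14.09, 6.05, 2.07, 4.81, 301.35, 1.86, 0.45),
    c(6.64, 10.16, 24.86, 1.25, 0.64, 13.94, 6.11, 2.67, 2.32, 423.48, 2.90, 0.69),
    c(6.97,  6.18, 27.19, 0.84, 0.50, 14.90, 5.25, 1.59, 1.34, 293.32, 2.10, 0.19),
    c(6.91,  2.99, 19.43, 0.56, 0.44, 14.77, 3.70, 1.82, 1.74, 295.59, 1.35, 0.28),
    c(7.02,  6.37, 24.65, 0.81, 0.53, 13.51, 4.37, 1.45, 3.96, 251.15, 1.49, 0.10),
    c(7.23,  6.75, 21.04, 1.08, 0.56, 13.64, 4.11, 2.14, 2.38, 308.82, 1.58, 0.10),
    c(7.19,  3.19, 23.21, 0.68, 0.46, 14.59, 3.26, 0.85, 0.88, 236.07, 0.88, 0.10),
    c(7.07,  3.09, 22.23, 0.53, 0.41, 14.85, 4.20, 1.63, 1.46, 280.85, 0.84, 0.10)
  )
  s <- rbind(
    c(0.04, 0.26, 3.67, 0.02, 0.01, 0.27, 0.29, 0.23, 1.89,  9.56, 0.32, 0.05),
    c(0.12, 0.35, 2.25, 0.02, 0.07, 0.36, 0.68, 0.45, 1.25, 25.39, 0.26, 0.04),
    c(0.06, 0.33, 2.31, 0.04, 0.04, 0.15, 0.91, 0.26, 0.66, 21.14, 0.51, 0.16),
    c(0.08, 0.38, 2.31, 0.05, 0.02, 0.20, 0.27, 0.16, 1.49, 37.30, 0.30, 0.16),
    c(0.06, 0.29, 0.94, 0.02, 0.03, 0.32, 0.32, 0.14, 0.45,  8.99, 0.19, 0.01),
    c(0.11, 0.26, 1.27, 0.03, 0.04, 0.32, 0.94, 0.33, 0.84,  7.91, 0.10, 0.01),
    c(0.04, 0.24, 1.61, 0.03, 0.03, 0.66, 0.20, 0.20, 0.40,  5.14, 0.18, 0.01),
    c(0.03, 0.42, 1.61, 0.01, 0.02, 0.28, 0.83, 0.19, 0.60,  4.68, 0.06, 0.01)
  )
  cells <- expand.grid(density = c("VHD", "HD", "MD", "LD"),
                       depth = c("0-20", "20-40"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(density = cells$density[i], depth = cells$depth[i],
               variable = SOIL_VARIABLES, mean = m[i, ], sd = s[i, ],
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  soil_params(long)
}

# one-sided/two-sided truncated normal via inverse-CDF; sd = 0 degenerates to
# the mean (clamped into [lower, upper])
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a soil-property table for a design
#'
#' Draws every variable from a truncated normal with the per-cell mean and
#' SD given in `params`. Non-negativity is enforced by truncation at zero;
#' pH is truncated to \[3, 10\].
#'
#' @param design A [study_design()].
#' @param params A [soil_params()] table; defaults to [default_soil_params()].
#' @param seed Integer seed (draws are reproducible given the seed).
#' @return A data.frame: `sample_id`, `density`, `depth`, `replicate`, then
#'   one column per variable in `params`.
#' @export
#' @examples
#' soil <- generate_soil_table(study_design(), seed = 1)
#' dim(soil) # 48 samples
generate_soil_table <- function(design, params = default_soil_params(),
                                seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  params <- soil_params(as.data.frame(params))
  if (!is.null(seed)) set.seed(seed)
  md <- design_metadata(design)
  vars <- unique(params$variable)
  out <- md
  for (v in vars) out[[v]] <- NA_real_
  for (d in design$density_levels) {
    for (z in design$depth_levels) {
      rows <- which(md$density == d & md$depth == z)
      for (v in vars) {
        p <- params[params$density == d & params$depth == z &
                      params$variable == v, , drop = FALSE]
        if (nrow(p) != 1L) {
          stop(sprintf("missing soil parameters for cell %s/%s variable %s",
                       d, z, v))
        }
        bounds <- if (v == "pH") c(3, 10) else c(0, Inf)
        out[rows, v] <- rtruncnorm(length(rows), p$mean, p$sd,
                                   bounds[1], bounds[2])
      }
    }
  }
  out
}
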