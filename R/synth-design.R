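#' Density-by-depth sampling design
#'
#' Describes a factorial soil-sampling campaign: stand-density levels crossed
#' with soil-depth layers, each cell sampled with a fixed number of replicate
#' composite samples. The default reproduces the full campaign of the study
#' system this package emulates: four densities (very high to low) by two
#' depth layers by six replicates, i.e. 48 samples.
#'
#' @param density_levels Ordered character vector of stand-density labels,
#'   densest first. Default `c("VHD", "HD", "MD", "LD")`.
#' @param depth_levels Character vector of soil-layer labels (cm ranges).
#' @param replicates Positive integer, replicate composite samples per
#'   density-by-depth cell.
#' @param density_trees_ha Optional numeric vector of stand densities
#'   (trees per hectare) parallel to `density_levels`; used when density
#'   enters models as a quantitative variable.
#'
#' @return An object of class `"study_design"`: a list with the validated
#'   fields plus `n_samples`.
#' @seealso [design_metadata()] to expand the design into a per-sample
#'   metadata table.
#' @export
#' @examples
#' d <- study_design()
#' d$n_samples # 48
study_design <- function(density_levels = c("VHD", "HD", "MD", "LD"),
                         depth_levels = c("0-20", "20-40"),
                         replicates = 6L,
                         density_trees_ha = c(2450, 1633, 1067, 583)) {
  density_levels <- as.character(density_levels)
  depth_levels <- as.character(depth_levels)
  if (anyDuplicated(density_levels) || anyDuplicated(depth_levels)) {
    stop("design labels must be unique")
  }
  replicates <- as.integer(replicates)
  if (length(replicates) != 1L || is.na(replicates) || replicates < 1L) {
    stop("`replicates` must be a positive integer")
  }
  if (!is.null(density_trees_ha) &&
      length(density_trees_ha) != length(density_levels)) {
    stop("`density_trees_ha` must be parallel to `density_levels`")
  }
  structure(
    list(
      density_levels = density_levels,
      depth_levels = depth_levels,
      replicates = replicates,
      density_trees_ha = density_trees_ha,
      n_samples = length(density_levels) * length(depth_levels) * replicates
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:",
      length(x$density_levels), "densities x",
      length(x$depth_levels), "depths x",
      x$replicates, "replicates =", x$n_samples, "samples\n")
  invisible(x)
}

#' Per-sample metadata table for a design
#'
#' @param design A [study_design()].
#' @return A data.frame with columns `sample_id`, `density`, `depth`,
#'   `replicate` and (when the design carries quantitative densities)
#'   `trees_ha`; one row per sample, densities varying slowest.
#' @export
design_metadata <- function(design) {
  stopifnot(inherits(design, "study_design"))
  md <- expand.grid(
    replicate = seq_len(design$replicates),
    depth = design$depth_levels,
    density = design$density_levels,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("density", "depth", "replicate")]
  md$sample_id <- sprintf("%s_%s_r%d", md$density, md$depth, md$replicate)
  if (!is.null(design$density_trees_ha)) {
    md$trees_ha <- design$density_trees_ha[match(md$density, design$density_levels)]
  }
  md[, c("sample_id", "density", "depth", "replicate",
         intersect("trees_ha", names(md)))]
}
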