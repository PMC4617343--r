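#' Describe one species' conditioning design
#'
#' A design enumerates the conditioning types of one wasp species, the
#' sampling time points of each type, the number of biological replicates,
#' and whether an unconditioned control group is included. The two stock
#' designs mirror the study layout: 3 conditioning types x 3 time points
#' (15 min, 1 h, 4 h) plus an unconditioned control with 3 replicates gives
#' 30 samples for *C. glomerata*; one type x 3 time points (1 h, 4 h, 24 h)
#' plus control gives 12 samples for *C. rubecula*.
#'
#' @param species species label.
#' @param conditioning_types character vector of conditioning-type labels.
#' @param time_points character vector (shared by all types) or named list
#'   of per-type time-point vectors.
#' @param n_replicates biological replicates per group (>= 2).
#' @param unconditioned include an unconditioned control group?
#' @return an object of class `design_descriptor`.
#' @export
design_descriptor <- function(species, conditioning_types, time_points,
                              n_replicates = 3L, unconditioned = TRUE) {
  stopifnot(length(species) == 1L, length(conditioning_types) >= 1L)
  if (!is.list(time_points))
    time_points <- setNames(rep(list(time_points), length(conditioning_types)),
                            conditioning_types)
  if (!setequal(names(time_points), conditioning_types))
    stop("time_points must cover exactly the conditioning types")
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  structure(list(species = species,
                 conditioning_types = conditioning_types,
                 time_points = time_points[conditioning_types],
                 n_replicates = as.integer(n_replicates),
                 unconditioned = isTRUE(unconditioned)),
            class = "design_descriptor")
}

#' @rdname design_descriptor
#' @export
design_glomerata <- function(n_replicates = 3L) {
  design_descriptor("Cglom",
                    c("Glo-ARM", "Glo-LTM-short", "Glo-LTM-long"),
                    c("15m", "1h", "4h"), n_replicates)
}

#' @rdname design_descriptor
#' @export
design_rubecula <- function(n_replicates = 3L) {
  design_descriptor("Crub", "Rub-LTM-long", c("1h", "4h", "24h"),
                    n_replicates)
}

n_samples <- function(design) {
  sum(lengths(design$time_points)) * design$n_replicates +
    if (design$unconditioned) design$n_replicates else 0L
}

#' Specify a planted differential-expression effect
#'
#' @param role one of `ltm_only`, `arm_only`, `shared_same_direction`,
#'   `opposing`, `splice_specific`.
#' @param types conditioning types carrying the effect. For `opposing`,
#'   `shared_same_direction` and `splice_specific` the ARM type is implied
#'   in addition.
#' @param time_points time points affected (`NULL` = all of each type).
#' @param log2fc effect magnitude on the log2 scale.
#' @param n_genes number of genes assigned this role.
#' @export
effect_spec <- function(role, types, time_points = NULL, log2fc = 2,
                        n_genes = 10L) {
  role <- match.arg(role, c("ltm_only", "arm_only", "shared_same_direction",
                            "opposing", "splice_specific"))
  if (!is.finite(log2fc)) stop("log2fc must be finite")
  structure(list(role = role, types = types, time_points = time_points,
                 log2fc = log2fc, n_genes = as.integer(n_genes)),
            class = "effect_spec")
}

default_planted_effects <- function(design, n_genes) {
  arm <- grep("ARM", design$conditioning_types, value = TRUE)
  ltm <- setdiff(design$conditioning_types, arm)
  frac <- function(f) max(1L, round(f * n_genes))
  if (length(arm)) {
    list(effect_spec("ltm_only", ltm, n_genes = frac(0.03)),
         effect_spec("arm_only", arm, n_genes = frac(0.02)),
         effect_spec("shared_same_direction", ltm, n_genes = frac(0.02)),
         effect_spec("opposing", ltm, n_genes = frac(0.01)),
         effect_spec("splice_specific", ltm, n_genes = frac(0.01)))
  } else {
    list(effect_spec("ltm_only", ltm, n_genes = frac(0.05)))
  }
}

#' Configure the synthetic-data generator
#'
#' The defaults emulate one species of the study design: a transcriptome
#' with planted structural classes (8\% antisense in total), genes with
#' multiple splice variants, negative-binomial counts with a dispersion
#' trend `phi0 + a/mean`, log-scale replicate block effects, and planted
#' fold-change roles that exercise the LTM-vs-ARM comparison rules.
#'
#' @param seed master seed; all stages derive deterministic sub-streams.
#' @param n_genes number of genes to simulate.
#' @param multi_transcript_fraction fraction of genes with >1 splice
#'   variant (the study observed 24\%).
#' @param class_proportions named fractions over the structural classes
#'   `sense`, `antisense_to_protein`, `antisense_to_sense`, `lncRNA`,
#'   `unknown`; must sum to 1.
#' @param design a [design_descriptor()].
#' @param library_size_range integer pair; sizes are drawn log-uniformly.
#' @param baseline_logmean_sd sd of baseline log-abundance across
#'   transcripts.
#' @param dispersion_phi0 asymptotic NB dispersion.
#' @param dispersion_a trend numerator: dispersion = phi0 + a / mean.
#' @param block_effect_sd sd of the log-scale replicate effect.
#' @param planted_effects list of [effect_spec()] objects.
#' @param boundary_margin minimum distance of simulated alignment coverages
#'   and identities from the classification thresholds (capped near 1 for
#'   the identity thresholds).
#' @param n_decoys number of extra near-threshold decoy transcripts.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 500L,
                       multi_transcript_fraction = 0.24,
                       class_proportions = c(sense = 0.57,
                                             antisense_to_protein = 0.05,
                                             antisense_to_sense = 0.03,
                                             lncRNA = 0.05,
                                             unknown = 0.30),
                       design = design_glomerata(),
                       library_size_range = c(1e6, 5e6),
                       baseline_logmean_sd = 1.5,
                       dispersion_phi0 = 0.05,
                       dispersion_a = 2,
                       block_effect_sd = 0.1,
                       planted_effects = NULL,
                       boundary_margin = 0.1,
                       n_decoys = 16L) {
  classes <- c("sense", "antisense_to_protein", "antisense_to_sense",
               "lncRNA", "unknown")
  if (!setequal(names(class_proportions), classes))
    stop("class_proportions must name exactly: ", paste(classes, collapse = ", "))
  class_proportions <- class_proportions[classes]
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (any(class_proportions < 0 | class_proportions > 1))
    stop("class_proportions must lie in [0, 1]")
  stopifnot(inherits(design, "design_descriptor"),
            length(library_size_range) == 2L,
            all(library_size_range > 0),
            baseline_logmean_sd > 0, dispersion_phi0 > 0, dispersion_a >= 0,
            block_effect_sd >= 0,
            boundary_margin > 0, boundary_margin < 0.5)
  if (is.null(planted_effects))
    planted_effects <- default_planted_effects(design, n_genes)
  for (e in planted_effects) {
    stopifnot(inherits(e, "effect_spec"))
    if (!all(e$types %in% design$conditioning_types))
      stop("effect_spec names a conditioning type absent from the design")
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 multi_transcript_fraction = multi_transcript_fraction,
                 class_proportions = class_proportions, design = design,
                 library_size_range = library_size_range,
                 baseline_logmean_sd = baseline_logmean_sd,
                 dispersion_phi0 = dispersion_phi0,
                 dispersion_a = dispersion_a,
                 block_effect_sd = block_effect_sd,
                 planted_effects = planted_effects,
                 boundary_margin = boundary_margin,
                 n_decoys = as.integer(n_decoys)),
            class = "sim_config")
}
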