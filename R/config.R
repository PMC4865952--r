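#' Variant-level quality-control and rarity filter settings
#'
#' Holds the thresholds applied by [qc_filter()], [consequence_filter()],
#' [frequency_filter()] and [case_control_filter()].  The defaults are the
#' published exome-filtering criteria for recessive-disease discovery in a
#' consanguineous family: consensus quality >= 20, per-sample depth between
#' 4 and 500, annotated copy number <= 2, adjacent SNPs at least 5 bp apart,
#' and a population-frequency ceiling of 0.5% (variants *above* 0.5% are
#' removed; novel variants are always retained).
#'
#' @param min_quality Minimum per-sample consensus quality (phred-like).
#' @param min_depth,max_depth Per-sample read-depth window.
#' @param max_copy_number Maximum annotated copy number at the site; sites
#'   without a copy-number annotation always pass this gate.
#' @param min_adjacent_distance_bp Minimum distance between two retained
#'   SNPs on the same chromosome; both members of a closer pair are removed.
#'   Indels are exempt.
#' @param max_pop_freq Population-frequency ceiling (exclusive: a variant at
#'   exactly this frequency is kept).
#' @param retained_consequences Consequence classes kept by
#'   [consequence_filter()].
#' @param strict_absence If `TRUE`, [case_control_filter()] requires controls
#'   to carry no copy of the alternate allele; the default only forbids a
#'   homozygous alternate genotype in controls, so heterozygous carrier
#'   parents are allowed (the segregation pattern expected under autosomal
#'   recessive inheritance).
#'
#' @return A list of class `hbd_filter_config`.
#' @seealso [window_config()], [ibd_config()], [pipeline_config()]
#' @export
#' @examples
#' cfg <- filter_config()
#' cfg$max_pop_freq
filter_config <- function(min_quality = 20,
                          min_depth = 4,
                          max_depth = 500,
                          max_copy_number = 2,
                          min_adjacent_distance_bp = 5,
                          max_pop_freq = 0.005,
                          retained_consequences = c("nonsynonymous",
                                                    "frameshift",
                                                    "splice_acceptor",
                                                    "splice_donor"),
                          strict_absence = FALSE) {
  cfg <- list(min_quality = min_quality, min_depth = min_depth,
              max_depth = max_depth, max_copy_number = max_copy_number,
              min_adjacent_distance_bp = min_adjacent_distance_bp,
              max_pop_freq = max_pop_freq,
              retained_consequences = retained_consequences,
              strict_absence = isTRUE(strict_absence))
  class(cfg) <- c("hbd_filter_config", "list")
  problems <- validate_filter_config(cfg)
  if (length(problems)) abort(paste(problems, collapse = "; "))
  cfg
}

#' Sliding-window homozygosity-mapping settings
#'
#' Parameters for zygosity classification from allele-read fractions and for
#' the windowed detection of per-sample homozygous stretches.  Defaults are
#' the published mapping rules: autosomal SNPs with >= 20x coverage are
#' markers; a site is a homozygous marker when one allele holds >= 95% of
#' reads at >= 5x, heterozygous at 30-70% alternate reads and >= 10x, and
#' ambiguous otherwise; qualified windows hold 500 consecutive markers with
#' at most two heterozygous calls and no inter-marker gap above 500 kb, and
#' coalesced windows must span at least 1 Mb to be reported.
#'
#' @param marker_selection_min_depth Coverage below which a site is
#'   `unclassified` for that sample (marker-selection gate).
#' @param hom_major_fraction Major-allele read fraction at or above which a
#'   site is homozygous.
#' @param hom_min_depth Minimum depth for a homozygous call.
#' @param het_low,het_high Alternate-read fraction band for heterozygous
#'   calls (inclusive).
#' @param het_min_depth Minimum depth for a heterozygous call.
#' @param window_size Markers per window.
#' @param max_het_per_window Maximum heterozygous markers tolerated per
#'   window.
#' @param max_gap_bp Maximum distance between adjacent markers inside a
#'   window.
#' @param min_stretch_bp Minimum span of a reported homozygous stretch; also
#'   the floor re-applied to case-shared and control-excluded HBD fragments.
#' @param apply_marker_depth_gate If `FALSE`, only the per-class 5x/10x
#'   depth gates are applied and the 20x selection gate is skipped
#'   (an alternative reading of the marker-selection rule).
#'
#' @return A list of class `hbd_window_config`.
#' @export
window_config <- function(marker_selection_min_depth = 20,
                          hom_major_fraction = 0.95,
                          hom_min_depth = 5,
                          het_low = 0.30,
                          het_high = 0.70,
                          het_min_depth = 10,
                          window_size = 500,
                          max_het_per_window = 2,
                          max_gap_bp = 500000,
                          min_stretch_bp = 1000000,
                          apply_marker_depth_gate = TRUE) {
  cfg <- list(marker_selection_min_depth = marker_selection_min_depth,
              hom_major_fraction = hom_major_fraction,
              hom_min_depth = hom_min_depth,
              het_low = het_low, het_high = het_high,
              het_min_depth = het_min_depth,
              window_size = as.integer(window_size),
              max_het_per_window = as.integer(max_het_per_window),
              max_gap_bp = max_gap_bp, min_stretch_bp = min_stretch_bp,
              apply_marker_depth_gate = isTRUE(apply_marker_depth_gate))
  class(cfg) <- c("hbd_window_config", "list")
  problems <- validate_window_config(cfg)
  if (length(problems)) abort(paste(problems, collapse = "; "))
  cfg
}

#' Run-based IBD segment settings
#'
#' The run rule for identity-by-descent segments: a maximal run of at least
#' `min_run_snps` consecutive homozygous SNPs (no intervening heterozygote)
#' spanning at least `min_run_bp`.
#'
#' @param min_run_snps Minimum number of consecutive homozygous markers.
#' @param min_run_bp Minimum genomic span of the run in bp.
#' @return A list of class `hbd_ibd_config`.
#' @export
ibd_config <- function(min_run_snps = 50, min_run_bp = 1000000) {
  cfg <- list(min_run_snps = as.integer(min_run_snps),
              min_run_bp = min_run_bp)
  class(cfg) <- c("hbd_ibd_config", "list")
  problems <- validate_ibd_config(cfg)
  if (length(problems)) abort(paste(problems, collapse = "; "))
  cfg
}

#' Synthetic consanguineous-pedigree simulation settings
#'
#' Controls the gene-drop simulator: pedigree template, genome layout,
#' marker density, recombination rate, the planted causal recessive variant,
#' and the read-level noise model.  The defaults emulate an exome study of a
#' double-first-cousin-marriage family: 20 autosomes of 50 Mb, 2,000 markers
#' per chromosome with uniform(0.05, 0.5) allele frequencies, a uniform
#' 1 cM/Mb genetic map, mean sequencing depth 80x and a 1% base error rate.
#'
#' @param pedigree_template One of `"first_cousin_single"`,
#'   `"first_cousin_double"` or `"custom"` (see [build_pedigree()]).
#' @param n_chromosomes,chrom_length_bp Genome layout.
#' @param n_markers_per_chrom Markers simulated per chromosome.
#' @param maf_range Range of the uniform minor-allele-frequency draw.
#' @param recomb_rate Expected crossovers per Mb per meiosis (0.01 = 1
#'   cM/Mb).
#' @param causal_chrom,causal_pos Location of the planted causal variant.
#' @param mean_depth Mean of the Poisson per-site read depth.
#' @param base_error Per-read error rate; alternate-read counts are binomial
#'   with success probability `base_error` (hom-ref), 0.5 (het) or
#'   `1 - base_error` (hom-alt).
#' @param quality Constant per-sample consensus quality attached to
#'   simulated calls.
#' @param consequence_probs Named probabilities used to draw consequence
#'   annotations for non-causal sites.
#' @param seed Integer seed; all randomness in a simulation flows from it.
#' @return A list of class `hbd_sim_config`.
#' @export
sim_config <- function(pedigree_template = "first_cousin_double",
                       n_chromosomes = 20,
                       chrom_length_bp = 50e6,
                       n_markers_per_chrom = 2000,
                       maf_range = c(0.05, 0.5),
                       recomb_rate = 0.01,
                       causal_chrom = "chr1",
                       causal_pos = 25e6,
                       mean_depth = 80,
                       base_error = 0.01,
                       quality = 60,
                       consequence_probs = c(noncoding = 0.50,
                                             synonymous = 0.25,
                                             nonsynonymous = 0.20,
                                             splice_acceptor = 0.01,
                                             splice_donor = 0.01,
                                             frameshift = 0.0,
                                             other = 0.03),
                       seed = 1L) {
  cfg <- list(pedigree_template = pedigree_template,
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp,
              n_markers_per_chrom = as.integer(n_markers_per_chrom),
              maf_range = maf_range, recomb_rate = recomb_rate,
              causal_chrom = causal_chrom, causal_pos = causal_pos,
              mean_depth = mean_depth, base_error = base_error,
              quality = quality, consequence_probs = consequence_probs,
              seed = as.integer(seed))
  class(cfg) <- c("hbd_sim_config", "list")
  problems <- validate_sim_config(cfg)
  if (length(problems)) abort(paste(problems, collapse = "; "))
  cfg
}

#' Whole-pipeline configuration
#'
#' Aggregates the filter, window-mapping, IBD-run and simulation settings
#' together with the stage toggles of [run_pipeline()].  The defaults equal
#' the published thresholds throughout; print the object to see every
#' effective value.
#'
#' @param filter A [filter_config()].
#' @param window A [window_config()].
#' @param ibd An [ibd_config()].
#' @param sim A [sim_config()] (used only when the pipeline simulates its
#'   input).
#' @param use_window_stretches,use_ibd_runs Which homozygosity detector(s)
#'   feed the HBD stage.  When both are on, each sample's stretch set is the
#'   union of the windowed stretches and the IBD runs.
#' @param control_exclusion Either `"subtract"` (remove the overlapping
#'   portion and re-apply the minimum-length floor) or `"drop"` (discard a
#'   case-shared region on any control overlap).
#' @param seed Integer seed for simulation-driven runs.
#' @return A list of class `hbd_pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' validate_config(cfg)
pipeline_config <- function(filter = filter_config(),
                            window = window_config(),
                            ibd = ibd_config(),
                            sim = sim_config(),
                            use_window_stretches = TRUE,
                            use_ibd_runs = TRUE,
                            control_exclusion = c("subtract", "drop"),
                            seed = 1L) {
  control_exclusion <- match.arg(control_exclusion)
  cfg <- list(filter = filter, window = window, ibd = ibd, sim = sim,
              use_window_stretches = isTRUE(use_window_stretches),
              use_ibd_runs = isTRUE(use_ibd_runs),
              control_exclusion = control_exclusion,
              seed = as.integer(seed))
  class(cfg) <- c("hbd_pipeline_config", "list")
  problems <- validate_config(cfg)
  if (length(problems)) abort(paste(problems, collapse = "; "))
  cfg
}

validate_filter_config <- function(cfg) {
  p <- character()
  if (cfg$min_depth > cfg$max_depth) p <- c(p, "min_depth exceeds max_depth")
  if (cfg$max_pop_freq < 0 || cfg$max_pop_freq > 1)
    p <- c(p, "max_pop_freq must lie in [0, 1]")
  if (cfg$min_quality < 0) p <- c(p, "min_quality must be >= 0")
  if (cfg$min_adjacent_distance_bp < 0)
    p <- c(p, "min_adjacent_distance_bp must be >= 0")
  bad <- setdiff(cfg$retained_consequences, .consequence_levels)
  if (length(bad))
    p <- c(p, paste("unknown consequence class:", paste(bad, collapse = ", ")))
  p
}

validate_window_config <- function(cfg) {
  p <- character()
  if (!(cfg$het_low > 0 && cfg$het_low < cfg$het_high &&
        cfg$het_high < cfg$hom_major_fraction &&
        cfg$hom_major_fraction <= 1))
    p <- c(p, "need 0 < het_low < het_high < hom_major_fraction <= 1")
  if (cfg$window_size < 1) p <- c(p, "window_size must be >= 1")
  if (cfg$max_het_per_window < 0) p <- c(p, "max_het_per_window must be >= 0")
  if (cfg$max_gap_bp <= 0) p <- c(p, "max_gap_bp must be positive")
  if (cfg$min_stretch_bp < 0) p <- c(p, "min_stretch_bp must be >= 0")
  if (cfg$hom_min_depth < 0 || cfg$het_min_depth < 0 ||
      cfg$marker_selection_min_depth < 0)
    p <- c(p, "depth gates must be >= 0")
  p
}

validate_ibd_config <- function(cfg) {
  p <- character()
  if (cfg$min_run_snps < 1) p <- c(p, "min_run_snps must be >= 1")
  if (cfg$min_run_bp < 1) p <- c(p, "min_run_bp must be >= 1")
  p
}

validate_sim_config <- function(cfg) {
  p <- character()
  if (cfg$n_chromosomes < 1) p <- c(p, "n_chromosomes must be >= 1")
  if (cfg$chrom_length_bp <= 0) p <- c(p, "chrom_length_bp must be positive")
  if (cfg$n_markers_per_chrom < 1)
    p <- c(p, "n_markers_per_chrom must be >= 1")
  if (cfg$recomb_rate < 0) p <- c(p, "recomb_rate must be >= 0")
  if (cfg$causal_pos < 1 || cfg$causal_pos > cfg$chrom_length_bp)
    p <- c(p, "causal_pos must lie within chrom_length_bp")
  if (cfg$base_error < 0 || cfg$base_error > 0.5)
    p <- c(p, "base_error must lie in [0, 0.5]")
  if (cfg$mean_depth <= 0) p <- c(p, "mean_depth must be positive")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    p <- c(p, "maf_range must be increasing within (0, 0.5]")
  p
}

#' Validate a pipeline configuration
#'
#' Checks the invariants of every sub-configuration and returns the problems
#' found as a character vector; an empty vector means the configuration is
#' valid.  Problems are returned, not thrown.
#'
#' @param config A [pipeline_config()] (or a bare list with the same
#'   fields).
#' @return Character vector of problem descriptions (length 0 when valid).
#' @export
validate_config <- function(config) {
  p <- character()
  p <- c(p, validate_filter_config(config$filter),
         validate_window_config(config$window),
         validate_ibd_config(config$ibd),
         validate_sim_config(config$sim))
  if (!config$use_window_stretches && !config$use_ibd_runs)
    p <- c(p, "at least one of use_window_stretches / use_ibd_runs required")
  p
}

#' @export
print.hbd_pipeline_config <- function(x, ...) {
  cat("<hbd_pipeline_config>\n")
  flat <- function(v) paste(unlist(v), collapse = ", ")
  for (block in c("filter", "window", "ibd", "sim")) {
    cat(" ", block, ":\n", sep = "")
    for (nm in names(x[[block]])) {
      cat("    ", nm, " = ", flat(x[[block]][[nm]]), "\n", sep = "")
    }
  }
  cat("  use_window_stretches = ", x$use_window_stretches,
      ", use_ibd_runs = ", x$use_ibd_runs, "\n", sep = "")
  cat("  control_exclusion = ", x$control_exclusion,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
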