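# End-to-end orchestration: variant funnel -> marker map -> per-sample
# homozygous stretches (windowed and/or run-based) -> case-shared HBD ->
# control exclusion -> candidate prioritization, with a machine-readable
# run report of every stage count.

#' Run the full autozygosity-mapping pipeline
#'
#' Executes the variant funnel (quality control, consequence, population
#' frequency, case/control sharing), builds the marker map, detects each
#' genotyped sample's homozygous stretches with the windowed detector
#' and/or the run-based IBD rule (union when both are enabled), intersects
#' the cases' stretches into case-shared HBD regions, removes control
#' overlap, and prioritizes the variants that fall in the remaining regions
#' and segregate recessively.
#'
#' When `calls` is `NULL` the input is simulated with [simulate_family()]
#' from `config$sim` (seeded by `config$seed`), and the returned object
#' carries the simulation ground truth so recovery can be assessed.
#'
#' @param calls Variant tibble, or `NULL` to simulate.
#' @param pedigree Pedigree tibble (ignored when simulating).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the per-sample stretches
#'   and HBD regions (BED), the candidate table (TSV) and the run report
#'   (JSON) are written there.
#' @return An object of class `hbd_run`; see [tidy.hbd_run()],
#'   [glance.hbd_run()], [autoplot.hbd_run()].
#' @export
#' @examples
#' cfg <- pipeline_config(sim = sim_config(n_chromosomes = 4,
#'                                         n_markers_per_chrom = 400,
#'                                         causal_pos = 25e6, seed = 3))
#' run <- run_pipeline(config = cfg)
#' glance(run)
run_pipeline <- function(calls = NULL, pedigree = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  problems <- validate_config(config)
  if (length(problems)) {
    abort(paste0("invalid configuration: ",
                 paste(problems, collapse = "; ")))
  }
  sim <- NULL
  if (is.null(calls)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    sim <- simulate_family(sim_cfg)
    calls <- sim$calls
    pedigree <- sim$pedigree
  }
  if (is.null(pedigree)) abort("a pedigree is required")
  validate_pedigree(pedigree)
  if (!any(pedigree$role == "case")) {
    abort("configuration error: pedigree contains no case individuals")
  }
  assert_variant_table(calls)

  n_sites <- function(x) nrow(distinct(x, .data$chrom, .data$pos,
                                       .data$ref, .data$alt))
  stage <- function(name, f, input) {
    out <- f(input)
    list(name = name, n_in = n_sites(input), n_out = n_sites(out),
         calls = out)
  }

  s1 <- stage("qc", function(x) qc_filter(x, config$filter, pedigree),
              calls)
  s2 <- stage("consequence",
              function(x) consequence_filter(x, config$filter), s1$calls)
  s3 <- stage("frequency",
              function(x) frequency_filter(x, config$filter), s2$calls)
  s4 <- stage("case_control",
              function(x) case_control_filter(x, pedigree, config$filter,
                                              config$window), s3$calls)
  funnel <- bind_rows(lapply(list(s1, s2, s3, s4), function(s) {
    tibble(stage = s$name, n_in = s$n_in, n_out = s$n_out)
  }))
  if (any(funnel$n_out > funnel$n_in)) {
    abort("internal error: variant funnel is not monotone")
  }

  markers <- build_marker_map(calls, pedigree, config$window)
  genotyped <- pedigree$id[pedigree$role %in% c("case", "control")]
  stretches <- bind_rows(lapply(genotyped, function(s) {
    m <- sample_markers(markers, s)
    pieces <- list()
    if (config$use_window_stretches) {
      pieces$win <- homozygous_stretches(m, config = config$window)
    }
    if (config$use_ibd_runs) {
      pieces$run <- roh_runs(m, config$ibd)
    }
    per_sample <- if (length(pieces) > 1) {
      union_regions(bind_rows(pieces))
    } else {
      pieces[[1]] |> select(all_of(c("chrom", "start", "end")))
    }
    out <- finish_region_table(per_sample, sample_id = s)
    out$sample_id <- s
    out$provenance <- "per_sample_stretch"
    out
  }))

  cases <- pedigree$id[pedigree$role == "case"]
  controls <- pedigree$id[pedigree$role == "control"]
  hbd_shared <- case_shared_hbd(stretches, case_ids = cases,
                                config = config$window)
  ctrl_stretches <- stretches[stretches$sample_id %in% controls, ,
                              drop = FALSE]
  hbd_final <- exclude_control_overlap(hbd_shared, ctrl_stretches,
                                       config = config$window,
                                       mode = config$control_exclusion)
  candidates <- prioritize(s4$calls, hbd_final, pedigree, config$window)

  run <- structure(list(
    candidates = candidates,
    hbd_shared = hbd_shared,
    hbd_regions = hbd_final,
    stretches = stretches,
    markers = markers,
    funnel = funnel,
    n_markers = nrow(distinct(markers, .data$chrom, .data$pos)),
    pedigree = pedigree,
    config = config,
    seed = config$seed,
    version = as.character(packageVersion("hbdscan")),
    truth = if (!is.null(sim)) sim$truth else NULL),
    class = "hbd_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_regions_bed(run$stretches, file.path(out_dir, "stretches.bed"))
    write_regions_bed(bind_rows(run$hbd_shared, run$hbd_regions),
                      file.path(out_dir, "hbd.bed"))
    write_candidates_tsv(run$candidates,
                         file.path(out_dir, "candidates.tsv"))
    write_run_report(run, file.path(out_dir, "report.json"))
  }
  run
}

run_report_list <- function(run) {
  per_case <- run$stretches |>
    group_by(.data$sample_id) |>
    summarise(n_regions = dplyr::n(),
              total_bp = sum(.data$end - .data$start + 1),
              .groups = "drop")
  list(
    version = run$version,
    seed = run$seed,
    n_markers = run$n_markers,
    funnel = as.data.frame(run$funnel),
    per_sample_stretches = as.data.frame(per_case),
    n_case_shared_hbd = nrow(run$hbd_shared),
    n_hbd_control_excluded = nrow(run$hbd_regions),
    n_candidates = nrow(run$candidates),
    config = unclass_config(run$config))
}

unclass_config <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(cfg)
}

#' Write a run report as JSON
#'
#' The report holds the software version, seed, every stage's input/output
#' site counts (the discovery funnel), per-sample stretch totals, HBD and
#' candidate counts, and the full effective configuration.  It contains no
#' timestamps, so identical runs serialize byte-identically.
#'
#' @param run An `hbd_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  jsonlite::write_json(run_report_list(run), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run report written by [write_run_report()]
#'
#' @param path Path to the JSON report.
#' @return A list mirroring the report structure.
#' @export
read_run_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @export
print.hbd_run <- function(x, ...) {
  cat("<hbd_run> seed", x$seed, "\n")
  cat("  markers:", x$n_markers, "\n")
  f <- x$funnel
  cat("  variant funnel:",
      paste(sprintf("%s %d->%d", f$stage, f$n_in, f$n_out),
            collapse = ", "), "\n")
  cat("  case-shared HBD regions:", nrow(x$hbd_shared),
      "| after control exclusion:", nrow(x$hbd_regions), "\n")
  cat("  candidates:", nrow(x$candidates), "\n")
  invisible(x)
}

#' Tidy the candidate table of a pipeline run
#'
#' @param x An `hbd_run`.
#' @param ... Unused.
#' @return The candidate tibble (one row per prioritized variant).
#' @export
tidy.hbd_run <- function(x, ...) {
  x$candidates
}

#' One-row summary of a pipeline run
#'
#' @param x An `hbd_run`.
#' @param ... Unused.
#' @return A one-row tibble with marker, funnel, HBD and candidate counts,
#'   and — for simulated runs — whether the planted causal variant is
#'   among the candidates.
#' @export
glance.hbd_run <- function(x, ...) {
  causal_recovered <- NA
  if (!is.null(x$truth)) {
    causal <- x$truth$causal
    causal_recovered <- any(x$candidates$chrom == causal$chrom &
                              x$candidates$pos == causal$pos)
  }
  tibble(
    n_markers = x$n_markers,
    n_input_sites = x$funnel$n_in[1],
    n_filtered_sites = tail(x$funnel$n_out, 1),
    n_case_shared_hbd = nrow(x$hbd_shared),
    n_hbd_regions = nrow(x$hbd_regions),
    n_candidates = nrow(x$candidates),
    causal_recovered = causal_recovered,
    seed = x$seed)
}
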