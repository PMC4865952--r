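# Run-based IBD segments and the interval algebra that turns per-sample
# homozygous stretches into case-shared, control-excluded HBD regions.
# Interval set operations are delegated to IRanges per chromosome.

regions_to_iranges <- function(regions) {
  IRanges::IRanges(start = regions$start, end = regions$end)
}

iranges_to_regions <- function(ir, chrom) {
  if (!length(ir)) return(empty_region_table())
  tibble(chrom = chrom, start = IRanges::start(ir), end = IRanges::end(ir))
}

per_chrom_op <- function(a, b, op) {
  chroms <- union(unique(a$chrom), unique(b$chrom))
  out <- purrr::map(sort(chroms), function(ch) {
    ia <- regions_to_iranges(a[a$chrom == ch, , drop = FALSE])
    ib <- regions_to_iranges(b[b$chrom == ch, , drop = FALSE])
    iranges_to_regions(op(ia, ib), ch)
  })
  finish_region_table(bind_rows(out))
}

#' Detect run-based IBD segments for one sample
#'
#' Finds maximal runs of consecutive homozygous markers (no intervening
#' heterozygote) and keeps runs with at least `min_run_snps` markers
#' spanning at least `min_run_bp` — the run rule for homozygous
#' identity-by-descent segments (50 consecutive homozygous SNPs over at
#' least 1 Mb by default).
#'
#' @param markers Single-sample marker tibble (`chrom`, `pos`, `zygosity`
#'   in homozygous/heterozygous classes); ambiguous and unclassified sites
#'   must already be removed (see [sample_markers()]).
#' @param config An [ibd_config()].
#' @return Region tibble with provenance `ibd_run`.
#' @export
#' @examples
#' m <- tibble::tibble(chrom = "chr1", pos = seq(1, by = 30000, length = 60),
#'                     zygosity = "hom_ref")
#' roh_runs(m)
roh_runs <- function(markers, config = ibd_config()) {
  one_chrom <- function(m) {
    hom <- m$zygosity %in% c("hom_ref", "hom_alt")
    if (!any(hom)) return(empty_region_table())
    r <- rle(hom)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= config$min_run_snps
    if (!any(keep)) return(empty_region_table())
    out <- tibble(chrom = m$chrom[1],
                  start = m$pos[starts[keep]],
                  end = m$pos[ends[keep]],
                  n_markers = r$lengths[keep])
    out[region_length(out) >= config$min_run_bp, , drop = FALSE]
  }
  markers <- markers |>
    filter(.data$zygosity %in% c("hom_ref", "hom_alt", "het")) |>
    arrange(.data$chrom, .data$pos)
  out <- markers |> split(~chrom) |> purrr::map(one_chrom) |> bind_rows()
  finish_region_table(out, provenance = "ibd_run")
}

#' Intersect two region lists
#'
#' Standard per-chromosome interval intersection of two sorted,
#' non-overlapping region lists (1-based inclusive coordinates).
#'
#' @param a,b Region tibbles, each sorted and non-overlapping within
#'   chromosome.
#' @return Region tibble of the intersection.
#' @export
intersect_regions <- function(a, b) {
  assert_disjoint_sorted(a, "a")
  assert_disjoint_sorted(b, "b")
  per_chrom_op(a, b, IRanges::intersect)
}

#' Union of a region list
#'
#' Merges overlapping or book-ended intervals per chromosome.
#'
#' @param regions Region tibble.
#' @return Sorted, non-overlapping region tibble.
#' @export
union_regions <- function(regions) {
  assert_region_table(regions)
  out <- purrr::map(sort(unique(regions$chrom)), function(ch) {
    ir <- IRanges::reduce(
      regions_to_iranges(regions[regions$chrom == ch, , drop = FALSE]))
    iranges_to_regions(ir, ch)
  })
  finish_region_table(bind_rows(out))
}

#' Subtract one region list from another
#'
#' Removes from `a` every base covered by `b` (per-chromosome interval
#' difference).
#'
#' @param a,b Region tibbles; `a` sorted and non-overlapping.
#' @return Region tibble of the remainder.
#' @export
subtract_regions <- function(a, b) {
  assert_disjoint_sorted(a, "a")
  assert_region_table(b, "b")
  per_chrom_op(a, b, IRanges::setdiff)
}

#' Case-shared HBD regions
#'
#' Intersects the homozygous stretches of every case (n-way interval
#' intersection) and discards fragments shorter than `min_stretch_bp`: the
#' causal variant of a recessive disease in a consanguineous family must
#' lie in a homozygous-by-descent region shared by all affected
#' individuals.
#'
#' @param stretches Either a region tibble with a `sample_id` column
#'   covering every case, or a named list of per-case region tibbles.
#' @param case_ids Character vector of case sample ids (defaults to the
#'   samples present in `stretches`).
#' @param config A [window_config()] supplying `min_stretch_bp`.
#' @return Region tibble with provenance `case_shared_hbd`.
#' @export
case_shared_hbd <- function(stretches, case_ids = NULL,
                            config = window_config()) {
  per_case <- if (is.data.frame(stretches)) {
    ids <- case_ids %||% sort(unique(stretches$sample_id))
    setNames(lapply(ids, function(s)
      stretches[!is.na(stretches$sample_id) & stretches$sample_id == s, ,
                drop = FALSE]), ids)
  } else {
    if (!is.null(case_ids)) stretches[case_ids] else stretches
  }
  if (!length(per_case)) abort("case_shared_hbd requires at least one case")
  shared <- purrr::reduce(lapply(per_case, union_regions), intersect_regions)
  shared <- shared[region_length(shared) >= config$min_stretch_bp, ,
                   drop = FALSE]
  out <- finish_region_table(shared)
  out$provenance <- "case_shared_hbd"
  out$n_markers <- NA_integer_
  out
}

#' Exclude control overlap from case-shared HBD regions
#'
#' Removes, from each case-shared HBD region, every interval covered by any
#' control's homozygous stretches ("no overlap with the controls");
#' remaining fragments shorter than `min_stretch_bp` are discarded.  With
#' `mode = "drop"` a case-shared region overlapping any control stretch is
#' discarded entirely instead of being trimmed.
#'
#' @param hbd_regions Case-shared HBD region tibble.
#' @param control_stretches Region tibble (any provenance) pooling the
#'   controls' homozygous stretches, or a list of per-control tibbles.
#' @param config A [window_config()] supplying `min_stretch_bp`.
#' @param mode `"subtract"` (default) or `"drop"`.
#' @return Region tibble with provenance `hbd_control_excluded`.
#' @export
exclude_control_overlap <- function(hbd_regions, control_stretches,
                                    config = window_config(),
                                    mode = c("subtract", "drop")) {
  mode <- match.arg(mode)
  if (is.list(control_stretches) && !is.data.frame(control_stretches)) {
    control_stretches <- bind_rows(control_stretches)
  }
  hbd_regions <- finish_region_table(hbd_regions)
  if (!nrow(hbd_regions)) {
    return(finish_region_table(hbd_regions,
                               provenance = "hbd_control_excluded"))
  }
  if (is.null(control_stretches) || !nrow(control_stretches)) {
    out <- hbd_regions
    out$provenance <- "hbd_control_excluded"
    return(finish_region_table(out))
  }
  ctrl <- union_regions(control_stretches)
  if (mode == "drop") {
    hits <- intersect_regions(
      hbd_regions |> select(all_of(c("chrom", "start", "end"))), ctrl)
    keep <- rep(TRUE, nrow(hbd_regions))
    if (nrow(hits)) {
      for (i in seq_len(nrow(hbd_regions))) {
        h <- hits[hits$chrom == hbd_regions$chrom[i] &
                    hits$start <= hbd_regions$end[i] &
                    hits$end >= hbd_regions$start[i], , drop = FALSE]
        keep[i] <- nrow(h) == 0
      }
    }
    out <- hbd_regions[keep, , drop = FALSE]
  } else {
    out <- subtract_regions(
      hbd_regions |> select(all_of(c("chrom", "start", "end"))), ctrl)
  }
  out <- out[region_length(out) >= config$min_stretch_bp, , drop = FALSE]
  out$provenance <- "hbd_control_excluded"
  finish_region_table(out)
}
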