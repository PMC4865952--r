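# Sliding-window detection of per-sample homozygous stretches: qualified
# 500-marker windows are coalesced and unions shorter than 1 Mb discarded.

#' Scan one chromosome for qualified windows
#'
#' Slides a window of exactly `window_size` consecutive markers (step 1)
#' along a single sample's marker sequence on a single chromosome and emits
#' every window containing at most `max_het_per_window` heterozygous markers
#' and no adjacent-marker gap above `max_gap_bp`.  Chromosomes with fewer
#' than `window_size` markers emit nothing.
#'
#' @param markers Single-sample, single-chromosome marker tibble (`pos`,
#'   `zygosity` restricted to homozygous/heterozygous classes), position
#'   sorted.
#' @param config A [window_config()].
#' @return Tibble of marker-index ranges (`start_idx`, `end_idx`).
#' @export
scan_windows <- function(markers, config = window_config()) {
  if ("chrom" %in% names(markers) && length(unique(markers$chrom)) > 1) {
    abort("scan_windows expects markers from a single chromosome")
  }
  if (is.unsorted(markers$pos, strictly = FALSE)) {
    abort("markers must be position sorted")
  }
  n <- nrow(markers)
  w <- config$window_size
  if (n < w) return(tibble(start_idx = integer(), end_idx = integer()))
  het <- markers$zygosity == "het"
  ch <- c(0L, cumsum(het))
  het_count <- ch[(w + 1):(n + 1)] - ch[1:(n - w + 1)]
  if (n > 1) {
    big_gap <- diff(markers$pos) > config$max_gap_bp
    cg <- c(0L, cumsum(big_gap))
    # window starting at i spans gaps i .. i+w-2
    gap_count <- cg[(w):(n)] - cg[1:(n - w + 1)]
  } else {
    gap_count <- 0L
  }
  ok <- het_count <= config$max_het_per_window & gap_count == 0L
  tibble(start_idx = which(ok), end_idx = which(ok) + w - 1L)
}

#' Coalesce qualified windows into homozygous stretches
#'
#' Unions overlapping or adjacent qualified windows over their marker-index
#' ranges, maps every union to the genomic interval from its first to its
#' last marker, and discards unions spanning less than `min_stretch_bp`
#' (1 Mb by default).
#'
#' @param windows Window index ranges from [scan_windows()].
#' @param markers The marker tibble the indices refer to.
#' @param config A [window_config()].
#' @return Region tibble with provenance `per_sample_stretch`, sorted and
#'   non-overlapping.
#' @export
coalesce_windows <- function(windows, markers, config = window_config()) {
  if (!nrow(windows)) return(empty_region_table())
  windows <- windows |> arrange(.data$start_idx)
  merged_start <- integer()
  merged_end <- integer()
  cur_s <- windows$start_idx[1]
  cur_e <- windows$end_idx[1]
  for (i in seq_len(nrow(windows))[-1]) {
    if (windows$start_idx[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, windows$end_idx[i])
    } else {
      merged_start <- c(merged_start, cur_s)
      merged_end <- c(merged_end, cur_e)
      cur_s <- windows$start_idx[i]
      cur_e <- windows$end_idx[i]
    }
  }
  merged_start <- c(merged_start, cur_s)
  merged_end <- c(merged_end, cur_e)
  chrom <- if ("chrom" %in% names(markers)) markers$chrom[1] else NA_character_
  out <- tibble(
    chrom = chrom,
    start = markers$pos[merged_start],
    end = markers$pos[merged_end],
    n_markers = merged_end - merged_start + 1L)
  out <- out[region_length(out) >= config$min_stretch_bp, , drop = FALSE]
  finish_region_table(out, provenance = "per_sample_stretch")
}

#' Detect one sample's homozygous stretches genome-wide
#'
#' Convenience composition of [scan_windows()] and [coalesce_windows()] per
#' chromosome for one sample.
#'
#' @param markers Marker map from [build_marker_map()], or an
#'   already-extracted single-sample tibble (see [sample_markers()]) when
#'   `sample_id` is `NULL`.
#' @param sample_id Sample to analyse (ignored when `markers` has no
#'   `sample_id` column).
#' @param config A [window_config()].
#' @return Region tibble with provenance `per_sample_stretch`.
#' @export
homozygous_stretches <- function(markers, sample_id = NULL,
                                 config = window_config()) {
  seq_ <- if (!is.null(sample_id) && "sample_id" %in% names(markers)) {
    sample_markers(markers, sample_id)
  } else {
    markers |>
      filter(.data$zygosity %in% c("hom_ref", "hom_alt", "het")) |>
      arrange(.data$chrom, .data$pos)
  }
  out <- seq_ |>
    split(~chrom) |>
    purrr::map(function(m) {
      coalesce_windows(scan_windows(m, config), m, config)
    }) |>
    bind_rows()
  if (!nrow(out)) return(empty_region_table())
  finish_region_table(out |>
                        mutate(sample_id =
                                 sample_id %||% NA_character_),
                      provenance = "per_sample_stretch")
}

#' Brute-force homozygous-stretch oracle
#'
#' Exhaustively enumerates every window with an explicit per-window check,
#' marks the covered marker indices, converts maximal covered runs to
#' regions and applies the minimum-length floor.  Intended as an
#' independent oracle for [homozygous_stretches()] on small inputs.
#'
#' @param markers Single-sample marker tibble (`chrom`, `pos`, `zygosity`
#'   in homozygous/heterozygous classes); multiple chromosomes allowed.
#' @param config A [window_config()].
#' @return Region tibble with provenance `per_sample_stretch`.
#' @export
stretches_bruteforce <- function(markers, config = window_config()) {
  one_chrom <- function(m) {
    n <- nrow(m)
    w <- config$window_size
    covered <- rep(FALSE, n)
    if (n >= w) {
      for (i in seq_len(n - w + 1)) {
        idx <- i:(i + w - 1)
        if (sum(m$zygosity[idx] == "het") > config$max_het_per_window) next
        if (w > 1 && any(diff(m$pos[idx]) > config$max_gap_bp)) next
        covered[idx] <- TRUE
      }
    }
    if (!any(covered)) return(empty_region_table())
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    out <- tibble(chrom = m$chrom[1],
                  start = m$pos[starts[keep]],
                  end = m$pos[ends[keep]],
                  n_markers = ends[keep] - starts[keep] + 1L)
    out[region_length(out) >= config$min_stretch_bp, , drop = FALSE]
  }
  markers <- markers |>
    filter(.data$zygosity %in% c("hom_ref", "hom_alt", "het")) |>
    arrange(.data$chrom, .data$pos)
  out <- markers |> split(~chrom) |> purrr::map(one_chrom) |> bind_rows()
  finish_region_table(out, provenance = "per_sample_stretch")
}
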