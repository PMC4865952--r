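# Internal validators shared by the I/O, mapping and interval modules.

#' @noRd
assert_variant_table <- function(calls, arg = "calls") {
  needed <- c("chrom", "pos", "ref", "alt", "sample_id", "depth",
              "alt_reads", "quality")
  missing <- setdiff(needed, names(calls))
  if (length(missing)) {
    abort(sprintf("`%s` is missing columns: %s", arg,
                  paste(missing, collapse = ", ")))
  }
  bad <- which(calls$alt_reads > calls$depth)
  if (length(bad)) {
    abort(sprintf("`%s`: alt_reads exceeds depth in %d row(s) (first row %d)",
                  arg, length(bad), bad[1]))
  }
  if (any(calls$depth < 0, na.rm = TRUE) ||
      any(calls$quality < 0, na.rm = TRUE)) {
    abort(sprintf("`%s`: depth and quality must be non-negative", arg))
  }
  invisible(calls)
}

#' @noRd
assert_sorted_calls <- function(calls, arg = "calls") {
  key <- order(calls$chrom, calls$pos)
  site <- !duplicated(calls[c("chrom", "pos", "ref", "alt")])
  o <- order(calls$chrom[site], calls$pos[site])
  if (is.unsorted(o, strictly = FALSE) || any(o != seq_along(o))) {
    abort(sprintf("`%s` must be sorted by (chrom, pos)", arg))
  }
  invisible(key)
}

#' @noRd
assert_region_table <- function(regions, arg = "regions") {
  needed <- c("chrom", "start", "end")
  missing <- setdiff(needed, names(regions))
  if (length(missing)) {
    abort(sprintf("`%s` is missing columns: %s", arg,
                  paste(missing, collapse = ", ")))
  }
  if (any(regions$start > regions$end)) {
    abort(sprintf("`%s`: start must be <= end (1-based inclusive)", arg))
  }
  invisible(regions)
}

# Regions must be sorted and non-overlapping within chromosome before any
# set operation; mirrors the contract of the interval operations.
#' @noRd
assert_disjoint_sorted <- function(regions, arg = "regions") {
  assert_region_table(regions, arg)
  by_chr <- split(regions, regions$chrom)
  for (r in by_chr) {
    if (is.unsorted(r$start, strictly = FALSE)) {
      abort(sprintf("`%s` must be sorted by start within chromosome", arg))
    }
    if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)])) {
      abort(sprintf("`%s` must be non-overlapping within chromosome", arg))
    }
  }
  invisible(regions)
}

#' @noRd
empty_region_table <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         sample_id = character(), provenance = character(),
         n_markers = integer())
}

#' @noRd
finish_region_table <- function(regions, sample_id = NA_character_,
                                provenance = NA_character_) {
  if (!nrow(regions)) return(empty_region_table())
  if (!"sample_id" %in% names(regions)) regions$sample_id <- sample_id
  if (!"provenance" %in% names(regions)) regions$provenance <- provenance
  if (!"n_markers" %in% names(regions)) regions$n_markers <- NA_integer_
  regions |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end),
           n_markers = as.integer(.data$n_markers)) |>
    select(all_of(c("chrom", "start", "end", "sample_id", "provenance",
                    "n_markers"))) |>
    arrange(.data$chrom, .data$start, .data$end)
}

# Region length under the 1-based inclusive convention.
#' @noRd
region_length <- function(regions) regions$end - regions$start + 1L

#' @noRd
is_autosome <- function(chrom) {
  core <- sub("^chr", "", chrom, ignore.case = TRUE)
  !is.na(suppressWarnings(as.integer(core)))
}

#' @noRd
site_key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = "\r")
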