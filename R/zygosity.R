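# Marker selection and zygosity classification from allele-read fractions.

#' Classify zygosity from read counts
#'
#' Applies the read-fraction rules used for homozygosity mapping.  With
#' alternate-read fraction `f = alt_reads / depth`:
#'
#' * depth below the marker-selection gate (20x by default) gives
#'   `"unclassified"`;
#' * `f >= hom_major_fraction` gives `"hom_alt"` and
#'   `f <= 1 - hom_major_fraction` gives `"hom_ref"` (one allele holds at
#'   least 95% of reads), at `hom_min_depth` or more;
#' * `het_low <= f <= het_high` (30-70%) gives `"het"` at `het_min_depth`
#'   or more;
#' * anything else (e.g. 70-95% alternate reads) is `"ambiguous"`.
#'
#' Homozygous calls take precedence over heterozygous, which take precedence
#' over ambiguous; a site whose read fraction matches a class but whose
#' depth fails that class's gate is `"unclassified"`.
#'
#' @param depth,alt_reads Integer vectors of total and alternate read
#'   counts (`alt_reads <= depth`).
#' @param config A [window_config()].
#' @return Character vector of zygosity classes.
#' @export
#' @examples
#' classify_zygosity(c(30, 30, 30, 12), c(29, 15, 24, 12))
classify_zygosity <- function(depth, alt_reads, config = window_config()) {
  if (length(depth) != length(alt_reads)) {
    abort("depth and alt_reads must have equal length")
  }
  if (any(alt_reads > depth, na.rm = TRUE)) {
    abort("alt_reads exceeds depth")
  }
  if (any(depth < 0 | alt_reads < 0, na.rm = TRUE)) {
    abort("read counts must be non-negative")
  }
  f <- ifelse(depth > 0, alt_reads / depth, NA_real_)
  out <- rep("ambiguous", length(depth))
  is_hom_alt <- !is.na(f) & f >= config$hom_major_fraction
  is_hom_ref <- !is.na(f) & f <= 1 - config$hom_major_fraction
  is_het <- !is.na(f) & f >= config$het_low & f <= config$het_high
  out[is_het & depth >= config$het_min_depth] <- "het"
  out[is_het & depth < config$het_min_depth] <- "unclassified"
  hom_ok <- depth >= config$hom_min_depth
  out[is_hom_alt & hom_ok] <- "hom_alt"
  out[is_hom_ref & hom_ok] <- "hom_ref"
  out[(is_hom_alt | is_hom_ref) & !hom_ok] <- "unclassified"
  if (config$apply_marker_depth_gate) {
    out[depth < config$marker_selection_min_depth] <- "unclassified"
  }
  out[depth == 0] <- "unclassified"
  out
}

#' Build the per-sample marker map
#'
#' Selects autosomal SNP sites as markers and classifies each genotyped
#' sample's zygosity at every marker with [classify_zygosity()].  Indels and
#' sex-chromosome sites are excluded; positions are unique (the first allele
#' at a multi-allelic position is used).
#'
#' @param calls Variant tibble.
#' @param pedigree Optional pedigree; when given, only individuals with
#'   role `"case"` or `"control"` are classified.
#' @param config A [window_config()].
#' @return A long tibble `chrom`, `pos`, `sample_id`, `zygosity` sorted by
#'   `(chrom, pos)`.
#' @export
build_marker_map <- function(calls, pedigree = NULL,
                             config = window_config()) {
  assert_variant_table(calls)
  snps <- calls |>
    filter(.data$vclass == "snp", is_autosome(.data$chrom))
  if (!is.null(pedigree)) {
    genotyped <- pedigree$id[pedigree$role %in% c("case", "control")]
    snps <- snps |> filter(.data$sample_id %in% genotyped)
  }
  if (!nrow(snps)) {
    return(tibble(chrom = character(), pos = integer(),
                  sample_id = character(), zygosity = character()))
  }
  akey <- site_key(snps)
  pkey <- paste(snps$chrom, snps$pos)
  ua <- !duplicated(akey)
  keep_allele <- akey[ua][!duplicated(pkey[ua])]
  snps <- snps[akey %in% keep_allele, , drop = FALSE]
  snps |>
    mutate(zygosity = classify_zygosity(.data$depth, .data$alt_reads,
                                        config)) |>
    select(all_of(c("chrom", "pos", "sample_id", "zygosity"))) |>
    arrange(.data$chrom, .data$pos, .data$sample_id)
}

#' Extract one sample's usable marker sequence
#'
#' Filters a marker map to one sample and drops `ambiguous` and
#' `unclassified` sites, leaving the homozygous/heterozygous sequence the
#' window scan and run detection operate on.
#'
#' @param markers Marker map from [build_marker_map()].
#' @param sample_id Sample to extract.
#' @return Tibble `chrom`, `pos`, `zygosity` sorted by `(chrom, pos)`.
#' @export
sample_markers <- function(markers, sample_id) {
  markers |>
    filter(.data$sample_id == .env$sample_id,
           .data$zygosity %in% c("hom_ref", "hom_alt", "het")) |>
    select(all_of(c("chrom", "pos", "zygosity"))) |>
    arrange(.data$chrom, .data$pos)
}
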