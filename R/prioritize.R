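# Final funnel stage: restrict filtered variants to the HBD regions and
# keep those whose genotypes segregate under a strict autosomal recessive
# model (all cases homozygous-alternate, no control homozygous, obligate
# carrier parents heterozygous or missing).

#' Restrict variants to a set of regions
#'
#' Keeps variant calls whose position lies inside one of the given regions
#' (1-based inclusive ends on both sides).
#'
#' @param calls Variant tibble.
#' @param regions Region tibble, sorted and non-overlapping within
#'   chromosome.
#' @return The subset of `calls` falling in a region.
#' @export
variants_in_regions <- function(calls, regions) {
  assert_variant_table(calls)
  if (!nrow(regions) || !nrow(calls)) return(calls[0, , drop = FALSE])
  assert_disjoint_sorted(regions)
  keep <- rep(FALSE, nrow(calls))
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    idx <- which(calls$chrom == ch)
    if (!length(idx)) next
    hit <- IRanges::overlapsAny(
      IRanges::IRanges(start = calls$pos[idx], width = 1L),
      regions_to_iranges(r))
    keep[idx] <- hit
  }
  calls[keep, , drop = FALSE]
}

#' Check autosomal recessive segregation of one variant
#'
#' Returns `TRUE` exactly when every case is homozygous for the alternate
#' allele, no control is homozygous-alternate, and every genotyped parent
#' of a case who is not a case (an obligate carrier) is heterozygous or has
#' no usable genotype.  This is the segregation pattern of a fully
#' penetrant recessive allele in a consanguineous family: affected
#' individuals homozygous, carrier parents heterozygous.
#'
#' @param genotypes Either a named character vector of zygosity classes or
#'   a tibble with columns `sample_id` and `zygosity`.
#' @param pedigree Pedigree tibble.
#' @return Logical scalar.
#' @export
#' @examples
#' ped <- build_pedigree("first_cousin_single")
#' cases <- ped$id[ped$role == "case"]
#' gt <- stats::setNames(rep("hom_alt", length(cases)), cases)
#' check_ar_segregation(gt, ped)
check_ar_segregation <- function(genotypes, pedigree) {
  if (is.data.frame(genotypes)) {
    genotypes <- setNames(genotypes$zygosity, genotypes$sample_id)
  }
  gt_of <- function(id) {
    z <- genotypes[id]
    ifelse(is.na(z) | z %in% c("ambiguous", "unclassified"),
           NA_character_, z)
  }
  cases <- pedigree$id[pedigree$role == "case"]
  controls <- pedigree$id[pedigree$role == "control"]
  case_gt <- gt_of(cases)
  if (length(cases) == 0) return(FALSE)
  if (any(is.na(case_gt)) || any(case_gt != "hom_alt")) return(FALSE)
  ctrl_gt <- gt_of(controls)
  if (any(!is.na(ctrl_gt) & ctrl_gt == "hom_alt")) return(FALSE)
  carriers <- setdiff(
    unique(c(pedigree$father_id[pedigree$id %in% cases],
             pedigree$mother_id[pedigree$id %in% cases])), NA)
  carriers <- setdiff(carriers, cases)
  carrier_gt <- gt_of(carriers[carriers %in% names(genotypes)])
  if (any(!is.na(carrier_gt) & carrier_gt != "het")) return(FALSE)
  TRUE
}

#' Prioritize recessive candidate variants
#'
#' Intersects filtered variant calls with the control-excluded HBD regions
#' and keeps the variants whose genotype pattern passes
#' [check_ar_segregation()].  Candidates are emitted unranked, sorted by
#' `(chrom, pos)`; the `notes` column is free text for externally computed
#' annotations (conservation, pathogenicity predictions) and is never
#' filled by the package.
#'
#' @param calls Filtered variant tibble (output of the variant funnel).
#' @param hbd_regions Region tibble, typically provenance
#'   `hbd_control_excluded`.
#' @param pedigree Pedigree tibble.
#' @param window A [window_config()] for genotype classification.
#' @return One row per candidate: variant annotation, containing region
#'   (`region_id`, `region_start`, `region_end`), `segregation_ok`,
#'   `notes`, and one `gt_` genotype column per genotyped individual.
#' @export
prioritize <- function(calls, hbd_regions, pedigree,
                       window = window_config()) {
  in_regions <- variants_in_regions(calls, hbd_regions)
  genotyped <- pedigree$id[pedigree$role %in% c("case", "control")]
  empty <- tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), vclass = character(), consequence = character(),
    pop_freq = double(), region_id = character(),
    region_start = integer(), region_end = integer(),
    segregation_ok = logical(), notes = character())
  for (s in genotyped) empty[[paste0("gt_", s)]] <- character()
  if (!nrow(in_regions)) return(empty)

  gt <- in_regions |>
    mutate(zygosity = classify_zygosity(.data$depth, .data$alt_reads,
                                        window))
  sites <- gt |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
             .data$vclass, .data$consequence, .data$pop_freq)
  rows <- purrr::pmap(sites, function(chrom, pos, ref, alt, vclass,
                                      consequence, pop_freq) {
    g <- gt[gt$chrom == chrom & gt$pos == pos & gt$ref == ref &
              gt$alt == alt, , drop = FALSE]
    gvec <- setNames(g$zygosity, g$sample_id)
    reg <- hbd_regions[hbd_regions$chrom == chrom &
                         hbd_regions$start <= pos &
                         hbd_regions$end >= pos, , drop = FALSE][1, ]
    row <- tibble(
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      vclass = vclass, consequence = consequence, pop_freq = pop_freq,
      region_id = sprintf("%s:%d-%d", reg$chrom, reg$start, reg$end),
      region_start = reg$start, region_end = reg$end,
      segregation_ok = check_ar_segregation(gvec, pedigree),
      notes = NA_character_)
    for (s in genotyped) {
      z <- gvec[s]
      row[[paste0("gt_", s)]] <-
        if (is.na(z)) NA_character_ else unname(z)
    }
    row
  })
  bind_rows(rows) |>
    filter(.data$segregation_ok) |>
    arrange(.data$chrom, .data$pos, .data$alt)
}
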