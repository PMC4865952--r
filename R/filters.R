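# The variant funnel: quality control, consequence class, population
# frequency and case/control sharing.  Each filter takes the long variant
# tibble first and returns the surviving subset, so stages chain with the
# pipe.  A variant site is identified by (chrom, pos, ref, alt); filters
# keep or drop whole sites, never individual sample rows.

site_groups <- function(calls) {
  interaction(calls$chrom, calls$pos, calls$ref, calls$alt, drop = TRUE,
              lex.order = TRUE)
}

#' Quality-control filter for variant calls
#'
#' Retains a variant site only when, in every genotyped individual with
#' nonzero depth, the consensus quality is at least `min_quality`, the depth
#' lies in `[min_depth, max_depth]`, and the annotated copy number (when
#' present) is at most `max_copy_number`.  Sites with no covered individual
#' are dropped.  Afterwards, every SNP that has another retained SNP at a
#' different position on the same chromosome closer than
#' `min_adjacent_distance_bp` is removed (both members of a too-close pair
#' go; the boundary is inclusive, so SNPs exactly `min_adjacent_distance_bp`
#' apart are kept).  Indels are exempt from the adjacency rule and do not
#' count as neighbours.
#'
#' @param calls Variant tibble sorted by `(chrom, pos)`.
#' @param config A [filter_config()].
#' @param pedigree Optional pedigree tibble; when given, only individuals
#'   with role `"case"` or `"control"` are considered genotyped for the
#'   per-sample gates.
#' @return The surviving subset of `calls`, in input order.
#' @export
qc_filter <- function(calls, config = filter_config(), pedigree = NULL) {
  assert_variant_table(calls)
  assert_sorted_calls(calls)
  if (!nrow(calls)) return(calls)
  obs <- calls
  if (!is.null(pedigree)) {
    genotyped <- pedigree$id[pedigree$role %in% c("case", "control")]
    obs <- obs |> filter(.data$sample_id %in% genotyped)
  }
  covered <- obs$depth > 0
  row_ok <- obs$quality >= config$min_quality &
    obs$depth >= config$min_depth & obs$depth <= config$max_depth &
    (is.na(obs$copy_number) | obs$copy_number <= config$max_copy_number)
  akey_obs <- site_key(obs)
  akey_all <- site_key(calls)
  sites <- unique(akey_all)
  sid_obs <- match(akey_obs, sites)
  has_cov <- tabulate(sid_obs[covered], nbins = length(sites)) > 0
  has_fail <- tabulate(sid_obs[covered & !row_ok],
                       nbins = length(sites)) > 0
  keep_site <- has_cov & !has_fail
  kept <- calls[keep_site[match(akey_all, sites)], , drop = FALSE]

  # Adjacency rule on the retained SNP positions, cluster-wise removal:
  # any SNP with another retained SNP at a different position closer than
  # the threshold goes, regardless of which member came first.
  snp <- kept[kept$vclass == "snp", c("chrom", "pos")]
  snp <- snp[!duplicated(paste(snp$chrom, snp$pos)), , drop = FALSE]
  o <- order(snp$chrom, snp$pos)
  snp <- snp[o, , drop = FALSE]
  n <- nrow(snp)
  too_close <- logical(n)
  if (n > 1) {
    same <- snp$chrom[-1] == snp$chrom[-n]
    close <- same & (snp$pos[-1] - snp$pos[-n]) < config$min_adjacent_distance_bp
    too_close[-1] <- close
    too_close[-n] <- too_close[-n] | close
  }
  drop_key <- paste(snp$chrom[too_close], snp$pos[too_close])
  is_dropped <- kept$vclass == "snp" &
    paste(kept$chrom, kept$pos) %in% drop_key
  kept[!is_dropped, , drop = FALSE] |>
    arrange(.data$chrom, .data$pos, .data$alt, .data$sample_id)
}

#' Consequence-class filter
#'
#' Keeps exactly the protein-affecting consequence classes configured in
#' `retained_consequences` (by default nonsynonymous SNVs, frameshift
#' indels, and splice acceptor/donor variants); variants annotated as
#' synonymous, non-coding or other are removed.
#'
#' @inheritParams qc_filter
#' @return The surviving subset of `calls`.
#' @export
consequence_filter <- function(calls, config = filter_config()) {
  assert_variant_table(calls)
  calls |> filter(.data$consequence %in% config$retained_consequences)
}

#' Population-frequency filter
#'
#' Removes variants whose maximum annotated population frequency is strictly
#' greater than `max_pop_freq` (default 0.5%).  Variants without a frequency
#' annotation are novel and always kept; a variant at exactly the threshold
#' is kept.
#'
#' @inheritParams qc_filter
#' @return The surviving subset of `calls`.
#' @export
frequency_filter <- function(calls, config = filter_config()) {
  assert_variant_table(calls)
  bad <- !is.na(calls$pop_freq) & (calls$pop_freq < 0 | calls$pop_freq > 1)
  if (any(bad)) {
    abort(sprintf("pop_freq outside [0, 1] at %s:%d",
                  calls$chrom[bad][1], calls$pos[bad][1]))
  }
  calls |> filter(is.na(.data$pop_freq) |
                    .data$pop_freq <= config$max_pop_freq)
}

#' Case/control sharing filter for recessive candidates
#'
#' Classifies every observation with the read-fraction zygosity rules (see
#' [classify_zygosity()]) and keeps a variant only when it is carried
#' (heterozygous or homozygous-alternate) by every case, homozygous in at
#' least one case, and compatible with absence in controls.  By default a
#' control may be a heterozygous carrier but must not be
#' homozygous-alternate; with `strict_absence = TRUE` in the filter
#' configuration, controls may not carry the allele at all.
#'
#' @inheritParams qc_filter
#' @param pedigree Pedigree tibble with at least one `"case"` role.
#' @param window A [window_config()] supplying the zygosity classification
#'   thresholds.
#' @return The surviving subset of `calls`.
#' @export
case_control_filter <- function(calls, pedigree,
                                config = filter_config(),
                                window = window_config()) {
  assert_variant_table(calls)
  cases <- pedigree$id[pedigree$role == "case"]
  controls <- pedigree$id[pedigree$role == "control"]
  if (!length(cases)) abort("pedigree contains no case individuals")
  if (!nrow(calls)) return(calls)
  gt <- calls |>
    mutate(zygosity = classify_zygosity(.data$depth, .data$alt_reads,
                                        window))
  verdict <- gt |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(
      all_cases_carry = all(cases %in%
        .data$sample_id[.data$zygosity %in% c("het", "hom_alt")]),
      any_case_hom = any(.data$sample_id %in% cases &
                           .data$zygosity == "hom_alt"),
      control_hom = any(.data$sample_id %in% controls &
                          .data$zygosity == "hom_alt"),
      control_carries = any(.data$sample_id %in% controls &
                              .data$zygosity %in% c("het", "hom_alt")),
      .groups = "drop") |>
    filter(.data$all_cases_carry, .data$any_case_hom, !.data$control_hom,
           !(config$strict_absence & .data$control_carries))
  calls |> semi_join(verdict, by = c("chrom", "pos", "ref", "alt"))
}
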