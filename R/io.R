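# Readers and writers for the formats the pipeline touches: multi-sample
# variant tables (VCF v4.2 or a long TSV dialect), PED pedigrees with an
# optional role column, BED3+ region output and the candidate table.

#' Read a multi-sample variant table
#'
#' Reads variant calls with per-sample read-level observations into the long
#' tibble layout used throughout the package: one row per variant allele per
#' sample, with columns `chrom`, `pos`, `ref`, `alt`, `vclass`,
#' `consequence`, `pop_freq`, `copy_number`, `sample_id`, `depth`,
#' `alt_reads`, `quality`.
#'
#' For VCF input the per-sample `DP` and `AD` FORMAT fields are required;
#' `GQ` is used as the per-sample consensus quality when present, otherwise
#' the site `QUAL` is propagated to every sample.  INFO keys `CSQCLASS`
#' (consequence class), `POPFREQ` (maximum annotated population frequency)
#' and `CN` (copy-number flag) are honoured when present.  Multi-allelic
#' records are split into one row-group per alternate allele, with
#' `alt_reads` taken from the matching `AD` entry.  Missing per-sample data
#' becomes an observation with depth 0 (never imputed).
#'
#' @param path Path to the input file.
#' @param format `"vcf"` or `"tsv"`; guessed from the file extension by
#'   default.
#' @param pedigree Optional pedigree tibble from [read_pedigree()]; when
#'   given, sample ids not present in the pedigree raise an error.
#' @return A tibble sorted by `(chrom, pos)`.
#' @export
#' @examples
#' dir <- tempfile(); suite <- make_fixture_suite(dir, seed = 7)
#' calls <- read_variants(file.path(dir, "qc_fixture.tsv"))
#' dplyr::count(calls, chrom, pos)
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          pedigree = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  calls <- switch(format,
                  vcf = read_variants_vcf(path),
                  tsv = read_variants_tsv(path))
  if (!is.null(pedigree)) {
    extra <- setdiff(unique(calls$sample_id), pedigree$id)
    if (length(extra)) {
      abort(sprintf(
        "sample id(s) in variant table but not in pedigree: %s",
        paste(extra, collapse = ", ")))
    }
  }
  assert_variant_table(calls)
  calls |> arrange(.data$chrom, .data$pos, .data$alt, .data$sample_id)
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) return(empty_variant_table())
  samples <- colnames(vcf@gt)[-1]
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ",
                                          as.numeric = TRUE))
  info1 <- function(key) vcfR::extract.info(vcf, element = key)
  csq <- info1("CSQCLASS")
  pf <- suppressWarnings(as.numeric(info1("POPFREQ")))
  cn <- suppressWarnings(as.integer(info1("CN")))
  vc <- info1("VCLASS")

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ref <- fix$REF[i]
    ad_i <- strsplit(ifelse(is.na(ad[i, ]), "", ad[i, ]), ",", fixed = TRUE)
    for (k in seq_along(alts)) {
      alt_reads <- vapply(ad_i, function(v) {
        x <- suppressWarnings(as.integer(v[k + 1]))
        if (length(v) < k + 1 || is.na(x)) 0L else x
      }, integer(1))
      depth <- ifelse(is.na(dp[i, ]), 0L, as.integer(dp[i, ]))
      qual <- if (!is.null(gq) && !all(is.na(gq[i, ]))) {
        ifelse(is.na(gq[i, ]), 0, gq[i, ])
      } else {
        q <- suppressWarnings(as.numeric(fix$QUAL[i]))
        rep(ifelse(is.na(q), 0, q), length(samples))
      }
      vclass <- if (!is.null(vc) && !is.na(vc[i])) {
        tolower(vc[i])
      } else if (nchar(ref) == nchar(alts[k])) "snp" else "indel"
      rows[[length(alts) * (i - 1) + k]] <- tibble(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = ref, alt = alts[k], vclass = vclass,
        consequence = if (is.null(csq) || is.na(csq[i])) "other"
                      else tolower(csq[i]),
        pop_freq = if (is.null(pf)) NA_real_ else pf[i],
        copy_number = if (is.null(cn)) NA_integer_ else cn[i],
        sample_id = samples,
        depth = unname(depth),
        alt_reads = unname(pmin(alt_reads, depth)),
        quality = unname(as.numeric(qual)))
    }
  }
  bind_rows(rows)
}

variant_tsv_cols <- function() {
  readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    vclass = readr::col_character(), consequence = readr::col_character(),
    pop_freq = readr::col_double(), copy_number = readr::col_integer(),
    sample_id = readr::col_character(), depth = readr::col_integer(),
    alt_reads = readr::col_integer(), quality = readr::col_double())
}

read_variants_tsv <- function(path) {
  calls <- readr::read_tsv(path, col_types = variant_tsv_cols(),
                           comment = "#", progress = FALSE)
  probs <- readr::problems(calls)
  if (nrow(probs)) {
    abort(sprintf("malformed variant record at line %s of %s",
                  paste(unique(probs$row), collapse = ", "), path))
  }
  calls
}

empty_variant_table <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), vclass = character(), consequence = character(),
         pop_freq = double(), copy_number = integer(),
         sample_id = character(), depth = integer(), alt_reads = integer(),
         quality = double())
}

#' Write a variant table to the TSV dialect
#'
#' @param calls Variant tibble as returned by [read_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(calls, path) {
  assert_variant_table(calls)
  readr::write_tsv(calls[names(empty_variant_table())], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a pedigree file
#'
#' Reads a whitespace-delimited 6-column PED file (`family`, `id`,
#' `father`, `mother`, `sex`, `phenotype`) with an optional seventh `role`
#' column.  Phenotype 2 maps to `affected = TRUE`.  When no role column is
#' present, affected individuals default to role `"case"`, unaffected
#' individuals with a recorded phenotype (1) to `"control"`, and individuals
#' with missing phenotype to `"unused"`.
#'
#' @param path Path to the PED file.
#' @return A tibble with columns `id`, `father_id`, `mother_id`, `sex`,
#'   `affected`, `role`.
#' @export
read_pedigree <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 6)) {
    abort(sprintf("malformed pedigree record at line %d: expected >= 6 fields",
                  which(nf < 6)[1]))
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:7][1:7]))
  ped <- tibble(
    id = m[, 2],
    father_id = ifelse(m[, 3] %in% c("0", "."), NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] %in% c("0", "."), NA_character_, m[, 4]),
    sex_code = m[, 5],
    phenotype = m[, 6],
    role_raw = if (ncol(m) >= 7) tolower(m[, 7]) else NA_character_)
  if (anyDuplicated(ped$id)) {
    abort(sprintf("duplicated individual id: %s",
                  ped$id[duplicated(ped$id)][1]))
  }
  bad_sex <- !(ped$sex_code %in% c("1", "2", "0"))
  if (any(bad_sex)) {
    warn(sprintf("unknown sex code for %s; stored as unknown",
                 paste(ped$id[bad_sex], collapse = ", ")))
  }
  ped <- ped |>
    mutate(
      sex = dplyr::case_when(.data$sex_code == "1" ~ "male",
                             .data$sex_code == "2" ~ "female",
                             TRUE ~ "unknown"),
      affected = .data$phenotype == "2",
      role = dplyr::case_when(
        !is.na(.data$role_raw) & .data$role_raw != "na" ~ .data$role_raw,
        .data$phenotype == "2" ~ "case",
        .data$phenotype == "1" ~ "control",
        TRUE ~ "unused")) |>
    select(all_of(c("id", "father_id", "mother_id", "sex", "affected",
                    "role")))
  validate_pedigree(ped)
  ped
}

#' @noRd
validate_pedigree <- function(ped) {
  bad_role <- setdiff(unique(ped$role), c("case", "control", "unused"))
  if (length(bad_role)) {
    abort(sprintf("unknown pedigree role: %s", paste(bad_role, collapse = ", ")))
  }
  for (col in c("father_id", "mother_id")) {
    ref <- ped[[col]]
    missing <- setdiff(ref[!is.na(ref)], ped$id)
    if (length(missing)) {
      abort(sprintf("%s refers to non-existent individual(s): %s",
                    col, paste(missing, collapse = ", ")))
    }
  }
  # Kahn-style peel to detect cyclic parentage.
  remaining <- ped
  repeat {
    founders <- with(remaining,
                     (is.na(father_id) | !(father_id %in% id)) &
                     (is.na(mother_id) | !(mother_id %in% id)))
    if (!any(founders)) break
    remaining <- remaining[!founders, , drop = FALSE]
    if (!nrow(remaining)) break
  }
  if (nrow(remaining)) {
    abort(sprintf("cyclic parentage involving: %s",
                  paste(remaining$id, collapse = ", ")))
  }
  invisible(ped)
}

#' Write a pedigree to PED format
#'
#' Inverse of [read_pedigree()]; writes 6 PED columns plus the role column.
#'
#' @param pedigree Pedigree tibble.
#' @param path Output path.
#' @param family_id Family id written in column 1.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path, family_id = "FAM1") {
  sex_code <- c(male = "1", female = "2", unknown = "0")[pedigree$sex]
  lines <- paste(family_id, pedigree$id,
                 ifelse(is.na(pedigree$father_id), "0", pedigree$father_id),
                 ifelse(is.na(pedigree$mother_id), "0", pedigree$mother_id),
                 sex_code,
                 ifelse(pedigree$affected, "2",
                        ifelse(pedigree$role == "control", "1", "0")),
                 toupper(pedigree$role),
                 sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write regions to BED
#'
#' Converts the package's 1-based inclusive regions to 0-based half-open
#' BED coordinates (`start - 1`, `end`) and writes BED3+ lines with
#' `provenance`, `n_markers` and `sample_id` as extra columns, after a
#' header comment.  Ordering is deterministic: `(chrom, start, end,
#' sample_id)`.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, plus optional
#'   `sample_id`, `provenance`, `n_markers`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  assert_region_table(regions)
  regions <- finish_region_table(regions)
  header <- "#chrom\tstart\tend\tprovenance\tn_markers\tsample_id"
  regions <- regions |>
    arrange(.data$chrom, .data$start, .data$end, .data$sample_id)
  lines <- c(header, if (nrow(regions)) paste(
    regions$chrom, format(regions$start - 1L, scientific = FALSE,
                          trim = TRUE),
    format(regions$end, scientific = FALSE, trim = TRUE),
    ifelse(is.na(regions$provenance), ".", regions$provenance),
    ifelse(is.na(regions$n_markers), ".", regions$n_markers),
    ifelse(is.na(regions$sample_id), ".", regions$sample_id),
    sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read regions from a BED file written by [write_regions_bed()]
#'
#' @param path Path to the BED file.
#' @return Region tibble in 1-based inclusive coordinates.
#' @export
read_regions_bed <- function(path) {
  bed <- readr::read_tsv(
    path, comment = "#", progress = FALSE,
    col_names = c("chrom", "start0", "end", "provenance", "n_markers",
                  "sample_id"),
    col_types = readr::cols(
      chrom = readr::col_character(), start0 = readr::col_integer(),
      end = readr::col_integer(), provenance = readr::col_character(),
      n_markers = readr::col_character(),
      sample_id = readr::col_character()))
  if (!nrow(bed)) return(empty_region_table())
  bed |>
    mutate(start = .data$start0 + 1L,
           n_markers = suppressWarnings(as.integer(.data$n_markers)),
           provenance = if_else(.data$provenance == ".", NA_character_,
                                .data$provenance),
           sample_id = if_else(.data$sample_id == ".", NA_character_,
                               .data$sample_id)) |>
    select(all_of(c("chrom", "start", "end", "sample_id", "provenance",
                    "n_markers"))) |>
    arrange(.data$chrom, .data$start, .data$end)
}

#' Write the candidate-variant table
#'
#' One row per candidate with the variant annotation, its containing HBD
#' region id, the per-individual genotype matrix (`gt_` columns, in
#' pedigree order) and the segregation verdict.  Column order is stable, so
#' the file round-trips through [read_candidates_tsv()] unchanged.
#'
#' @param candidates Candidate tibble from [prioritize()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  fixed <- c("chrom", "pos", "ref", "alt", "vclass", "consequence",
             "pop_freq", "region_id", "region_start", "region_end",
             "segregation_ok", "notes")
  gt_cols <- grep("^gt_", names(candidates), value = TRUE)
  readr::write_tsv(candidates[c(fixed, gt_cols)], path, progress = FALSE)
  invisible(path)
}

#' Read a candidate table written by [write_candidates_tsv()]
#'
#' @param path Path to the TSV file.
#' @return Candidate tibble.
#' @export
read_candidates_tsv <- function(path) {
  out <- readr::read_tsv(
    path, progress = FALSE,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character(),
      vclass = readr::col_character(), consequence = readr::col_character(),
      pop_freq = readr::col_double(), region_id = readr::col_character(),
      region_start = readr::col_integer(),
      region_end = readr::col_integer(),
      segregation_ok = readr::col_logical(), notes = readr::col_character(),
      .default = readr::col_character()))
  probs <- readr::problems(out)
  if (nrow(probs)) {
    abort(sprintf("malformed candidate record at line %s of %s",
                  paste(unique(probs$row), collapse = ", "), path))
  }
  out
}
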