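# Deterministic fixture generation: every file the tests need is produced
# by code from a single seed, including a minimal VCF v4.2 writer so the
# VCF reading path can be exercised round-trip.

#' Write a variant table as VCF v4.2
#'
#' One record per variant allele with FORMAT `DP:AD:GQ` per sample and the
#' INFO keys `VCLASS`, `CSQCLASS`, `POPFREQ` and `CN` that
#' [read_variants()] understands.  Samples missing an observation at a site
#' are written with depth 0.
#'
#' @param calls Variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(calls, path) {
  assert_variant_table(calls)
  samples <- sort(unique(calls$sample_id))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hbdscan",
    "##INFO=<ID=VCLASS,Number=1,Type=String,Description=\"Variant class\">",
    "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=POPFREQ,Number=1,Type=Float,Description=\"Max population allele frequency\">",
    "##INFO=<ID=CN,Number=1,Type=Integer,Description=\"Copy number flag\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  sites <- calls |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .data$vclass,
             .data$consequence, .data$pop_freq, .data$copy_number) |>
    arrange(.data$chrom, .data$pos, .data$alt)
  records <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    obs <- calls[calls$chrom == s$chrom & calls$pos == s$pos &
                   calls$ref == s$ref & calls$alt == s$alt, , drop = FALSE]
    obs <- obs[match(samples, obs$sample_id), , drop = FALSE]
    gt <- ifelse(
      is.na(obs$sample_id),
      ".:0:0,0:0",
      sprintf("%s:%d:%d,%d:%d",
              c("0/0", "0/1", "1/1")[1 + (obs$alt_reads > 0) +
                                       (obs$alt_reads >= obs$depth / 2 &
                                          obs$alt_reads > 0)],
              obs$depth, obs$depth - obs$alt_reads, obs$alt_reads,
              as.integer(round(obs$quality))))
    info <- paste0(
      "VCLASS=", toupper(s$vclass), ";CSQCLASS=", toupper(s$consequence),
      if (!is.na(s$pop_freq)) sprintf(";POPFREQ=%.15g", s$pop_freq) else "",
      if (!is.na(s$copy_number)) sprintf(";CN=%d", s$copy_number) else "")
    paste(c(s$chrom, s$pos, ".", s$ref, s$alt,
            sprintf("%g", max(obs$quality, na.rm = TRUE)), "PASS", info,
            "GT:DP:AD:GQ", gt), collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, records), path)
  invisible(path)
}

qc_fixture_calls <- function() {
  mk <- function(pos, depth, alt_n, quality) {
    tibble(chrom = "chr1", pos = as.integer(pos), ref = "A", alt = "G",
           vclass = "snp", consequence = "nonsynonymous",
           pop_freq = NA_real_, copy_number = NA_integer_,
           sample_id = "S1", depth = as.integer(depth),
           alt_reads = as.integer(alt_n), quality = as.numeric(quality))
  }
  bind_rows(
    mk(100000, 50, 50, 15),    # fails quality < 20
    mk(200000, 3, 3, 60),      # fails depth < 4
    mk(300000, 600, 600, 60),  # fails depth > 500
    mk(400000, 50, 50, 60),    # adjacency pair, 4 bp apart: both removed
    mk(400004, 50, 50, 60),
    mk(500000, 50, 50, 60))    # the lone survivor
}

uniform_marker_track <- function(n, spacing_bp = 1000,
                                 sample_id = "S1") {
  tibble(chrom = "chr1",
         pos = as.integer(1 + (seq_len(n) - 1) * spacing_bp),
         sample_id = sample_id, zygosity = "hom_ref")
}

#' Write the deterministic fixture suite
#'
#' Generates, from a single seed, every file fixture the test suite uses:
#' the six-variant quality-control fixture, the 1,200- and 600-marker
#' uniform window fixtures, the template pedigrees, a small simulated
#' family (variant TSV and VCF, pedigree, ground-truth tract BED and
#' genotype TSV), and a manifest of MD5 checksums.  The same seed always
#' produces byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the manifest tibble (`file`, `md5`).
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  p <- function(...) file.path(out_dir, ...)

  write_variants_tsv(qc_fixture_calls(), p("qc_fixture.tsv"))
  readr::write_tsv(uniform_marker_track(1200), p("markers_1200.tsv"),
                   progress = FALSE)
  readr::write_tsv(uniform_marker_track(600), p("markers_600.tsv"),
                   progress = FALSE)
  write_pedigree(build_pedigree("first_cousin_single"),
                 p("fam_single.ped"))
  write_pedigree(build_pedigree("first_cousin_double"),
                 p("fam_double.ped"))

  sim <- simulate_family(sim_config(
    n_chromosomes = 2, chrom_length_bp = 10e6, n_markers_per_chrom = 300,
    causal_chrom = "chr1", causal_pos = 5e6, seed = seed))
  write_variants_tsv(sim$calls, p("sim_calls.tsv"))
  write_variants_vcf(sim$calls, p("sim_calls.vcf"))
  write_pedigree(sim$pedigree, p("sim.ped"))
  write_regions_bed(sim$truth$tracts, p("sim_truth_tracts.bed"))
  readr::write_tsv(sim$truth$genotypes, p("sim_truth_genotypes.tsv"),
                   progress = FALSE)

  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  readr::write_tsv(manifest, p("manifest.tsv"), progress = FALSE)
  invisible(manifest)
}
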