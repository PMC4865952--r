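# Shared builders for the test suite.  Everything is generated in code;
# no stored fixtures.

# A single-sample marker track on one chromosome from a zygosity vector.
marker_track <- function(zygosity, spacing = 1000L, chrom = "chr1",
                         start = 1L) {
  tibble::tibble(chrom = chrom,
                 pos = as.integer(start + (seq_along(zygosity) - 1) *
                                    spacing),
                 zygosity = zygosity)
}

# Random single-sample marker instance with sparse heterozygotes and
# occasional oversized gaps, for oracle-equivalence testing.
random_marker_instance <- function(n, het_prob = NULL,
                                   big_gap_prob = 0.002) {
  if (is.null(het_prob)) het_prob <- stats::runif(1, 0, 0.01)
  gaps <- ifelse(stats::runif(n - 1) < big_gap_prob,
                 stats::runif(n - 1, 5e5 + 1, 1.5e6),
                 stats::runif(n - 1, 500, 40000))
  pos <- as.integer(round(cumsum(c(1, gaps))))
  zyg <- sample(c("hom_ref", "hom_alt", "het"), n, replace = TRUE,
                prob = c((1 - het_prob) / 2, (1 - het_prob) / 2, het_prob))
  marker_track(zyg)[0, ] |>
    dplyr::bind_rows(tibble::tibble(chrom = "chr1", pos = pos,
                                    zygosity = zyg))
}

# One variant site across a set of samples from target zygosity classes,
# using clean read counts (depth 100) that classify unambiguously.
call_from_zygosity <- function(zygosity_by_sample, chrom = "chr1",
                               pos = 1000000L, pop_freq = NA_real_,
                               consequence = "nonsynonymous") {
  depth <- 100L
  n_alt <- vapply(zygosity_by_sample, function(z) {
    switch(z, hom_ref = 0L, het = 50L, hom_alt = 100L, missing = 0L,
           stop("bad zygosity"))
  }, integer(1))
  dp <- ifelse(zygosity_by_sample == "missing", 0L, depth)
  n_alt <- ifelse(dp == 0L, 0L, n_alt)
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = "A", alt = "C",
    vclass = "snp", consequence = consequence, pop_freq = pop_freq,
    copy_number = NA_integer_, sample_id = names(zygosity_by_sample),
    depth = dp, alt_reads = n_alt,
    quality = 60)
}

# A minimal case/control pedigree: two affected siblings, genotyped
# parents as controls.
toy_pedigree <- function() {
  tibble::tibble(
    id = c("FA", "MO", "A1", "A2", "U1"),
    father_id = c(NA, NA, "FA", "FA", "FA"),
    mother_id = c(NA, NA, "MO", "MO", "MO"),
    sex = c("male", "female", "female", "male", "male"),
    affected = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    role = c("control", "control", "case", "case", "control"))
}

# Reduced simulation settings for fast end-to-end tests.
small_sim_config <- function(seed = 1L, ...) {
  sim_config(n_chromosomes = 3, chrom_length_bp = 20e6,
             n_markers_per_chrom = 800, causal_chrom = "chr1",
             causal_pos = 10e6, seed = seed, ...)
}

# Random region list: sorted, non-overlapping within chromosome by
# construction (alternating widths and gaps).
random_regions <- function(n, chrom = "chr1") {
  widths <- sample.int(3e6, n)
  gaps <- sample.int(2e6, n) + 1L
  ends <- cumsum(as.numeric(widths + gaps))
  starts <- ends - widths + 1
  tibble::tibble(chrom = chrom, start = as.integer(starts),
                 end = as.integer(ends))
}
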