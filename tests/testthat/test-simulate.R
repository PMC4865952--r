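# The gene-drop simulator: pedigree templates, recombination, allele
# assignment, read noise, and ground-truth consistency.

test_that("templates wire up the expected consanguinity structure", {
  single <- build_pedigree("first_cousin_single")
  expect_equal(sum(single$role == "case"), 2)
  # the cases' parents are first cousins: their grandparental couple is
  # shared
  parents <- single[single$id %in% c("C1", "C2"), ]
  gp_of <- function(id) {
    p <- single[single$id == id, ]
    unlist(single[single$id %in% c(p$father_id, p$mother_id),
                  c("father_id", "mother_id")])
  }
  expect_length(intersect(na.omit(gp_of("C1")), na.omit(gp_of("C2"))), 2)

  double <- build_pedigree("first_cousin_double")
  expect_equal(sum(double$role == "case"), 4)
  expect_equal(sum(double$role == "control"), 2)
  expect_error(build_pedigree("no_such_template"))
  # custom requires an explicit pedigree
  expect_error(build_pedigree("custom"), "requires")
  trio <- toy_pedigree()
  expect_equal(as.data.frame(build_pedigree("custom", custom = trio)),
               as.data.frame(trio))
})

test_that("zero recombination transmits whole parental haplotypes", {
  cfg <- sim_config(recomb_rate = 0, n_chromosomes = 2,
                    chrom_length_bp = 10e6, causal_pos = 5e6, seed = 1)
  set.seed(1)
  drop <- gene_drop(build_pedigree("first_cousin_double"), cfg)
  for (id in names(drop$haplotypes)) {
    for (ch in names(drop$haplotypes[[id]])) {
      for (h in drop$haplotypes[[id]][[ch]]) {
        expect_length(h$lab, 1)  # one founder label end-to-end
      }
    }
  }
})

test_that("founders carry no autozygous tracts", {
  cfg <- small_sim_config(seed = 2)
  set.seed(2)
  drop <- gene_drop(build_pedigree("first_cousin_double"), cfg)
  founders <- drop$pedigree$id[is.na(drop$pedigree$father_id)]
  expect_equal(sum(drop$truth_tracts$sample_id %in% founders), 0)
  expect_equal(unname(autozygous_fraction(drop, founders)),
               rep(0, length(founders)))
})

test_that("an outbred pedigree has zero autozygosity", {
  cfg <- small_sim_config(seed = 3)
  set.seed(3)
  drop <- gene_drop(build_pedigree("custom", custom = toy_pedigree()), cfg,
                    condition_on_causal = FALSE)
  expect_equal(unname(autozygous_fraction(drop)),
               rep(0, nrow(toy_pedigree())))
})

test_that("first-cousin offspring autozygosity converges to F = 1/16", {
  ped <- build_pedigree("first_cousin_single")
  cfg <- sim_config(pedigree_template = "first_cousin_single",
                    n_chromosomes = 10, chrom_length_bp = 50e6, seed = 1)
  set.seed(20240901)
  fr <- replicate(400, {
    d <- gene_drop(ped, cfg, condition_on_causal = FALSE)
    mean(autozygous_fraction(d, c("P1", "P2")))
  })
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 1 / 16), 3 * se)
})

test_that("conditioned drops make every case homozygous at the causal locus", {
  for (seed in c(4, 5, 6)) {
    sim <- simulate_family(small_sim_config(seed = seed))
    g <- sim$truth$genotypes
    causal <- sim$truth$causal
    at_causal <- g[g$chrom == causal$chrom & g$pos == causal$pos, ]
    ped <- sim$pedigree
    cases <- ped$id[ped$role == "case"]
    controls <- ped$id[ped$role == "control"]
    expect_equal(at_causal$g[match(cases, at_causal$sample_id)],
                 rep(2L, length(cases)))
    expect_equal(at_causal$g[match(controls, at_causal$sample_id)],
                 rep(1L, length(controls)))
    # the causal variant is novel; every other site carries its MAF
    expect_true(is.na(causal$pop_freq))
    expect_true(all(!is.na(
      sim$calls$pop_freq[sim$calls$pos != causal$pos |
                           sim$calls$chrom != causal$chrom])))
  }
})

test_that("genotypes are Mendelian-consistent at every marker", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 15e6,
                    n_markers_per_chrom = 150, causal_pos = 7.5e6,
                    seed = 9)
  set.seed(9)
  ped <- build_pedigree("first_cousin_double")
  drop <- gene_drop(ped, cfg)
  al <- assign_alleles(drop, cfg, samples = "all")
  wide <- tidyr::pivot_wider(al$genotypes, names_from = "sample_id",
                             values_from = "g")
  for (i in seq_len(nrow(ped))) {
    fa <- ped$father_id[i]
    mo <- ped$mother_id[i]
    if (is.na(fa)) next
    g_child <- wide[[ped$id[i]]]
    g_fa <- wide[[fa]]
    g_mo <- wide[[mo]]
    lo <- (g_fa == 2) + (g_mo == 2)
    hi <- 2 - (g_fa == 0) - (g_mo == 0)
    expect_true(all(g_child >= lo & g_child <= hi),
                label = sprintf("Mendelian consistency for %s", ped$id[i]))
  }
})

test_that("noiseless reads classify back to the true genotypes", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 15e6,
                    n_markers_per_chrom = 200, causal_pos = 7.5e6,
                    base_error = 0, mean_depth = 150, seed = 12)
  sim <- simulate_family(cfg)
  m <- build_marker_map(sim$calls, sim$pedigree)
  joined <- dplyr::inner_join(m, sim$truth$genotypes,
                              by = c("chrom", "pos", "sample_id"))
  expect_equal(joined$zygosity,
               c("hom_ref", "het", "hom_alt")[joined$g + 1L])
  # with base_error 0, homozygous-alternate reads are all-alternate
  hom <- sim$calls |>
    dplyr::semi_join(sim$truth$genotypes |> dplyr::filter(g == 2),
                     by = c("chrom", "pos", "sample_id"))
  expect_equal(hom$alt_reads, hom$depth)
})

test_that("simulated heterozygous sites have balanced allele reads", {
  sim <- simulate_family(small_sim_config(seed = 33))
  het <- sim$calls |>
    dplyr::semi_join(sim$truth$genotypes |> dplyr::filter(g == 1),
                     by = c("chrom", "pos", "sample_id")) |>
    dplyr::filter(depth > 0)
  f <- het$alt_reads / het$depth
  expect_gt(length(f), 500)
  expect_lt(abs(mean(f) - 0.5), 0.01)
})

test_that("simulation is reproducible from its seed", {
  s1 <- simulate_family(small_sim_config(seed = 123))
  s2 <- simulate_family(small_sim_config(seed = 123))
  expect_equal(as.data.frame(s1$calls), as.data.frame(s2$calls))
  expect_equal(as.data.frame(s1$truth$tracts),
               as.data.frame(s2$truth$tracts))
  s3 <- simulate_family(small_sim_config(seed = 124))
  expect_false(identical(s1$calls, s3$calls))
})
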