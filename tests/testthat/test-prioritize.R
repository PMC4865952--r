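# Region membership and autosomal recessive segregation logic.

test_that("region membership uses 1-based inclusive boundaries", {
  region <- tibble::tibble(chrom = "chr20", start = 1126746L,
                           end = 4842635L)
  at <- function(pos) call_from_zygosity(c(S1 = "hom_alt"),
                                         chrom = "chr20", pos = pos)
  # a known recessive-candidate locus inside the interval
  expect_equal(nrow(variants_in_regions(at(2840713L), region)), 1)
  expect_equal(nrow(variants_in_regions(at(1126746L), region)), 1)
  expect_equal(nrow(variants_in_regions(at(4842635L), region)), 1)
  expect_equal(nrow(variants_in_regions(at(4842636L), region)), 0)
  expect_equal(nrow(variants_in_regions(at(1126745L), region)), 0)
  expect_equal(nrow(variants_in_regions(at(2840713L), region[0, ])), 0)
})

test_that("segregation verdicts match exhaustive enumeration on a trio-plus-sibling pedigree", {
  ped <- toy_pedigree()  # FA, MO controls; A1, A2 cases; U1 control sib
  classes <- c("hom_ref", "het", "hom_alt", "missing")
  grid <- expand.grid(FA = classes, MO = classes, A1 = classes,
                      A2 = classes, U1 = classes,
                      stringsAsFactors = FALSE)
  # independent statement of the rule set
  expected <- with(grid, {
    cases_hom <- A1 == "hom_alt" & A2 == "hom_alt"
    control_hom <- FA == "hom_alt" | MO == "hom_alt" | U1 == "hom_alt"
    carriers_ok <- (FA %in% c("het", "missing")) &
      (MO %in% c("het", "missing"))
    cases_hom & !control_hom & carriers_ok
  })
  got <- vapply(seq_len(nrow(grid)), function(i) {
    z <- unlist(grid[i, ])
    z[z == "missing"] <- "unclassified"
    check_ar_segregation(z, ped)
  }, logical(1))
  expect_equal(got, unname(expected))
  # the canonical pattern: affected homozygous, parents heterozygous
  expect_true(check_ar_segregation(
    c(FA = "het", MO = "het", A1 = "hom_alt", A2 = "hom_alt",
      U1 = "hom_ref"), ped))
})

test_that("prioritize returns segregating variants inside HBD regions only", {
  ped <- toy_pedigree()
  region <- tibble::tibble(chrom = "chr1", start = 1000000L,
                           end = 4000000L, sample_id = NA_character_,
                           provenance = "hbd_control_excluded",
                           n_markers = NA_integer_)
  seg <- c(FA = "het", MO = "het", A1 = "hom_alt", A2 = "hom_alt",
           U1 = "hom_ref")
  nonseg <- c(FA = "het", MO = "het", A1 = "het", A2 = "hom_alt",
              U1 = "hom_ref")
  calls <- dplyr::bind_rows(
    call_from_zygosity(seg, pos = 1500000L),
    call_from_zygosity(seg, pos = 2500000L),
    call_from_zygosity(nonseg, pos = 3000000L),
    call_from_zygosity(seg, pos = 9000000L))  # outside the region
  out <- prioritize(calls, region, ped)
  expect_equal(out$pos, c(1500000L, 2500000L))
  expect_true(all(out$segregation_ok))
  expect_equal(unique(out$region_id), "chr1:1000000-4000000")
  expect_equal(out$gt_A1, c("hom_alt", "hom_alt"))
  expect_equal(out$gt_FA, c("het", "het"))

  # permutation invariance of input order
  out2 <- prioritize(calls[sample.int(nrow(calls)), ] |>
                       dplyr::arrange(chrom, pos, alt, sample_id),
                     region, ped)
  expect_equal(as.data.frame(out), as.data.frame(out2))

  # no HBD regions: empty candidate list with stable columns
  none <- prioritize(calls, region[0, ], ped)
  expect_equal(nrow(none), 0)
  expect_true(all(c("region_id", "segregation_ok", "gt_A1") %in%
                    names(none)))
})

test_that("candidates from a simulated family include the planted variant", {
  sim <- simulate_family(small_sim_config(seed = 77))
  run <- run_pipeline(sim$calls, sim$pedigree,
                      pipeline_config(sim = sim$config, seed = 77))
  causal <- sim$truth$causal
  expect_true(any(run$candidates$chrom == causal$chrom &
                    run$candidates$pos == causal$pos))
  # every candidate lies inside a control-excluded HBD region
  if (nrow(run$candidates)) {
    inside <- vapply(seq_len(nrow(run$candidates)), function(i) {
      any(run$hbd_regions$chrom == run$candidates$chrom[i] &
            run$hbd_regions$start <= run$candidates$pos[i] &
            run$hbd_regions$end >= run$candidates$pos[i])
    }, logical(1))
    expect_true(all(inside))
  }
})
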