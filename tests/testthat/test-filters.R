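# The variant funnel: QC thresholds, consequence classes, population
# frequency and recessive case/control sharing.

test_that("the six-site QC fixture leaves exactly one survivor", {
  calls <- hbdscan:::qc_fixture_calls()
  out <- qc_filter(calls)
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 500000L)
})

test_that("QC boundaries are inclusive where specified", {
  base <- hbdscan:::qc_fixture_calls()[6, ]
  at <- function(pos, ...) {
    row <- base
    row$pos <- as.integer(pos)
    fields <- list(...)
    for (nm in names(fields)) row[[nm]] <- fields[[nm]]
    row
  }
  # exactly min/max depth and min quality pass
  edge <- dplyr::bind_rows(at(1e6, depth = 4L, alt_reads = 4L),
                           at(2e6, depth = 500L, alt_reads = 0L),
                           at(3e6, quality = 20))
  expect_equal(nrow(qc_filter(edge)), 3)
  # two SNPs exactly 5 bp apart are both retained (>= 5 bp rule)
  pair5 <- dplyr::bind_rows(at(1e6), at(1e6 + 5))
  expect_equal(nrow(qc_filter(pair5)), 2)
  # 4 bp apart: both removed
  pair4 <- dplyr::bind_rows(at(1e6), at(1e6 + 4))
  expect_equal(nrow(qc_filter(pair4)), 0)
  # indels are exempt from adjacency
  ind <- dplyr::bind_rows(at(1e6), at(1e6 + 2, vclass = "indel"))
  out <- qc_filter(ind)
  expect_equal(nrow(out), 2)
  # copy number above the ceiling fails; absent passes
  cn <- dplyr::bind_rows(at(1e6, copy_number = 3L),
                         at(2e6, copy_number = 2L))
  expect_equal(qc_filter(cn)$pos, 2000000L)
  # all-missing site (depth 0 everywhere) is dropped
  expect_equal(nrow(qc_filter(at(1e6, depth = 0L, alt_reads = 0L))), 0)
  # unsorted input is rejected
  expect_error(qc_filter(dplyr::bind_rows(at(2e6), at(1e6))), "sorted")
})

test_that("consequence filter keeps exactly the protein-affecting set", {
  ped_samples <- c(S1 = "het")
  mk <- function(pos, csq) call_from_zygosity(ped_samples, pos = pos,
                                              consequence = csq)
  calls <- dplyr::bind_rows(
    mk(1e6, "synonymous"), mk(2e6, "nonsynonymous"), mk(3e6, "noncoding"),
    mk(4e6, "frameshift"), mk(5e6, "splice_acceptor"),
    mk(6e6, "splice_donor"), mk(7e6, "other"))
  out <- consequence_filter(calls)
  expect_setequal(out$consequence,
                  c("nonsynonymous", "frameshift", "splice_acceptor",
                    "splice_donor"))
  all_other <- dplyr::bind_rows(mk(1e6, "other"), mk(2e6, "other"))
  expect_equal(nrow(consequence_filter(all_other)), 0)
})

test_that("frequency filter is exclusive at 0.5% and keeps novel variants", {
  mk <- function(pos, f) call_from_zygosity(c(S1 = "het"), pos = pos,
                                            pop_freq = f)
  calls <- dplyr::bind_rows(mk(1e6, 0.006), mk(2e6, 0.005), mk(3e6, NA))
  out <- frequency_filter(calls)
  expect_setequal(out$pos, c(2000000L, 3000000L))
  expect_error(frequency_filter(mk(1e6, 1.5)), "\\[0, 1\\]")
})

test_that("case/control sharing implements the recessive pattern", {
  ped <- build_pedigree("first_cousin_double")
  cases <- ped$id[ped$role == "case"]
  controls <- ped$id[ped$role == "control"]
  gt <- function(case_z, control_z) {
    z <- c(stats::setNames(case_z, cases),
           stats::setNames(control_z, controls))
    call_from_zygosity(z)
  }
  keep <- function(calls, ...) nrow(case_control_filter(calls, ped, ...)) > 0

  # hom-alt in all cases, het controls: kept under the default reading
  expect_true(keep(gt(rep("hom_alt", 4), rep("het", 2))))
  # ... but removed under the literal absence reading
  expect_false(keep(gt(rep("hom_alt", 4), rep("het", 2)),
                    filter_config(strict_absence = TRUE)))
  # hom-ref controls pass either way
  expect_true(keep(gt(rep("hom_alt", 4), rep("hom_ref", 2)),
                   filter_config(strict_absence = TRUE)))
  # missing in one case: not shared by all cases
  expect_false(keep(gt(c("missing", rep("hom_alt", 3)), rep("het", 2))))
  # het in all cases, never homozygous: removed
  expect_false(keep(gt(rep("het", 4), rep("het", 2))))
  # homozygous control: removed
  expect_false(keep(gt(rep("hom_alt", 4), c("hom_alt", "het"))))
  # a pedigree without cases is a configuration error
  no_cases <- ped |> dplyr::mutate(role = "control")
  expect_error(case_control_filter(gt(rep("hom_alt", 4), rep("het", 2)),
                                   no_cases), "no case")
})

test_that("filters are idempotent subsets and consequence/frequency commute", {
  withr::local_seed(7)
  sim <- simulate_family(small_sim_config(seed = 21))
  calls <- sim$calls
  cfg <- filter_config()
  ped <- sim$pedigree

  a <- qc_filter(calls, cfg, ped)
  expect_true(nrow(a) <= nrow(calls))
  expect_equal(as.data.frame(qc_filter(a, cfg, ped)), as.data.frame(a))

  b1 <- frequency_filter(consequence_filter(a, cfg), cfg)
  b2 <- consequence_filter(frequency_filter(a, cfg), cfg)
  expect_equal(as.data.frame(b1), as.data.frame(b2))
  expect_equal(as.data.frame(consequence_filter(b1, cfg)),
               as.data.frame(b1))
  expect_equal(as.data.frame(frequency_filter(b1, cfg)),
               as.data.frame(b1))

  d <- case_control_filter(b1, ped, cfg)
  expect_true(nrow(d) <= nrow(b1))
  expect_equal(as.data.frame(case_control_filter(d, ped, cfg)),
               as.data.frame(d))
})

test_that("survivor counts respond monotonically to thresholds", {
  withr::local_seed(13)
  sim <- simulate_family(small_sim_config(seed = 22))
  calls <- sim$calls
  strict <- nrow(qc_filter(calls, filter_config(min_quality = 70)))
  default <- nrow(qc_filter(calls, filter_config()))
  lax <- nrow(qc_filter(calls, filter_config(min_quality = 0)))
  expect_true(strict <= default)
  expect_true(default <= lax)

  tight <- nrow(frequency_filter(calls, filter_config(max_pop_freq = 0)))
  mid <- nrow(frequency_filter(calls, filter_config(max_pop_freq = 0.1)))
  wide <- nrow(frequency_filter(calls, filter_config(max_pop_freq = 1)))
  expect_true(tight <= mid && mid <= wide)
})
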