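# Run-based IBD segment detection and the HBD interval algebra.

test_that("the 50-SNP / 1 Mb run rule rejects short and narrow runs", {
  # 49 consecutive homozygous markers over ~2 Mb: too few SNPs
  m49 <- marker_track(rep("hom_ref", 49), spacing = 42000L)
  expect_equal(nrow(roh_runs(m49)), 0)
  # 50 homozygous markers over ~1.5 Mb: qualifies
  m50 <- marker_track(rep("hom_ref", 50), spacing = 30000L)
  r <- roh_runs(m50)
  expect_equal(nrow(r), 1)
  expect_equal(r$n_markers, 50L)
  expect_true(r$end - r$start + 1 >= 1e6)
  # 50 homozygous markers over ~0.5 Mb: too narrow
  m_narrow <- marker_track(rep("hom_alt", 50), spacing = 10000L)
  expect_equal(nrow(roh_runs(m_narrow)), 0)
  # an intervening heterozygote splits the run; two 49-marker halves
  # both fall below the SNP-count floor
  z <- rep("hom_ref", 99)
  z[50] <- "het"
  expect_equal(nrow(roh_runs(marker_track(z, spacing = 30000L))), 0)
  # with one more marker per side, both halves qualify separately
  z2 <- rep("hom_ref", 101)
  z2[51] <- "het"
  expect_equal(nrow(roh_runs(marker_track(z2, spacing = 30000L))), 2)
})

test_that("roh_runs equals an explicit maximal-run scan on random instances", {
  brute_runs <- function(m, cfg) {
    out <- list()
    for (ch in unique(m$chrom)) {
      x <- m[m$chrom == ch, , drop = FALSE]
      i <- 1
      while (i <= nrow(x)) {
        if (x$zygosity[i] %in% c("hom_ref", "hom_alt")) {
          j <- i
          while (j < nrow(x) &&
                 x$zygosity[j + 1] %in% c("hom_ref", "hom_alt")) j <- j + 1
          if (j - i + 1 >= cfg$min_run_snps &&
              x$pos[j] - x$pos[i] + 1 >= cfg$min_run_bp) {
            out[[length(out) + 1]] <- tibble::tibble(
              chrom = ch, start = x$pos[i], end = x$pos[j],
              n_markers = j - i + 1L)
          }
          i <- j + 1
        } else {
          i <- i + 1
        }
      }
    }
    dplyr::bind_rows(out)
  }
  withr::local_seed(321)
  cfg <- ibd_config(min_run_snps = 20, min_run_bp = 3e5)
  for (i in 1:30) {
    m <- random_marker_instance(sample(50:500, 1),
                                het_prob = stats::runif(1, 0, 0.1))
    fast <- roh_runs(m, cfg)
    slow <- brute_runs(m, cfg)
    expect_equal(nrow(fast), nrow(slow))
    if (nrow(slow)) {
      expect_equal(fast$start, slow$start)
      expect_equal(fast$end, slow$end)
      expect_equal(fast$n_markers, slow$n_markers)
    }
  }
})

test_that("interval intersection behaves as set intersection", {
  a <- tibble::tibble(chrom = "chr1", start = 1000000L, end = 3000000L)
  b <- tibble::tibble(chrom = "chr1", start = 2000000L, end = 5000000L)
  out <- intersect_regions(a, b)
  expect_equal(out$start, 2000000L)
  expect_equal(out$end, 3000000L)

  disjoint <- tibble::tibble(chrom = "chr1", start = 9000000L,
                             end = 9500000L)
  expect_equal(nrow(intersect_regions(a, disjoint)), 0)
  expect_equal(nrow(intersect_regions(a, b |>
                                        dplyr::mutate(chrom = "chr2"))), 0)
  # idempotence
  withr::local_seed(8)
  r <- random_regions(6)
  expect_equal(as.data.frame(intersect_regions(r, r) |>
                               dplyr::select(chrom, start, end)),
               as.data.frame(r))
  # unsorted input rejected
  expect_error(intersect_regions(r[c(2, 1), ], r), "sorted")
})

test_that("case-shared HBD is the n-way intersection over cases", {
  shared <- tibble::tibble(chrom = "chr2", start = 2000000L,
                           end = 5000000L)
  per_case <- list(
    A = dplyr::bind_rows(shared,
                         tibble::tibble(chrom = "chr2", start = 30000000L,
                                        end = 34000000L)),
    B = tibble::tibble(chrom = "chr2", start = 1000000L, end = 5000000L),
    C = tibble::tibble(chrom = "chr2", start = 2000000L, end = 8000000L),
    D = shared)
  out <- case_shared_hbd(per_case)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 2000000L)
  expect_equal(out$end, 5000000L)
  expect_equal(out$provenance, "case_shared_hbd")

  # single case: identity
  single <- case_shared_hbd(per_case["B"])
  expect_equal(single$start, 1000000L)
  expect_equal(single$end, 5000000L)

  # permutation invariance
  out2 <- case_shared_hbd(per_case[c("D", "B", "A", "C")])
  expect_equal(as.data.frame(out), as.data.frame(out2))

  expect_error(case_shared_hbd(list()), "at least one")
})

test_that("case-shared output is contained in every case's stretches", {
  withr::local_seed(99)
  for (i in 1:15) {
    per_case <- lapply(1:3, function(j) random_regions(sample(2:6, 1)))
    names(per_case) <- paste0("S", 1:3)
    out <- case_shared_hbd(per_case, config = window_config(min_stretch_bp = 0))
    for (s in names(per_case)) {
      leftover <- subtract_regions(out |>
                                     dplyr::select(chrom, start, end),
                                   per_case[[s]])
      expect_equal(nrow(leftover), 0)
    }
  }
})

test_that("control exclusion subtracts overlap and re-applies the length floor", {
  hbd <- tibble::tibble(chrom = "chr1", start = 1000000L, end = 5000000L,
                        sample_id = NA_character_,
                        provenance = "case_shared_hbd",
                        n_markers = NA_integer_)
  ctrl <- tibble::tibble(chrom = "chr1", start = 2000000L, end = 2500000L)
  out <- exclude_control_overlap(hbd, ctrl)
  expect_equal(nrow(out), 2)
  expect_equal(out$start, c(1000000L, 2500001L))
  expect_equal(out$end, c(1999999L, 5000000L))
  expect_true(all(out$end - out$start + 1 >= 1e6))
  expect_equal(unique(out$provenance), "hbd_control_excluded")

  # total overlap: nothing remains
  all_cover <- tibble::tibble(chrom = "chr1", start = 1L, end = 10000000L)
  expect_equal(nrow(exclude_control_overlap(hbd, all_cover)), 0)

  # no controls: regions pass through unchanged (relabelled)
  none <- exclude_control_overlap(hbd, ctrl[0, ])
  expect_equal(none$start, hbd$start)
  expect_equal(none$end, hbd$end)

  # drop mode discards on any overlap
  dropped <- exclude_control_overlap(hbd, ctrl, mode = "drop")
  expect_equal(nrow(dropped), 0)
  far <- tibble::tibble(chrom = "chr1", start = 20000000L,
                        end = 21000000L)
  kept <- exclude_control_overlap(hbd, far, mode = "drop")
  expect_equal(nrow(kept), 1)
})

test_that("control-excluded regions never overlap control stretches", {
  withr::local_seed(17)
  for (i in 1:15) {
    hbd <- random_regions(sample(2:5, 1))
    ctrl <- random_regions(sample(2:5, 1))
    out <- exclude_control_overlap(hbd, ctrl,
                                   config = window_config(min_stretch_bp = 0))
    if (nrow(out)) {
      expect_equal(nrow(intersect_regions(
        out |> dplyr::select(chrom, start, end), ctrl)), 0)
    }
  }
})
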