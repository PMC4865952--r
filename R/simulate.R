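# Gene-drop simulation of consanguineous pedigrees with a planted causal
# recessive variant.  Founder haplotypes carry unique labels; each meiosis
# recombines the parental haplotypes with a Poisson number of crossovers at
# uniform positions (uniform genetic map, no interference).  Autozygous
# tracts are the intervals where an individual's two haplotype labels
# coincide, which is the ground truth the mapping stages are tested
# against.

# A haplotype is a list(end = numeric segment ends in (0, L], lab =
# integer founder-haplotype label per segment); segment j covers
# (end[j-1], end[j]].

label_at <- function(hap, pos) {
  hap$lab[findInterval(pos - 1e-9, hap$end) + 1L]
}

merge_runs <- function(ends, labs) {
  if (length(labs) <= 1) return(list(end = ends, lab = labs))
  keep <- c(labs[-length(labs)] != labs[-1], TRUE)
  list(end = ends[keep], lab = labs[keep])
}

# One meiosis on one chromosome.  When force_lab is given, the phase is
# chosen so that the gamete carries that founder label at force_pos
# (conditional gene drop; the phase prior is uniform, so conditioning is
# exact).
meiosis <- function(h1, h2, chrom_len, recomb_rate,
                    force_lab = NA_integer_, force_pos = NA_real_) {
  n_xo <- rpois(1, recomb_rate * chrom_len / 1e6)
  xo <- if (n_xo > 0) sort(runif(n_xo, 0, chrom_len)) else numeric()
  if (!is.na(force_lab)) {
    on1 <- label_at(h1, force_pos) == force_lab
    on2 <- label_at(h2, force_pos) == force_lab
    need <- if (on1 && on2) sample(1:2, 1)
            else if (on1) 1L else if (on2) 2L
            else sample(1:2, 1)
    seg <- sum(xo < force_pos) + 1L
    first <- if (seg %% 2L == 1L) need else 3L - need
  } else {
    first <- sample(1:2, 1)
  }
  if (n_xo == 0) return(if (first == 1L) h1 else h2)
  bounds <- c(0, xo, chrom_len)
  ends <- numeric(0)
  labs <- integer(0)
  for (j in seq_len(length(bounds) - 1L)) {
    src <- if ((j + first) %% 2L == 0L) h1 else h2
    lo <- bounds[j]
    hi <- bounds[j + 1L]
    starts <- c(0, src$end[-length(src$end)])
    idx <- which(src$end > lo & starts < hi)
    ends <- c(ends, pmin(src$end[idx], hi))
    labs <- c(labs, src$lab[idx])
  }
  merge_runs(ends, labs)
}

topo_order <- function(pedigree) {
  placed <- character()
  ids <- pedigree$id
  out <- character()
  while (length(out) < length(ids)) {
    ready <- vapply(seq_along(ids), function(i) {
      !(ids[i] %in% out) &&
        (is.na(pedigree$father_id[i]) || pedigree$father_id[i] %in% out) &&
        (is.na(pedigree$mother_id[i]) || pedigree$mother_id[i] %in% out)
    }, logical(1))
    if (!any(ready)) abort("pedigree is not acyclic")
    out <- c(out, ids[ready])
  }
  out
}

#' Build a pedigree from a consanguinity template
#'
#' Returns a pedigree tibble for one of the built-in templates:
#'
#' * `"first_cousin_single"`: one grandparental couple, two sibling lines
#'   marrying unrelated founders, a first-cousin couple, and two offspring
#'   of that couple (inbreeding coefficient F = 1/16), who are the
#'   designated cases; their parents are the controls.
#' * `"first_cousin_double"`: one grandparental couple with two sibling
#'   lines of two children each, forming two first-cousin couples — three
#'   affected children under the first couple and one under the second
#'   (four cases), with one genotyped unaffected parent from each couple as
#'   the two controls.  This mirrors a family with two couples of
#'   first-cousin marriage, four sequenced affected individuals and two
#'   sequenced unaffected parents.
#' * `"custom"`: pass your own pedigree tibble via `custom`; it is
#'   validated and returned.
#'
#' Template pedigrees carry attributes used by the conditional gene drop:
#' the founder haplotype designated to carry the planted risk allele and
#' the list of transmissions that must pass it down to make every case
#' homozygous.
#'
#' @param template Template name.
#' @param custom Pedigree tibble (only for `template = "custom"`).
#' @return Pedigree tibble (`id`, `father_id`, `mother_id`, `sex`,
#'   `affected`, `role`).
#' @export
#' @examples
#' build_pedigree("first_cousin_double")
build_pedigree <- function(template = c("first_cousin_double",
                                        "first_cousin_single", "custom"),
                           custom = NULL) {
  template <- match.arg(template)
  if (template == "custom") {
    if (is.null(custom)) abort("custom template requires a pedigree tibble")
    validate_pedigree(custom)
    return(custom)
  }
  ped <- if (template == "first_cousin_single") {
    tibble(
      id = c("GP1", "GP2", "S1", "S2", "U1", "U2", "C1", "C2", "P1", "P2"),
      father_id = c(NA, NA, "GP1", "GP1", NA, NA, "S1", "U2", "C1", "C1"),
      mother_id = c(NA, NA, "GP2", "GP2", NA, NA, "U1", "S2", "C2", "C2"),
      sex = c("male", "female", "male", "female", "female", "male",
              "male", "female", "female", "male"),
      affected = c(rep(FALSE, 8), TRUE, TRUE),
      role = c(rep("unused", 6), "control", "control", "case", "case"))
  } else {
    tibble(
      id = c("G1", "G2", "A1", "B1", "FA", "FB", "X1", "X2", "Y1", "Y2",
             "C1", "C2", "C3", "C4"),
      father_id = c(NA, NA, "G1", "G1", NA, NA, "A1", "A1", "FB", "FB",
                    "X1", "X1", "X1", "Y2"),
      mother_id = c(NA, NA, "G2", "G2", NA, NA, "FA", "FA", "B1", "B1",
                    "Y1", "Y1", "Y1", "X2"),
      sex = c("male", "female", "male", "female", "female", "male",
              "male", "female", "female", "male",
              "female", "male", "male", "male"),
      affected = c(rep(FALSE, 10), rep(TRUE, 4)),
      role = c(rep("unused", 6), "unused", "control", "control", "unused",
               rep("case", 4)))
  }
  validate_pedigree(ped)
  if (template == "first_cousin_single") {
    attr(ped, "carrier_founder") <- "GP1"
    attr(ped, "carrier_path") <- tibble(
      parent = c("GP1", "GP1", "S1", "S2", "C1", "C1", "C2", "C2"),
      child = c("S1", "S2", "C1", "C2", "P1", "P2", "P1", "P2"))
  } else {
    attr(ped, "carrier_founder") <- "G1"
    attr(ped, "carrier_path") <- tibble(
      parent = c("G1", "G1", "A1", "A1", "B1", "B1",
                 "X1", "X1", "X1", "Y1", "Y1", "Y1", "X2", "Y2"),
      child = c("A1", "B1", "X1", "X2", "Y1", "Y2",
                "C1", "C2", "C3", "C1", "C2", "C3", "C4", "C4"))
  }
  ped
}

#' Gene-drop simulation down a pedigree
#'
#' Drops uniquely labelled founder haplotypes through every meiosis of the
#' pedigree.  Crossover counts per meiosis and chromosome are Poisson with
#' mean `recomb_rate * chrom_length_bp / 1e6`, at uniform positions.  With
#' `condition_on_causal = TRUE` (and a template pedigree carrying a carrier
#' path), the transmissions on the carrier path are conditioned to pass the
#' carrier founder haplotype at the causal position, making every
#' designated case autozygous there; all other randomness is untouched, so
#' the drop is an exact draw from the conditional distribution.
#'
#' Randomness is taken from the current RNG state; seed via `set.seed()` or
#' use [simulate_family()], which seeds from its configuration.
#'
#' @param pedigree Pedigree tibble, typically from [build_pedigree()].
#' @param config A [sim_config()].
#' @param condition_on_causal Condition the drop on the causal-carrier
#'   transmission path (ignored when the pedigree has no carrier path).
#' @return A list of class `hbd_gene_drop`: `haplotypes` (per individual,
#'   per chromosome, a pair of label-segment haplotypes), `truth_tracts`
#'   (region tibble of autozygous tracts per individual), `founder_haps`
#'   (label bookkeeping), `carrier_lab`, `pedigree`, `config`.
#' @export
gene_drop <- function(pedigree, config = sim_config(),
                      condition_on_causal = TRUE) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  L <- config$chrom_length_bp
  founders <- pedigree$id[is.na(pedigree$father_id) &
                            is.na(pedigree$mother_id)]
  hap_labels <- tibble(
    founder = rep(founders, each = 2),
    hap = rep(1:2, length(founders)),
    lab = seq_len(2L * length(founders)))
  carrier_founder <- attr(pedigree, "carrier_founder")
  carrier_lab <- if (!is.null(carrier_founder)) {
    hap_labels$lab[hap_labels$founder == carrier_founder &
                     hap_labels$hap == 1L]
  } else {
    NA_integer_
  }
  path <- if (condition_on_causal && !is.null(attr(pedigree, "carrier_path")))
    attr(pedigree, "carrier_path") else tibble(parent = character(),
                                               child = character())

  haps <- list()
  for (f in founders) {
    labs <- hap_labels$lab[hap_labels$founder == f]
    haps[[f]] <- lapply(chroms, function(ch) {
      list(list(end = L, lab = labs[1]), list(end = L, lab = labs[2]))
    })
    names(haps[[f]]) <- chroms
  }
  ord <- topo_order(pedigree)
  causal_chrom <- config$causal_chrom
  for (id in setdiff(ord, founders)) {
    i <- match(id, pedigree$id)
    fa <- pedigree$father_id[i]
    mo <- pedigree$mother_id[i]
    haps[[id]] <- lapply(chroms, function(ch) {
      force_fa <- any(path$parent == fa & path$child == id) &&
        ch == causal_chrom
      force_mo <- any(path$parent == mo & path$child == id) &&
        ch == causal_chrom
      g_fa <- meiosis(haps[[fa]][[ch]][[1]], haps[[fa]][[ch]][[2]], L,
                      config$recomb_rate,
                      force_lab = if (force_fa) carrier_lab else NA_integer_,
                      force_pos = config$causal_pos)
      g_mo <- meiosis(haps[[mo]][[ch]][[1]], haps[[mo]][[ch]][[2]], L,
                      config$recomb_rate,
                      force_lab = if (force_mo) carrier_lab else NA_integer_,
                      force_pos = config$causal_pos)
      list(g_fa, g_mo)
    })
    names(haps[[id]]) <- chroms
  }

  t_ch <- character(0); t_s <- numeric(0); t_e <- numeric(0)
  t_id <- character(0)
  for (id in pedigree$id) {
    for (ch in chroms) {
      iv <- autozygous_intervals(haps[[id]][[ch]])
      if (length(iv$start)) {
        t_ch <- c(t_ch, rep(ch, length(iv$start)))
        t_s <- c(t_s, iv$start)
        t_e <- c(t_e, iv$end)
        t_id <- c(t_id, rep(id, length(iv$start)))
      }
    }
  }
  tracts <- finish_region_table(
    tibble(chrom = t_ch, start = t_s, end = t_e, sample_id = t_id),
    provenance = NA_character_)

  structure(list(haplotypes = haps, truth_tracts = tracts,
                 founder_haps = hap_labels, carrier_lab = carrier_lab,
                 pedigree = pedigree, config = config),
            class = "hbd_gene_drop")
}

# Intervals where the two haplotype labels coincide, as bare vectors
# (1-based inclusive integer bp); called once per individual and
# chromosome, so it must stay allocation-light.
autozygous_intervals <- function(pair) {
  bounds <- sort(unique(c(pair[[1]]$end, pair[[2]]$end)))
  lowers <- c(0, bounds[-length(bounds)])
  mids <- (lowers + bounds) / 2
  same <- label_at(pair[[1]], mids) == label_at(pair[[2]], mids)
  if (!any(same)) return(list(start = numeric(0), end = numeric(0)))
  r <- rle(same)
  e_idx <- cumsum(r$lengths)
  s_idx <- e_idx - r$lengths + 1L
  keep <- r$values
  starts <- floor(lowers[s_idx[keep]]) + 1
  ends <- floor(bounds[e_idx[keep]])
  ok <- starts <= ends
  list(start = starts[ok], end = ends[ok])
}

#' Fraction of the genome autozygous per individual
#'
#' @param drop A gene drop from [gene_drop()].
#' @param ids Individuals to report (default: all).
#' @return Named numeric vector of autozygous genome fractions.
#' @export
autozygous_fraction <- function(drop, ids = NULL) {
  ids <- ids %||% drop$pedigree$id
  genome <- drop$config$n_chromosomes * drop$config$chrom_length_bp
  vapply(ids, function(id) {
    t <- drop$truth_tracts[drop$truth_tracts$sample_id == id, , drop = FALSE]
    if (!nrow(t)) 0 else sum(region_length(t)) / genome
  }, numeric(1))
}

#' Assign marker alleles to founder haplotypes and derive genotypes
#'
#' Draws marker positions (uniform per chromosome, deduplicated and sorted)
#' and minor-allele frequencies, assigns alleles independently per founder
#' haplotype per marker, places the causal risk allele on exactly the
#' carrier founder haplotype, and reads each individual's genotypes off the
#' dropped haplotype labels — so genotypes are Mendelian-consistent by
#' construction.
#'
#' @param drop A gene drop from [gene_drop()].
#' @param config A [sim_config()].
#' @param samples `"genotyped"` (cases and controls only, the default) or
#'   `"all"`.
#' @return List with `markers` (site annotation: `chrom`, `pos`, `ref`,
#'   `alt`, `maf`, `is_causal`, `consequence`, `pop_freq`) and `genotypes`
#'   (long tibble `chrom`, `pos`, `sample_id`, `g` with alternate-allele
#'   dosage 0/1/2).
#' @export
assign_alleles <- function(drop, config = sim_config(),
                           samples = c("genotyped", "all")) {
  samples <- match.arg(samples)
  ped <- drop$pedigree
  ids <- if (samples == "all") ped$id
         else ped$id[ped$role %in% c("case", "control")]
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  bases <- c("A", "C", "G", "T")

  marker_list <- lapply(chroms, function(ch) {
    pos <- sort(unique(ceiling(runif(config$n_markers_per_chrom, 0,
                                     config$chrom_length_bp))))
    if (ch == config$causal_chrom) {
      pos <- sort(unique(c(pos, as.integer(config$causal_pos))))
    }
    maf <- runif(length(pos), config$maf_range[1], config$maf_range[2])
    ref <- sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1),
                  character(1))
    csq <- sample(names(config$consequence_probs), length(pos),
                  replace = TRUE, prob = config$consequence_probs)
    tibble(chrom = ch, pos = as.integer(pos), ref = ref, alt = unname(alt),
           maf = maf, is_causal = FALSE, consequence = csq,
           pop_freq = maf)
  })
  names(marker_list) <- chroms
  ci <- which(marker_list[[config$causal_chrom]]$pos ==
                as.integer(config$causal_pos))
  marker_list[[config$causal_chrom]]$is_causal[ci] <- TRUE
  marker_list[[config$causal_chrom]]$consequence[ci] <- "nonsynonymous"
  marker_list[[config$causal_chrom]]$pop_freq[ci] <- NA_real_

  n_labs <- nrow(drop$founder_haps)
  allele_list <- lapply(chroms, function(ch) {
    m <- marker_list[[ch]]
    a <- matrix(rbinom(n_labs * nrow(m), 1, rep(m$maf, each = n_labs)),
                nrow = n_labs)
    causal <- which(m$is_causal)
    if (length(causal)) {
      a[, causal] <- 0L
      a[drop$carrier_lab, causal] <- 1L
    }
    a
  })
  names(allele_list) <- chroms

  geno <- purrr::map(ids, function(id) {
    purrr::map(chroms, function(ch) {
      m <- marker_list[[ch]]
      pair <- drop$haplotypes[[id]][[ch]]
      l1 <- label_at(pair[[1]], m$pos)
      l2 <- label_at(pair[[2]], m$pos)
      a <- allele_list[[ch]]
      tibble(chrom = ch, pos = m$pos, sample_id = id,
             g = a[cbind(l1, seq_len(nrow(m)))] +
               a[cbind(l2, seq_len(nrow(m)))])
    }) |> bind_rows()
  }) |> bind_rows()

  list(markers = bind_rows(marker_list), genotypes = geno)
}

#' Simulate read-level variant calls from true genotypes
#'
#' Per sample and site, depth is Poisson(`mean_depth`) and the
#' alternate-read count is binomial with success probability `base_error`
#' for homozygous-reference, 0.5 for heterozygous and `1 - base_error` for
#' homozygous-alternate genotypes.  Consensus quality is the constant
#' configured value, so quality-gate behaviour is fully controllable.
#'
#' @param alleles Output of [assign_alleles()].
#' @param config A [sim_config()].
#' @return A variant tibble in the layout of [read_variants()].
#' @export
simulate_reads <- function(alleles, config = sim_config()) {
  g <- alleles$genotypes |>
    left_join(alleles$markers, by = c("chrom", "pos"))
  n <- nrow(g)
  depth <- rpois(n, config$mean_depth)
  p <- c(config$base_error, 0.5, 1 - config$base_error)[g$g + 1L]
  alt_reads <- rbinom(n, depth, p)
  g |>
    mutate(vclass = "snp", copy_number = NA_integer_,
           depth = as.integer(depth), alt_reads = as.integer(alt_reads),
           quality = as.numeric(config$quality)) |>
    select(all_of(c("chrom", "pos", "ref", "alt", "vclass", "consequence",
                    "pop_freq", "copy_number", "sample_id", "depth",
                    "alt_reads", "quality"))) |>
    arrange(.data$chrom, .data$pos, .data$alt, .data$sample_id)
}

#' Simulate a complete consanguineous-family exome study
#'
#' Seeds the RNG from `config$seed`, builds the template pedigree, runs the
#' conditional gene drop, assigns alleles and simulates read-level calls.
#' The returned ground truth carries the autozygous tracts of every
#' individual, the planted causal variant and the true genotype dosages,
#' for recovery testing of the mapping and prioritization stages.
#'
#' @param config A [sim_config()].
#' @return A list of class `hbd_sim`: `calls`, `pedigree`, `truth`
#'   (`tracts`, `causal`, `genotypes`), `config`.
#' @export
#' @examples
#' sim <- simulate_family(sim_config(n_chromosomes = 2,
#'                                   n_markers_per_chrom = 200,
#'                                   chrom_length_bp = 10e6,
#'                                   causal_pos = 5e6, seed = 42))
#' dplyr::n_distinct(sim$calls$pos)
simulate_family <- function(config = sim_config()) {
  set.seed(config$seed)
  ped <- build_pedigree(config$pedigree_template)
  drop <- gene_drop(ped, config, condition_on_causal = TRUE)
  alleles <- assign_alleles(drop, config)
  calls <- simulate_reads(alleles, config)
  causal <- alleles$markers |> filter(.data$is_causal)
  structure(list(
    calls = calls,
    pedigree = ped,
    truth = list(tracts = drop$truth_tracts,
                 causal = causal,
                 genotypes = alleles$genotypes,
                 carrier_lab = drop$carrier_lab),
    config = config), class = "hbd_sim")
}

#' True case-shared autozygous segments
#'
#' Intersects the ground-truth autozygous tracts of every case, optionally
#' keeping only segments of at least `min_bp` — the reference against which
#' HBD recovery is measured.
#'
#' @param sim An `hbd_sim` from [simulate_family()].
#' @param min_bp Minimum segment length to keep.
#' @return Region tibble.
#' @export
true_shared_segments <- function(sim, min_bp = 0) {
  cases <- sim$pedigree$id[sim$pedigree$role == "case"]
  per_case <- lapply(cases, function(s) {
    sim$truth$tracts[sim$truth$tracts$sample_id == s, , drop = FALSE]
  })
  shared <- purrr::reduce(lapply(per_case, union_regions), intersect_regions)
  shared[region_length(shared) >= min_bp, , drop = FALSE]
}
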