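#' Configure a sex-biased-migration simulation
#'
#' Forward-time Wright-Fisher island model with separate sexes and
#' uniparental inheritance: every offspring inherits its mtDNA sequence
#' from a mother drawn uniformly within its deme, male offspring inherit
#' the MSY string from a father drawn the same way, and adults migrate
#' between demes with sex-specific probabilities before reproducing.
#'
#' Residence presets encode postmarital residence as a migration asymmetry:
#' under matrilocality husbands relocate, so male migration exceeds female
#' migration (`m_male > m_female`); patrilocality is the mirror; the
#' neutral preset sets both equal. Explicit `m_female`/`m_male` values
#' override the preset but must respect its ordering.
#'
#' @param n_demes Number of demes (default 10).
#' @param females_per_deme,males_per_deme Individuals of each sex per deme
#'   (defaults 50, 50).
#' @param residence_mode `"matrilocal"`, `"patrilocal"` or `"neutral"`.
#' @param m_female,m_male Per-generation migration probabilities in
#'   `[0, 1]`; defaults come from the preset (0.02/0.2 matrilocal, 0.2/0.02
#'   patrilocal, 0.1/0.1 neutral).
#' @param mu_mt,mu_y Per-site per-generation mutation rates (default 1e-4).
#' @param L_mt,L_y Sequence lengths in sites (default 1000).
#' @param generations Generations to evolve (default 200).
#' @param sample_size Samples drawn per deme per sex at the end (default
#'   20).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_demes = 10L,
                              females_per_deme = 50L,
                              males_per_deme = 50L,
                              residence_mode = c("neutral", "matrilocal", "patrilocal"),
                              m_female = NULL,
                              m_male = NULL,
                              mu_mt = 1e-4,
                              mu_y = 1e-4,
                              L_mt = 1000L,
                              L_y = 1000L,
                              generations = 200L,
                              sample_size = 20L,
                              seed = 1L) {
  residence_mode <- match.arg(residence_mode)
  preset <- switch(residence_mode,
                   matrilocal = c(f = 0.02, m = 0.2),
                   patrilocal = c(f = 0.2, m = 0.02),
                   neutral = c(f = 0.1, m = 0.1))
  m_female <- m_female %||% unname(preset["f"])
  m_male <- m_male %||% unname(preset["m"])
  cfg <- list(n_demes = as.integer(n_demes),
              females_per_deme = as.integer(females_per_deme),
              males_per_deme = as.integer(males_per_deme),
              residence_mode = residence_mode,
              m_female = m_female, m_male = m_male,
              mu_mt = mu_mt, mu_y = mu_y,
              L_mt = as.integer(L_mt), L_y = as.integer(L_y),
              generations = as.integer(generations),
              sample_size = as.integer(sample_size),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_demes >= 1L, females_per_deme >= 1L, males_per_deme >= 1L,
              generations >= 0L, L_mt >= 1L, L_y >= 1L, sample_size >= 1L)
    if (any(c(m_female, m_male, mu_mt, mu_y) < 0) ||
        any(c(m_female, m_male) > 1)) {
      stop("rates must lie in [0, 1]", call. = FALSE)
    }
  })
  if (residence_mode == "matrilocal" && !(cfg$m_male > cfg$m_female)) {
    stop("matrilocal preset requires m_male > m_female", call. = FALSE)
  }
  if (residence_mode == "patrilocal" && !(cfg$m_female > cfg$m_male)) {
    stop("patrilocal preset requires m_female > m_male", call. = FALSE)
  }
  if (cfg$sample_size > cfg$females_per_deme || cfg$sample_size > cfg$males_per_deme) {
    stop("sample_size exceeds deme size for at least one sex", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# mutate integer-coded sequences in place: draw the number of mutation
# events binomially, then scatter them over (individual, site) cells.
mutate_matrix <- function(mat, mu, n_states) {
  n_cells <- length(mat)
  if (n_cells == 0L || mu <= 0) return(mat)
  n_mut <- stats::rbinom(1L, n_cells, mu)
  if (n_mut == 0L) return(mat)
  cells <- sample.int(n_cells, n_mut, replace = TRUE)
  if (n_states == 2L) {
    mat[cells] <- 1L - mat[cells]
  } else {
    # new base uniform among the other n_states - 1
    shift <- sample.int(n_states - 1L, n_mut, replace = TRUE)
    mat[cells] <- (mat[cells] - 1L + shift) %% n_states + 1L
  }
  mat
}

migrate <- function(deme, m, n_demes) {
  if (m <= 0 || n_demes < 2L) return(deme)
  movers <- which(stats::runif(length(deme)) < m)
  if (length(movers) == 0L) return(deme)
  # uniform destination among the other demes
  dest <- sample.int(n_demes - 1L, length(movers), replace = TRUE)
  deme[movers] <- ifelse(dest >= deme[movers], dest + 1L, dest)
  deme
}

draw_parent <- function(pool, n_offspring) {
  # rescue: if migration emptied a deme of one sex, draw metapopulation-wide
  if (length(pool) == 0L) return(integer(0))
  pool[sample.int(length(pool), n_offspring, replace = TRUE)]
}

#' Simulate multi-deme uniparental data under sex-specific migration
#'
#' Runs the forward-time model of [simulation_config()]: each generation,
#' adults migrate (island model, uniform destination, one event per
#' individual), then each deme produces a fixed number of offspring of
#' each sex whose mothers and fathers are drawn uniformly among the deme's
#' post-migration residents, and finally offspring sequences mutate
#' (per-site Bernoulli substitutions: uniform among the other three bases
#' for mtDNA, allele flips for the biallelic MSY sites). If migration
#' leaves a deme without residents of one sex, parents of that sex are
#' drawn metapopulation-wide for that generation.
#'
#' Founders carry independent random sequences and a lineage label; labels
#' are inherited with the marker, so with mutation rate 0 the haplotype
#' partition equals the founder-lineage partition. Lineage labels serve as
#' pseudo-haplogroups downstream.
#'
#' At the end, `sample_size` females and `sample_size` males are drawn
#' without replacement per deme. The mtDNA alignment covers both sexes;
#' the MSY genotype table covers males only (alleles `A`/`G`).
#'
#' @param cfg A `simulation_config`.
#' @return A `simulated_dataset`: `mt_alignment` (an `alignment_set`),
#'   `y_genotypes` (a `genotype_table`), `metadata`, `mt_haplogroups` and
#'   `y_haplogroups` (pseudo-haplogroup assignment data frames), and
#'   `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  nd <- cfg$n_demes
  nf <- cfg$females_per_deme * nd
  nm <- cfg$males_per_deme * nd

  f_mt <- matrix(sample.int(4L, nf * cfg$L_mt, replace = TRUE), nf, cfg$L_mt)
  m_mt <- matrix(sample.int(4L, nm * cfg$L_mt, replace = TRUE), nm, cfg$L_mt)
  m_y <- matrix(sample.int(2L, nm * cfg$L_y, replace = TRUE) - 1L, nm, cfg$L_y)
  f_deme <- rep(seq_len(nd), each = cfg$females_per_deme)
  m_deme <- rep(seq_len(nd), each = cfg$males_per_deme)
  f_mtlin <- paste0("MT", seq_len(nf))          # founders: females seed mt lineages
  m_mtlin <- paste0("MTm", seq_len(nm))         # male founders' mt dies with them
  m_ylin <- paste0("Y", seq_len(nm))

  for (g in seq_len(cfg$generations)) {
    f_deme <- migrate(f_deme, cfg$m_female, nd)
    m_deme <- migrate(m_deme, cfg$m_male, nd)
    mothers <- integer(0)
    fathers <- integer(0)
    for (d in seq_len(nd)) {
      fpool <- which(f_deme == d)
      mpool <- which(m_deme == d)
      if (length(fpool) == 0L) fpool <- seq_len(nf)
      if (length(mpool) == 0L) mpool <- seq_len(nm)
      mothers <- c(mothers,
                   draw_parent(fpool, cfg$females_per_deme + cfg$males_per_deme))
      fathers <- c(fathers, draw_parent(mpool, cfg$males_per_deme))
    }
    # offspring layout per deme: females first, then males
    is_female <- unlist(lapply(seq_len(nd), function(d) {
      c(rep(TRUE, cfg$females_per_deme), rep(FALSE, cfg$males_per_deme))
    }))
    f_idx <- mothers[is_female]
    m_idx <- mothers[!is_female]
    new_f_mt <- f_mt[f_idx, , drop = FALSE]
    new_m_mt <- f_mt[m_idx, , drop = FALSE]
    new_m_y <- m_y[fathers, , drop = FALSE]
    new_f_lin <- f_mtlin[f_idx]
    new_m_lin <- f_mtlin[m_idx]
    new_y_lin <- m_ylin[fathers]

    f_mt <- mutate_matrix(new_f_mt, cfg$mu_mt, 4L)
    m_mt <- mutate_matrix(new_m_mt, cfg$mu_mt, 4L)
    m_y <- mutate_matrix(new_m_y, cfg$mu_y, 2L)
    f_mtlin <- new_f_lin
    m_mtlin <- new_m_lin
    m_ylin <- new_y_lin
    f_deme <- rep(seq_len(nd), each = cfg$females_per_deme)
    m_deme <- rep(seq_len(nd), each = cfg$males_per_deme)
  }

  # sample without replacement per deme per sex
  samp_f <- unlist(lapply(seq_len(nd), function(d) {
    pool <- which(f_deme == d)
    sort(pool[sample.int(length(pool), cfg$sample_size)])
  }))
  samp_m <- unlist(lapply(seq_len(nd), function(d) {
    pool <- which(m_deme == d)
    sort(pool[sample.int(length(pool), cfg$sample_size)])
  }))

  bases <- c("A", "C", "G", "T")
  f_ids <- sprintf("D%02dF%03d", f_deme[samp_f], stats::ave(samp_f, f_deme[samp_f], FUN = seq_along))
  m_ids <- sprintf("D%02dM%03d", m_deme[samp_m], stats::ave(samp_m, m_deme[samp_m], FUN = seq_along))
  mt_mat <- rbind(
    matrix(bases[f_mt[samp_f, , drop = FALSE]], nrow = length(samp_f)),
    matrix(bases[m_mt[samp_m, , drop = FALSE]], nrow = length(samp_m))
  )
  rownames(mt_mat) <- c(f_ids, m_ids)
  alleles <- c("A", "G")
  y_mat <- matrix(alleles[m_y[samp_m, , drop = FALSE] + 1L], nrow = length(samp_m))

  meta <- as_sample_metadata(data.frame(
    sample_id = c(f_ids, m_ids),
    population = sprintf("deme%02d", c(f_deme[samp_f], m_deme[samp_m])),
    language_family = cfg$residence_mode,
    country = "sim",
    dataset_tag = "sim",
    stringsAsFactors = FALSE
  ))
  structure(
    list(
      mt_alignment = new_alignment_set(mt_mat),
      y_genotypes = new_genotype_table(m_ids, seq_len(cfg$L_y), y_mat),
      metadata = meta,
      mt_haplogroups = data.frame(
        sample_id = c(f_ids, m_ids),
        haplogroup = c(f_mtlin[samp_f], m_mtlin[samp_m]),
        stringsAsFactors = FALSE),
      y_haplogroups = data.frame(
        sample_id = m_ids, haplogroup = m_ylin[samp_m],
        stringsAsFactors = FALSE),
      config = cfg
    ),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "<simulated_dataset> %d demes, %d mtDNA samples x %d sites, %d MSY samples x %d sites (%s, seed %d)\n",
    x$config$n_demes, nrow(x$mt_alignment$seqs), ncol(x$mt_alignment$seqs),
    length(x$y_genotypes$sample_ids), length(x$y_genotypes$site_positions),
    x$config$residence_mode, x$config$seed
  ))
  invisible(x)
}

within_deme_H <- function(ht) {
  n <- rowSums(ht$counts)
  mean(vapply(rownames(ht$counts)[n >= 2], function(p) {
    haplotype_diversity(ht$counts[p, ])$H
  }, numeric(1L)))
}

#' Matrilocal vs patrilocal diversity contrast
#'
#' Runs mirror-image matrilocal and patrilocal simulations (sex migration
#' rates swapped, everything else equal) in replicate pairs and compares
#' mean within-deme haplotype diversity for the maternal (mtDNA) and
#' paternal (MSY) marker. Under matrilocality, relocating husbands mix
#' paternal lineages among demes, so within-deme MSY diversity is expected
#' to exceed the patrilocal mirror's, and conversely for mtDNA.
#'
#' @param cfg_base A `simulation_config`; its migration rates define the
#'   matrilocal preset (`m_male > m_female` enforced by swapping if
#'   needed), and the mirror swaps them.
#' @param replicates Number of replicate pairs (>= 10; default 20).
#' @param n_boot Bootstrap resamples for the difference-of-means interval.
#' @return A `residence_contrast` data frame with one row per marker:
#'   replicate means under each preset, difference of means, a 95%
#'   bootstrap interval for the difference, and the fraction of replicate
#'   pairs in which the matrilocal run had the higher within-deme
#'   diversity.
#' @export
residence_contrast <- function(cfg_base, replicates = 20L, n_boot = 1000L) {
  stopifnot(inherits(cfg_base, "simulation_config"))
  if (replicates < 10L) stop("need at least 10 replicate pairs", call. = FALSE)
  mf <- min(cfg_base$m_female, cfg_base$m_male)
  mm <- max(cfg_base$m_female, cfg_base$m_male)
  res <- array(NA_real_, c(replicates, 2L, 2L),
               dimnames = list(NULL, c("matrilocal", "patrilocal"), c("mt", "y")))
  for (r in seq_len(replicates)) {
    for (mode in c("matrilocal", "patrilocal")) {
      cfg <- cfg_base
      cfg$residence_mode <- mode
      cfg$m_female <- if (mode == "matrilocal") mf else mm
      cfg$m_male <- if (mode == "matrilocal") mm else mf
      cfg$seed <- (cfg_base$seed + 7919L * r +
                     if (mode == "matrilocal") 0L else 104729L) %% .Machine$integer.max
      sim <- simulate_dataset(cfg)
      res[r, mode, "mt"] <- within_deme_H(collapse_haplotypes(sim$mt_alignment, sim$metadata))
      res[r, mode, "y"] <- within_deme_H(genotype_haplotypes(sim$y_genotypes, sim$metadata))
    }
  }
  set.seed(cfg_base$seed)
  summarize <- function(marker) {
    diff <- res[, "matrilocal", marker] - res[, "patrilocal", marker]
    boot <- replicate(n_boot, mean(diff[sample.int(replicates, replace = TRUE)]))
    data.frame(
      marker = marker,
      mean_matrilocal = mean(res[, "matrilocal", marker]),
      mean_patrilocal = mean(res[, "patrilocal", marker]),
      diff_of_means = mean(diff),
      boot_lower = unname(stats::quantile(boot, 0.025)),
      boot_upper = unname(stats::quantile(boot, 0.975)),
      prop_matrilocal_higher = mean(diff > 0),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(summarize("mt"), summarize("y"))
  attr(out, "replicate_values") <- res
  class(out) <- c("residence_contrast", "data.frame")
  out
}

#' Write deterministic miniature fixture files
#'
#' Generates the small input files used throughout the documentation and
#' tests: `toy_alignment` (4 short aligned sequences + metadata),
#' `toy_genotypes` (4 samples x 5 sites of which 2 contain a missing
#' call), `ma_like` (a genotype table of 6 samples carrying one identical
#' haplotype, the fixed-for-one-lineage population case), and
#' `paper_mask_panel` (a gapless, N-free 16569-column alignment panel on
#' which the default mask removes exactly its 81 positions).
#'
#' @param kind One of `"toy_alignment"`, `"toy_genotypes"`, `"ma_like"`,
#'   `"paper_mask_panel"`.
#' @param seed Integer seed.
#' @param dir Output directory (default a fresh tempdir subdirectory).
#' @return Named list of written file paths, invisibly.
#' @export
make_fixtures <- function(kind, seed = 1L, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  paths <- switch(
    kind,
    toy_alignment = {
      seqs <- matrix(sample(bases, 4L * 12L, replace = TRUE), 4L, 12L,
                     dimnames = list(paste0("S", 1:4), NULL))
      seqs[2L, ] <- seqs[1L, ]  # one shared haplotype
      aln <- new_alignment_set(seqs)
      fa <- file.path(dir, "toy_alignment.fasta")
      write_fasta_alignment(aln, fa)
      mt <- file.path(dir, "toy_alignment_meta.tsv")
      utils::write.table(
        data.frame(sample_id = paste0("S", 1:4),
                   population = c("A", "A", "A", "B")),
        mt, sep = "\t", quote = FALSE, row.names = FALSE)
      list(alignment = fa, metadata = mt)
    },
    toy_genotypes = {
      calls <- matrix(sample(c("A", "G"), 4L * 5L, replace = TRUE), 4L, 5L)
      calls[1L, 2L] <- "N"
      calls[3L, 4L] <- "N"
      g <- new_genotype_table(paste0("S", 1:4), c(100L, 200L, 300L, 400L, 500L), calls)
      gt <- file.path(dir, "toy_genotypes.tsv")
      write_genotype_table(g, gt)
      mt <- file.path(dir, "toy_genotypes_meta.tsv")
      utils::write.table(
        data.frame(sample_id = paste0("S", 1:4),
                   population = c("A", "A", "B", "B")),
        mt, sep = "\t", quote = FALSE, row.names = FALSE)
      list(genotypes = gt, metadata = mt)
    },
    ma_like = {
      hap <- sample(c("A", "G"), 10L, replace = TRUE)
      calls <- matrix(rep(hap, each = 6L), 6L, 10L)
      g <- new_genotype_table(sprintf("Ma%02d", 1:6),
                              seq(1000L, by = 1000L, length.out = 10L), calls)
      gt <- file.path(dir, "ma_like_genotypes.tsv")
      write_genotype_table(g, gt)
      mt <- file.path(dir, "ma_like_meta.tsv")
      utils::write.table(
        data.frame(sample_id = sprintf("Ma%02d", 1:6), population = "Ma"),
        mt, sep = "\t", quote = FALSE, row.names = FALSE)
      list(genotypes = gt, metadata = mt)
    },
    paper_mask_panel = {
      L <- 16569L
      seqs <- matrix(sample(bases, 3L * L, replace = TRUE), 3L, L,
                     dimnames = list(c("REF", "P1", "P2"), NULL))
      aln <- new_alignment_set(seqs)
      fa <- file.path(dir, "mask_panel.fasta")
      write_fasta_alignment(aln, fa)
      mt <- file.path(dir, "mask_panel_meta.tsv")
      utils::write.table(
        data.frame(sample_id = c("REF", "P1", "P2"), population = "panel"),
        mt, sep = "\t", quote = FALSE, row.names = FALSE)
      list(alignment = fa, metadata = mt)
    },
    stop("unknown fixture kind '", kind, "'", call. = FALSE)
  )
  invisible(paths)
}
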