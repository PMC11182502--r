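#' Build a pipeline configuration
#'
#' @param marker `"mtdna"` (FASTA alignment input) or `"msy"` (genotype
#'   table input).
#' @param alignment,genotypes Input path for the marker's data file.
#' @param metadata Path to the sample metadata TSV.
#' @param haplogroups Optional path to a haplogroup assignment TSV; when
#'   given, a correspondence analysis of haplogroup frequencies is run.
#' @param reference_id Optional reference record for mtDNA coordinates.
#' @param mask_file Optional mask TSV; default is the packaged mtDNA mask
#'   for `marker = "mtdna"`, no mask for `"msy"`.
#' @param keep_n_columns Keep N-containing alignment columns? Default
#'   `FALSE`.
#' @param missing_token Missing-call token for genotype tables.
#' @param n_permutations Permutations for the PhiST tests.
#' @param nmds_dims NMDS dimensions.
#' @param seed Integer seed recorded in the manifest and used for all
#'   stochastic stages.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(marker = c("mtdna", "msy"),
                            alignment = NULL, genotypes = NULL,
                            metadata, haplogroups = NULL,
                            reference_id = NULL, mask_file = NULL,
                            keep_n_columns = FALSE, missing_token = "N",
                            n_permutations = 1000L, nmds_dims = 2L,
                            seed = 1L, out_dir) {
  marker <- match.arg(marker)
  cfg <- list(marker = marker, alignment = alignment, genotypes = genotypes,
              metadata = metadata, haplogroups = haplogroups,
              reference_id = reference_id, mask_file = mask_file,
              keep_n_columns = keep_n_columns, missing_token = missing_token,
              n_permutations = as.integer(n_permutations),
              nmds_dims = as.integer(nmds_dims), seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$marker == "mtdna") {
    if (is.null(cfg$alignment)) {
      stop("marker 'mtdna' requires an 'alignment' FASTA input", call. = FALSE)
    }
    if (!is.null(cfg$genotypes)) {
      stop("marker 'mtdna' takes a FASTA alignment, not a genotype table",
           call. = FALSE)
    }
  } else {
    if (is.null(cfg$genotypes)) {
      stop("marker 'msy' requires a 'genotypes' table input", call. = FALSE)
    }
    if (!is.null(cfg$alignment)) {
      stop("marker 'msy' takes a genotype table, not a FASTA alignment",
           call. = FALSE)
    }
  }
  for (p in c(cfg$alignment, cfg$genotypes, cfg$metadata, cfg$haplogroups,
              cfg$mask_file)) {
    if (!file.exists(p)) stop("input file does not exist: ", p, call. = FALSE)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Accepts the same fields as [pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full uniparental-marker analysis
#'
#' Orchestrates the stages in order: read inputs; (mtDNA) mask the
#' alignment / (MSY) drop sites with missing calls; collapse haplotypes;
#' per-population diversity summary; haplotype sharing matrix; pairwise
#' PhiST with permutation p-values; NMDS of the PhiST matrix; and, when
#' haplogroup assignments are supplied, correspondence analysis of the
#' haplogroup frequency table. All results are written as TSV (matrices,
#' coordinates) plus a JSON manifest recording package version,
#' parameters, seed, effective length and filter counts, so a run is fully
#' reproducible from the manifest. Rerunning with the same configuration
#' gives identical outputs.
#'
#' @param cfg A `pipeline_config` (or path to a YAML file).
#' @return The output directory, invisibly; side effect: files
#'   `diversity.tsv`, `sharing.tsv`, `phist.tsv`, `phist_pvalues.tsv`,
#'   `nmds_coords.tsv`, optionally `ca_rows.tsv`/`ca_columns.tsv`, and
#'   `manifest.json` under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- read_metadata(cfg$metadata)
  log_msg <- function(...) message("[uniparental] ", sprintf(...))

  if (cfg$marker == "mtdna") {
    aln <- read_fasta_alignment(cfg$alignment, reference_id = cfg$reference_id)
    log_msg("read %d aligned sequences x %d columns", nrow(aln$seqs), ncol(aln$seqs))
    mask <- if (!is.null(cfg$mask_file)) read_mask(cfg$mask_file) else default_mtdna_mask()
    masked <- apply_mask(aln, mask, drop_n_columns = !cfg$keep_n_columns)
    log_msg("masked %d columns; effective length %d",
            nrow(masked$removed_columns), masked$effective_length)
    x <- masked
    filter_info <- list(removed_columns = nrow(masked$removed_columns),
                        effective_length = masked$effective_length)
  } else {
    g <- read_genotype_table(cfg$genotypes, missing_token = cfg$missing_token)
    n0 <- length(g$site_positions)
    g <- drop_missing_sites(g)
    log_msg("retained %d of %d sites after missing-call filter",
            length(g$site_positions), n0)
    x <- g
    filter_info <- list(sites_input = n0, sites_retained = length(g$site_positions))
  }

  ht <- if (cfg$marker == "mtdna") collapse_haplotypes(x, meta) else genotype_haplotypes(x, meta)
  log_msg("%d haplotypes across %d samples in %d populations",
          length(ht$haplotype_ids), sum(ht$counts), nrow(ht$counts))

  div <- diversity_summary(x, meta)
  utils::write.table(div, file.path(cfg$out_dir, "diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sm <- sharing_matrix(ht)
  write_matrix(unclass(sm), file.path(cfg$out_dir, "sharing.tsv"))

  pr <- pairwise_phist(x, meta, n_permutations = cfg$n_permutations, seed = cfg$seed)
  write_matrix(pr$phi_st, file.path(cfg$out_dir, "phist.tsv"))
  write_matrix(pr$p_values, file.path(cfg$out_dir, "phist_pvalues.tsv"))

  ord <- nmds(phist_for_nmds(pr), k = cfg$nmds_dims)
  coords <- cbind(ord$points, stress_pct = ord$stress)
  write_matrix(coords, file.path(cfg$out_dir, "nmds_coords.tsv"))
  log_msg("NMDS stress %.3f%% in %d dimensions", ord$stress, cfg$nmds_dims)

  ca_inertia <- NULL
  if (!is.null(cfg$haplogroups)) {
    hg <- read_haplogroups(cfg$haplogroups)
    ft <- frequency_table(hg, meta)
    ca <- correspondence_analysis(ft$counts)
    write_matrix(ca$points, file.path(cfg$out_dir, "ca_rows.tsv"))
    write_matrix(ca$column_points, file.path(cfg$out_dir, "ca_columns.tsv"))
    ca_inertia <- as.list(ca$inertia_per_axis)
    log_msg("CA total inertia %.4f over %d axes", ca$total_inertia, ca$k)
  }

  manifest <- list(
    package = "uniparental",
    version = as.character(utils::packageVersion("uniparental")),
    marker = cfg$marker,
    parameters = cfg[c("reference_id", "mask_file", "keep_n_columns",
                       "missing_token", "n_permutations", "nmds_dims")],
    seed = cfg$seed,
    filter = filter_info,
    n_haplotypes = length(ht$haplotype_ids),
    n_samples = sum(ht$counts),
    populations = rownames(ht$counts),
    nmds_stress_pct = ord$stress,
    ca_inertia_per_axis = ca_inertia
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(cfg$out_dir)
}
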