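#' Per-population haplogroup frequency table
#'
#' Tabulates haplogroup assignments into a populations-by-haplogroups count
#' matrix. Star labels (paragroups such as `R*`: assigned to the clade but
#' to none of its defined subclades) are kept distinct from their non-star
#' parents. Every sample in the metadata must be assigned, and every
#' assigned sample must be in the metadata.
#'
#' @param assignments Data frame with columns `sample_id` and `haplogroup`
#'   (see [read_haplogroups()]).
#' @param meta Sample metadata.
#' @return A `haplogroup_freq_table`: list with `counts` (populations x
#'   haplogroups), `frequencies` (rows summing to 1), `overall_counts` and
#'   `overall_frequencies`.
#' @export
frequency_table <- function(assignments, meta) {
  meta <- as_sample_metadata(as.data.frame(meta))
  unassigned <- setdiff(meta$sample_id, assignments$sample_id)
  if (length(unassigned) > 0L) {
    stop("sample(s) without haplogroup assignment: ",
         paste(unassigned, collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(assignments$sample_id, meta$sample_id)
  if (length(orphan) > 0L) {
    stop("assigned sample(s) absent from metadata: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  pop <- stats::setNames(meta$population, meta$sample_id)[assignments$sample_id]
  pops <- unique(meta$population)
  labels <- unique(assignments$haplogroup)
  counts <- matrix(0L, length(pops), length(labels),
                   dimnames = list(pops, labels))
  tab <- table(factor(pop, levels = pops),
               factor(assignments$haplogroup, levels = labels))
  counts[] <- as.integer(tab)
  new_haplogroup_freq_table(counts)
}

new_haplogroup_freq_table <- function(counts) {
  overall <- colSums(counts)
  structure(
    list(counts = counts,
         frequencies = counts / rowSums(counts),
         overall_counts = overall,
         overall_frequencies = overall / sum(overall)),
    class = "haplogroup_freq_table"
  )
}

#' @export
print.haplogroup_freq_table <- function(x, ...) {
  cat(sprintf("<haplogroup_freq_table> %d populations x %d haplogroups (%d samples)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Singleton haplogroup statistics
#'
#' A singleton is a haplogroup carried by exactly one sample overall.
#'
#' @param t A `haplogroup_freq_table`.
#' @return List with `n_haplogroups`, `n_singletons`, and `pct` (percent of
#'   haplogroups that are singletons, rounded to 2 decimals).
#' @export
singleton_stats <- function(t) {
  stopifnot(inherits(t, "haplogroup_freq_table"))
  if (ncol(t$counts) == 0L) stop("empty haplogroup table", call. = FALSE)
  nh <- ncol(t$counts)
  ns <- sum(t$overall_counts == 1L)
  list(n_haplogroups = nh, n_singletons = ns, pct = round(100 * ns / nh, 2))
}

#' Roll fine haplogroup labels up to major groups
#'
#' Maps each fine label to a major group by longest-prefix match against a
#' rule set. The trailing star is stripped before matching (so `R*` matches
#' a rule `R`); whether the original label was a paragroup is recorded in
#' the `star_labels` attribute. Labels matched by no rule are collected
#' under `"other"` with a warning. Totals are conserved exactly.
#'
#' @param t A `haplogroup_freq_table`.
#' @param rules Data frame with columns `prefix` and `major`; two rules may
#'   not share a prefix (ambiguity is an error).
#' @return A `haplogroup_freq_table` over the major labels.
#' @export
rollup <- function(t, rules) {
  stopifnot(inherits(t, "haplogroup_freq_table"))
  if (!all(c("prefix", "major") %in% names(rules))) {
    stop("rules need columns 'prefix' and 'major'", call. = FALSE)
  }
  if (anyDuplicated(rules$prefix)) {
    stop("ambiguous rule set: duplicated prefix(es) ",
         paste(unique(rules$prefix[duplicated(rules$prefix)]), collapse = ", "),
         call. = FALSE)
  }
  fine <- colnames(t$counts)
  bare <- sub("\\*$", "", fine)
  major <- vapply(bare, function(lbl) {
    hits <- rules$prefix[startsWith(lbl, rules$prefix)]
    if (length(hits) == 0L) return(NA_character_)
    rules$major[rules$prefix == hits[which.max(nchar(hits))]]
  }, character(1L))
  if (anyNA(major)) {
    warning("label(s) matched by no rule collected under 'other': ",
            paste(fine[is.na(major)], collapse = ", "), call. = FALSE)
    major[is.na(major)] <- "other"
  }
  majors <- unique(major)
  out <- matrix(0L, nrow(t$counts), length(majors),
                dimnames = list(rownames(t$counts), majors))
  for (m in majors) {
    out[, m] <- as.integer(rowSums(t$counts[, major == m, drop = FALSE]))
  }
  res <- new_haplogroup_freq_table(out)
  attr(res, "star_labels") <- fine[grepl("\\*$", fine)]
  attr(res, "rollup_map") <- stats::setNames(major, fine)
  res
}

#' Packaged major-group rollup rules
#'
#' Reads the rollup rule file shipped with the package for the given
#' marker. These rule sets are a reconstruction of common major-group
#' binnings (mtDNA macro-haplogroups M, B, F, ...; MSY O1b, O2a, ...), not
#' an authoritative nomenclature.
#'
#' @param marker `"mtdna"` or `"msy"`.
#' @return Data frame of rollup rules (`prefix`, `major`).
#' @export
default_rollup_rules <- function(marker = c("mtdna", "msy")) {
  marker <- match.arg(marker)
  path <- system.file("extdata", paste0("rollup_", marker, ".tsv"),
                      package = "uniparental", mustWork = TRUE)
  utils::read.delim(path, colClasses = "character")
}
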