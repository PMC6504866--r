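#' Run the full reference-library analysis pipeline
#'
#' Orchestrates: read -> (corrections) -> length filter -> crop -> haplotype
#' collapse -> distance matrix -> species summaries -> delimitation
#' (internal barcode-gap scan and/or ingested partitions) -> misidentification
#' screen -> congruence -> sampling-effort regression, writing every table
#' plus a JSON manifest to the output directory. Identical config and seed
#' produce identical artifacts.
#'
#' @param config a list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{fasta}{input aligned FASTA (required).}
#'     \item{outdir}{output directory (required; created).}
#'     \item{model}{"K2P" (default), "TN93" or "p".}
#'     \item{min_bp}{length filter (default 486); \code{allowlist}: exempt ids.}
#'     \item{crop}{optional list(start, width) alignment window.}
#'     \item{corrections}{optional correction TSV applied before analysis.}
#'     \item{delimit}{optional list(pmids, X) for the internal barcode-gap
#'       scan (defaults used when entries missing).}
#'     \item{partitions}{optional named character vector of external
#'       partition TSV paths (GMYC/PTP/RESL outputs).}
#'     \item{misid}{optional list(t_self, t_other, exclude_flagged).}
#'     \item{bootstrap_reps}{replicates for summary SEs (default 0 = skip).}
#'     \item{seed}{integer seed for bootstrap randomness.}
#'   }
#'   At least one of \code{delimit} / \code{partitions} must be present.
#' @return the manifest, invisibly (also written as \code{manifest.json}).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  need <- function(x, what) if (is.null(x)) stop("config missing '", what, "'") else x
  fasta <- need(config$fasta, "fasta")
  outdir <- need(config$outdir, "outdir")
  if (is.null(config$delimit) && is.null(config$partitions))
    stop("no delimitation source: supply 'delimit' grid and/or 'partitions'")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  model <- if (is.null(config$model)) "K2P" else config$model
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("barcodegap")),
    r_version = as.character(getRversion()),
    seed = seed, model = model,
    inputs = list(fasta = unname(tools::md5sum(fasta))))

  aln <- stage("read", read_alignment(fasta))
  manifest$counts <- list(input = length(aln))

  if (!is.null(config$corrections)) {
    corr <- stage("corrections", read_corrections(config$corrections))
    aln <- stage("corrections", apply_corrections(aln, corr))
    manifest$counts$corrected <- nrow(corr)
  }

  min_bp <- if (is.null(config$min_bp)) 486 else config$min_bp
  allow <- if (is.null(config$allowlist)) character() else config$allowlist
  aln <- stage("length_filter", apply_length_filter(aln, min_bp, allow))
  manifest$counts$post_filter <- length(aln)

  if (!is.null(config$crop))
    aln <- stage("crop", crop_alignment(aln, config$crop$start, config$crop$width))
  else if (length(unique(nchar(aln$seqs))) > 1L) {
    w <- min(nchar(aln$seqs))
    aln <- stage("crop", crop_alignment(aln, 1L, w))
    manifest$crop_width <- w
  }

  col <- stage("collapse", collapse_haplotypes(aln))
  hap <- col$alignment
  sp_ok <- assert_species_preserved(aln, hap)
  if (!isTRUE(sp_ok))
    stop("pipeline stage 'collapse' failed: species eliminated: ",
         paste(attr(sp_ok, "missing"), collapse = ", "))
  write_haplotype_map(col$map, file.path(outdir, "haplotype_map.tsv"))
  manifest$counts$haplotypes <- length(hap)

  dm <- stage("distances",
              suppressWarnings(distance_matrix(hap, model)))
  write_distance_matrix(dm, file.path(outdir, "distance_matrix.tsv"))

  mis_cfg <- config$misid
  t_self <- if (is.null(mis_cfg$t_self)) 0.05 else mis_cfg$t_self
  t_other <- if (is.null(mis_cfg$t_other)) 0.02 else mis_cfg$t_other
  flags <- stage("misid_screen",
                 flag_misidentifications(dm, hap$labels, t_self, t_other))
  write_misid_flags(flags, file.path(outdir, "misid_flags.tsv"))
  manifest$counts$flagged <- nrow(flags)
  exclude <- if (is.null(mis_cfg$exclude_flagged) || isTRUE(mis_cfg$exclude_flagged))
    flags$id else character()

  summ <- stage("summaries",
                suppressWarnings(species_summaries(dm, hap$labels, exclude)))
  write_tsv(summ, file.path(outdir, "species_summaries.tsv"))
  pairs <- stage("summaries",
                 species_pair_minima(dm, hap$labels, exclude))
  write_tsv(pairs, file.path(outdir, "species_pair_minima.tsv"))

  reps <- if (is.null(config$bootstrap_reps)) 0L else as.integer(config$bootstrap_reps)
  if (reps > 0L) {
    multi <- summ$species[summ$n >= 2L]
    keep_ids <- hap$labels$id[!(hap$labels$id %in% exclude)]
    boot_aln <- subset_alignment(hap, keep_ids)
    se <- vapply(seq_along(multi), function(i)
      as.numeric(bootstrap_se(boot_aln, stat_mean_intraspecific(multi[i], model),
                              reps = reps, seed = seed + i)), 1)
    write_tsv(data.frame(species = multi, se_mean_intra = se),
              file.path(outdir, "bootstrap_se.tsv"))
  }

  parts <- list()
  if (!is.null(config$delimit)) {
    pmids <- if (is.null(config$delimit$pmids)) default_pmid_grid()
    else as.numeric(config$delimit$pmids)
    Xs <- if (is.null(config$delimit$X)) c(1, 1.5)
    else as.numeric(config$delimit$X)
    parts <- stage("delimitation", abgd_scan(dm, pmids, Xs))
  }
  if (!is.null(config$partitions)) {
    ext <- lapply(config$partitions, function(pth) stage("partitions", read_partition(pth)))
    nm <- if (!is.null(names(config$partitions))) names(config$partitions)
    else vapply(ext, `[[`, "", "method")
    names(ext) <- nm
    parts <- c(parts, ext)
  }
  write_tsv(scan_summary(parts), file.path(outdir, "delimitation_scan.tsv"))
  for (nm in names(parts))
    write_partition(parts[[nm]], file.path(outdir, paste0("partition_", nm, ".tsv")))

  lab_for_cong <- hap$labels
  if (length(exclude))
    lab_for_cong <- lab_for_cong[!(lab_for_cong$id %in% exclude), , drop = FALSE]
  cong <- stage("congruence", congruence_table(parts, lab_for_cong))
  write_tsv(cong, file.path(outdir, "congruence_table.tsv"))
  if (length(parts) >= 3L)
    write_tsv(stage("congruence", method_consensus_score(parts, lab_for_cong)),
              file.path(outdir, "method_consensus.tsv"))

  reg <- stage("regression",
               regression_summary(parts, lab_for_cong, col$map))
  write_tsv(reg, file.path(outdir, "regression_table.tsv"))

  manifest$n_partitions <- length(parts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
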