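#' Pipeline run configuration
#'
#' Defaults are the study values: significance threshold `-log10(p) > 4`,
#' QTL window 1 Mb with at least 3 significant SNPs, allele filters
#' MAF > 10% / MAC > 1 / missing < 30%, chilling temperatures
#' 4/8/10/12/16 degrees C, and gene-level SNP cutoff p < 1e-4.
#'
#' @param lod_threshold Significance threshold on `-log10(p)` (strict `>`).
#' @param qtl_window QTL clustering window in bp.
#' @param qtl_min_snps Minimum significant SNPs per QTL.
#' @param filter A [filter_policy()].
#' @param temperatures Chilling temperatures (degrees C).
#' @param p_max_gene Supporting-SNP cutoff for candidate genes (strict `<`).
#' @param seed Integer seed recorded in the run manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(lod_threshold = 4, qtl_window = 1e6, qtl_min_snps = 3,
                       filter = filter_policy(),
                       temperatures = c(4, 8, 10, 12, 16),
                       p_max_gene = 1e-4, seed = 1) {
  stopifnot(lod_threshold > 0, qtl_window > 0, qtl_min_snps >= 1,
            inherits(filter, "filter_policy"))
  structure(list(lod_threshold = lod_threshold, qtl_window = qtl_window,
                 qtl_min_snps = qtl_min_snps, filter = filter,
                 temperatures = temperatures, p_max_gene = p_max_gene,
                 seed = as.integer(seed)), class = "run_config")
}

trait_label <- function(trait, temperature) {
  if (trait == "LT50") "LT50"
  else paste0(substr(trait, 1, 1), temperature)   # E10, L12, ...
}

#' Run the full chilling-tolerance mapping pipeline on a synthetic panel
#'
#' Chains every stage: genotype and phenotype simulation, trait averaging,
#' LT50 estimation, SNP filtering, IBS kinship, one EMMAX scan per trait
#' (EL and LTSS at each temperature plus LT50), QTL calling, unique and
#' multi-trait merging, genome coverage, optional legacy-QTL annotation and
#' the candidate-gene cascade. Stage artifacts and a JSON run manifest
#' (inputs, parameter values, stage counts, seed — no timestamps, so reruns
#' with the same seed are byte-identical) are written under `out_dir`.
#'
#' @param sim A [sim_config()] describing the synthetic scenario.
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing artifacts.
#' @param annotation Optional gene table (see [read_gene_annotation()]) for
#'   the candidate stage.
#' @param legacy Optional legacy-QTL table (see [read_bed()]).
#' @return List with `panel`, `traits`, `lt50`, `scans` (per trait label),
#'   `qtls`, `merged`, `qmt`, `coverage`, `candidates` (or `NULL`),
#'   `truth`, `manifest`.
#' @export
run_pipeline <- function(sim = sim_config(), config = run_config(),
                         out_dir = NULL, annotation = NULL, legacy = NULL) {
  stopifnot(inherits(sim, "sim_config"), inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }

  panel <- simulate_genotypes(sim)
  phen <- simulate_phenotypes(panel, sim)
  traits <- average_replicates(phen$raw)
  lt50 <- lt50_table(phen$raw)
  filtered <- filter_snps(panel, config$filter)
  K <- ibs_kinship(filtered)

  slices <- list()
  for (tv in sim$temperatures) {
    slices[[trait_label("EL", tv)]] <- trait_values(traits, "EL", tv)
    slices[[trait_label("LTSS", tv)]] <- trait_values(traits, "LTSS", tv)
  }
  slices[["LT50"]] <- trait_values(lt50, "LT50")

  scans <- list()
  qtl_rows <- list()
  for (lab in names(slices)) {
    sc <- emmax_scan(filtered, slices[[lab]], K = K)
    scans[[lab]] <- sc
    q <- call_qtl(significant_snps(sc, config$lod_threshold),
                  window = config$qtl_window, min_snps = config$qtl_min_snps,
                  trait = lab)
    if (nrow(q)) qtl_rows[[lab]] <- q
  }
  qtls <- if (length(qtl_rows)) do.call(rbind, qtl_rows) else
    call_qtl(significant_snps(scans[[1]], Inf))
  rownames(qtls) <- NULL
  merged <- merge_unique(qtls)
  qmt <- multi_trait(merged)
  coverage <- genome_coverage(merged, sim$chromosome_lengths)
  if (!is.null(legacy)) qmt <- legacy_overlap(qmt, legacy)

  candidates <- NULL
  if (!is.null(annotation) && nrow(qmt)) {
    scan_all <- do.call(rbind, lapply(names(scans), function(lab) {
      s <- scans[[lab]]; s$trait <- lab; s
    }))
    candidates <- candidate_funnel(qmt, annotation, scan_all,
                                   clusters = panel$accessions$cluster,
                                   p_max = config$p_max_gene)
  }

  emit("genotypes.tsv", function(p)
    write_genotype_matrix(panel, p, file.path(out_dir, "clusters.csv")))
  emit("phenotypes.csv", function(p) write_phenotypes(phen$raw, p))
  emit("trait_table.csv", function(p)
    write.csv(rbind(traits, lt50), p, row.names = FALSE, quote = FALSE))
  emit("truth.json", function(p)
    jsonlite::write_json(phen$truth, p, auto_unbox = TRUE, digits = NA))
  for (lab in names(scans)) {
    lab_local <- lab
    emit(sprintf("scan_%s.tsv", lab_local), function(p)
      write_scan(scans[[lab_local]], p))
  }
  if (nrow(merged))
    emit("qtl_unique.bed", function(p) write_bed(merged, p))
  if (nrow(qmt))
    emit("qtl_multitrait.csv", function(p)
      write.csv(qmt[, setdiff(names(qmt), c("members", "sources"))], p,
                row.names = FALSE, quote = FALSE))

  manifest <- list(
    parameters = list(seed = sim$seed,
                      n_accessions = nrow(panel$geno),
                      n_snps = ncol(panel$geno),
                      fst = sim$fst,
                      temperatures = sim$temperatures,
                      lod_threshold = config$lod_threshold,
                      qtl_window = config$qtl_window,
                      qtl_min_snps = config$qtl_min_snps,
                      maf_min = config$filter$maf_min,
                      mac_min = config$filter$mac_min,
                      missing_max = config$filter$missing_max,
                      p_max_gene = config$p_max_gene),
    counts = list(snps_after_filter = ncol(filtered$geno),
                  accessions_with_lt50 = nrow(lt50),
                  lt50_exclusions = nrow(attr(lt50, "exclusions")),
                  qtl_called = nrow(qtls),
                  qtl_unique = nrow(merged),
                  qtl_multitrait = nrow(qmt),
                  genome_coverage = coverage,
                  candidate_funnel = if (is.null(candidates)) NULL
                                     else as.list(candidates$counts)))
  emit("manifest.json", function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))

  list(panel = panel, traits = traits, lt50 = lt50, scans = scans,
       qtls = qtls, merged = merged, qmt = qmt, coverage = coverage,
       candidates = candidates, truth = phen$truth, manifest = manifest)
}
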