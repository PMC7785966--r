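#' Run the full core-collection pipeline
#'
#' Chains the analysis end to end: input (a synthetic panel or files read
#' by the caller), diversity summary, genetic structure (UPGMA tree, PCoA,
#' AMOVA, pairwise PhiPT), the LDSS ladder, selection of the best core by
#' the retention-threshold rule, and quality evaluation of the selected
#' core.  All stage outputs are written under `out_dir` together with a
#' run manifest (seed, parameters, md5 digest of every file): re-running
#' with the same inputs reproduces every output bit-identically.
#'
#' @param out_dir output directory (created if needed).
#' @param panel a `"synthetic_panel"` or a list with elements `genotypes`,
#'   `metabolites`, `populations`; if `NULL` a panel is simulated from
#'   `config`.
#' @param config [synthetic_config()] used when `panel` is `NULL`
#'   (default [paper_like_config()] with `seed`).
#' @param seed seed for simulation and AMOVA permutations.
#' @param ratios LDSS sampling-ratio ladder.
#' @param sizes optional explicit ladder sizes (override `ratios`).
#' @param ra_threshold minimum Ra (%) a checkpoint must retain to qualify
#'   as the final core.
#' @param n_permutations AMOVA permutations.
#' @return Invisibly, a list with all stage results (`panel`, `diversity`,
#'   `tree`, `pcoa`, `amova`, `pairwise_phipt`, `ladder`, `selected`,
#'   `evaluation`, `manifest`).
#' @export
run_pipeline <- function(out_dir, panel = NULL, config = NULL, seed = 1,
                         ratios = c(0.40, 0.35, 0.30, 0.25, 0.20, 0.15, 0.10),
                         sizes = NULL, ra_threshold = 90,
                         n_permutations = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.null(panel)) {
    if (is.null(config)) config <- paper_like_config(seed = seed)
    panel <- stage("simulate", generate_panel(config))
    write_genotypes(panel$genotypes, file.path(out_dir, "genotypes.csv"),
                    dialect = "genalex_csv", populations = panel$populations)
    write_metabolites(panel$metabolites, file.path(out_dir, "metabolites.csv"))
  }
  g <- panel$genotypes
  met <- panel$metabolites
  pops <- panel$populations

  div <- stage("diversity", diversity_summary(g))
  write_report(div, file.path(out_dir, "diversity.json"))
  write_report(div$per_locus, file.path(out_dir, "diversity_per_locus.tsv"),
               format = "tsv")

  d <- stage("distance", genetic_distance(g, "band_sq_euclidean"))
  d_sm <- stage("distance", genetic_distance(g, "simple_matching"))
  tree <- stage("upgma", upgma(d_sm))
  write_tree_newick(tree, file.path(out_dir, "upgma.nwk"))
  pc <- stage("pcoa", pcoa(d, n_axes = 2))
  utils::write.table(
    data.frame(accession = rownames(pc$coordinates), pc$coordinates,
               population = as.character(unclass(pops)[rownames(pc$coordinates)])),
    file.path(out_dir, "pcoa.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  am <- stage("amova", amova(d, pops, n_permutations = n_permutations,
                             seed = seed))
  write_report(am, file.path(out_dir, "amova.json"))
  pp <- stage("pairwise_phipt",
              pairwise_phipt(d, pops, n_permutations = n_permutations,
                             seed = seed))
  write_report(list(phi_pt = pp$phi_pt), file.path(out_dir, "pairwise_phipt.json"))

  lad <- stage("ldss", ldss_ladder(g, met, ratios = ratios, sizes = sizes, d = d))
  utils::write.table(lad$core$removal_log, file.path(out_dir, "removal_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_report(lad$table, file.path(out_dir, "ladder_summary.tsv"), format = "tsv")
  for (nm in names(lad$core$checkpoints))
    writeLines(lad$core$checkpoints[[nm]],
               file.path(out_dir, sprintf("core_%s.txt", nm)))

  selected <- stage("select", select_core(lad, ra_threshold = ra_threshold))
  ev <- stage("evaluate",
              evaluate_core(lad$core$checkpoints[[selected]], g, met,
                            populations = pops, d = d))
  write_report(list(selected = selected,
                    parameters = ev$parameters,
                    t_tests = ev$t_tests,
                    metabolites = ev$metabolites),
               file.path(out_dir, "evaluation.json"))
  utils::write.table(ev$pcoa, file.path(out_dir, "pcoa_core_overlay.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    tool = "corekit",
    version = as.character(utils::packageVersion("corekit")),
    seed = seed,
    parameters = list(ratios = ratios, sizes = sizes,
                      ra_threshold = ra_threshold,
                      n_permutations = n_permutations),
    selected_core = selected,
    outputs = stats::setNames(as.list(unname(tools::md5sum(file.path(out_dir, files)))),
                              files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(panel = panel, diversity = div, tree = tree, pcoa = pc,
                 amova = am, pairwise_phipt = pp, ladder = lad,
                 selected = selected, evaluation = ev, manifest = manifest))
}
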