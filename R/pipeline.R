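# End-to-end orchestration: population-level DEGs + concordance ->
# cross-platform stable REOs -> RankComp and paired individual-level calls
# -> dysregulation frequencies -> universality filter -> validation ->
# downstream enrichment/network/methylation. Every stage writes a TSV with
# a fixed column order; a JSON manifest records inputs, parameters and
# seeds so a rerun is byte-identical.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Default pipeline parameters
#'
#' @param alpha_fdr FDR level used by every testing stage.
#' @param universal_threshold Dual-cohort universality threshold.
#' @param validation_threshold Threshold for the validation pass flag.
#' @param ci_method Binomial CI method for frequency tables.
#' @param max_iter RankComp refinement iteration cap.
#' @param methyl_threshold Strict hypermethylation frequency threshold.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(alpha_fdr = 0.05, universal_threshold = 0.90,
                            validation_threshold = 0.90,
                            ci_method = "clopper-pearson", max_iter = 10L,
                            methyl_threshold = 0.50) {
  thresholds <- c(alpha_fdr, universal_threshold, validation_threshold,
                  methyl_threshold)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("all thresholds must lie strictly in (0, 1)")
  list(alpha_fdr = alpha_fdr, universal_threshold = universal_threshold,
       validation_threshold = validation_threshold, ci_method = ci_method,
       max_iter = as.integer(max_iter), methyl_threshold = methyl_threshold)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

# Core runner over in-memory inputs. `inputs` is a list with elements:
# cohort_a, cohort_b (PairedCohort, discovery), normal_p1, normal_p2
# (ExpressionMatrix, two-platform normal compendia), tumors
# (ExpressionMatrix, unpaired), paired (PairedCohort), validation
# (PairedCohort, optional), collection/network/cancer_genes/methylation
# (optional knowledgebases).
run_stages <- function(inputs, params, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  results$popdeg <- run_stage("popdeg", {
    ta <- paired_t_degs(inputs$cohort_a, alpha_fdr = params$alpha_fdr)
    tb <- paired_t_degs(inputs$cohort_b, alpha_fdr = params$alpha_fdr)
    conc <- concordance(ta, tb)
    candidates <- reproducible_degs(ta, tb)
    write_tsv(as.data.frame(ta), file.path(out_dir, "popdeg_a.tsv"))
    write_tsv(as.data.frame(tb), file.path(out_dir, "popdeg_b.tsv"))
    write_tsv(candidates, file.path(out_dir, "candidates.tsv"))
    write_tsv(data.frame(n_overlap = conc$n_overlap,
                         n_same_direction = conc$n_same_direction,
                         percent_same = conc$percent_same,
                         p_value = conc$p_value),
              file.path(out_dir, "concordance.tsv"))
    stage_log("popdeg", "%d candidates; concordance %s over %d overlaps",
              nrow(candidates),
              if (is.na(conc$percent_same)) "NA"
              else sprintf("%.2f%%", conc$percent_same), conc$n_overlap)
    list(table_a = ta, table_b = tb, concordance = conc, candidates = candidates)
  })

  results$reo <- run_stage("reo", {
    ra <- stable_reos(inputs$normal_p1, alpha_fdr = params$alpha_fdr)
    rb <- stable_reos(inputs$normal_p2, alpha_fdr = params$alpha_fdr)
    cross <- intersect_stable_reos(ra, rb)
    write_reo_set(cross, file.path(out_dir, "crossplatform_reos.tsv"))
    stage_log("reo", "%d + %d stable pairs -> %d cross-platform (conflicts: %d)",
              nrow(ra$pairs), nrow(rb$pairs), nrow(cross$pairs),
              attr(cross, "n_conflicts"))
    list(reos_p1 = ra, reos_p2 = rb, cross = cross)
  })

  results$rankcomp <- run_stage("rankcomp", {
    calls <- rankcomp_calls(inputs$tumors, results$reo$cross,
                            alpha_fdr = params$alpha_fdr,
                            max_iter = params$max_iter)
    freq <- dysregulation_frequency(calls, ci_method = params$ci_method)
    write_tsv(data.frame(gene = rownames(calls$status), calls$status,
                         check.names = FALSE),
              file.path(out_dir, "rankcomp_calls.tsv"))
    write_tsv(freq, file.path(out_dir, "freq_unpaired.tsv"))
    stage_log("rankcomp", "%d UP and %d DOWN calls over %d samples",
              sum(calls$status == "UP"), sum(calls$status == "DOWN"),
              ncol(calls$status))
    list(calls = calls, freq = freq)
  })

  results$paired <- run_stage("paired", {
    calls <- paired_calls(inputs$paired)
    freq <- dysregulation_frequency(calls, ci_method = params$ci_method)
    write_tsv(data.frame(gene = rownames(calls$status), calls$status,
                         check.names = FALSE),
              file.path(out_dir, "paired_calls.tsv"))
    write_tsv(freq, file.path(out_dir, "freq_paired.tsv"))
    stage_log("paired", "calls over %d pairs", ncol(calls$status))
    list(calls = calls, freq = freq)
  })

  results$universal <- run_stage("universal", {
    uni <- select_universal(results$rankcomp$freq, results$paired$freq,
                            results$popdeg$candidates,
                            threshold = params$universal_threshold)
    write_tsv(as.data.frame(uni), file.path(out_dir, "universal.tsv"))
    stage_log("universal", "%d of %d candidates qualify at threshold %.2f",
              sum(uni$qualifying), nrow(uni), params$universal_threshold)
    uni
  })

  if (!is.null(inputs$validation) && any(results$universal$qualifying)) {
    results$validation <- run_stage("validation", {
      val <- validate_on_cohort(results$universal, inputs$validation,
                                threshold = params$validation_threshold)
      write_tsv(val, file.path(out_dir, "validation.tsv"))
      stage_log("validation", "%d/%d pass at threshold %.2f",
                sum(val$pass, na.rm = TRUE), nrow(val),
                params$validation_threshold)
      val
    })
  }

  uni_genes <- results$universal$gene[results$universal$qualifying]
  uni_up <- results$universal$gene[results$universal$qualifying &
                                     results$universal$direction == "UP"]
  uni_down <- results$universal$gene[results$universal$qualifying &
                                       results$universal$direction == "DOWN"]

  if (!is.null(inputs$collection) && length(uni_genes)) {
    results$enrichment <- run_stage("enrich", {
      enr <- hypergeom_enrichment(uni_genes, inputs$collection,
                                  alpha_fdr = params$alpha_fdr)
      write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
      stage_log("enrich", "%d significant set(s)", sum(enr$significant))
      enr
    })
  }

  if (!is.null(inputs$network) && length(uni_genes)) {
    results$network <- run_stage("network", {
      sub_up <- direct_neighbors(inputs$network, uni_up)
      sub_down <- direct_neighbors(inputs$network, uni_down)
      write_tsv(rbind(
        data.frame(gene = sub_up$seeds, role = "seed_up",
                   degree = as.integer(sub_up$seed_degrees),
                   stringsAsFactors = FALSE),
        data.frame(gene = sub_down$seeds, role = "seed_down",
                   degree = as.integer(sub_down$seed_degrees),
                   stringsAsFactors = FALSE),
        data.frame(gene = sub_up$neighbors, role = "neighbor_up",
                   degree = NA_integer_, stringsAsFactors = FALSE),
        data.frame(gene = sub_down$neighbors, role = "neighbor_down",
                   degree = NA_integer_, stringsAsFactors = FALSE)),
        file.path(out_dir, "network_nodes.tsv"))
      write_tsv(rbind(cbind(sub_up$edges, subnetwork = "up"),
                      cbind(sub_down$edges, subnetwork = "down")),
                file.path(out_dir, "network_edges.tsv"))
      cg <- NULL
      if (!is.null(inputs$cancer_genes)) {
        cg <- rbind(
          cancer_gene_enrichment(c(uni_up, sub_up$neighbors),
                                 inputs$cancer_genes, inputs$network$nodes),
          cancer_gene_enrichment(c(uni_down, sub_down$neighbors),
                                 inputs$cancer_genes, inputs$network$nodes))
        cg$query <- c("up_plus_neighbors", "down_plus_neighbors")
        write_tsv(cg, file.path(out_dir, "cancer_gene_enrichment.tsv"))
      }
      stage_log("network", "up: %d neighbors; down: %d neighbors",
                length(sub_up$neighbors), length(sub_down$neighbors))
      list(up = sub_up, down = sub_down, cancer = cg)
    })
  }

  if (!is.null(inputs$methylation) && length(uni_down)) {
    results$methylation <- run_stage("methylation", {
      hm <- hypermethylation_frequency(inputs$methylation, genes = uni_down,
                                       freq_threshold = params$methyl_threshold)
      write_tsv(hm, file.path(out_dir, "methylation.tsv"))
      stage_log("methylation", "%d/%d downregulated gene(s) hypermethylated",
                sum(hm$hypermethylated), nrow(hm))
      hm
    })
  }

  results
}

write_manifest <- function(out_dir, params, seeds, inputs_desc) {
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    tool = "unideg",
    version = as.character(utils::packageVersion("unideg")),
    parameters = params,
    seeds = seeds,
    inputs = inputs_desc,
    outputs = outputs,
    output_md5 = as.list(tools::md5sum(file.path(out_dir, outputs))))
  names(manifest$output_md5) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the full pipeline from a configuration
#'
#' The configuration lists input file paths and parameters; every input is
#' read with the package's readers, the stages run in order, and all
#' outputs (stage TSVs, a JSON manifest with parameters/seeds/output
#' checksums, and a one-page summary) land in `out_dir`. Any stage error
#' aborts with the stage name; partial outputs are retained next to a
#' `FAILED` marker.
#'
#' @param config Named list (or path to a YAML file, read with the `yaml`
#'   package) with elements: `cohort_a_tumor`, `cohort_a_normal`,
#'   `cohort_b_tumor`, `cohort_b_normal`, `normal_p1`, `normal_p2`,
#'   `tumors`, `paired_tumor`, `paired_normal` (expression TSV paths;
#'   paired matrices are paired column-by-column in order), optional
#'   `validation_tumor`/`validation_normal`, `gene_sets` (GMT), `network`
#'   (edge list), `cancer_genes` (gene list), `methylation_tumor`/
#'   `methylation_normal`, plus any [pipeline_params()] name.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  par_names <- names(formals(pipeline_params))
  params <- do.call(pipeline_params, config[intersect(names(config), par_names)])
  paths <- config[setdiff(names(config), par_names)]
  missing <- unlist(paths[!vapply(paths, function(p)
    is.character(p) && file.exists(p), logical(1L))])
  if (length(missing))
    stop("config references missing file(s): ", paste(missing, collapse = ", "))

  read_cohort <- function(tumor_path, normal_path) {
    tum <- read_expression_matrix(tumor_path)
    nor <- read_expression_matrix(normal_path)
    paired_cohort(tum, nor, data.frame(tumor = sample_ids(tum),
                                       normal = sample_ids(nor),
                                       stringsAsFactors = FALSE))
  }
  inputs <- list(
    cohort_a = read_cohort(paths$cohort_a_tumor, paths$cohort_a_normal),
    cohort_b = read_cohort(paths$cohort_b_tumor, paths$cohort_b_normal),
    normal_p1 = read_expression_matrix(paths$normal_p1, platform = "p1"),
    normal_p2 = read_expression_matrix(paths$normal_p2, platform = "p2"),
    tumors = read_expression_matrix(paths$tumors),
    paired = read_cohort(paths$paired_tumor, paths$paired_normal))
  if (!is.null(paths$validation_tumor))
    inputs$validation <- read_cohort(paths$validation_tumor, paths$validation_normal)
  if (!is.null(paths$gene_sets)) inputs$collection <- read_gmt(paths$gene_sets)
  if (!is.null(paths$network)) inputs$network <- read_network(paths$network)
  if (!is.null(paths$cancer_genes))
    inputs$cancer_genes <- read_gene_list(paths$cancer_genes)
  if (!is.null(paths$methylation_tumor))
    inputs$methylation <- read_cohort(paths$methylation_tumor,
                                      paths$methylation_normal)

  results <- run_stages(inputs, params, out_dir)
  write_summary(out_dir, results, params)
  input_md5 <- as.list(tools::md5sum(unlist(paths)))
  names(input_md5) <- names(paths)
  write_manifest(out_dir, params, seeds = config$seed %||% NA,
                 inputs_desc = input_md5)
  invisible(results)
}

write_summary <- function(out_dir, results, params) {
  uni <- results$universal
  lines <- c(
    "unideg pipeline summary",
    "=======================",
    sprintf("population-level candidates: %d (concordance %s over %d overlaps, p = %.3g)",
            nrow(results$popdeg$candidates),
            if (is.na(results$popdeg$concordance$percent_same)) "NA"
            else sprintf("%.2f%%", results$popdeg$concordance$percent_same),
            results$popdeg$concordance$n_overlap,
            results$popdeg$concordance$p_value),
    sprintf("cross-platform stable REOs: %d pairs over %d genes (conflicts: %d)",
            nrow(results$reo$cross$pairs),
            length(results$reo$cross$gene_universe),
            attr(results$reo$cross, "n_conflicts")),
    sprintf("universal DEGs at threshold %.2f: %d (%d up, %d down)",
            params$universal_threshold, sum(uni$qualifying),
            sum(uni$qualifying & uni$direction == "UP"),
            sum(uni$qualifying & uni$direction == "DOWN")))
  if (!is.null(results$validation))
    lines <- c(lines, sprintf("validation: %d/%d pass at threshold %.2f",
                              sum(results$validation$pass, na.rm = TRUE),
                              nrow(results$validation),
                              params$validation_threshold))
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(lines)
}

#' The packaged synthetic demonstration design
#'
#' A cohort family sized for desk-scale validation: 230 genes of which 15
#' are planted up and 15 down at per-sample frequency 0.95 with effect
#' `4 * noise_sd`; a 74-sample normal compendium plus a 32-sample
#' distorted second-platform compendium; two 25-pair discovery cohorts; 100
#' unpaired tumors; a 60-pair frequency cohort; and a 24-pair validation
#' cohort.
#'
#' @param seed Integer master seed; sub-cohorts derive independent seeds
#'   from it.
#' @param noise_sd Log2 noise SD (0 gives the deterministic variant).
#' @return Named list of `CohortDesign`s plus the planted gene map.
#' @export
demo_design <- function(seed = 1L, noise_sd = 0.5) {
  n_genes <- 230L
  spread <- 1.0
  genes <- default_gene_ids(n_genes)
  # Rank-based callers are blind, by construction, to a further upshift of
  # a gene that is already near the top of the expression distribution (no
  # partners left to cross), and symmetrically for downshifts near the
  # bottom. At transcriptome scale that border region is negligible; at
  # 230-gene toy scale it would dominate. Planted genes are therefore
  # placed at mid-distribution baseline ranks: upregulated plants in the
  # lower-mid percentiles, downregulated plants in the upper-mid.
  mu <- design_baselines(cohort_design(n_genes, 2L, 1L, noise_sd = noise_sd,
                                       baseline_spread = spread,
                                       seed = seed, baseline_seed = seed))
  ranks <- order(mu)
  pick <- ranks[round(seq(0.15, 0.85, length.out = 30L) * n_genes)]
  up <- data.frame(gene = genes[pick[1:15]], frequency = 0.95,
                   effect = 4 * max(noise_sd, 0.5), stringsAsFactors = FALSE)
  down <- data.frame(gene = genes[pick[16:30]], frequency = 0.95,
                     effect = 4 * max(noise_sd, 0.5), stringsAsFactors = FALSE)
  base <- function(n_normal, n_tumor, sub)
    cohort_design(n_genes, n_normal, n_tumor, planted_up = up,
                  planted_down = down, noise_sd = noise_sd,
                  baseline_spread = spread, seed = stream_seed(seed, 100L + sub),
                  baseline_seed = seed)
  list(genes = genes,
       planted = rbind(cbind(up, direction = "UP"),
                       cbind(down, direction = "DOWN")),
       normal = base(74L, 1L, 1L),
       normal_p2 = base(32L, 1L, 2L),
       cohort_a = base(2L, 25L, 3L),
       cohort_b = base(2L, 25L, 4L),
       tumors = base(2L, 100L, 5L),
       paired = base(2L, 60L, 6L),
       validation = base(2L, 24L, 7L),
       seed = as.integer(seed))
}

#' Generate the demo inputs in memory
#'
#' @param seed Master seed.
#' @param noise_sd Log2 noise SD.
#' @return List of pipeline inputs (see [run_pipeline()]) plus `truth`
#'   entries for the tumor-bearing cohorts and the `planted` map.
#' @export
generate_demo_inputs <- function(seed = 1L, noise_sd = 0.5) {
  dd <- demo_design(seed, noise_sd)
  normal_p1 <- generate_normal_cohort(dd$normal)
  normal_p2 <- generate_platform_view(generate_normal_cohort(dd$normal_p2),
                                      distortion_id = "cube",
                                      extra_noise_sd = 0,
                                      seed = stream_seed(seed, 108L))
  tum <- generate_tumor_cohort(dd$tumors)
  pc <- generate_paired_cohort(dd$paired)
  val <- generate_paired_cohort(dd$validation)
  know <- generate_toy_knowledge(dd$genes, n_sets = 20L,
                                 set_size_range = c(5L, 20L), n_edges = 300L,
                                 n_cancer_genes = 25L,
                                 seed = stream_seed(seed, 109L),
                                 plant = list(genes = dd$planted$gene[1:15],
                                              size = 20L))
  down_genes <- dd$planted$gene[dd$planted$direction == "DOWN"]
  methyl <- generate_methylation_cohort(
    n_genes = length(dd$genes), n_pairs = 115L,
    planted_hyper = setNames(rep(0.9, length(down_genes)), down_genes),
    seed = stream_seed(seed, 110L))
  list(cohort_a = generate_paired_cohort(dd$cohort_a)$cohort,
       cohort_b = generate_paired_cohort(dd$cohort_b)$cohort,
       normal_p1 = normal_p1, normal_p2 = normal_p2,
       tumors = tum$tumor, tumors_truth = tum$truth,
       paired = pc$cohort, paired_truth = pc$truth,
       validation = val$cohort, validation_truth = val$truth,
       collection = know$collection, network = know$network,
       cancer_genes = know$cancer_genes, methylation = methyl,
       planted = dd$planted, design = dd)
}

#' Run the synthetic demonstration end-to-end
#'
#' Generates the demo cohorts, runs every pipeline stage, writes all
#' artifacts to `out_dir` and compares the recovered universal DEG set with
#' the planted genes.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param noise_sd Log2 noise SD of the generated cohorts.
#' @return Invisibly, a list with the stage `results`, the demo `inputs`,
#'   and `recovery` (planted genes, recovered genes, counts of missed and
#'   spurious genes).
#' @export
run_demo <- function(out_dir, seed = 1L, noise_sd = 0.5) {
  inputs <- generate_demo_inputs(seed, noise_sd)
  params <- pipeline_params()
  results <- run_stages(inputs, params, out_dir)
  recovered <- results$universal$gene[results$universal$qualifying]
  planted <- inputs$planted$gene
  recovery <- list(planted = planted, recovered = recovered,
                   n_planted = length(planted), n_recovered = length(recovered),
                   n_missed = length(setdiff(planted, recovered)),
                   n_spurious = length(setdiff(recovered, planted)))
  write_summary(out_dir, results, params)
  write_manifest(out_dir, params,
                 seeds = list(master = seed, noise_sd = noise_sd),
                 inputs_desc = list(source = "synthetic demo design"))
  stage_log("demo", "recovered %d/%d planted genes (%d spurious)",
            length(planted) - recovery$n_missed, length(planted),
            recovery$n_spurious)
  invisible(list(results = results, inputs = inputs, recovery = recovery))
}
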