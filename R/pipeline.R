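#' Build an analysis configuration
#'
#' @param scores,sutures,metadata Paths to the score matrix, suture map,
#'   and specimen metadata CSVs (required).
#' @param tree Optional newick path; enables the phylogenetic stages.
#' @param absences Optional CSV path with columns `specimen,suture`
#'   listing absent-bone cells.
#' @param alpha Significance level for counting pairwise comparisons.
#' @param outdir Output directory, or `NULL` to skip writing files.
#' @param seed Integer seed for any resampling-based p-values.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(scores, sutures, metadata, tree = NULL,
                            absences = NULL, alpha = 0.05,
                            outdir = NULL, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  cfg <- list(scores = scores, sutures = sutures, metadata = metadata,
              tree = tree, absences = absences, alpha = alpha,
              outdir = outdir, seed = as.integer(seed))
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [analysis_config()]. Relative paths are resolved against the YAML
#'   file's directory.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p) && file.exists(file.path(base, p)))
      file.path(base, p) else p
  }
  analysis_config(scores = resolve(y$scores), sutures = resolve(y$sutures),
                  metadata = resolve(y$metadata), tree = resolve(y$tree),
                  absences = resolve(y$absences),
                  alpha = if (is.null(y$alpha)) 0.05 else y$alpha,
                  outdir = y$outdir,
                  seed = if (is.null(y$seed)) 1L else y$seed)
}

#' Run the full suture-fusion analysis
#'
#' End-to-end orchestration: ingest and validate the score matrix,
#' suture map, and metadata; apply the absent-bone rule and interpolate
#' missing scores along each species' size-ordered ontogenetic series;
#' compute closure tables at all four levels (suture, specimen,
#' species-stage, region); build fusion sequences and compare region
#' orders with the Krogman reference (overall and per infraclass); run
#' all pairwise species sequence comparisons with Bonferroni correction;
#' and, when a tree is supplied, estimate Brownian-motion ancestral
#' states of adult total closure and fit the adult closure-size PGLS.
#' Stages whose inputs are missing are skipped with a message. When
#' `outdir` is set, every table is written as CSV plus a `report.json`
#' of headline numbers.
#'
#' @param config An `analysis_config`.
#' @return An `analysis_report` list.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  for (f in c("scores", "sutures", "metadata")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop("input file for '", f, "' not found: ", config[[f]])
    }
  }

  smap <- read_suture_map(config$sutures)
  mat <- read_score_matrix(config$scores, smap)
  meta <- utils::read.csv(config$metadata, stringsAsFactors = FALSE)
  if (!is.null(config$absences) && file.exists(config$absences)) {
    ab <- utils::read.csv(config$absences, stringsAsFactors = FALSE)
    mat <- apply_absent_bone_rule(mat, ab)
  }
  mat <- interpolate_unknowns(mat, ontogenetic_order(meta))
  validation <- validate_dataset(mat, smap, meta)

  adults <- meta$specimen_id[!is.na(meta$stage) & meta$stage == "A"]
  adults <- intersect(adults, rownames(mat))

  suture_all <- suture_closure_scores(mat)
  suture_adult <- if (length(adults)) suture_closure_scores(mat, adults)
  specimen_tot <- specimen_total_closure(mat)
  stage_avg <- stage_averages(specimen_tot, meta)
  region_adult <- if (length(adults)) region_averages(suture_adult, smap)

  sequence_all <- rank_closure(suture_all)
  krogman <- list()
  if (!is.null(region_adult)) {
    krogman$all <- compare_to_krogman(region_adult)
    for (ic in unique(meta$infraclass)) {
      ids <- intersect(
        meta$specimen_id[meta$infraclass == ic & !is.na(meta$stage) &
                           meta$stage == "A"], rownames(mat))
      if (length(ids) >= 2) {
        krogman[[ic]] <- compare_to_krogman(
          region_averages(suture_closure_scores(mat, ids), smap))
      }
    }
  } else {
    message("no adult specimens: region/Krogman stage skipped")
  }

  per_species <- lapply(split(meta$specimen_id, meta$species), function(ids) {
    suture_closure_scores(mat, intersect(ids, rownames(mat)))
  })
  pairwise <- if (length(per_species) >= 2)
    pairwise_species_comparison(per_species)
  n_signif <- if (!is.null(pairwise))
    count_significant(pairwise, config$alpha)

  # size / ontogeny stages need centroid sizes
  sizes <- NULL; correlations <- NULL; anova <- NULL
  if (!is.null(meta$centroid_size) && any(!is.na(meta$centroid_size))) {
    sizes <- percent_adult_cs(meta)
    meta <- assign_age_categories(meta, sizes)
    sizes$stage <- meta$stage[match(sizes$specimen_id, meta$specimen_id)]
    correlations <- rbind(
      spearman_closure_size(specimen_tot, sizes, "overall"),
      spearman_closure_size(specimen_tot, sizes, "per_species"),
      spearman_closure_size(specimen_tot, sizes, "adults_only"))
  } else {
    message("no centroid sizes: size-correlate stage skipped")
  }
  anova <- tryCatch(anova_by_origin(suture_all, smap),
                    error = function(e) {
                      message("ANOVA skipped: ", conditionMessage(e))
                      NULL
                    })

  # phylogenetic stages
  ancestral <- NULL; pgls <- NULL
  if (!is.null(config$tree)) {
    if (!file.exists(config$tree)) stop("tree file not found: ", config$tree)
    tree <- read_newick(config$tree)
    sp_adult <- meta[match(adults, meta$specimen_id), , drop = FALSE]
    have <- intersect(unique(sp_adult$species), tree$tip.label)
    if (length(have) >= 3) {
      tree_p <- prune_to_tips(tree, have)
      tot <- specimen_tot$closure_pct[match(sp_adult$specimen_id,
                                            specimen_tot$specimen)]
      adult_by_sp <- tapply(tot, sp_adult$species, max)[have]
      ancestral <- bm_ancestral_ml(tree_p, adult_by_sp)
      if (!is.null(sizes)) {
        cs <- tapply(sizes$log_cs[match(sp_adult$specimen_id,
                                        sizes$specimen_id)],
                     sp_adult$species, max)[have]
        pgls <- tryCatch(
          pgls_brownian(adult_by_sp, cs, tree_p),
          error = function(e) {
            message("PGLS skipped: ", conditionMessage(e)); NULL
          })
      }
    } else {
      message("fewer than 3 adult species on the tree: phylogenetic ",
              "stage skipped")
    }
  } else {
    message("no tree supplied: ancestral/PGLS stage skipped")
  }

  report <- list(validation = validation,
                 closure = list(suture_all = suture_all,
                                suture_adult = suture_adult,
                                specimen = specimen_tot,
                                species_stage = stage_avg,
                                region_adult = region_adult),
                 sequence = sequence_all,
                 krogman = krogman,
                 pairwise = pairwise,
                 n_significant_pairs = n_signif,
                 correlations = correlations,
                 anova = anova,
                 ancestral = ancestral,
                 pgls = pgls,
                 alpha = config$alpha,
                 version = as.character(utils::packageVersion("suturekit")))
  class(report) <- "analysis_report"

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' Write an analysis report to disk
#'
#' CSV per table plus `report.json` with the headline numbers.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (!is.null(x)) utils::write.csv(as.data.frame(x),
                                      file.path(dir, name),
                                      row.names = FALSE)
  }
  wr(report$closure$suture_all, "closure_suture_all.csv")
  wr(report$closure$suture_adult, "closure_suture_adult.csv")
  wr(report$closure$specimen, "closure_specimen.csv")
  wr(report$closure$species_stage, "closure_species_stage.csv")
  wr(report$closure$region_adult, "closure_region_adult.csv")
  wr(report$sequence, "fusion_sequence.csv")
  wr(report$pairwise, "pairwise_comparisons.csv")
  wr(report$correlations, "spearman_correlations.csv")
  if (!is.null(report$ancestral)) {
    wr(data.frame(node = names(report$ancestral$node_states),
                  state = as.numeric(report$ancestral$node_states)),
       "ancestral_states.csv")
  }

  headline <- list(
    n_specimens = nrow(report$closure$specimen),
    n_sutures = nrow(report$closure$suture_all),
    n_significant_pairs = report$n_significant_pairs,
    krogman_tau = lapply(report$krogman, function(k) k$tau),
    anova_p = if (!is.null(report$anova)) report$anova$p,
    bm_sigma2 = if (!is.null(report$ancestral)) report$ancestral$sigma2,
    bm_root_state = if (!is.null(report$ancestral))
      as.numeric(report$ancestral$node_states[1]),
    pgls_slope = if (!is.null(report$pgls))
      as.numeric(report$pgls$coefficients[2]),
    pgls_slope_p = if (!is.null(report$pgls)) report$pgls$slope_p,
    pgls_aic = if (!is.null(report$pgls)) report$pgls$aic,
    alpha = report$alpha,
    version = report$version)
  jsonlite::write_json(headline, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Suture fusion analysis report\n")
  cat("  specimens:", nrow(x$closure$specimen),
      " sutures:", nrow(x$closure$suture_all), "\n")
  for (nm in names(x$krogman)) {
    cat(sprintf("  Krogman concordance (%s): tau = %.3f\n",
                nm, x$krogman[[nm]]$tau))
  }
  if (!is.null(x$n_significant_pairs)) {
    cat("  significant pairwise comparisons:", x$n_significant_pairs,
        "of", nrow(x$pairwise), "\n")
  }
  if (!is.null(x$ancestral)) {
    cat(sprintf("  BM ancestral root state: %.2f%% (sigma2 = %.4g)\n",
                x$ancestral$node_states[1], x$ancestral$sigma2))
  }
  if (!is.null(x$pgls)) {
    cat(sprintf("  adult PGLS slope: %.4f (p = %.3f, AIC = %.2f)\n",
                x$pgls$coefficients[2], x$pgls$slope_p, x$pgls$aic))
  }
  invisible(x)
}
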