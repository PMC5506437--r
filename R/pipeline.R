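#' Configuration of the end-to-end pipeline
#'
#' Bundles the synthetic-cohort parameters and every analysis constant of
#' the pipeline: the covariate list, detection threshold, branch cutpoints,
#' FDR summary thresholds, the number of top miRNAs carried into
#' coexpression, and the permutation plan. Validation enforces
#' `0 < eligibility_prop <= lower < upper <= 1` and descending FDR
#' thresholds before any stage runs.
#'
#' @param sim A [sim_params()] object describing the synthetic cohort.
#' @param covariates Covariate columns for the association models.
#' @param threshold Cq detection limit (cycles).
#' @param eligibility_prop,lower,upper Branch-rule constants.
#' @param fdr_thresholds Descending FDR summary thresholds.
#' @param k_top Number of top miRNAs for the coexpression stage.
#' @param n_permutations Permutation replicates for calibration.
#' @param n_gene_sets,gene_set_size Size of the gene-set fixture built for
#'   the enrichment stage.
#' @param seed Integer seed for every stage's randomness.
#' @return An object of class `pipeline_config` (validated list).
#' @export
pipeline_config <- function(sim = sim_params(),
                            covariates = c("sex", "age", "height_in", "bmi",
                                           "rna_conc", "ratio_260_280",
                                           "rna_quality"),
                            threshold = 27,
                            eligibility_prop = 0.05,
                            lower = 0.10, upper = 0.90,
                            fdr_thresholds = c(0.10, 0.05, 0.01, 0.001),
                            k_top = 15,
                            n_permutations = 100,
                            n_gene_sets = 10,
                            gene_set_size = 25,
                            seed = 1L) {
  cfg <- list(sim = sim, covariates = covariates, threshold = threshold,
              eligibility_prop = eligibility_prop, lower = lower,
              upper = upper, fdr_thresholds = fdr_thresholds,
              k_top = as.integer(k_top),
              n_permutations = as.integer(n_permutations),
              n_gene_sets = as.integer(n_gene_sets),
              gene_set_size = as.integer(gene_set_size),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg$sim, "sim_params"))
  if (!(cfg$eligibility_prop > 0 && cfg$eligibility_prop <= cfg$lower &&
        cfg$lower < cfg$upper && cfg$upper <= 1))
    abort("need 0 < eligibility_prop <= lower < upper <= 1")
  if (is.unsorted(rev(cfg$fdr_thresholds)))
    abort("fdr_thresholds must be descending")
  if (cfg$k_top < 0 || cfg$n_permutations < 1)
    abort("k_top must be >= 0 and n_permutations >= 1")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: top-level analysis keys plus a
#' `sim` block mirroring [sim_params()] whose `mirna_specs` is a list of
#' [mirna_spec()] field maps and whose `mrna_specs` mirrors [mrna_spec()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$mirna_specs))
    sim_args$mirna_specs <- lapply(sim_args$mirna_specs,
                                   function(m) do.call(mirna_spec, m))
  if (!is.null(sim_args$mrna_specs))
    sim_args$mrna_specs <- do.call(mrna_spec, sim_args$mrna_specs)
  sim <- do.call(sim_params, sim_args)
  args <- y[setdiff(names(y), "sim")]
  args$sim <- sim
  do.call(pipeline_config, args)
}

#' Run the full pipeline: simulate, associate, permute, coexpress, enrich,
#' report
#'
#' Executes every stage against one configuration and writes versioned
#' artifacts to `out_dir`: stage output tables (TSV), a calibration report
#' (JSON + TSV), a Markdown report, a stage-granular log, and a
#' machine-readable `manifest.json` recording the seed, the stage file
#' lists, and an MD5 checksum per artifact (log excluded), so that two runs
#' with the same configuration can be verified byte-identical. Any stage
#' failure aborts with the stage name.
#'
#' @param config A `pipeline_config` object.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(config, out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage_files <- list()
  in_dir <- function(f) file.path(out_dir, f)
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error"))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(res)))
    res
  }

  ## 1. simulate ------------------------------------------------------
  sim_out <- run_stage("simulate", {
    dat <- simulate_cohort(config$sim)
    write_cohort(dat$cohort, in_dir("cohort.tsv"))
    write_cq_matrix(dat$cq, in_dir("cq_matrix.tsv"))
    files <- c("cohort.tsv", "cq_matrix.tsv")
    if (!is.null(dat$mrna)) {
      write_expression(dat$mrna, in_dir("mrna_matrix.tsv"))
      universe <- attr(dat$mrna, "universe")
      blocks <- attr(dat$mrna, "blocks")
      block_genes <- unique(unlist(blocks, use.names = FALSE))
      make_geneset_fixture(block_genes, config$n_gene_sets,
                           min(config$gene_set_size, length(universe)),
                           universe, seed = config$seed,
                           file = in_dir("gene_sets.gmt"))
      # prediction fixture: planted block pairs are "true" targets, plus
      # decoy pairs drawn from the null genes
      set.seed(config$seed + 11L)
      pred <- bind_rows(
        bind_rows(unname(imap(blocks,
                              function(g, m) tibble(mirna = m, gene = g)))),
        tibble(mirna = sample(names(blocks),
                              min(50, length(universe)), replace = TRUE),
               gene = sample(universe, min(50, length(universe)))))
      readr::write_tsv(distinct(pred), in_dir("predictions.tsv"))
      # signature fixture: half block genes, half random background
      sig_n <- min(150, length(universe))
      sig <- unique(c(head(block_genes, sig_n %/% 2),
                      sample(universe, sig_n)))[seq_len(sig_n)]
      writeLines(sort(sig), in_dir("signature.txt"))
      files <- c(files, "mrna_matrix.tsv", "gene_sets.gmt",
                 "predictions.tsv", "signature.txt")
    }
    note("simulate: %d participants, %d miRNAs", nrow(dat$cohort),
         length(config$sim$mirna_specs))
    stage_files[["simulate"]] <- files
    dat
  })

  ## 2. associate -----------------------------------------------------
  assoc <- run_stage("associate", {
    res <- suppressWarnings(associate_all(
      sim_out$cohort, sim_out$cq, config$covariates,
      threshold = config$threshold,
      eligibility_prop = config$eligibility_prop,
      lower = config$lower, upper = config$upper))
    readr::write_tsv(as_tibble(res), in_dir("associations.tsv"))
    readr::write_tsv(threshold_summary(res$q[!is.na(res$q)],
                                       config$fdr_thresholds),
                     in_dir("fdr_summary.tsv"))
    trend <- fit_age_trend(sim_out$cohort)
    readr::write_tsv(trend$coefs, in_dir("age_trend.tsv"))
    readr::write_tsv(trend$bins, in_dir("age_trend_bins.tsv"))
    note("associate: %d miRNAs, %d eligible", nrow(res),
         sum(res$branch != "ineligible"))
    stage_files[["associate"]] <- c("associations.tsv", "fdr_summary.tsv",
                                     "age_trend.tsv", "age_trend_bins.tsv")
    res
  })

  ## 3. permute -------------------------------------------------------
  run_stage("permute", {
    calib <- suppressWarnings(permutation_calibration(
      sim_out$cohort, sim_out$cq, config$covariates,
      n_replicates = config$n_permutations, seed = config$seed + 100L,
      threshold = config$threshold,
      eligibility_prop = config$eligibility_prop,
      lower = config$lower, upper = config$upper))
    readr::write_tsv(tidy(calib), in_dir("calibration_replicates.tsv"))
    jsonlite::write_json(as.list(glance(calib)), in_dir("calibration.json"),
                         auto_unbox = TRUE, digits = NA)
    note("permute: %d replicates, pooled type-I at 0.05 = %.4f",
         calib$n_replicates, calib$type1$empirical[1])
    stage_files[["permute"]] <- c("calibration_replicates.tsv",
                                   "calibration.json")
    NULL
  })

  ## 4. coexpress -----------------------------------------------------
  pairs <- run_stage("coexpress", {
    if (is.null(sim_out$mrna)) {
      note("coexpress: no mRNA matrix configured; stage skipped")
      stage_files[["coexpress"]] <- character()
      NULL
    } else {
      top <- suppressWarnings(select_top_mirnas(assoc, config$k_top))
      pr <- suppressWarnings(coexpress_pairs(
        sim_out$cohort, sim_out$cq, sim_out$mrna, top, config$covariates,
        threshold = config$threshold))
      pred <- read_predictions(in_dir("predictions.tsv"))
      pr <- targetscan_overlap(pr, pred)
      readr::write_tsv(as_tibble(pr), in_dir("coexpression_pairs.tsv"))
      sig <- readLines(in_dir("signature.txt"))
      ov <- signature_overlap(pr, sig)
      jsonlite::write_json(
        list(n_pairs_significant = sum(pr$significant),
             n_unique_genes = length(unique(pr$gene[pr$significant])),
             n_predicted_significant = attr(pr, "n_predicted_significant"),
             signature_pairs = ov$n_pairs, signature_genes = ov$n_genes),
        in_dir("coexpression_summary.json"), auto_unbox = TRUE, digits = NA)
      note("coexpress: %d pairs, %d significant", nrow(pr),
           sum(pr$significant))
      stage_files[["coexpress"]] <- c("coexpression_pairs.tsv",
                                       "coexpression_summary.json")
      pr
    }
  })

  ## 5. enrich --------------------------------------------------------
  run_stage("enrich", {
    if (is.null(pairs)) {
      note("enrich: no coexpression pairs; stage skipped")
      stage_files[["enrich"]] <- character()
    } else {
      universe <- attr(sim_out$mrna, "universe")
      selected <- unique(pairs$gene[pairs$significant])
      enr <- suppressWarnings(
        hypergeom_enrich(selected, in_dir("gene_sets.gmt"), universe))
      readr::write_tsv(as_tibble(enr), in_dir("enrichment.tsv"))
      note("enrich: %d sets tested", nrow(enr))
      stage_files[["enrich"]] <- "enrichment.tsv"
    }
    NULL
  })

  ## 6. report --------------------------------------------------------
  run_stage("report", {
    render_report(out_dir, k_top = config$k_top)
    stage_files[["report"]] <- "report.md"
    note("report: written")
    NULL
  })

  writeLines(log_lines, in_dir("pipeline.log"))
  all_files <- unlist(stage_files, use.names = FALSE)
  checksums <- as.list(tools::md5sum(file.path(out_dir, all_files)))
  names(checksums) <- all_files
  manifest <- list(
    seed = config$seed,
    n_participants = config$sim$n_participants,
    stages = stage_files,
    checksums = checksums)
  jsonlite::write_json(manifest, in_dir("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x), "", formatC(x, digits = digits, format = "g"))
}

md_table <- function(df) {
  cells <- vapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  }, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Render the human-readable pipeline report
#'
#' Builds a Markdown report from the artifacts in a pipeline run
#' directory: a cohort characteristics table (mean (SD) by sex), the
#' sex-specific age trend, the top association table, the FDR threshold
#' sentences in the form "N (x%) had FDR q value < t", and the enrichment
#' table. A missing artifact omits its section with a notice. Every number
#' shown is read from a stage output file.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @param k_top Rows shown in the association table.
#' @return The report text (character vector of lines), invisibly; the
#'   report is written to `report.md` in `run_dir`.
#' @export
render_report <- function(run_dir, k_top = 15) {
  lines <- c("# Pipeline report", "")
  f <- function(name) file.path(run_dir, name)

  if (file.exists(f("cohort.tsv"))) {
    co <- read_cohort(f("cohort.tsv"))
    sumstat <- function(d) {
      tibble(Characteristic = c("Age, years", "Grip strength, kg",
                                "Height, inches", "BMI, kg/m2"),
             value = sprintf("%.1f (%.1f)",
                             c(mean(d$age), mean(d$grip_kg),
                               mean(d$height_in), mean(d$bmi)),
                             c(sd(d$age), sd(d$grip_kg),
                               sd(d$height_in), sd(d$bmi))))
    }
    tab <- sumstat(co) |>
      rename(Overall = "value") |>
      mutate(Men = sumstat(co[co$sex == "M", ])$value,
             Women = sumstat(co[co$sex == "F", ])$value)
    lines <- c(lines, "## Cohort characteristics", "",
               sprintf("N = %d; %d%% women.", nrow(co),
                       round(100 * mean(co$sex == "F"))), "",
               md_table(tab), "")
  } else {
    lines <- c(lines, "## Cohort characteristics", "",
               "_cohort.tsv missing; section omitted_", "")
  }

  if (file.exists(f("age_trend.tsv"))) {
    tr <- readr::read_tsv(f("age_trend.tsv"), show_col_types = FALSE)
    lines <- c(lines, "## Age trend of grip strength (quadratic fit by sex)",
               "", md_table(tr), "")
  }

  lines <- c(lines, "## Top miRNA associations with grip strength", "")
  if (file.exists(f("associations.tsv"))) {
    as_tab <- readr::read_tsv(f("associations.tsv"), show_col_types = FALSE)
    elig <- as_tab[!is.na(as_tab$q), ]
    if (nrow(elig) == 0) {
      lines <- c(lines, "no eligible miRNAs", "")
    } else {
      top <- elig |> arrange(.data$q, .data$adaptive_p, .data$mirna) |>
        head(k_top) |>
        select("mirna", n = "n_assayed", "branch", "beta_cont", "se_cont",
               "p_cont", "beta_bin", "se_bin", "p_bin", "adaptive_p", "q")
      lines <- c(lines, md_table(top), "")
    }
    if (file.exists(f("fdr_summary.tsv"))) {
      fs <- readr::read_tsv(f("fdr_summary.tsv"), show_col_types = FALSE)
      sent <- sprintf("%d (%d%%) had FDR q value < %s", fs$count,
                      round(fs$percent), format(fs$threshold))
      lines <- c(lines,
                 sprintf("Among %d miRNAs interrogated: %s.", nrow(elig),
                         paste(sent, collapse = ", ")), "")
    }
  } else {
    lines <- c(lines, "_associations.tsv missing; section omitted_", "")
  }

  lines <- c(lines, "## Gene-set enrichment of coexpressed genes", "")
  if (file.exists(f("enrichment.tsv"))) {
    en <- readr::read_tsv(f("enrichment.tsv"), show_col_types = FALSE)
    lines <- c(lines, md_table(head(en, 10)), "")
  } else {
    lines <- c(lines, "_enrichment.tsv missing; section omitted_", "")
  }

  writeLines(lines, f("report.md"))
  invisible(lines)
}
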