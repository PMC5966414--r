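## End-to-end orchestration: tile -> call -> permute -> annotate ->
## associate, with a machine-readable run manifest.

#' Aggregate per-sample calls into a tile matrix
#'
#' Convenience wrapper: strand-merges each sample's calls, tiles them and
#' assembles the cross-sample matrix.
#'
#' @param calls Named list (by sample_id) of CpG call tables.
#' @param sheet Sample sheet.
#' @param params A [tiling_params()].
#' @return A \code{tile_matrix}.
#' @export
tile_samples <- function(calls, sheet, params = tiling_params()) {
  per_sample <- lapply(calls, function(x)
    aggregate_tiles(merge_strands(x), params))
  build_matrix(per_sample, sheet)
}

#' Pipeline configuration
#'
#' @param sample_sheet Path to the sample sheet TSV (must carry a
#'   \code{path} column of per-sample CpG call files).
#' @param gene_models Path to gene models.
#' @param gene_dialect \code{"bed12"} or \code{"gtf"}.
#' @param expression Optional path to a genes x samples expression TSV.
#' @param chrom_sizes Optional path to a chromosome-sizes TSV
#'   (\code{chrom}, \code{length}); required for the association stage.
#' @param call_dialect CpG call file dialect.
#' @param out_dir Output directory.
#' @param target_tissue Target tissue.
#' @param newborn_age,adult_age Newborn and adult ages in weeks.
#' @param tiling A [tiling_params()].
#' @param dmr A [dmr_params()].
#' @param direction DMR direction for the main call set.
#' @param n_perm Permutations for the significance test.
#' @param min_fold,de_alpha Upregulation rule for the association stage.
#' @param bg_multiplier Background segments per DMR.
#' @param seed Global seed propagated to all stochastic stages.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(sample_sheet, gene_models = NULL,
                            gene_dialect = c("bed12", "gtf"),
                            expression = NULL, chrom_sizes = NULL,
                            call_dialect = c("bismark_cov", "methratio"),
                            out_dir = "postdmr_out",
                            target_tissue = "hepatocyte",
                            newborn_age = 1, adult_age = 15,
                            tiling = tiling_params(), dmr = dmr_params(),
                            direction = c("hypo", "denovo"),
                            n_perm = 10000L, min_fold = 1.5,
                            de_alpha = 0.05, bg_multiplier = 1L,
                            seed = 1L) {
  structure(list(sample_sheet = sample_sheet, gene_models = gene_models,
                 gene_dialect = match.arg(gene_dialect),
                 expression = expression, chrom_sizes = chrom_sizes,
                 call_dialect = match.arg(call_dialect), out_dir = out_dir,
                 target_tissue = target_tissue, newborn_age = newborn_age,
                 adult_age = adult_age, tiling = tiling, dmr = dmr,
                 direction = match.arg(direction),
                 n_perm = as.integer(n_perm), min_fold = min_fold,
                 de_alpha = de_alpha, bg_multiplier = as.integer(bg_multiplier),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; nested
#' \code{tiling:} and \code{dmr:} blocks onto [tiling_params()] and
#' [dmr_params()].
#'
#' @param path YAML file.
#' @param overrides Named list of values taking precedence over the file.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  tl <- do.call(tiling_params, y$tiling %||% list())
  dm <- do.call(dmr_params, y$dmr %||% list())
  y$tiling <- NULL; y$dmr <- NULL
  do.call(pipeline_config, c(y, list(tiling = tl, dmr = dm)))
}

#' Run the DMR pipeline
#'
#' Stages, in order: \code{tile} (read calls, build the matrix),
#' \code{call} (tissue-specific + postnatal DMRs), \code{permtest},
#' \code{annotate}, \code{associate}. \code{stages} selects a prefix of
#' that order. Every stage writes its output under \code{out_dir}; a JSON
#' manifest records package version, parameters, seed, input checksums and
#' completed stages. A rerun with the same inputs, parameters and seed is
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param stages Last stage to run (all by default).
#' @return Result bundle: \code{tile_matrix}, \code{dmrs}, \code{perm},
#'   \code{annotated}, \code{association}, \code{manifest} (elements are
#'   NULL for stages not run), invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("associate", "annotate", "permtest",
                                    "call", "tile")) {
  stopifnot(inherits(config, "pipeline_config"))
  last <- match.arg(stages)
  order <- c("tile", "call", "permtest", "annotate", "associate")
  todo <- order[seq_len(match(last, order))]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(tile_matrix = NULL, dmrs = NULL, perm = NULL,
              annotated = NULL, association = NULL)
  done <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  inputs <- c(config$sample_sheet, config$gene_models, config$expression,
              config$chrom_sizes)

  ## tile
  res$tile_matrix <- stage("tile", {
    sheet <- read_sample_sheet(config$sample_sheet)
    .assert("path" %in% names(sheet),
            "sample sheet needs a 'path' column for pipeline runs")
    base <- dirname(config$sample_sheet)
    files <- ifelse(file.exists(sheet$path), sheet$path,
                    file.path(base, sheet$path))
    calls <- setNames(
      lapply(files, read_cpg_calls, dialect = config$call_dialect),
      sheet$sample_id)
    inputs <- c(inputs, files)
    tm <- tile_samples(calls, sheet[, .(sample_id, tissue, age_weeks,
                                        genotype, replicate)],
                       config$tiling)
    write_tile_matrix(tm, file.path(config$out_dir, "tiles"))
    tm
  })
  done <- c(done, "tile")

  if ("call" %in% todo) {
    res$dmrs <- stage("call", {
      means <- tissue_means(res$tile_matrix, age_filter = config$adult_age)
      spec <- call_tissue_specific(means, config$target_tissue,
                                   config$direction, config$dmr)
      dmrs <- call_postnatal(res$tile_matrix, spec, config$target_tissue,
                             config$newborn_age, config$adult_age,
                             config$dmr)
      write_dmr_bed(dmrs, file.path(config$out_dir, "dmrs.bed"))
      dmr_audit_table(dmrs, file.path(config$out_dir, "dmr_audit.tsv"))
      dmrs
    })
    done <- c(done, "call")
  }

  if ("permtest" %in% todo) {
    res$perm <- stage("permtest", {
      pr <- permutation_test(res$tile_matrix, config$target_tissue,
                             config$dmr, n_perm = config$n_perm,
                             seed = .derive_seed(config$seed, 11L),
                             age_filter = config$adult_age,
                             direction = config$direction)
      write_permutation_report(pr, file.path(config$out_dir,
                                             "permutation.tsv"))
      pr
    })
    done <- c(done, "permtest")
  }

  genes <- NULL
  if (any(c("annotate", "associate") %in% todo)) {
    .assert(!is.null(config$gene_models),
            "gene_models path required for annotation/association")
    genes <- read_gene_models(config$gene_models, config$gene_dialect)
  }

  if ("annotate" %in% todo) {
    res$annotated <- stage("annotate", {
      annotate_dmrs(res$dmrs, genes,
                    path = file.path(config$out_dir, "dmrs_annotated.tsv"))
    })
    done <- c(done, "annotate")
  }

  if ("associate" %in% todo) {
    res$association <- stage("associate", {
      .assert(!is.null(config$expression) && !is.null(config$chrom_sizes),
              "expression and chrom_sizes paths required for association")
      sheet <- read_sample_sheet(config$sample_sheet)
      expr <- read_expression(config$expression, sheet)
      up <- upregulated_genes(expr, config$newborn_age, config$adult_age,
                              config$min_fold, config$de_alpha)
      cs <- data.table::fread(config$chrom_sizes)
      sizes <- setNames(as.numeric(cs[[2]]), as.character(cs[[1]]))
      assoc <- dmr_gene_enrichment(res$dmrs, genes, up, sizes,
                                   bg_multiplier = config$bg_multiplier,
                                   seed = .derive_seed(config$seed, 12L))
      write_association_report(assoc, file.path(config$out_dir,
                                                "association.tsv"))
      assoc
    })
    done <- c(done, "associate")
  }

  manifest <- list(
    package = "postdmr",
    version = as.character(utils::packageVersion("postdmr")),
    seed = config$seed,
    parameters = list(
      target_tissue = config$target_tissue,
      newborn_age = config$newborn_age, adult_age = config$adult_age,
      direction = config$direction, n_perm = config$n_perm,
      tiling = unclass(config$tiling), dmr = unclass(config$dmr)),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    stages_completed = done)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
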